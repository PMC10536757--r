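# Internal helpers shared across modules.

#' Run code with a locally seeded RNG
#'
#' Evaluates `expr` with the RNG seeded to `seed` and restores the caller's
#' RNG state afterwards, so library code never disturbs the user's stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a stage-specific sub-seed from a master seed; kept below 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1000003 + h) %% 2147483647L)
}

# Euclidean length of a polyline given as an n x 2 matrix.
polyline_length <- function(xy) {
  if (nrow(xy) < 2) return(0)
  sum(sqrt(rowSums((xy[-1, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE])^2)))
}

# Cumulative vertex distances along a polyline (first entry 0).
polyline_cumdist <- function(xy) {
  if (nrow(xy) < 2) return(0)
  c(0, cumsum(sqrt(rowSums((xy[-1, , drop = FALSE] -
                              xy[-nrow(xy), , drop = FALSE])^2))))
}

# Point at arc-length offset s along a polyline; s clamped to [0, L].
polyline_interpolate <- function(xy, s) {
  cd <- polyline_cumdist(xy)
  L <- cd[length(cd)]
  s <- min(max(s, 0), L)
  i <- findInterval(s, cd, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(xy) - 1L)
  seg_len <- cd[i + 1] - cd[i]
  t <- if (seg_len > 0) (s - cd[i]) / seg_len else 0
  xy[i, ] + t * (xy[i + 1, ] - xy[i, ])
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
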