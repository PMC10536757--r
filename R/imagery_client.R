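# Thin, swappable image-source layer. The default source reads images from a
# fixture directory laid out as <root>/<point_id>_<heading>.png; a documented
# client stub shows the adapter shape for a real static street-imagery API
# (paid and rate-limited, so it is opt-in and never exercised by tests).
# Fetches are cached and idempotent; a missing image is a status, not an
# error, and feeds mark_missing().

#' Configure an image source
#'
#' @param mode `"fixtures"` (default) or `"api"`.
#' @param root fixture directory (fixtures mode).
#' @param endpoint API base URL (api mode).
#' @param api_key API key (required in api mode).
#' @param cache_dir optional cache directory mirroring the fixture layout.
#' @return An `image_source` object with an internal remote-call counter.
#' @export
image_source <- function(mode = c("fixtures", "api"), root = NULL,
                         endpoint = NULL, api_key = NULL, cache_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixtures") {
    if (is.null(root) || !dir.exists(root))
      stopf("fixtures mode requires an existing root directory")
  } else {
    if (is.null(api_key) || !nzchar(api_key))
      stopf("api mode requires an api_key")
    if (is.null(endpoint)) stopf("api mode requires an endpoint")
  }
  state <- new.env(parent = emptyenv())
  state$remote_calls <- 0L
  structure(list(mode = mode, root = root, endpoint = endpoint,
                 api_key = api_key, cache_dir = cache_dir, state = state),
            class = "image_source")
}

request_filename <- function(point_id, heading_deg) {
  sprintf("%s_%d.png", point_id, heading_deg)
}

#' Fetch one image
#'
#' @param request one-row data.frame (or list) with `point_id`,
#'   `heading_deg`.
#' @param source an [image_source].
#' @return List `status` (`"fetched"`/`"missing"`) and `bytes` (raw vector or
#'   `NULL`).
#' @export
fetch_image <- function(request, source) {
  fn <- request_filename(request$point_id, request$heading_deg)
  if (!is.null(source$cache_dir)) {
    cached <- file.path(source$cache_dir, fn)
    if (file.exists(cached))
      return(list(status = "fetched",
                  bytes = readBin(cached, "raw", file.size(cached))))
  }
  if (source$mode == "fixtures") {
    path <- file.path(source$root, fn)
    source$state$remote_calls <- source$state$remote_calls + 1L
    if (!file.exists(path)) return(list(status = "missing", bytes = NULL))
    bytes <- readBin(path, "raw", file.size(path))
  } else {
    # Adapter shape for a real static street-imagery API: one GET per
    # (lat, lon, heading). Deliberately not implemented here; tests and the
    # synthetic pipeline never perform remote access.
    stopf("api mode is a documented stub; no remote access is performed (request %s/%s)",
          request$point_id, request$heading_deg)
  }
  if (!is.null(source$cache_dir)) {
    dir.create(source$cache_dir, recursive = TRUE, showWarnings = FALSE)
    writeBin(bytes, file.path(source$cache_dir, fn))
  }
  list(status = "fetched", bytes = bytes)
}

#' Fetch all requests and record statuses
#'
#' @param requests data.frame from [make_requests].
#' @param source an [image_source].
#' @return `requests` with `status` updated to `fetched`/`missing`.
#' @export
fetch_images <- function(requests, source) {
  requests$status <- vapply(seq_len(nrow(requests)), function(i)
    fetch_image(requests[i, ], source)$status, "")
  requests
}

#' Number of remote (non-cache) fetches performed by a source
#' @param source an [image_source].
#' @return Integer count.
#' @export
remote_call_count <- function(source) source$state$remote_calls
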