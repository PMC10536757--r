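# Per-pixel labelling backend contract, mask summarization into class pixel
# fractions, and the class-collapsing taxonomy (bicycle + rider -> cyclist;
# road + car + truck + motorcycle -> vehicle).
#
# Features are expressed as fractions of image area rather than absolute
# pixel counts so that image resolution is irrelevant and measures transfer
# across image sizes.

#' The 19-class street-scene label palette
#'
#' Class names in trainId order (0-18) of the standard street-scene
#' segmentation palette; pixel value 255 denotes void/unlabelled.
#' @export
sv_classes <- function() {
  c("road", "sidewalk", "building", "wall", "fence", "pole",
    "traffic_light", "traffic_sign", "vegetation", "terrain", "sky",
    "person", "rider", "car", "truck", "bus", "train", "motorcycle",
    "bicycle")
}

#' Collapsed class names added on top of the raw palette
#' @export
sv_collapsed_classes <- function() c("cyclist", "vehicle")

# Which pixel classes feed which prediction target.
sv_feature_sets <- function() {
  list(trees = "vegetation",
       sidewalk_length = "sidewalk",
       pedestrians = "person",
       bicycles = "cyclist",
       vehicles = c("road", "car", "truck", "person"),
       traffic_lights = c("pole", "traffic_light", "traffic_sign"),
       traffic_signs = c("pole", "traffic_light", "traffic_sign"))
}

sv_void <- 255L

#' Run a segmentation backend over an image
#'
#' The backend is a pluggable contract: any function taking the image and
#' returning an integer matrix of the same dimensions with values in 0-18 or
#' 255 (void). A deterministic synthetic segmenter ships with the package;
#' adapters for real convolutional models satisfy the same contract.
#'
#' @param image a numeric matrix/array (any representation the backend
#'   understands); its spatial dimensions are `dim(image)[1:2]`.
#' @param backend function(image) -> integer label matrix.
#' @return Integer label matrix (class `segmentation_mask`).
#' @export
segment_image <- function(image, backend) {
  if (!is.function(backend)) stopf("backend must be a function(image) -> label matrix")
  mask <- backend(image)
  if (!is.matrix(mask)) stopf("backend contract violated: result is not a matrix")
  want <- dim(image)[1:2]
  if (!all(dim(mask) == want))
    stopf("backend contract violated: mask is %dx%d but image is %dx%d",
          nrow(mask), ncol(mask), want[1], want[2])
  v <- as.integer(mask)
  if (any(is.na(v)) || any(v != mask) || any(v < 0 | (v > 18 & v != sv_void)))
    stopf("backend contract violated: labels must be integers in 0-18 or 255")
  storage.mode(mask) <- "integer"
  class(mask) <- c("segmentation_mask", class(mask))
  mask
}

#' Summarize a label mask into per-class pixel fractions
#'
#' @param mask integer matrix of labels in 0-18 or 255 (void).
#' @return Named list with one fraction per raw class plus `void_fraction`;
#'   the 19 class fractions and the void fraction sum to 1.
#' @export
summarize_mask <- function(mask) {
  if (length(mask) == 0) stopf("cannot summarize a zero-area mask")
  v <- as.integer(mask)
  if (any(is.na(v)) || any(v < 0 | (v > 18 & v != sv_void)))
    stopf("mask contains labels outside 0-18/255")
  counts <- tabulate(v + 1L, nbins = 19L)
  total <- length(v)
  out <- as.list(counts / total)
  names(out) <- sv_classes()
  out$void_fraction <- sum(v == sv_void) / total
  out
}

#' Collapse raw class fractions into the modelling taxonomy
#'
#' Adds `cyclist` (= bicycle + rider) and `vehicle` (= road + car + truck +
#' motorcycle). `bus` is retained but flagged as excluded from modelling;
#' `terrain` and `sky` are flagged unused. `pole` is retained because it
#' feeds the sign/light models.
#'
#' @param summary named list or one-row data.frame of raw class fractions.
#' @return The input plus `cyclist` and `vehicle` entries, with attributes
#'   `excluded_from_modeling` and `unused`.
#' @export
collapse_classes <- function(summary) {
  s <- as.list(summary)
  miss <- setdiff(sv_classes(), names(s))
  if (length(miss)) stopf("summary missing class fraction(s): %s",
                          paste(miss, collapse = ", "))
  s$cyclist <- s$bicycle + s$rider
  s$vehicle <- s$road + s$car + s$truck + s$motorcycle
  attr(s, "excluded_from_modeling") <- "bus"
  attr(s, "unused") <- c("terrain", "sky")
  s
}

# Add cyclist/vehicle columns to a summaries data.frame.
collapse_summary_frame <- function(summaries) {
  summaries$cyclist <- summaries$bicycle + summaries$rider
  summaries$vehicle <- summaries$road + summaries$car +
    summaries$truck + summaries$motorcycle
  summaries
}

#' Read a label mask from a single-channel PNG
#'
#' Pixel value = class index 0-18, 255 = void.
#' @param path PNG file.
#' @return Integer label matrix.
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  mask <- round(img * 255)
  storage.mode(mask) <- "integer"
  bad <- mask < 0 | (mask > 18 & mask != sv_void)
  if (any(bad)) stopf("'%s' contains pixel values outside the label palette", path)
  mask
}

#' Write a label mask to a single-channel PNG
#' @param mask integer label matrix.
#' @param path output file.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Summarize a directory of mask PNGs into a summaries table
#'
#' Masks are named `<point_id>_<heading>.png`.
#' @param dir directory of mask PNGs.
#' @return data.frame with `point_id`, `heading_deg`, the 19 raw class
#'   fraction columns, `void_fraction`, and collapsed columns.
#' @export
summarize_mask_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stopf("no mask PNGs found in '%s'", dir)
  rows <- lapply(files, function(f) {
    base <- sub("\\.png$", "", basename(f))
    m <- regmatches(base, regexec("^(.*)_([0-9]+)$", base))[[1]]
    if (length(m) != 3) stopf("mask filename '%s' is not <point_id>_<heading>.png",
                              basename(f))
    s <- summarize_mask(read_mask(f))
    cbind(data.frame(point_id = m[2], heading_deg = as.integer(m[3]),
                     stringsAsFactors = FALSE),
          as.data.frame(s))
  })
  collapse_summary_frame(do.call(rbind, rows))
}
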