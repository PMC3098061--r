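#' Grayscale image container
#'
#' A 2-D field of non-negative real intensities in arbitrary linear units,
#' the common input to every detector.  Coordinates are (row, col), 0-based,
#' with pixel centers at integers.
#'
#' @param pixels numeric matrix of finite, non-negative intensities.
#' @param bit_origin provenance of the data: `"8"`, `"16"` or `"float"`.
#' @return An object of class `gray_image` with fields `pixels`, `height`,
#'   `width`, `bit_origin`.
#' @export
gray_image <- function(pixels, bit_origin = "float") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  storage.mode(pixels) <- "double"
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("image intensities must be finite")
  if (any(pixels < 0))
    stop("image intensities must be >= 0")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have height >= 1 and width >= 1")
  bit_origin <- match.arg(as.character(bit_origin), c("8", "16", "float"))
  structure(list(pixels = pixels, height = nrow(pixels),
                 width = ncol(pixels), bit_origin = bit_origin),
            class = "gray_image")
}

#' Coerce to a gray_image
#' @param x matrix or `gray_image`.
#' @param ... passed to [gray_image()].
#' @return a `gray_image`.
#' @export
as_gray_image <- function(x, ...) {
  if (inherits(x, "gray_image")) return(x)
  gray_image(x, ...)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, origin %s-bit, range [%.4g, %.4g]>\n",
              x$height, x$width, x$bit_origin,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Binary detection/reference mask
#'
#' @param pixels matrix coercible to 0/1; same shape as its source image.
#' @return object of class `binary_mask` with integer 0/1 field `pixels`.
#' @export
binary_mask <- function(pixels) {
  if (is.logical(pixels)) pixels <- pixels + 0L
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (!all(pixels %in% c(0, 1))) stop("mask values must be 0 or 1")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d, %d foreground px>\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

#' Sub-pixel point list
#'
#' @param points data.frame (or 2-col matrix) with columns `row`, `col` in
#'   0-based pixel coordinates.
#' @return object of class `point_list` with fields `points` and `count`.
#' @export
point_list <- function(points = data.frame(row = numeric(0), col = numeric(0))) {
  if (is.matrix(points)) points <- data.frame(row = points[, 1], col = points[, 2])
  stopifnot(is.data.frame(points), all(c("row", "col") %in% names(points)))
  points <- points[, c("row", "col"), drop = FALSE]
  rownames(points) <- NULL
  structure(list(points = points, count = nrow(points)), class = "point_list")
}

#' @export
print.point_list <- function(x, ...) {
  cat(sprintf("<point_list of %d points>\n", x$count))
  if (x$count > 0) print(utils::head(x$points, 5))
  invisible(x)
}

#' Detection result
#'
#' Common output of all detectors: a binary mask and/or a sub-pixel point
#' list.  FPD and SPL emit points only; all mask-based methods emit a mask
#' (centroids derivable).  SE additionally carries a deblended label matrix.
#'
#' @param method_id one of BPF, FPD, HD, KDE, LC, LEF, MGI, MW, SE, SPL, THE.
#' @param mask optional [binary_mask()].
#' @param points optional [point_list()].
#' @param params named list of the parameters used.
#' @param labels optional integer matrix of deblended object labels.
#' @return object of class `detection_result`.
#' @export
detection_result <- function(method_id, mask = NULL, points = NULL,
                             params = list(), labels = NULL) {
  method_id <- match.arg(method_id, .method_ids)
  if (is.null(mask) && is.null(points))
    stop("a detection result needs a mask or a point list")
  if (method_id %in% c("FPD", "SPL") && !is.null(mask))
    stop(method_id, " reports point locations only, not a segmentation mask")
  structure(list(mask = mask, points = points, method_id = method_id,
                 params = params, labels = labels),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result %s: %d objects>\n",
              x$method_id, count_objects(x)))
  invisible(x)
}

# centroids (row, col) of 8-connected components of a mask, 0-based
mask_centroids <- function(mask) {
  px <- if (inherits(mask, "binary_mask")) mask$pixels else mask
  lab <- label_components_cpp(px, 8L)
  n <- max(lab)
  if (n == 0L)
    return(data.frame(row = numeric(0), col = numeric(0)))
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  data.frame(row = as.numeric(tapply(idx[, 1] - 1, l, mean)),
             col = as.numeric(tapply(idx[, 2] - 1, l, mean)))
}
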