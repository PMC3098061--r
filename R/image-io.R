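#' RGB to grayscale conversion
#'
#' Standard luma weighting 0.2989 R + 0.5870 G + 0.1140 B, coefficients used
#' exactly as printed (they sum to 0.9999; no renormalization).
#'
#' @param r,g,b equal-shape non-negative numeric matrices.
#' @return a [gray_image()].
#' @export
rgb_to_gray <- function(r, g, b) {
  dims <- list(dim(r), dim(g), dim(b))
  if (!identical(dims[[1]], dims[[2]]) || !identical(dims[[1]], dims[[3]]))
    stop(sprintf(
      "channel shape mismatch: R %s, G %s, B %s",
      paste(dim(r), collapse = "x"), paste(dim(g), collapse = "x"),
      paste(dim(b), collapse = "x")))
  gray_image(0.2989 * r + 0.5870 * g + 0.1140 * b)
}

## ---- minimal baseline TIFF (uncompressed, single page) ----------------
## No TIFF library ships with the target R environment, so 8/16-bit
## grayscale and 8-bit RGB, uncompressed, are handled directly.

tiff_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  endian <- if (identical(magic, charToRaw("II"))) "little"
            else if (identical(magic, charToRaw("MM"))) "big"
            else stop("not a TIFF file: ", path)
  ver <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
  if (ver != 42L) stop("corrupt TIFF header in ", path)
  ifd_off <- readBin(con, "integer", 1, 4, endian = endian)
  seek(con, ifd_off)
  n_entries <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
  tags <- list()
  for (k in seq_len(n_entries)) {
    tag <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
    typ <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
    cnt <- readBin(con, "integer", 1, 4, endian = endian)
    here <- seek(con)
    size <- c(1, 1, 2, 4, 8)[typ]
    if (is.na(size)) { seek(con, here + 4); next }
    vals <- if (size * cnt <= 4) {
      v <- switch(typ,
        readBin(con, "integer", cnt, 1, signed = FALSE),
        readBin(con, "integer", cnt, 1, signed = FALSE),
        readBin(con, "integer", cnt, 2, signed = FALSE, endian = endian),
        readBin(con, "integer", cnt, 4, endian = endian))
      v
    } else {
      off <- readBin(con, "integer", 1, 4, endian = endian)
      seek(con, off)
      v <- switch(typ,
        readBin(con, "integer", cnt, 1, signed = FALSE),
        readBin(con, "integer", cnt, 1, signed = FALSE),
        readBin(con, "integer", cnt, 2, signed = FALSE, endian = endian),
        readBin(con, "integer", cnt, 4, endian = endian),
        { a <- readBin(con, "integer", 2 * cnt, 4, endian = endian)
          a[seq(1, 2 * cnt, 2)] / a[seq(2, 2 * cnt, 2)] })
      v
    }
    tags[[as.character(tag)]] <- vals
    seek(con, here + 4)
  }
  need <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF tag ", id, " missing in ", path)
      default
    } else v
  }
  width  <- need(256); height <- need(257)
  bits   <- need(258, 1L); comp <- need(259, 1L)
  offs   <- need(273); spp <- need(277, 1L)
  rps    <- need(278, height); counts <- need(279)
  if (comp != 1L) stop("unsupported TIFF compression (", comp, ") in ", path)
  if (!all(bits %in% c(8L, 16L)))
    stop("unsupported TIFF bit depth in ", path)
  bits <- bits[1]
  raw_all <- raw(0)
  for (k in seq_along(offs)) {
    seek(con, offs[k])
    raw_all <- c(raw_all, readBin(con, "raw", counts[k]))
  }
  vals <- if (bits == 8L) as.integer(raw_all)
          else readBin(raw_all, "integer", length(raw_all) / 2, 2,
                       signed = FALSE, endian = endian)
  if (spp == 1L) {
    m <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
    list(gray = m, bits = bits, channels = NULL)
  } else if (spp == 3L) {
    a <- aperm(array(vals, dim = c(3, width, height)), c(3, 2, 1))
    list(gray = NULL, bits = bits,
         channels = list(r = a[, , 1], g = a[, , 2], b = a[, , 3]))
  } else stop("unsupported TIFF samples-per-pixel (", spp, ") in ", path)
}

tiff_write <- function(m, path, bits = 16L) {
  stopifnot(bits %in% c(8L, 16L))
  h <- nrow(m); w <- ncol(m)
  maxv <- if (bits == 8L) 255 else 65535
  m <- round(pmin(pmax(m, 0), maxv))
  con <- file(path, "wb")
  on.exit(close(con))
  data_off <- 8L
  nbytes <- h * w * (bits / 8L)
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, 2, endian = "little")
  writeBin(as.integer(data_off + nbytes), con, 4, endian = "little")
  vals <- as.integer(t(m))              # TIFF is row-major
  if (bits == 8L) writeBin(as.raw(vals), con)
  else writeBin(vals, con, 2, endian = "little")
  entry <- function(tag, typ, cnt, val) {
    writeBin(as.integer(tag), con, 2, endian = "little")
    writeBin(as.integer(typ), con, 2, endian = "little")
    writeBin(as.integer(cnt), con, 4, endian = "little")
    if (typ == 3L && cnt == 1L) {
      writeBin(as.integer(val), con, 2, endian = "little")
      writeBin(0L, con, 2, endian = "little")
    } else writeBin(as.integer(val), con, 4, endian = "little")
  }
  writeBin(8L, con, 2, endian = "little")      # 8 IFD entries
  entry(256, 4, 1, w); entry(257, 4, 1, h)
  entry(258, 3, 1, bits); entry(259, 3, 1, 1)
  entry(262, 3, 1, 1)                          # BlackIsZero
  entry(273, 4, 1, data_off); entry(278, 4, 1, h)
  entry(279, 4, 1, nbytes)
  writeBin(0L, con, 4, endian = "little")      # no next IFD
  invisible(path)
}

#' Load a grayscale image from TIFF or PNG
#'
#' 8/16-bit intensities are preserved exactly (no rescaling); RGB input is
#' converted with [rgb_to_gray()].  PNG files (read via the `png` package,
#' which returns values in \[0, 1\]) are scaled back to 0..255.
#'
#' @param path file path ending in .tif/.tiff or .png.
#' @return a [gray_image()].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tf <- tiff_read(path)
    if (!is.null(tf$gray))
      gray_image(tf$gray, bit_origin = as.character(tf$bits))
    else {
      g <- rgb_to_gray(tf$channels$r, tf$channels$g, tf$channels$b)
      g$bit_origin <- as.character(tf$bits)
      g
    }
  } else if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) {
      a <- a * 255
      rgb_to_gray(a[, , 1], a[, , 2], a[, , 3])
    } else gray_image(a * 255, bit_origin = "8")
  } else stop("unsupported image format: .", ext)
}

#' Save a grayscale image (16-bit TIFF)
#' @param img a [gray_image()] or matrix.
#' @param path output .tif path.
#' @param bits 8 or 16.
#' @export
save_image <- function(img, path, bits = 16L) {
  px <- if (inherits(img, "gray_image")) img$pixels else img
  tiff_write(px, path, bits = as.integer(bits))
}

#' Save / load a binary mask (PNG or TIFF)
#' @param mask a [binary_mask()] or 0/1 matrix.
#' @param path .png or .tif output path.
#' @export
save_mask <- function(mask, path) {
  px <- if (inherits(mask, "binary_mask")) mask$pixels else mask
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(px * 1.0, path)
  else if (ext %in% c("tif", "tiff")) tiff_write(px * 255, path, bits = 8L)
  else stop("unsupported mask format: .", ext)
  invisible(path)
}

#' @rdname save_mask
#' @export
load_mask <- function(path) {
  g <- load_image(path)
  binary_mask(g$pixels > 0.5 * max(g$pixels, 1))
}

#' Save / load a point list as CSV (header `row,col`)
#' @param points a [point_list()] or data.frame with `row`, `col`.
#' @param path .csv path.
#' @export
save_points <- function(points, path) {
  df <- if (inherits(points, "point_list")) points$points else points
  write.csv(df[, c("row", "col")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname save_points
#' @export
load_points <- function(path) {
  df <- read.csv(path)
  if (!all(c("row", "col") %in% names(df)))
    stop("point CSV must have a `row,col` header: ", path)
  point_list(df)
}

## ---- shared filtering utilities ---------------------------------------

# discrete Gaussian taps, radius ceil(4 sigma), normalised to unit sum
gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian low-pass prefilter
#'
#' Optional noise-suppression stage applied ahead of a detector; whether it
#' is used, and its sigma, is a per-method per-dataset choice (default off).
#' `sigma = 0` returns the input unchanged.  Borders are reflected.
#'
#' @param img a [gray_image()].
#' @param sigma Gaussian standard deviation in pixels, `>= 0`.
#' @return a [gray_image()].
#' @export
lowpass_prefilter <- function(img, sigma) {
  img <- as_gray_image(img)
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(img)
  out <- conv_sep_symm(img$pixels, gaussian_kernel_1d(sigma))
  gray_image(pmax(out, 0), bit_origin = img$bit_origin)
}

# Gaussian smoothing for plain matrices (internal)
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  conv_sep_symm(m, gaussian_kernel_1d(sigma))
}

# discrete Euclidean disc structuring element of given radius
disc_se <- function(radius) {
  r <- max(0L, as.integer(round(radius)))
  d <- 2L * r + 1L
  x <- matrix(rep(-r:r, d), d, d)
  (x^2 + t(x)^2) <= radius^2 + 1e-9
}

# grayscale opening with a flat disc of radius r
gray_open_disc <- function(m, radius) {
  se <- disc_se(radius)
  gray_dilate_cpp(gray_erode_cpp(m, se), se)
}
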