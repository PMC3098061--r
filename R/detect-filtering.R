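## Filtering/enhancement detectors that output a segmentation mask:
## BPF, KDE, LC, LEF, MW, SE, THE.  Each is deterministic given
## (image, params); every mask has the input's shape.

.empty_mask <- function(px) matrix(0L, nrow(px), ncol(px))

# Otsu with the degenerate-histogram rule: an (all-near-)constant
# enhancement residual maps to an empty mask, not an arbitrary split.
.otsu_mask <- function(m) {
  th <- tryCatch(otsu_threshold(m), error = function(e) NULL)
  if (is.null(th)) .empty_mask(m) else (m > th) + 0L
}

## ---- BPF ---------------------------------------------------------------

#' Band-pass filter detector parameters
#'
#' @param cutoffs four normalized frequencies (w1, w2, w3, w4) in \[0, 1\]
#'   (1 = Nyquist) with `w1 < w2 <= w3 < w4`; the pass band is
#'   \[w2, w3\] with transition bands outside.
#' @return object of class `bpf_params`.
#' @export
bpf_params <- function(cutoffs) {
  stopifnot(length(cutoffs) == 4, all(cutoffs >= 0), all(cutoffs <= 1))
  if (!(cutoffs[1] < cutoffs[2] && cutoffs[2] <= cutoffs[3] &&
        cutoffs[3] < cutoffs[4]))
    stop("cutoffs must satisfy w1 < w2 <= w3 < w4")
  structure(list(cutoffs = as.numeric(cutoffs)), class = "bpf_params")
}

# windowed-sinc (Hamming) FIR low-pass, fc in (0, 1] Nyquist units,
# n taps (odd), unit DC gain
.fir_lowpass <- function(fc, n) {
  m <- (n - 1) / 2
  x <- -m:m
  h <- fc * ifelse(x == 0, 1, sin(pi * fc * x) / (pi * fc * x))
  w <- 0.54 + 0.46 * cos(pi * x / m)     # Hamming
  h <- h * w
  h / sum(h)
}

#' Band-pass filtering detector (BPF)
#'
#' The image is filtered with a zero-phase FIR band-pass realized as the
#' difference of two separable windowed-sinc low-passes (cut-offs at the
#' transition-band midpoints), then binarized with Otsu's threshold.  DC is
#' rejected exactly (both low-passes have unit DC gain).  A residual whose
#' dynamic range falls below 1% of the input's is treated as signal-free
#' and yields an empty mask (degenerate-histogram rule).
#'
#' @param img a [gray_image()].
#' @param p a [bpf_params()].
#' @return a [detection_result()].
#' @export
detect_bpf <- function(img, p) {
  img <- as_gray_image(img)
  stopifnot(inherits(p, "bpf_params"))
  w <- p$cutoffs
  n <- round(4 / (w[2] - w[1]))
  if (n %% 2 == 0) n <- n + 1
  n <- max(n, 5)
  n <- min(n, 2L * min(img$height, img$width) - 1L)
  fc_lo <- (w[1] + w[2]) / 2
  fc_hi <- (w[3] + w[4]) / 2
  filt <- conv_sep_symm(img$pixels, .fir_lowpass(fc_hi, n)) -
          conv_sep_symm(img$pixels, .fir_lowpass(fc_lo, n))
  rng_in <- diff(range(img$pixels))
  # signal-present decision on the filter's fully-supported interior:
  # reflective padding leaves border transients that must not veto the
  # degenerate-residual rule
  m <- min((n - 1) %/% 2,
           (min(img$height, img$width) - 1) %/% 4)
  interior <- filt[(1 + m):(img$height - m), (1 + m):(img$width - m)]
  bw <- if (diff(range(interior)) < 0.01 * max(rng_in, .Machine$double.eps))
    .empty_mask(filt) else .otsu_mask(filt)
  detection_result("BPF", mask = binary_mask(bw),
                   params = list(cutoffs = w))
}

## ---- KDE ---------------------------------------------------------------

.kde_kernels <- c("uniform", "gaussian", "epanechnikov", "triangle",
                  "quartic", "triweight", "cosine")

#' Kernel density estimation detector parameters
#' @param R circular window radius in pixels (`>= 1`).
#' @param h smoothing parameter (`> 0`); kernel argument is distance / h.
#' @param kernel kernel family name.
#' @return object of class `kde_params`.
#' @export
kde_params <- function(R, h, kernel = "uniform") {
  stopifnot(R >= 1, h > 0)
  kernel <- match.arg(kernel, .kde_kernels)
  structure(list(R = as.integer(R), h = h, kernel = kernel),
            class = "kde_params")
}

#' Kernel density estimation detector (KDE / Parzen window)
#'
#' Each pixel is replaced by the kernel-weighted average of the pixels
#' within a circular window of radius R (normalized by the cardinality of
#' the in-bounds window set); the smoothed image is binarized with Otsu's
#' threshold.  The kernel family is rarely decisive.
#'
#' @param img a [gray_image()].
#' @param p a [kde_params()].
#' @return a [detection_result()].
#' @export
detect_kde <- function(img, p) {
  img <- as_gray_image(img)
  stopifnot(inherits(p, "kde_params"))
  if (p$R > min(img$height, img$width) / 2)
    stop("KDE radius R exceeds half the image size")
  sm <- kde_smooth_cpp(img$pixels, p$R, p$h,
                       match(p$kernel, .kde_kernels) - 1L)
  detection_result("KDE", mask = binary_mask(.otsu_mask(sm)),
                   params = unclass(p))
}

## ---- LC ----------------------------------------------------------------

#' Local comparison detector parameters
#' @param R circular filter radius in pixels (`>= 2`).
#' @param alpha scaling factor applied to the original pixel value in the
#'   comparison (tunes the segmentation threshold).
#' @return object of class `lc_params`.
#' @export
lc_params <- function(R, alpha) {
  if (R < 2) stop("LC radius R must be >= 2 (quadrants would be empty)")
  stopifnot(alpha > 0)
  structure(list(R = as.integer(R), alpha = alpha), class = "lc_params")
}

# the four quadrant mean filters (NE, SE, SW, NW) of a circular window;
# center excluded, each renormalized to unit sum.  Axis pixels go to the
# counter-clockwise quadrant.
lc_quadrant_filters <- function(R) {
  d <- 2L * R + 1L
  drow <- matrix(rep(-R:R, d), d, d)
  dcol <- t(drow)
  in_disc <- (drow^2 + dcol^2) <= R^2 + 1e-9
  in_disc[R + 1L, R + 1L] <- FALSE
  theta <- atan2(-drow, dcol)            # image rows grow downward
  q <- list(
    NE = theta >= 0 & theta < pi / 2,
    NW = theta >= pi / 2 & theta < pi,
    SW = theta >= pi | theta < -pi / 2,
    SE = theta >= -pi / 2 & theta < 0)
  lapply(q, function(sel) {
    k <- (in_disc & sel) + 0
    k / sum(k)
  })
}

#' Local comparison and selection detector (LC)
#'
#' A circular mean filter of radius R is split into four directional
#' quarters (NE, SE, SW, NW).  A pixel is marked as object iff
#' `alpha * f(i, j)` strictly exceeds the maximum of the four
#' direction-filtered values there, so object presence is decided on local
#' features and a non-uniform background is tolerated.
#'
#' @param img a [gray_image()].
#' @param p an [lc_params()].
#' @return a [detection_result()].
#' @export
detect_lc <- function(img, p) {
  img <- as_gray_image(img)
  stopifnot(inherits(p, "lc_params"))
  filts <- lc_quadrant_filters(p$R)
  mx <- Reduce(pmax, lapply(filts, function(k) conv2_symm(img$pixels, k)))
  bw <- (p$alpha * img$pixels > mx) + 0L
  detection_result("LC", mask = binary_mask(bw), params = unclass(p))
}

## ---- LEF ---------------------------------------------------------------

#' Local enhancement filtering detector parameters
#'
#' The kernel geometry is kept fixed by default to avoid extra tuning; the
#' sensitivity weight `th_s` is the single free parameter.
#'
#' @param th_s sensitivity weight for thresholding (`> 0`).
#' @param kernel_size odd square kernel side (default 9).
#' @param inner_radius radius of the inner circular area (default 2); the
#'   circle must lie strictly inside the square kernel.
#' @param target_mean image mean after intensity normalization (default 100).
#' @return object of class `lef_params`.
#' @export
lef_params <- function(th_s, kernel_size = 9L, inner_radius = 2L,
                       target_mean = 100) {
  stopifnot(th_s > 0, target_mean > 0)
  kernel_size <- as.integer(kernel_size)
  if (kernel_size %% 2 == 0) stop("kernel_size must be odd")
  if (2 * inner_radius + 1 >= kernel_size)
    stop("inner circle must lie strictly inside the square kernel")
  structure(list(th_s = th_s, kernel_size = kernel_size,
                 inner_radius = as.integer(inner_radius),
                 target_mean = target_mean), class = "lef_params")
}

#' Local spot enhancement filtering detector (LEF)
#'
#' Matched filtering for spot-like structures: the image mean is first
#' rescaled to `target_mean` (removing global intensity differences), then
#' a spot-likelihood image is formed as the ratio of the mean over an inner
#' circular area to the mean over the surrounding square-minus-circle area
#' (epsilon-guarded).  Pixels whose likelihood exceeds
#' `th_s * sd(likelihood)` are detected; if the likelihood is essentially
#' constant (sd below 1e-9) the mask is empty (threshold floor).
#'
#' @param img a [gray_image()].
#' @param p an [lef_params()].
#' @return a [detection_result()].
#' @export
detect_lef <- function(img, p) {
  img <- as_gray_image(img)
  stopifnot(inherits(p, "lef_params"))
  mu <- mean(img$pixels)
  if (mu <= 0)
    return(detection_result("LEF", mask = binary_mask(.empty_mask(img$pixels)),
                            params = unclass(p)))
  f <- img$pixels * (p$target_mean / mu)
  d <- p$kernel_size
  r <- (d - 1L) / 2L
  drow <- matrix(rep(-r:r, d), d, d)
  inner <- (drow^2 + t(drow)^2) <= p$inner_radius^2 + 1e-9
  outer <- !inner
  k_in <- inner / sum(inner)
  k_out <- outer / sum(outer)
  lik <- conv2_symm(f, k_in) / (conv2_symm(f, k_out) + 1e-6)
  s <- stats::sd(lik)
  bw <- if (s < 1e-9) .empty_mask(f) else (lik > p$th_s * s) + 0L
  detection_result("LEF", mask = binary_mask(bw), params = unclass(p))
}

## ---- MW ----------------------------------------------------------------

#' Multiscale wavelet product detector parameters
#' @param J number of scales (`>= 2`, at most 6 for images of 64 px or more).
#' @param l_d detection level applied to the multiscale product (`> 0`).
#' @return object of class `mw_params`.
#' @export
mw_params <- function(J, l_d) {
  stopifnot(J >= 2, l_d > 0)
  structure(list(J = as.integer(J), l_d = l_d), class = "mw_params")
}

# B3-spline kernel taps with 2^(i-1)-1 zeros inserted between them
.atrous_kernel <- function(scale) {
  base <- c(1, 4, 6, 4, 1) / 16
  gap <- 2^(scale - 1) - 1
  n <- 5L + 4L * gap
  k <- numeric(n)
  k[seq(1, n, by = gap + 1)] <- base
  k
}

#' A trous B3-spline wavelet decomposition
#'
#' Undecimated separable decomposition: `A_i` is obtained from `A_{i-1}`
#' with the \[1/16, 1/4, 3/8, 1/4, 1/16\] kernel dilated by inserted zeros,
#' and `W_i = A_{i-1} - A_i`.  The telescoping identity
#' `A_0 = A_J + sum(W_i)` holds exactly.
#'
#' @param img a [gray_image()] or matrix.
#' @param J number of scales.
#' @return list with `W` (list of wavelet planes) and `A` (final smooth).
#' @export
mw_decompose <- function(img, J) {
  A <- if (inherits(img, "gray_image")) img$pixels else img
  support <- 4 * 2^(J - 1) + 1
  if (min(dim(A)) < support)
    stop("image smaller than the dilated kernel support at scale J")
  W <- vector("list", J)
  for (i in seq_len(J)) {
    A_next <- conv_sep_symm(A, .atrous_kernel(i))
    W[[i]] <- A - A_next
    A <- A_next
  }
  list(W = W, A = A)
}

#' Multiscale product of wavelet coefficients detector (MW)
#'
#' Spots, unlike noise or large structures, persist across wavelet scales,
#' so they survive in the pixelwise product of the planes.  Each plane is
#' hard-thresholded at `3 * sigma_i` with `sigma_i = MAD(W_i) / 0.67`
#' before multiplication; the product is thresholded at the detection
#' level `l_d`.
#'
#' @param img a [gray_image()].
#' @param p an [mw_params()].
#' @return a [detection_result()].
#' @export
detect_mw <- function(img, p) {
  img <- as_gray_image(img)
  stopifnot(inherits(p, "mw_params"))
  dec <- mw_decompose(img, p$J)
  P <- 1
  for (W in dec$W) {
    sigma <- median(abs(W - median(W))) / 0.67
    Wt <- ifelse(W >= 3 * sigma, W, 0)
    P <- P * Wt
  }
  detection_result("MW", mask = binary_mask((P > p$l_d) + 0L),
                   params = unclass(p))
}

## ---- SE ----------------------------------------------------------------

#' SourceExtractor-style detector parameters
#' @param block_size background-estimation block side in pixels
#'   (`>= 8`, at most the smaller image dimension).
#' @param th_detect scaling of the standard deviation of
#'   background-subtracted intensities in the threshold (`> 0`).
#' @param th_bg scaling of the local background estimate in the threshold
#'   (`>= 0`); 0 recovers the original formulation.
#' @param gauss_sigma Gaussian filtering sigma after background removal.
#' @param deblend_nslices number of intensity slices for deblending
#'   (fixed default 30).
#' @param deblend_min_contrast minimum fraction of an object's integrated
#'   intensity a branch must carry to split off.
#' @return object of class `se_params`.
#' @export
se_params <- function(block_size, th_detect, th_bg = 0, gauss_sigma = 1,
                      deblend_nslices = 30L, deblend_min_contrast = 0.005) {
  stopifnot(block_size >= 8, th_detect > 0, th_bg >= 0, gauss_sigma > 0,
            deblend_nslices >= 1,
            deblend_min_contrast > 0, deblend_min_contrast < 1)
  structure(list(block_size = as.integer(block_size), th_detect = th_detect,
                 th_bg = th_bg, gauss_sigma = gauss_sigma,
                 deblend_nslices = as.integer(deblend_nslices),
                 deblend_min_contrast = deblend_min_contrast),
            class = "se_params")
}

# iterative sigma clipping of one block's intensities around the median
.clip_block <- function(x, max_iter = 50L) {
  s0 <- stats::sd(x)
  if (!is.finite(s0) || s0 == 0)
    return(list(bg = x[1], clipped = x))
  for (k in seq_len(max_iter)) {
    med <- median(x); s <- stats::sd(x)
    if (!is.finite(s) || s == 0) break
    keep <- x >= med - 3 * s & x <= med + 3 * s
    if (all(keep)) break
    x <- x[keep]
  }
  s_final <- stats::sd(x)
  if (!is.finite(s_final)) s_final <- 0
  bg <- if (abs(s_final - s0) / s0 < 0.2) mean(x)
        else 2.5 * median(x) - 1.5 * mean(x)
  list(bg = bg, clipped = x)
}

#' Blockwise background estimation by iterative sigma clipping
#'
#' Per block the intensity histogram is clipped at both ends until it
#' converges within three standard deviations around the median.  If the
#' standard deviation changed by less than 20% overall, the clipped mean is
#' the background; otherwise `BG = 2.5 * Median - 1.5 * Mean` of the
#' clipped set.  Blockwise values are bilinearly interpolated to pixel
#' resolution (clamped beyond the outermost block centers).
#'
#' @param img a [gray_image()].
#' @param block_size block side in pixels; partial edge blocks are allowed.
#' @return a [gray_image()] background estimate.
#' @export
se_estimate_background <- function(img, block_size) {
  img <- as_gray_image(img)
  f <- img$pixels
  h <- nrow(f); w <- ncol(f)
  rb <- unique(c(seq(1L, h, by = block_size), h + 1L))
  cb <- unique(c(seq(1L, w, by = block_size), w + 1L))
  nr <- length(rb) - 1L; nc <- length(cb) - 1L
  bg <- matrix(0, nr, nc)
  rc <- numeric(nr); cc <- numeric(nc)
  for (bi in seq_len(nr)) {
    rows <- rb[bi]:(rb[bi + 1L] - 1L)
    rc[bi] <- mean(rows) - 1
    for (bj in seq_len(nc)) {
      cols <- cb[bj]:(cb[bj + 1L] - 1L)
      if (bi == 1L) cc[bj] <- mean(cols) - 1
      bg[bi, bj] <- .clip_block(as.vector(f[rows, cols]))$bg
    }
  }
  gray_image(pmax(.bilinear_grid(bg, rc, cc, h, w), 0))
}

# bilinear interpolation of a coarse grid (centers rc x cc, 0-based) onto
# an h x w pixel grid, constant beyond the outer centers
.bilinear_grid <- function(vals, rc, cc, h, w) {
  interp1 <- function(centers, n) {
    pos <- 0:(n - 1)
    if (length(centers) == 1L)
      return(list(lo = rep(1L, n), hi = rep(1L, n), t = rep(0, n)))
    lo <- findInterval(pos, centers, all.inside = TRUE)
    hi <- lo + 1L
    t <- (pos - centers[lo]) / (centers[hi] - centers[lo])
    t <- pmin(pmax(t, 0), 1)
    list(lo = lo, hi = hi, t = t)
  }
  ri <- interp1(rc, h); ci <- interp1(cc, w)
  top <- vals[ri$lo, ci$lo, drop = FALSE] * (1 - ri$t) +
         vals[ri$hi, ci$lo, drop = FALSE] * ri$t
  bot <- vals[ri$lo, ci$hi, drop = FALSE] * (1 - ri$t) +
         vals[ri$hi, ci$hi, drop = FALSE] * ri$t
  top * rep(1 - ci$t, each = h) + bot * rep(ci$t, each = h)
}

# single-pass top-down deblending: split a connected component when, at
# some slice level, it separates into >= 2 sub-branches each carrying more
# than min_contrast of the object's integrated intensity.  Remaining object
# pixels join the nearest branch (by centroid distance).
.deblend <- function(filt, bw, nslices, min_contrast) {
  labs <- label_components_cpp(bw, 8L)
  n <- max(labs)
  out <- matrix(0L, nrow(bw), ncol(bw))
  next_id <- 0L
  for (obj in seq_len(n)) {
    sel <- labs == obj
    idx <- which(sel, arr.ind = TRUE)
    vals <- filt[sel]
    tmin <- min(vals); peak <- max(vals)
    total <- sum(vals - tmin)
    split_found <- FALSE
    if (peak > tmin && total > 0 && nslices > 1) {
      for (k in (nslices - 1L):1L) {
        lev <- tmin + k * (peak - tmin) / nslices
        sub <- matrix(0L, nrow(bw), ncol(bw))
        sub[sel][vals > lev] <- 1L
        sl <- label_components_cpp(sub, 8L)
        ns <- max(sl)
        if (ns < 2L) next
        ints <- vapply(seq_len(ns), function(s)
          sum(filt[sl == s] - tmin), numeric(1))
        strong <- which(ints > min_contrast * total)
        if (length(strong) >= 2L) {
          cents <- lapply(strong, function(s)
            colMeans(which(sl == s, arr.ind = TRUE)))
          branch_of <- integer(nrow(idx))
          for (q in seq_len(nrow(idx))) {
            sl_here <- sl[idx[q, 1], idx[q, 2]]
            if (sl_here %in% strong) {
              branch_of[q] <- match(sl_here, strong)
            } else {
              d2 <- vapply(cents, function(ce)
                sum((idx[q, ] - ce)^2), numeric(1))
              branch_of[q] <- which.min(d2)
            }
          }
          for (b in seq_along(strong)) {
            next_id <- next_id + 1L
            bi <- idx[branch_of == b, , drop = FALSE]
            out[bi] <- next_id
          }
          split_found <- TRUE
          break
        }
      }
    }
    if (!split_found) {
      next_id <- next_id + 1L
      out[idx] <- next_id
    }
  }
  out
}

#' SourceExtractor-style detector (SE)
#'
#' Estimates the background in blocks ([se_estimate_background()]), removes
#' it, Gaussian-filters the residual, and thresholds pixelwise at
#' `th_detect * sigma + th_bg * BG` where sigma is the standard deviation
#' of the background-subtracted intensities.  Merged detections are
#' deblended by the 30-slice branch scheme; the deblended labels accompany
#' the mask.
#'
#' @param img a [gray_image()].
#' @param p an [se_params()].
#' @return a [detection_result()] carrying `labels`.
#' @export
detect_se <- function(img, p) {
  img <- as_gray_image(img)
  stopifnot(inherits(p, "se_params"))
  if (p$block_size > min(img$height, img$width))
    stop("block_size exceeds the smaller image dimension")
  bg <- se_estimate_background(img, p$block_size)$pixels
  sub <- img$pixels - bg
  filt <- gauss_smooth(sub, p$gauss_sigma)
  sigma <- stats::sd(sub)
  bw <- (filt > p$th_detect * sigma + p$th_bg * bg) + 0L
  labels <- .deblend(filt, bw, p$deblend_nslices, p$deblend_min_contrast)
  detection_result("SE", mask = binary_mask(bw), params = unclass(p),
                   labels = labels)
}

## ---- THE ---------------------------------------------------------------

#' Top-hat detector parameters
#' @param r structuring-element disc radius in pixels (`>= 1`).
#' @return object of class `the_params`.
#' @export
the_params <- function(r) {
  stopifnot(r >= 1)
  structure(list(r = r), class = "the_params")
}

#' Top-hat filtering detector (THE)
#'
#' Grayscale opening with a flat disc of radius r acts as a local
#' background estimate; the residual `f - (f o E(r))` enhances structures
#' up to roughly that size and is binarized with Kapur's maximum-entropy
#' threshold (slightly more conservative than Otsu on spot images).  A
#' degenerate residual histogram yields an empty mask.
#'
#' @param img a [gray_image()].
#' @param p a [the_params()].
#' @return a [detection_result()].
#' @export
detect_the <- function(img, p) {
  img <- as_gray_image(img)
  stopifnot(inherits(p, "the_params"))
  fdiff <- img$pixels - gray_open_disc(img$pixels, p$r)
  th <- tryCatch(kapur_entropy_threshold(fdiff), error = function(e) NULL)
  bw <- if (is.null(th)) .empty_mask(fdiff) else (fdiff > th) + 0L
  detection_result("THE", mask = binary_mask(bw), params = unclass(p))
}
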