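## Point-output detectors: FPD and SPL report sub-pixel locations, never
## segmentation masks.

#' Feature point detection parameters
#' @param w kernel window half-size in pixels (`>= 1`).
#' @param r_pct percentile in (0, 100): the fraction of local-maximum
#'   candidates (by restored intensity) kept; lower is stricter.
#' @param T_s non-particle discrimination threshold: squared Mahalanobis
#'   distance cut in the (m0, m2) intensity-moment space.
#' @param lambda_n Gaussian kernel width (fixed 1 in the original method).
#' @return object of class `fpd_params`.
#' @export
fpd_params <- function(w, r_pct, T_s = Inf, lambda_n = 1) {
  stopifnot(w >= 1, r_pct > 0, r_pct < 100, T_s > 0, lambda_n > 0)
  structure(list(w = as.integer(w), r_pct = r_pct, T_s = T_s,
                 lambda_n = lambda_n), class = "fpd_params")
}

# restoration kernel: normalized Gaussian minus boxcar mean over the
# (2w+1)^2 window; zero-mean by construction
fpd_kernel <- function(w, lambda_n = 1) {
  d <- 2L * w + 1L
  i <- matrix(rep(-w:w, d), d, d)
  G <- exp(-(i^2 + t(i)^2) / (4 * lambda_n^2))
  G / sum(G) - 1 / d^2
}

# strict local maxima of m within a (2h+1)^2 window; 0-based coords
.strict_local_maxima <- function(m, h) {
  wm <- window_max_cpp(m, h)
  cand <- which(m == wm, arr.ind = TRUE)
  nr <- nrow(m); nc <- ncol(m)
  keep <- logical(nrow(cand))
  for (q in seq_len(nrow(cand))) {
    i <- cand[q, 1]; j <- cand[q, 2]
    rows <- max(1, i - h):min(nr, i + h)
    cols <- max(1, j - h):min(nc, j + h)
    win <- m[rows, cols]
    keep[q] <- sum(win == m[i, j]) == 1L
  }
  cand[keep, , drop = FALSE]
}

#' Feature point detection (FPD)
#'
#' Image restoration by convolution with a Gaussian-minus-boxcar kernel
#' (background suppression plus spot enhancement), local-maximum candidate
#' detection, retention of the `r_pct` highest percentile of candidates,
#' intensity-weighted centroid refinement, and non-particle discrimination
#' in the (m0, m2) moment space by a Mahalanobis-distance cut at `T_s`.
#'
#' @param img a [gray_image()].
#' @param p an [fpd_params()].
#' @return a [detection_result()] with points only.
#' @export
detect_fpd <- function(img, p) {
  img <- as_gray_image(img)
  stopifnot(inherits(p, "fpd_params"))
  restored <- conv2_symm(img$pixels, fpd_kernel(p$w, p$lambda_n))
  cand <- .strict_local_maxima(restored, p$w)
  if (nrow(cand) == 0L)
    return(detection_result("FPD", points = point_list(),
                            params = unclass(p)))
  vals <- restored[cand]
  keep_n <- ceiling(nrow(cand) * p$r_pct / 100)
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord[seq_len(keep_n)], , drop = FALSE]
  nr <- nrow(restored); nc <- ncol(restored)
  pts <- matrix(0, nrow(cand), 2)
  m0 <- numeric(nrow(cand)); m2 <- numeric(nrow(cand))
  for (q in seq_len(nrow(cand))) {
    i <- cand[q, 1]; j <- cand[q, 2]
    rows <- max(1, i - p$w):min(nr, i + p$w)
    cols <- max(1, j - p$w):min(nc, j + p$w)
    wts <- pmax(restored[rows, cols], 0)
    s <- sum(wts)
    if (s <= 0) { pts[q, ] <- c(i - 1, j - 1); next }
    ri <- matrix(rep(rows - 1, length(cols)), length(rows))
    ci <- t(matrix(rep(cols - 1, length(rows)), length(cols)))
    r0 <- sum(ri * wts) / s
    c0 <- sum(ci * wts) / s
    pts[q, ] <- c(r0, c0)
    m0[q] <- s
    m2[q] <- sum(((ri - r0)^2 + (ci - c0)^2) * wts) / s
  }
  if (is.finite(p$T_s) && nrow(pts) >= 3L) {
    X <- cbind(m0, m2)
    mu <- colMeans(X)
    S <- stats::cov(X) + diag(1e-12, 2)
    d2 <- stats::mahalanobis(X, mu, S)
    sel <- d2 <= p$T_s
    pts <- pts[sel, , drop = FALSE]
  }
  detection_result("FPD", points = point_list(pts), params = unclass(p))
}

#' Sub-pixel localization parameters
#' @param alpha limit for type I errors in the local-maxima test,
#'   in (0, 1); lower is stricter.
#' @param psf_sigma fixed Gaussian PSF sigma in pixels for the fit.
#' @param max_iter iteration cap for the Gaussian fit.
#' @param tol convergence tolerance on the center shift, pixels.
#' @return object of class `spl_params`.
#' @export
spl_params <- function(alpha, psf_sigma = 1.5, max_iter = 50L, tol = 0.01) {
  stopifnot(alpha > 0, alpha < 1, psf_sigma > 0, max_iter >= 1, tol > 0)
  structure(list(alpha = alpha, psf_sigma = psf_sigma,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "spl_params")
}

# Gauss-Newton fit of A exp(-d^2 / 2 sigma^2) + c on a window;
# sigma fixed, free amplitude/center/offset
.fit_gauss2d <- function(win, rows, cols, r0, c0, A0, off0, sigma,
                         max_iter, tol) {
  ri <- matrix(rep(rows, length(cols)), length(rows))
  ci <- t(matrix(rep(cols, length(rows)), length(cols)))
  y <- as.vector(win)
  th <- c(A0, r0, c0, off0)
  seed <- c(r0, c0)
  for (it in seq_len(max_iter)) {
    g <- exp(-((ri - th[2])^2 + (ci - th[3])^2) / (2 * sigma^2))
    pred <- th[1] * g + th[4]
    res <- y - as.vector(pred)
    J <- cbind(as.vector(g),
               as.vector(th[1] * g * (ri - th[2]) / sigma^2),
               as.vector(th[1] * g * (ci - th[3]) / sigma^2),
               1)
    delta <- tryCatch(
      solve(crossprod(J) + diag(1e-9, 4), crossprod(J, res)),
      error = function(e) NULL)
    if (is.null(delta)) return(list(center = seed, converged = FALSE))
    th_new <- th + as.vector(delta)
    move <- sqrt(sum((th_new[2:3] - th[2:3])^2))
    th <- th_new
    if (sqrt(sum((th[2:3] - seed)^2)) > 1.5)   # refinement must stay local
      return(list(center = seed, converged = FALSE))
    if (move < tol) return(list(center = th[2:3], converged = TRUE))
  }
  list(center = seed, converged = FALSE)
}

#' Sub-pixel location detection (SPL)
#'
#' Local maxima (strictly brighter than their 8 neighbors) are tested
#' against the local background: a candidate of height `f - bg_mean`
#' survives iff it exceeds the `(1 - alpha)` normal quantile times the
#' local background standard deviation (type-I-error control).  Survivors
#' are refined by iterative least-squares fitting of a 2-D Gaussian with
#' fixed `psf_sigma` and free amplitude/center/offset inside a
#' `(4 psf_sigma + 1)` window; the local background is the outer ring of
#' that window.  Non-convergent fits keep the integer-pixel location
#' (reported via a message).
#'
#' @param img a [gray_image()].
#' @param p an [spl_params()].
#' @return a [detection_result()] with points only.
#' @export
detect_spl <- function(img, p) {
  img <- as_gray_image(img)
  stopifnot(inherits(p, "spl_params"))
  f <- img$pixels
  nr <- nrow(f); nc <- ncol(f)
  hw <- max(2L, as.integer(ceiling(2 * p$psf_sigma)))
  cand <- .strict_local_maxima(f, 1L)
  if (nrow(cand) == 0L)
    return(detection_result("SPL", points = point_list(),
                            params = unclass(p)))
  # Sidak-corrected quantile: a candidate is the maximum of its 3x3
  # neighborhood, so the per-candidate type-I level alpha requires the
  # (1 - alpha)^(1/9) quantile of the background distribution
  q <- qnorm((1 - p$alpha)^(1 / 9))
  out <- list(); n_fail <- 0L
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    rows <- max(1, i - hw):min(nr, i + hw)
    cols <- max(1, j - hw):min(nc, j + hw)
    win <- f[rows, cols]
    ring <- win[row(win) == 1 | row(win) == nrow(win) |
                col(win) == 1 | col(win) == ncol(win)]
    bg_mean <- mean(ring)
    bg_sd <- stats::sd(ring)
    height <- f[i, j] - bg_mean
    if (!is.finite(bg_sd)) bg_sd <- 0
    if (height <= q * bg_sd) next
    fit <- .fit_gauss2d(win, rows - 1, cols - 1, i - 1, j - 1,
                        A0 = height, off0 = bg_mean, sigma = p$psf_sigma,
                        max_iter = p$max_iter, tol = p$tol)
    if (!fit$converged) n_fail <- n_fail + 1L
    ctr <- fit$center
    # refinement stays within 1 px of its seed maximum
    ctr <- pmin(pmax(ctr, c(i - 2, j - 2)), c(i, j))
    out[[length(out) + 1L]] <- ctr
  }
  if (n_fail > 0L)
    message("SPL: ", n_fail, " Gaussian fit(s) did not converge; ",
            "integer-pixel locations kept")
  pts <- if (length(out)) do.call(rbind, out) else
    matrix(numeric(0), 0, 2)
  detection_result("SPL", points = point_list(pts), params = unclass(p))
}
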