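## Histogram thresholding primitives shared by several detectors.
## Histograms are built on [min, max] of the image with nbins equal-width
## bins; candidate thresholds are the interior bin edges; criterion ties
## break toward the lowest threshold (more conservative foreground).

.hist_probs <- function(x, nbins) {
  mn <- min(x); mx <- max(x)
  if (!is.finite(mn) || mx - mn <= 0)
    stop("degenerate histogram: constant image")
  breaks <- seq(mn, mx, length.out = nbins + 1)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins)
  list(p = counts / length(x), breaks = breaks,
       mids = (breaks[-1] + breaks[-(nbins + 1)]) / 2)
}

#' Otsu's threshold
#'
#' Threshold maximizing the between-class variance over histogram bin
#' edges.  Deterministic; errors on a constant image ("degenerate
#' histogram") so that callers can decide the fallback.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param nbins number of equal-width histogram bins (default 256).
#' @return the threshold value (a bin edge).
#' @export
otsu_threshold <- function(img, nbins = 256L) {
  px <- if (inherits(img, "gray_image")) img$pixels else img
  stopifnot(nbins >= 2)
  h <- .hist_probs(as.vector(px), nbins)
  w0 <- cumsum(h$p)[-nbins]
  mu0 <- cumsum(h$p * h$mids)[-nbins]
  muT <- sum(h$p * h$mids)
  crit <- ifelse(w0 <= 0 | w0 >= 1, -Inf,
                 (muT * w0 - mu0)^2 / (w0 * (1 - w0)))
  h$breaks[which.max(crit) + 1L]
}

#' Kapur's maximum-entropy threshold
#'
#' Threshold maximizing the sum of foreground and background Shannon
#' entropies of the normalized histogram partitions; zero-probability bins
#' contribute zero entropy.
#'
#' @inheritParams otsu_threshold
#' @return the threshold value (a bin edge).
#' @export
kapur_entropy_threshold <- function(img, nbins = 256L) {
  px <- if (inherits(img, "gray_image")) img$pixels else img
  stopifnot(nbins >= 2)
  h <- .hist_probs(as.vector(px), nbins)
  p <- h$p
  plogp <- ifelse(p > 0, p * log(p), 0)
  P0 <- cumsum(p)[-nbins]
  S0 <- cumsum(plogp)[-nbins]
  ST <- sum(plogp)
  crit <- rep(-Inf, nbins - 1L)
  ok <- P0 > 0 & P0 < 1
  crit[ok] <- (log(P0[ok]) - S0[ok] / P0[ok]) +
              (log(1 - P0[ok]) - (ST - S0[ok]) / (1 - P0[ok]))
  h$breaks[which.max(crit) + 1L]
}

#' Two-cluster k-means binarization of intensities
#'
#' 1-D Lloyd's algorithm with deterministic farthest-point initialization
#' (centers at the image minimum and maximum), so downstream detectors are
#' reproducible.  The brighter cluster maps to 1.  A constant image yields
#' an all-zero mask (no structures).
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param max_iter iteration cap for Lloyd updates.
#' @return a [binary_mask()].
#' @export
kmeans2_binarize <- function(img, max_iter = 100L) {
  px <- if (inherits(img, "gray_image")) img$pixels else img
  x <- as.vector(px)
  if (max(x) - min(x) <= 0)
    return(binary_mask(matrix(0L, nrow(px), ncol(px))))
  cen <- c(min(x), max(x))
  for (it in seq_len(max_iter)) {
    cut <- mean(cen)
    hi <- x > cut
    new_cen <- c(mean(x[!hi]), mean(x[hi]))
    if (anyNA(new_cen)) break
    if (max(abs(new_cen - cen)) < 1e-12) { cen <- new_cen; break }
    cen <- new_cen
  }
  binary_mask(matrix((x > mean(cen)) + 0L, nrow(px), ncol(px)))
}
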