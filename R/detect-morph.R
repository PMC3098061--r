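## Morphology-driven detectors: h-dome reconstruction (HD) and
## granulometric morphometry (MGI).

#' h-dome transform
#'
#' `H = f - R(f; f - h)` where `R` is grayscale reconstruction by dilation
#' of the marker `f - h` under the mask `f`.  The marker is anchored to
#' `f` on the image border: the background is assumed to continue beyond
#' the field of view, so a plateau touching the border is background, not
#' a dome (a constant image therefore has `H` identically 0, while an
#' isolated interior peak keeps a dome of exactly `h`).  The dome image
#' satisfies `0 <= H <= h` everywhere.
#'
#' @param img a [gray_image()] or numeric matrix (any real values).
#' @param h dome height, `> 0`.
#' @return numeric matrix of dome heights.
#' @export
hdome_transform <- function(img, h) {
  stopifnot(h > 0)
  f <- if (inherits(img, "gray_image")) img$pixels else img
  marker <- f - h
  marker[1, ] <- f[1, ]; marker[nrow(f), ] <- f[nrow(f), ]
  marker[, 1] <- f[, 1]; marker[, ncol(f)] <- f[, ncol(f)]
  f - reconstruct_dilation_cpp(marker, f)
}

#' h-dome detector parameters
#' @param sigma_L LoG filtering scale in pixels (`> 0`).
#' @param h dome height in intensity units (`> 0`).
#' @param s sampling exponent (`>= 1`): dome values are raised to this
#'   power before being used as a sampling probability map.
#' @param sigma_M maximum allowed object scale in pixels; also the
#'   mean-shift bandwidth.
#' @param n_samples sampling budget.
#' @param seed RNG seed for the sampling stage (part of the parameters so
#'   runs are reproducible bit-for-bit).
#' @return object of class `hd_params`.
#' @export
hd_params <- function(sigma_L, h, s = 2, sigma_M = 3, n_samples = 500L,
                      seed = 42L) {
  stopifnot(sigma_L > 0, h > 0, s >= 1, sigma_M > 0, n_samples >= 10)
  structure(list(sigma_L = sigma_L, h = h, s = s, sigma_M = sigma_M,
                 n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "hd_params")
}

# scale-normalized negative LoG kernel (bright spots -> positive peaks),
# zero-mean so the background is subtracted
.neg_log_kernel <- function(sigma) {
  r <- max(2L, ceiling(4 * sigma))
  d <- 2L * r + 1L
  x <- matrix(rep(-r:r, d), d, d)
  d2 <- x^2 + t(x)^2
  k <- -(d2 - 2 * sigma^2) / sigma^2 * exp(-d2 / (2 * sigma^2))
  k - mean(k)
}

# mean-shift with a flat kernel of the given bandwidth; returns the
# converged mode of every sample point
.mean_shift <- function(P, bandwidth, tol = 1e-3, max_iter = 200L) {
  M <- P
  for (it in seq_len(max_iter)) {
    shift <- 0
    for (q in seq_len(nrow(M))) {
      d2 <- (P[, 1] - M[q, 1])^2 + (P[, 2] - M[q, 2])^2
      sel <- d2 <= bandwidth^2
      new_m <- c(mean(P[sel, 1]), mean(P[sel, 2]))
      shift <- max(shift, sqrt(sum((new_m - M[q, ])^2)))
      M[q, ] <- new_m
    }
    if (shift < tol) break
  }
  M
}

#' h-dome detector (HD)
#'
#' The image is LoG-filtered at scale `sigma_L` (spots become positive
#' peaks on a subtracted background), the dome of height `h` is extracted
#' by grayscale reconstruction, raised to the power `s` and normalized into
#' a probability map.  `n_samples` pixels are drawn from that map (fixed
#' seed), clustered with flat-kernel mean-shift at bandwidth `sigma_M`
#' (modes merged within `sigma_M / 2`), and clusters are accepted when
#' their RMS sample spread is at most `sigma_M` and they carry at least 1%
#' of the samples; larger or negligible structures are rejected.  The mask
#' collects each accepted cluster's supporting dome pixels (the
#' 8-connected component of dome >= h/2 at the cluster centroid), and the
#' centroids are returned as a point list.
#'
#' @param img a [gray_image()].
#' @param p an [hd_params()].
#' @return a [detection_result()] with mask and points.
#' @export
detect_hd <- function(img, p) {
  img <- as_gray_image(img)
  stopifnot(inherits(p, "hd_params"))
  empty <- function() detection_result(
    "HD", mask = binary_mask(.empty_mask(img$pixels)),
    points = NULL, params = unclass(p))
  F <- conv2_symm(img$pixels, .neg_log_kernel(p$sigma_L))
  dome <- hdome_transform(F, p$h)
  prob <- pmax(dome, 0)^p$s
  tot <- sum(prob)
  if (tot <= 0) return(empty())
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(p$seed)
  idx <- sample.int(length(prob), p$n_samples, replace = TRUE,
                    prob = as.vector(prob))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  P <- cbind((idx - 1) %% nrow(prob), (idx - 1) %/% nrow(prob))  # 0-based
  M <- .mean_shift(P, p$sigma_M)
  # merge modes within sigma_M / 2
  reps <- matrix(numeric(0), 0, 2)
  cl <- integer(nrow(M))
  for (q in seq_len(nrow(M))) {
    if (nrow(reps) > 0) {
      d2 <- (reps[, 1] - M[q, 1])^2 + (reps[, 2] - M[q, 2])^2
      hit <- which(d2 <= (p$sigma_M / 2)^2)
    } else hit <- integer(0)
    if (length(hit) > 0) cl[q] <- hit[1]
    else { reps <- rbind(reps, M[q, ]); cl[q] <- nrow(reps) }
  }
  # cluster acceptance: enough sample mass, sample spread at most sigma_M,
  # and a genuine dome at the centroid -- the 8-connected component of
  # dome >= h/2 must exist (the structure rose by h above its
  # surroundings) and have equivalent radius at most 2 sigma_M; broad
  # backgrounds fail one of these even when sparse sampling makes their
  # local sample clusters look tight
  min_mass <- max(3L, ceiling(0.01 * p$n_samples))
  cents <- list(); mask <- .empty_mask(img$pixels)
  half_lab <- label_components_cpp((dome >= p$h / 2) + 0L, 8L)
  lab_area <- if (max(half_lab) > 0) tabulate(half_lab[half_lab > 0],
                                              max(half_lab)) else integer(0)
  for (k in seq_len(nrow(reps))) {
    sel <- cl == k
    if (sum(sel) < min_mass) next
    ctr <- c(mean(P[sel, 1]), mean(P[sel, 2]))
    spread <- sqrt(mean((P[sel, 1] - ctr[1])^2 + (P[sel, 2] - ctr[2])^2))
    if (spread > p$sigma_M) next
    ci <- round(ctr) + 1
    lab <- half_lab[min(max(ci[1], 1), nrow(mask)),
                    min(max(ci[2], 1), ncol(mask))]
    if (lab == 0) next
    if (sqrt(lab_area[lab] / pi) > 2 * p$sigma_M) next
    cents[[length(cents) + 1L]] <- ctr
    mask[half_lab == lab] <- 1L
  }
  if (length(cents) == 0L) return(empty())
  detection_result("HD", mask = binary_mask(mask),
                   points = point_list(do.call(rbind, cents)),
                   params = unclass(p))
}

## ---- MGI ---------------------------------------------------------------

#' Granulometric size density
#'
#' `G(d)` is the loss of integrated intensity between grayscale openings
#' with discs of successive (odd) diameters; its peaks indicate the
#' dominant object scales.  The two highest peaks are selected as `d_low`
#' and `d_high`.
#'
#' @param img a [gray_image()] or matrix.
#' @param d_max largest disc diameter probed (`>= 3`).
#' @return object of class `mgi_state` with fields `G` (data.frame of
#'   diameters and size-density values), `d_low`, `d_high`.
#' @export
granulometry <- function(img, d_max = 21L) {
  stopifnot(d_max >= 3)
  f <- if (inherits(img, "gray_image")) img$pixels else img
  ds <- seq(1L, as.integer(d_max), by = 2L)
  # pattern-spectrum convention: G(d) is the intensity removed by the
  # first opening LARGER than d, so structures of diameter d register at d
  # (an opening with a disc of the object's own diameter still retains it)
  sums <- vapply(c(ds, d_max + 2L), function(d)
    sum(gray_open_disc(f, (d - 1) / 2)), numeric(1))
  # discrete discs are not perfectly nested; enforce the theoretical
  # monotone sieve property before differencing so G >= 0
  sums <- cummin(sums)
  G <- sums[-length(sums)] - sums[-1]
  n <- length(G)
  is_peak <- vapply(seq_len(n), function(k) {
    left_ok <- k == 1L || G[k] > G[k - 1L]
    right_ok <- k == n || G[k] >= G[k + 1L]
    left_ok && right_ok && G[k] > 0
  }, logical(1))
  peaks <- which(is_peak)
  if (length(peaks) < 2L)
    stop("scale selection failed: fewer than two peaks in G(d)")
  top2 <- peaks[order(G[peaks], decreasing = TRUE)][1:2]
  structure(list(G = data.frame(d = ds, G = G),
                 d_low = ds[min(top2)], d_high = ds[max(top2)]),
            class = "mgi_state")
}

#' Granulometric morphometry detector (MGI)
#'
#' Fully automatic (no free parameters): granulometry selects the two
#' dominant scales, the difference of the corresponding openings
#' `I o E(d_low) - I o E(d_high)` isolates structures between those
#' scales, a 2-cluster k-means mask of the original image restricts the
#' search to bright regions, and integral thresholding (keeping the
#' brightest pixels until `fraction` of the cumulative masked intensity is
#' reached) yields the spots.  On near-empty images the scale selection
#' can fail; the detector then returns an empty mask with a warning.
#'
#' @param img a [gray_image()].
#' @param d_max largest disc diameter probed.
#' @param fraction integral-thresholding fraction of cumulative masked
#'   intensity (default 0.95).
#' @return a [detection_result()].
#' @export
detect_mgi <- function(img, d_max = 21L, fraction = 0.95) {
  img <- as_gray_image(img)
  params <- list(d_max = d_max, fraction = fraction)
  st <- tryCatch(granulometry(img, d_max), error = function(e) {
    warning("MGI: ", conditionMessage(e), "; returning empty mask")
    NULL
  })
  if (is.null(st))
    return(detection_result("MGI", mask = binary_mask(.empty_mask(img$pixels)),
                            params = params))
  I_low <- gray_open_disc(img$pixels, (st$d_low - 1) / 2)
  I_high <- gray_open_disc(img$pixels, (st$d_high - 1) / 2)
  dif <- I_low - I_high
  km <- kmeans2_binarize(img)$pixels
  vals <- dif[km == 1L & dif > 0]
  bw <- .empty_mask(dif)
  if (length(vals) > 0 && sum(vals) > 0) {
    # integral threshold: keep the brightest pixels of the masked
    # difference image until `fraction` of its cumulative intensity is
    # covered; flat regions (difference ~ 0) never enter
    sv <- sort(vals, decreasing = TRUE)
    cum <- cumsum(sv)
    th <- sv[which(cum >= fraction * sum(sv))[1]]
    bw <- (dif >= th & km == 1L) + 0L
  }
  detection_result("MGI", mask = binary_mask(bw),
                   params = c(params, list(d_low = st$d_low,
                                           d_high = st$d_high)))
}
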