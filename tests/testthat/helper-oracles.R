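# Independent brute-force oracles and tiny fixture builders.  These stay
# deliberately naive (explicit loops) so they are independent of the code
# paths they check.

# symmetric-padding index (edge repeated)
refl_idx <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

oracle_conv2 <- function(img, ker) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(ker); kc <- ncol(ker)
  cr <- (kr - 1) %/% 2; cc <- (kc - 1) %/% 2
  out <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    s <- 0
    for (a in 1:kr) for (b in 1:kc)
      s <- s + ker[a, b] *
        img[refl_idx(i + a - 1 - cr, nr), refl_idx(j + b - 1 - cc, nc)]
    out[i, j] <- s
  }
  out
}

# exhaustive between-class-variance scan over the same histogram layout
oracle_otsu <- function(x, nbins = 256L) {
  x <- as.vector(x)
  mn <- min(x); mx <- max(x)
  breaks <- seq(mn, mx, length.out = nbins + 1)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(idx, nbins) / length(x)
  mids <- (breaks[-1] + breaks[-(nbins + 1)]) / 2
  best <- -Inf; best_k <- NA
  for (k in 1:(nbins - 1)) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[1:k] * mids[1:k]) / w0
    mu1 <- sum(p[(k + 1):nbins] * mids[(k + 1):nbins]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best + 1e-15) { best <- v; best_k <- k }
  }
  breaks[best_k + 1]
}

oracle_kapur <- function(x, nbins = 256L) {
  x <- as.vector(x)
  breaks <- seq(min(x), max(x), length.out = nbins + 1)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(idx, nbins) / length(x)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  best <- -Inf; best_k <- NA
  for (k in 1:(nbins - 1)) {
    P0 <- sum(p[1:k]); P1 <- 1 - P0
    if (P0 <= 0 || P1 <= 0) next
    v <- ent(p[1:k] / P0) + ent(p[(k + 1):nbins] / P1)
    if (v > best + 1e-12) { best <- v; best_k <- k }
  }
  breaks[best_k + 1]
}

# grayscale erosion/dilation/opening by explicit min/max loops
# (+Inf / -Inf outside the image)
oracle_open_disc <- function(img, radius) {
  r <- as.integer(round(radius))
  offs <- expand.grid(a = -r:r, b = -r:r)
  offs <- offs[offs$a^2 + offs$b^2 <= radius^2 + 1e-9, ]
  nr <- nrow(img); nc <- ncol(img)
  er <- matrix(Inf, nr, nc)
  for (i in 1:nr) for (j in 1:nc)
    for (q in seq_len(nrow(offs))) {
      ii <- i + offs$a[q]; jj <- j + offs$b[q]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
        er[i, j] <- min(er[i, j], img[ii, jj])
    }
  di <- matrix(-Inf, nr, nc)
  for (i in 1:nr) for (j in 1:nc)
    for (q in seq_len(nrow(offs))) {
      ii <- i + offs$a[q]; jj <- j + offs$b[q]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
        di[i, j] <- max(di[i, j], er[ii, jj])
    }
  di
}

# grayscale reconstruction by iterated elementary geodesic dilation
oracle_reconstruct <- function(marker, mask) {
  J <- pmin(marker, mask)
  repeat {
    nr <- nrow(J); nc <- ncol(J)
    D <- J
    for (i in 1:nr) for (j in 1:nc)
      for (a in -1:1) for (b in -1:1) {
        ii <- i + a; jj <- j + b
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
          D[i, j] <- max(D[i, j], J[ii, jj])
      }
    D <- pmin(D, mask)
    if (all(D == J)) return(J)
    J <- D
  }
}

# 8-connected component count by flood fill
oracle_count_components <- function(mask) {
  mask <- mask > 0
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  n <- 0
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || seen[i, j]) next
    n <- n + 1
    stack <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (a in -1:1) for (b in -1:1) {
        ii <- p[1] + a; jj <- p[2] + b
        if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
            mask[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  n
}

# exhaustive one-to-one assignment: maximize matches, then minimize total
# distance; returns c(tp, total_distance)
oracle_assignment <- function(cost, feasible) {
  nd <- nrow(cost); nr <- ncol(cost)
  best_tp <- -1; best_dist <- Inf
  k <- min(nd, nr)
  idx_sets <- utils::combn(nd, k, simplify = FALSE)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (q in seq_along(v))
      for (p in perms(v[-q])) out[[length(out) + 1L]] <- c(v[q], p)
    out
  }
  for (ds in idx_sets) for (rs in perms(seq_len(nr))) {
    rs <- rs[seq_len(k)]
    tp <- 0; dist <- 0
    for (q in seq_len(k)) {
      if (feasible[ds[q], rs[q]]) { tp <- tp + 1; dist <- dist + cost[ds[q], rs[q]] }
    }
    if (tp > best_tp || (tp == best_tp && dist < best_dist)) {
      best_tp <- tp; best_dist <- dist
    }
  }
  c(tp = best_tp, dist = best_dist)
}

# analytic Gaussian spot image (0-based center)
spot_image <- function(n, ctr, sigma, peak, bg = 0) {
  ri <- matrix(rep(0:(n - 1), n), n, n)
  ci <- t(ri)
  bg + peak * exp(-((ri - ctr[1])^2 + (ci - ctr[2])^2) / (2 * sigma^2))
}

# the scaled-down benchmark world used by the stochastic tests
test_world <- function(seed, ...) {
  sim_config(image_size = 96, n_cells = 6, seed = seed, ...)
}
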