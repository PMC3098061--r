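# 1-D frequency response of a symmetric FIR at normalized frequency f
# (1 = Nyquist)
fir_response <- function(k, f) {
  m <- (length(k) - 1) / 2
  sum(k * cos(pi * f * (-m:m)))
}

test_that("BPF rejects DC and out-of-band structure, passes spot frequencies", {
  const <- gray_image(matrix(40, 48, 48))
  expect_equal(sum(detect_bpf(const, bpf_params(c(.1, .2, .5, .7)))$mask$pixels), 0)
  # single Gaussian spot, sigma 2 px: dominant frequencies well inside
  # [0.08, 0.5] (spatial sigma 2 -> spectral sigma ~0.16 Nyquist)
  img <- spot_image(64, c(31, 31), 2, 80, bg = 10)
  det <- detect_bpf(gray_image(img), bpf_params(c(0.04, 0.08, 0.5, 0.7)))
  expect_equal(det$mask$pixels[32, 32], 1L)
  expect_equal(max(spotbench:::label_components_cpp(det$mask$pixels, 8L)), 1)
  # pure low-frequency sinusoid below w1: attenuation measured from the
  # designed filter's own response, then the mask must be empty
  p <- bpf_params(c(0.15, 0.25, 0.5, 0.7))
  n <- 41  # round(4 / (w2 - w1)) rounded odd
  k_lo <- spotbench:::.fir_lowpass(0.2, n)
  k_hi <- spotbench:::.fir_lowpass(0.6, n)
  att <- fir_response(k_hi, 0.05) - fir_response(k_lo, 0.05)
  expect_lt(abs(att), 0.01)
  sine <- 50 + 20 * sin(2 * pi * 0.05 / 2 * outer(0:95, 0:95, `+`))
  expect_equal(sum(detect_bpf(gray_image(sine), p)$mask$pixels), 0)
  expect_error(bpf_params(c(0.5, 0.2, 0.3, 0.9)), "cutoffs")
})

test_that("KDE smoothing equals a brute-force windowed mean and handles edges", {
  # uniform kernel whose support covers the window: averaging preserves
  # constants exactly, so the degenerate rule yields an empty mask
  const <- gray_image(matrix(7, 32, 32))
  expect_equal(sum(detect_kde(const, kde_params(2, 2))$mask$pixels), 0)
  set.seed(4)
  img <- matrix(runif(9, 0, 10), 3, 3)
  sm <- spotbench:::kde_smooth_cpp(img, 1L, 1, 0L)  # uniform, R = 1
  for (i in 1:3) for (j in 1:3) {
    s <- 0; n <- 0
    for (a in -1:1) for (b in -1:1) {
      if (a^2 + b^2 > 1) next
      ii <- i + a; jj <- j + b
      if (ii >= 1 && ii <= 3 && jj >= 1 && jj <= 3) { s <- s + img[ii, jj]; n <- n + 1 }
    }
    expect_equal(sm[i, j], s / n)
  }
  # kernel-weighted variant against an independent loop (gaussian, R = 2)
  set.seed(5)
  img <- matrix(runif(64, 0, 10), 8, 8)
  sm <- spotbench:::kde_smooth_cpp(img, 2L, 1.5, 1L)
  i <- 4; j <- 5; s <- 0; n <- 0
  for (a in -2:2) for (b in -2:2) {
    d <- sqrt(a^2 + b^2)
    if (d > 2) next
    s <- s + exp(-0.5 * (d / 1.5)^2) * img[i + a, j + b]; n <- n + 1
  }
  expect_equal(sm[i, j], s / n)
  expect_error(detect_kde(gray_image(matrix(runif(64), 8)), kde_params(6, 1)),
               "half")
})

test_that("KDE kernel choice is not crucial at image-set level", {
  # compared at the benchmark set size (20 scenes), where sampling noise
  # in the pooled F-score is controlled
  scenes <- lapply(1:20, function(s) generate_scene(test_world(100 + s)))
  imgs <- lapply(scenes, `[[`, "gray")
  refs <- lapply(scenes, function(s)
    reference_annotation(points = s$truth_points, match_radius = 4))
  best <- vapply(c("uniform", "gaussian"), function(kn) {
    g <- param_grid("KDE", R = c(1, 2), h = c(0.5, 1, 2), kernel = kn)
    grid_search(imgs, refs, "KDE", g)$best_fscore
  }, numeric(1))
  expect_lt(abs(best[1] - best[2]), 0.05)
})

test_that("LC matches a per-pixel brute-force evaluation of the comparison rule", {
  const <- gray_image(matrix(5, 24, 24))
  expect_equal(sum(detect_lc(const, lc_params(3, 1))$mask$pixels), 0)
  # isolated bright pixel: quarter means exclude the center, so it wins
  one <- matrix(0, 21, 21); one[11, 11] <- 10
  det <- detect_lc(gray_image(one), lc_params(3, 1))
  expect_equal(det$mask$pixels[11, 11], 1L)
  # ring scene: center must not fire; full mask equals the brute force
  ring <- matrix(2, 21, 21)
  ri <- row(ring) - 11; ci <- col(ring) - 11
  ring[abs(sqrt(ri^2 + ci^2) - 6) < 1] <- 30
  p <- lc_params(4, 1.05)
  filts <- spotbench:::lc_quadrant_filters(4)
  mx <- Reduce(pmax, lapply(filts, function(k) oracle_conv2(ring, k)))
  expect_equal(detect_lc(gray_image(ring), p)$mask$pixels,
               (1.05 * ring > mx) + 0L)
  # at alpha = 1 the flat interior (and so the ring center) cannot fire
  expect_equal(detect_lc(gray_image(ring), lc_params(4, 1))$mask$pixels[11, 11],
               0L)
  expect_error(lc_params(1, 1), ">= 2")
  # quadrant filters: unit sums, no center, disjoint support covering disc
  for (k in filts) expect_equal(sum(k), 1)
  expect_true(all(vapply(filts, function(k) k[5, 5] == 0, logical(1))))
  expect_equal(max(Reduce(`+`, lapply(filts, function(k) (k > 0) + 0))), 1)
})

test_that("LEF likelihood thresholding behaves per the ratio formulation", {
  const <- gray_image(matrix(9, 32, 32))
  expect_equal(sum(detect_lef(const, lef_params(2))$mask$pixels), 0)
  # strong spot: likelihood maximal at the center, detected for th_s <= 2
  img <- spot_image(33, c(16, 16), 1.5, 100, bg = 10)
  p <- lef_params(2)
  det <- detect_lef(gray_image(img), p)
  expect_equal(det$mask$pixels[17, 17], 1L)
  # direct evaluation of the ratio at the center on the mean-normalized image
  f <- img * (100 / mean(img))
  d <- 9; r <- 4
  drow <- matrix(rep(-r:r, d), d, d)
  inner <- (drow^2 + t(drow)^2) <= 4 + 1e-9
  win <- f[13:21, 13:21]
  lik_center <- mean(win[inner]) / mean(win[!inner])
  expect_gt(lik_center, 1.5)
  # scale invariance: doubling intensities leaves the mask unchanged
  expect_equal(detect_lef(gray_image(2 * img), p)$mask$pixels,
               det$mask$pixels)
  expect_error(lef_params(2, kernel_size = 9, inner_radius = 4), "strictly")
})

test_that("MW decomposition satisfies the reconstruction identity and kernel sums", {
  set.seed(31)
  img <- matrix(runif(64 * 64, 0, 100), 64, 64)
  J <- 4
  dec <- mw_decompose(img, J)
  expect_equal(Reduce(`+`, dec$W) + dec$A, img, tolerance = 1e-9)
  for (i in 1:5) {
    k <- spotbench:::.atrous_kernel(i)
    expect_equal(sum(k), 1, tolerance = 1e-12)
    expect_equal(sum(k != 0), 5)
  }
  expect_error(mw_decompose(matrix(1, 8, 8), 3), "support")
})

test_that("MW hard thresholding suppresses pure noise", {
  set.seed(77)
  img <- matrix(abs(rnorm(96 * 96, 10, 1)), 96, 96)
  det <- detect_mw(gray_image(img), mw_params(3, 1e-9))
  expect_lt(mean(det$mask$pixels), 0.001)
})

test_that("SE background clipping follows the sigma-clip rules", {
  # constant block
  bg <- se_estimate_background(gray_image(matrix(42, 16, 16)), 16)
  expect_equal(bg$pixels, matrix(42, 16, 16))
  # printed fallback formula: BG = 2.5 * Median - 1.5 * Mean
  expect_equal(2.5 * 10 - 1.5 * 12, 7)
  # flat background with 1% bright outliers: clipped mean within [99, 101],
  # checked against an iterative-clipping loop oracle
  set.seed(6)
  x <- c(rnorm(990, 100, 1), rep(1000, 10))
  img <- matrix(sample(x), 25, 40)
  est <- se_estimate_background(gray_image(img), 40)$pixels
  y <- as.vector(img); s0 <- sd(y)
  repeat {
    keep <- abs(y - median(y)) <= 3 * sd(y)
    if (all(keep)) break
    y <- y[keep]
  }
  oracle_bg <- if (abs(sd(y) - s0) / s0 < 0.2) mean(y)
               else 2.5 * median(y) - 1.5 * mean(y)
  expect_gt(min(est), 99); expect_lt(max(est), 101)
  # single full-image block: every pixel equals the oracle value
  est1 <- se_estimate_background(gray_image(img), 64)$pixels
  expect_equal(unique(as.vector(est1)), oracle_bg, tolerance = 1e-9)
})

test_that("SE thresholding and deblending split merged sources correctly", {
  # th_bg = 0 equals the original formulation's code path by construction;
  # verify the documented parameter identity on a real scene
  sc <- generate_scene(test_world(42))
  d0 <- detect_se(sc$gray, se_params(16, 2, th_bg = 0))
  d1 <- detect_se(sc$gray, se_params(16, 2))
  expect_identical(d0$mask$pixels, d1$mask$pixels)
  # two spots 6 px apart merge at a low threshold but deblend into 2
  img <- spot_image(31, c(15, 12), 1.8, 100, bg = 20) +
         spot_image(31, c(15, 18), 1.8, 100)
  det <- detect_se(gray_image(img), se_params(31, 0.5, gauss_sigma = 1))
  expect_equal(max(spotbench:::label_components_cpp(det$mask$pixels, 8L)), 1)
  expect_equal(count_objects(det), 2)
  # analytic check: each peak's slice-branch carries far more than the
  # 0.005 contrast fraction (symmetric pair -> each about half)
  # single spot: deblending must return exactly 1 object
  img1 <- spot_image(31, c(15, 15), 2, 100, bg = 20)
  expect_equal(count_objects(detect_se(gray_image(img1),
                                       se_params(31, 0.5))), 1)
  expect_error(detect_se(sc$gray, se_params(200, 1)), "block_size")
})

test_that("THE top-hat residual matches a brute-force opening oracle", {
  set.seed(12)
  img <- matrix(runif(31 * 31, 0, 50), 31, 31)
  r <- 3
  open_o <- oracle_open_disc(img, r)
  fdiff <- img - open_o
  expect_true(all(fdiff >= -1e-12))            # anti-extensivity
  expect_equal(img - spotbench:::gray_open_disc(img, r), fdiff,
               tolerance = 1e-12)
  # disk of radius r-1 fully retained; disk of radius 2r has its interior
  # removed by the opening
  small <- matrix(0, 31, 31)
  ri <- row(small) - 16; ci <- col(small) - 16
  small[ri^2 + ci^2 <= (r - 1)^2] <- 10
  od <- spotbench:::gray_open_disc(small, r)
  expect_equal(max(od), 0)                     # small disk removed entirely
  big <- matrix(0, 31, 31)
  big[ri^2 + ci^2 <= (2 * r)^2] <- 10
  ob <- spotbench:::gray_open_disc(big, r)
  expect_equal(ob[16, 16], 10)                 # interior survives
  expect_equal(oracle_open_disc(big, r), ob, tolerance = 1e-12)
  # constant image -> residual identically 0 -> empty mask
  expect_equal(sum(detect_the(gray_image(matrix(4, 24, 24)),
                              the_params(2))$mask$pixels), 0)
})

test_that("detectors are deterministic and masks keep the input shape", {
  sc <- generate_scene(test_world(7))
  specs <- list(BPF = list(w1 = .05, w2 = .2, w3 = .5, w4 = .9),
                KDE = list(R = 1, h = 1), LC = list(R = 3, alpha = 1.3),
                LEF = list(th_s = 12), MW = list(J = 3, l_d = 1),
                SE = list(block_size = 16, th_detect = 3),
                THE = list(r = 3))
  for (m in names(specs)) {
    d1 <- detect_spots(sc$gray, m, specs[[m]])
    d2 <- detect_spots(sc$gray, m, specs[[m]])
    expect_identical(d1$mask$pixels, d2$mask$pixels)
    expect_equal(dim(d1$mask$pixels), c(96L, 96L))
    if (is.null(d1$labels))
      expect_equal(count_objects(d1),
                   oracle_count_components(d1$mask$pixels))
  }
})
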