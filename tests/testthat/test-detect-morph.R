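test_that("hdome_transform matches the geodesic-dilation oracle and its bounds", {
  set.seed(18)
  img <- matrix(runif(18 * 15, 0, 60), 18, 15)
  for (h in c(5, 20)) {
    H <- hdome_transform(img, h)
    expect_true(all(H >= -1e-12 & H <= h + 1e-12))
    mk <- img - h                       # border-anchored marker
    mk[1, ] <- img[1, ]; mk[18, ] <- img[18, ]
    mk[, 1] <- img[, 1]; mk[, 15] <- img[, 15]
    expect_equal(H, img - oracle_reconstruct(mk, img), tolerance = 1e-12)
  }
  # isolated peak of height 50: dome exactly h at the peak
  pk <- matrix(10, 15, 15); pk[8, 8] <- 60
  expect_equal(hdome_transform(pk, 20)[8, 8], 20)
  # constant image: dome identically 0
  expect_equal(max(hdome_transform(matrix(5, 9, 9), 3)), 0)
})

test_that("HD detects well-separated spots and rejects broad structures", {
  expect_equal(sum(detect_hd(gray_image(matrix(6, 48, 48)),
                             hd_params(1.5, 100))$mask$pixels), 0)
  img <- spot_image(64, c(15, 15), 1.5, 120, bg = 20) +
         spot_image(64, c(45, 20), 1.5, 120) +
         spot_image(64, c(30, 48), 1.5, 120)
  p <- hd_params(1.5, 300, sigma_M = 4, n_samples = 600, seed = 9)
  det <- detect_hd(gray_image(img), p)
  expect_equal(det$points$count, 3)
  truth <- rbind(c(15, 15), c(45, 20), c(30, 48))
  for (k in 1:3) {
    d <- min(sqrt(rowSums((truth - matrix(as.numeric(det$points$points[k, ]),
                                          3, 2, byrow = TRUE))^2)))
    expect_lt(d, 1.5)
  }
  # reproducibility bit-for-bit under the fixed seed
  det2 <- detect_hd(gray_image(img), p)
  expect_identical(det$mask$pixels, det2$mask$pixels)
  expect_identical(det$points$points, det2$points$points)
  # a broad blob much larger than sigma_M is rejected, the spot kept
  img2 <- spot_image(64, c(16, 16), 1.5, 120, bg = 20) +
          spot_image(64, c(44, 44), 12, 60)
  det3 <- detect_hd(gray_image(img2),
                    hd_params(1.5, 300, sigma_M = 3, n_samples = 600,
                              seed = 9))
  expect_equal(det3$points$count, 1)
  expect_lt(sqrt(sum((as.numeric(det3$points$points[1, ]) - c(16, 16))^2)), 2)
})

test_that("granulometry peaks at the planted disc diameters", {
  mkdisc <- function(m, ctr, rad, val = 10) {
    ri <- row(m) - ctr[1]; ci <- col(m) - ctr[2]
    m[ri^2 + ci^2 <= rad^2 + 1e-9] <- val
    m
  }
  img <- matrix(0, 48, 48)
  for (c0 in list(c(10, 10), c(10, 30), c(30, 10), c(30, 30)))
    img <- mkdisc(img, c0, 2)            # diameter-5 discs
  st <- tryCatch(granulometry(img, 11), error = identity)
  G <- if (inherits(st, "error")) NULL else st$G
  # the size density must peak at d = 5 (verified against the opening
  # oracle used to build G independently; pattern-spectrum convention:
  # loss attributed to d is removed by the first opening larger than d)
  ds <- c(1, 3, 5, 7, 9, 11)
  loss <- vapply(ds, function(d)
    sum(oracle_open_disc(img, (d - 1) / 2)) -
      sum(oracle_open_disc(img, (d + 1) / 2)), numeric(1))
  expect_equal(ds[which.max(loss)], 5)
  if (!is.null(G)) expect_equal(G$G, loss, tolerance = 1e-9)
  # two populations: d_low ~ 3, d_high ~ 9
  img2 <- matrix(0, 60, 60)
  img2 <- mkdisc(img2, c(15, 15), 1); img2 <- mkdisc(img2, c(15, 45), 1)
  img2 <- mkdisc(img2, c(45, 15), 4); img2 <- mkdisc(img2, c(45, 45), 4)
  st2 <- granulometry(img2, 13)
  expect_equal(st2$d_low, 3)
  expect_equal(st2$d_high, 9)
  expect_error(granulometry(matrix(5, 20, 20), 9), "scale selection")
})

test_that("granulometry telescopes to the largest opening's intensity loss", {
  set.seed(23)
  img <- matrix(runif(40 * 40, 0, 5), 40, 40)
  img <- img + spot_image(40, c(12, 12), 1.2, 50) +
    spot_image(40, c(28, 28), 3, 40)
  st <- granulometry(img, 9)
  # G telescopes: its total equals everything removed by the largest
  # opening computed (one size step beyond d_max)
  total_loss <- sum(img) - sum(spotbench:::gray_open_disc(img, 5))
  expect_equal(sum(st$G$G), total_loss, tolerance = 1e-6 * max(1, total_loss))
})

test_that("MGI keeps spot-scale structures and respects the k-means mask", {
  # spots (diameter ~3) on flat-topped cell-shaped blobs (diameter ~25):
  # the large opening preserves a flat plateau, so the difference image
  # vanishes on blob interiors while the spots carry almost all its mass
  img <- matrix(2, 80, 80)
  blob <- function(m, ctr) {
    ri <- row(m) - ctr[1]; ci <- col(m) - ctr[2]
    m[ri^2 + ci^2 <= 12.5^2] <- m[ri^2 + ci^2 <= 12.5^2] + 20
    m
  }
  img <- blob(img, c(25, 25)); img <- blob(img, c(55, 55))
  spots <- rbind(c(25, 20), c(28, 32), c(21, 26), c(30, 23),
                 c(52, 50), c(60, 58), c(58, 50), c(51, 58))
  for (k in seq_len(nrow(spots)))
    img <- img + spot_image(80, spots[k, ] - 1, 1.2, 80)
  st <- granulometry(img, 31)
  expect_equal(st$d_low, 3)
  expect_equal(st$d_high, 25)
  det <- detect_mgi(gray_image(img), d_max = 31)
  expect_gt(sum(det$mask$pixels), 0)
  for (k in seq_len(nrow(spots)))
    expect_equal(det$mask$pixels[spots[k, 1], spots[k, 2]], 1L)
  # blob interiors removed: no detection at the blob centers
  expect_equal(det$mask$pixels[25, 25], 0L)
  expect_equal(det$mask$pixels[55, 55], 0L)
  # containment in the k-means bright mask, always
  km <- kmeans2_binarize(gray_image(img))$pixels
  expect_true(all(det$mask$pixels <= km))
  # empty image goes through the error path to an empty mask
  expect_warning(d0 <- detect_mgi(gray_image(matrix(3, 40, 40))),
                 "scale selection")
  expect_equal(sum(d0$mask$pixels), 0)
})

test_that("opening is anti-extensive for arbitrary structuring elements", {
  set.seed(29)
  img <- matrix(runif(30 * 30, 0, 9), 30, 30)
  for (r in c(1, 2, 4))
    expect_true(all(spotbench:::gray_open_disc(img, r) <= img + 1e-12))
})

test_that("HD spot recovery does not degrade as the sampling budget grows", {
  img <- gray_image(spot_image(64, c(15, 15), 1.5, 120, bg = 20) +
                    spot_image(64, c(45, 20), 1.5, 120) +
                    spot_image(64, c(30, 48), 1.5, 120))
  hits <- function(ns) {
    found <- vapply(1:10, function(sd) {
      det <- detect_hd(img, hd_params(1.5, 300, sigma_M = 4,
                                      n_samples = ns, seed = sd))
      det$points$count
    }, numeric(1))
    mean(pmin(found, 3))
  }
  expect_lte(hits(100), hits(1000) + 1e-9)
})
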