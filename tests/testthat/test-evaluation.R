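det_from_points <- function(...) {
  detection_result("SPL", points = point_list(rbind(...)))
}

test_that("match_objects handles trivial and ambiguous cases like the oracle", {
  ref3 <- reference_annotation(
    points = point_list(rbind(c(5, 5), c(20, 20), c(40, 10))),
    match_radius = 4)
  empty <- detection_result("SPL", points = point_list())
  expect_equal(match_objects(empty, ref3), c(tp = 0L, fp = 0L, fn = 3L))
  exact <- det_from_points(c(5, 5), c(20, 20), c(40, 10))
  expect_equal(match_objects(exact, ref3), c(tp = 3L, fp = 0L, fn = 0L))
  # 3 detections, 2 references, one detection within radius of both:
  # compare against exhaustive enumeration of all one-to-one assignments
  refs <- rbind(c(10, 10), c(10, 15))
  dets <- rbind(c(10, 12.4), c(10, 16), c(30, 30))
  cost <- outer(1:3, 1:2, function(a, b)
    sqrt((dets[a, 1] - refs[b, 1])^2 + (dets[a, 2] - refs[b, 2])^2))
  feas <- cost <= 4
  oracle <- oracle_assignment(cost, feas)
  got <- match_objects(det_from_points(dets[1, ], dets[2, ], dets[3, ]),
                       reference_annotation(points = point_list(refs),
                                            match_radius = 4))
  expect_equal(unname(got["tp"]), unname(oracle["tp"]))
  expect_equal(got, c(tp = 2L, fp = 1L, fn = 0L))
})

test_that("mask-mode matching pairs overlapping components one-to-one", {
  ref <- matrix(0L, 20, 20)
  ref[3:5, 3:5] <- 1L; ref[12:14, 12:14] <- 1L
  det <- matrix(0L, 20, 20)
  det[4:6, 4:6] <- 1L                     # overlaps ref 1
  det[17:18, 2:3] <- 1L                   # overlaps nothing
  r <- reference_annotation(mask = binary_mask(ref))
  d <- detection_result("LC", mask = binary_mask(det))
  expect_equal(match_objects(d, r), c(tp = 1L, fp = 1L, fn = 1L))
})

test_that("score reproduces printed benchmark rows and empty conventions", {
  expect_equal(score(0, 0, 0)$precision, 1)
  expect_equal(score(0, 0, 0)$fscore, 1)
  expect_equal(score(0, 0, 5)$precision, 0)
  expect_equal(score(0, 5, 0)$recall, 0)
  rep <- score(935, 42, 65)
  expect_equal(rep$fscore, 2 * rep$precision * rep$recall /
                 (rep$precision + rep$recall))
})

test_that("pixel_score counts match a per-pixel loop oracle", {
  a <- matrix(0L, 8, 8); a[2:4, 2:4] <- 1L
  expect_equal(pixel_score(a, a)$fscore, 1)
  b <- 1L - a
  expect_equal(pixel_score(a, b)$tp, 0)
  expect_equal(pixel_score(a, b)$fscore, 0)
  set.seed(41)
  d <- matrix(rbinom(64, 1, 0.4), 8, 8)
  r <- matrix(rbinom(64, 1, 0.4), 8, 8)
  tp <- fp <- fn <- 0
  for (i in 1:8) for (j in 1:8) {
    if (d[i, j] == 1 && r[i, j] == 1) tp <- tp + 1
    if (d[i, j] == 1 && r[i, j] == 0) fp <- fp + 1
    if (d[i, j] == 0 && r[i, j] == 1) fn <- fn + 1
  }
  got <- pixel_score(d, r)
  expect_equal(c(got$tp, got$fp, got$fn), c(tp, fp, fn))
  expect_error(
    pixel_score(d, reference_annotation(points = point_list(rbind(c(1, 1))),
                                        match_radius = 2)),
    "mask-mode")
})

test_that("scoring invariants hold across random configurations", {
  set.seed(50)
  for (k in 1:50) {
    tp <- sample(0:20, 1); fp <- sample(0:10, 1); fn <- sample(0:10, 1)
    rep <- score(tp, fp, fn)
    if (tp + fp > 0 && tp + fn > 0) {
      expect_gte(rep$fscore, min(rep$precision, rep$recall) - 1e-12)
      expect_lte(rep$fscore, max(rep$precision, rep$recall) + 1e-12)
    }
    # swapping det/ref exchanges fp and fn, precision and recall
    swapped <- score(tp, fn, fp)
    expect_equal(swapped$precision, rep$recall)
    expect_equal(swapped$fscore, rep$fscore)
    # a spurious detection never raises precision; a deleted true
    # detection never raises recall
    if (tp + fp > 0)
      expect_lte(score(tp, fp + 1, fn)$precision, rep$precision)
    if (tp > 0)
      expect_lte(score(tp - 1, fp, fn + 1)$recall, rep$recall)
  }
})

test_that("tp + fn always equals the reference object count", {
  set.seed(51)
  ref_pts <- point_list(cbind(runif(12, 0, 50), runif(12, 0, 50)))
  ref <- reference_annotation(points = ref_pts, match_radius = 4)
  for (k in 1:10) {
    n <- sample(0:15, 1)
    det <- detection_result("SPL", points = point_list(
      cbind(runif(n, 0, 50), runif(n, 0, 50))))
    m <- match_objects(det, ref)
    expect_equal(unname(m["tp"] + m["fn"]), 12)
  }
})

test_that("count-distribution tests match exact references", {
  same <- list(a = c(3, 4, 5, 6), b = c(3, 4, 5, 6), c = c(3, 4, 5, 6))
  st <- compare_count_distributions(same)
  expect_equal(st$kruskal_H, 0)
  expect_equal(st$kruskal_p, 1)
  # exact two-sided rank-sum p for {1,2,3} vs {101,102,103} is 0.1
  st2 <- compare_count_distributions(list(a = c(1, 2, 3),
                                          b = c(101, 102, 103)))
  expect_equal(st2$wilcoxon_p["a", "b"], 0.1)
  expect_true(isSymmetric(st2$wilcoxon_p))
  expect_error(compare_count_distributions(list(a = 1:3)), "two methods")
})

test_that("Kruskal-Wallis type-I error is near nominal under the null", {
  set.seed(61)
  hits <- 0; nsim <- 400
  for (s in 1:nsim) {
    g <- list(rnorm(8), rnorm(8), rnorm(8))
    if (compare_count_distributions(g)$kruskal_p < 0.05) hits <- hits + 1
  }
  rate <- hits / nsim
  se <- sqrt(0.05 * 0.95 / nsim)
  expect_lt(abs(rate - 0.05), 4 * se + 0.01)
})
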