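## Object- and pixel-level scoring of detections against references, plus
## count-distribution statistics.

#' Reference annotation
#'
#' Ground truth for scoring: either a pixel-accurate binary mask (simulated
#' data) or a list of object locations with a fixed match radius (manual
#' annotation, where object areas are not outlined in detail and only
#' object-level comparison is meaningful).
#'
#' @param mask optional [binary_mask()].
#' @param points optional [point_list()].
#' @param match_radius centroid match radius in pixels (points mode).
#' @return object of class `reference_annotation`.
#' @export
reference_annotation <- function(mask = NULL, points = NULL,
                                 match_radius = 4) {
  if (is.null(mask) == is.null(points))
    stop("exactly one of mask/points must be given")
  if (!is.null(points) && match_radius <= 0)
    stop("match_radius must be > 0 in points mode")
  structure(list(mode = if (is.null(mask)) "points" else "mask",
                 mask = mask, points = points,
                 match_radius = match_radius),
            class = "reference_annotation")
}

# detected object centroids (0-based), honoring deblended labels
det_centroids <- function(det) {
  if (!is.null(det$points)) return(det$points$points)
  if (!is.null(det$labels) && max(det$labels) > 0) {
    lab <- det$labels
    idx <- which(lab > 0, arr.ind = TRUE)
    l <- lab[lab > 0]
    return(data.frame(row = as.numeric(tapply(idx[, 1] - 1, l, mean)),
                      col = as.numeric(tapply(idx[, 2] - 1, l, mean))))
  }
  mask_centroids(det$mask)
}

# maximal one-to-one assignment: feasible pairs get their distance as
# cost, infeasible pairs a prohibitive constant; minimizing total cost
# maximizes the number of matches, then minimizes total distance
.assign_match <- function(cost, feasible) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(integer(0))
  finite_max <- if (any(feasible)) max(cost[feasible]) else 0
  BIG <- (finite_max + 1) * (max(n, m) + 1) * 1e3
  C <- ifelse(feasible, cost, BIG)
  if (n <= m) {
    sol <- as.integer(clue::solve_LSAP(C))
    matched <- which(feasible[cbind(seq_len(n), sol)])
    cbind(det = matched, ref = sol[matched])
  } else {
    sol <- as.integer(clue::solve_LSAP(t(C)))
    matched <- which(feasible[cbind(sol, seq_len(m))])
    cbind(det = sol[matched], ref = matched)
  }
}

#' Match detected objects against a reference
#'
#' One-to-one assignment between detections and reference objects.  A pair
#' is matchable iff the centroid distance is at most `match_radius`
#' (points-mode reference) or the components overlap by at least one pixel
#' (mask mode).  The assignment maximizes the number of matches, breaking
#' ties by smallest total distance (Hungarian algorithm, so the result is
#' deterministic).  `tp` = matched pairs, `fp` = unmatched detections,
#' `fn` = unmatched references.
#'
#' @param det a [detection_result()].
#' @param ref a [reference_annotation()].
#' @return named integer vector `c(tp, fp, fn)`.
#' @export
match_objects <- function(det, ref) {
  stopifnot(inherits(det, "detection_result"),
            inherits(ref, "reference_annotation"))
  if (ref$mode == "points") {
    dp <- det_centroids(det)
    rp <- ref$points$points
    nd <- nrow(dp); nr <- nrow(rp)
    if (nd == 0L || nr == 0L)
      return(c(tp = 0L, fp = nd, fn = nr))
    cost <- outer(seq_len(nd), seq_len(nr), function(a, b)
      sqrt((dp$row[a] - rp$row[b])^2 + (dp$col[a] - rp$col[b])^2))
    pairs <- .assign_match(cost, cost <= ref$match_radius)
  } else {
    if (is.null(det$mask))
      stop("mask-mode matching needs a detection mask")
    det_lab <- if (!is.null(det$labels) && max(det$labels) > 0) det$labels
               else label_components_cpp(det$mask$pixels, 8L)
    ref_lab <- label_components_cpp(ref$mask$pixels, 8L)
    nd <- max(det_lab); nr <- max(ref_lab)
    if (nd == 0L || nr == 0L)
      return(c(tp = 0L, fp = nd, fn = nr))
    both <- det_lab > 0 & ref_lab > 0
    overlap <- matrix(FALSE, nd, nr)
    if (any(both)) {
      tab <- unique(cbind(det_lab[both], ref_lab[both]))
      overlap[tab] <- TRUE
    }
    dc <- as.matrix(.centroids_of_labels(det_lab))
    rc <- as.matrix(.centroids_of_labels(ref_lab))
    cost <- outer(seq_len(nd), seq_len(nr), function(a, b)
      sqrt((dc[a, 1] - rc[b, 1])^2 + (dc[a, 2] - rc[b, 2])^2))
    pairs <- .assign_match(cost, overlap)
  }
  tp <- nrow(pairs)
  if (ref$mode == "points") {
    c(tp = tp, fp = nrow(det_centroids(det)) - tp,
      fn = nrow(ref$points$points) - tp)
  } else {
    det_lab_n <- if (!is.null(det$labels) && max(det$labels) > 0)
      max(det$labels) else max(label_components_cpp(det$mask$pixels, 8L))
    c(tp = tp, fp = det_lab_n - tp,
      fn = max(label_components_cpp(ref$mask$pixels, 8L)) - tp)
  }
}

.centroids_of_labels <- function(lab) {
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  data.frame(row = as.numeric(tapply(idx[, 1] - 1, l, mean)),
             col = as.numeric(tapply(idx[, 2] - 1, l, mean)))
}

#' Precision, recall and F-score from raw counts
#'
#' `p = TP/(TP+FP)`, `r = TP/(TP+FN)`, `F = 2pr/(p+r)`.  Empty-denominator
#' conventions: no detections while references exist gives `p = 0`; no
#' references while detections exist gives `r = 0`; when detections and
#' references are both absent (`tp = fp = fn = 0`) the result is
#' `p = r = F = 1` -- an empty image correctly detected as empty is a
#' perfect result, which matters whenever acquiring empty images is
#' possible.
#'
#' @param tp,fp,fn non-negative integer counts.
#' @param level `"object"` or `"pixel"` (carried in the report).
#' @return object of class `eval_report` with fields `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `fscore`, `level`.
#' @export
score <- function(tp, fp, fn, level = "object") {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  level <- match.arg(level, c("object", "pixel"))
  if (tp + fp + fn == 0) {
    p <- r <- f <- 1
  } else {
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  structure(list(tp = tp, fp = fp, fn = fn, precision = p, recall = r,
                 fscore = f, level = level), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report %s: TP %d FP %d FN %d | p %.4f r %.4f F %.4f>\n",
              x$level, x$tp, x$fp, x$fn, x$precision, x$recall, x$fscore))
  invisible(x)
}

#' Evaluate a detection against a reference at object level
#' @param det a [detection_result()].
#' @param ref a [reference_annotation()].
#' @return an `eval_report`.
#' @export
evaluate_detection <- function(det, ref) {
  m <- match_objects(det, ref)
  score(m["tp"], m["fp"], m["fn"], level = "object")
}

#' Pixel-level precision/recall/F-score
#'
#' Per-pixel TP/FP/FN between a detection mask and a mask-mode reference.
#' Point-mode references cannot be scored at pixel level (point-output
#' detectors are omitted from pixel-level comparison).
#'
#' @param det_mask a [binary_mask()] (or 0/1 matrix).
#' @param ref_mask a [binary_mask()], 0/1 matrix, or a mask-mode
#'   [reference_annotation()].
#' @return an `eval_report` with `level = "pixel"`.
#' @export
pixel_score <- function(det_mask, ref_mask) {
  if (inherits(ref_mask, "reference_annotation")) {
    if (ref_mask$mode != "mask")
      stop("pixel-level scoring requires a mask-mode reference")
    ref_mask <- ref_mask$mask
  }
  d <- if (inherits(det_mask, "binary_mask")) det_mask$pixels else det_mask
  r <- if (inherits(ref_mask, "binary_mask")) ref_mask$pixels else ref_mask
  if (!identical(dim(d), dim(r))) stop("mask shapes differ")
  tp <- sum(d == 1L & r == 1L)
  fp <- sum(d == 1L & r == 0L)
  fn <- sum(d == 0L & r == 1L)
  score(tp, fp, fn, level = "pixel")
}

#' Compare per-method object-count distributions
#'
#' Kruskal-Wallis test of equal medians across all methods plus the matrix
#' of pairwise two-sided Wilcoxon rank-sum p-values (exact enumeration for
#' small samples without ties, normal approximation with tie correction
#' otherwise).
#'
#' @param counts named list (one entry per method) of per-image object
#'   counts.
#' @return list with `kruskal_H`, `kruskal_p`, `wilcoxon_p` (matrix).
#' @export
compare_count_distributions <- function(counts) {
  if (!is.list(counts) || length(counts) < 2L)
    stop("need counts for at least two methods")
  if (any(lengths(counts) < 2L))
    stop("need counts for at least two images per method")
  if (is.null(names(counts)))
    names(counts) <- paste0("method", seq_along(counts))
  kw <- kruskal.test(counts)
  n <- length(counts)
  W <- matrix(NA_real_, n, n, dimnames = list(names(counts), names(counts)))
  diag(W) <- 1
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    x <- counts[[a]]; y <- counts[[b]]
    exact <- length(x) <= 25 && length(y) <= 25 &&
      !any(duplicated(c(x, y)))
    pv <- suppressWarnings(
      wilcox.test(x, y, exact = exact, correct = !exact)$p.value)
    W[a, b] <- W[b, a] <- pv
  }
  list(kruskal_H = unname(kw$statistic), kruskal_p = kw$p.value,
       wilcoxon_p = W)
}
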