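## End-to-end experiment helpers: object counting, per-cell spot rates,
## and cross-method similarity.

#' Count detected objects
#'
#' Point-mode results report the point count; mask-mode results the number
#' of 8-connected components (or of deblended labels when the detector
#' provides them).
#'
#' @param det a [detection_result()].
#' @return integer count.
#' @export
count_objects <- function(det) {
  stopifnot(inherits(det, "detection_result"))
  if (!is.null(det$points)) return(det$points$count)
  if (!is.null(det$labels) && max(det$labels) > 0)
    return(max(det$labels))
  max(label_components_cpp(det$mask$pixels, 8L))
}

#' Spots per cell
#'
#' Cells are counted as 8-connected components of the Otsu-binarized
#' nucleus channel after a minimum-size filter (debris suppression); the
#' spot count is divided by the cell count.  Zero cells yields `NA`
#' (flagged missing, never infinity).
#'
#' @param spot_count integer number of detected spots.
#' @param nuclei_img nucleus-channel [gray_image()] or matrix.
#' @param min_size minimum nucleus component area in pixels (default 50).
#' @return spots per cell, or `NA_real_`.
#' @export
spots_per_cell <- function(spot_count, nuclei_img, min_size = 50L) {
  px <- if (inherits(nuclei_img, "gray_image")) nuclei_img$pixels
        else nuclei_img
  th <- tryCatch(otsu_threshold(px), error = function(e) NULL)
  if (is.null(th)) return(NA_real_)
  lab <- label_components_cpp((px > th) + 0L, 8L)
  if (max(lab) == 0L) return(NA_real_)
  sizes <- tabulate(lab[lab > 0], max(lab))
  n_cells <- sum(sizes >= min_size)
  if (n_cells == 0L) return(NA_real_)
  spot_count / n_cells
}

#' Cross-method similarity of object counts
#'
#' Pearson (or Spearman) correlation matrix of per-image object-count
#' vectors, plus average-linkage hierarchical clustering on the distance
#' `1 - correlation`.  Methods with constant count vectors have undefined
#' correlations (flagged `NA`) and are excluded from the clustering.
#'
#' @param counts named list (or data.frame / matrix with one column per
#'   method) of per-image object counts; at least 2 methods and 3 images.
#' @param method correlation type, `"pearson"` (default) or `"spearman"`.
#' @return list with `correlation` (matrix), `dendrogram`
#'   (stats::dendrogram or NULL), `hclust`, `linkage`.
#' @export
method_similarity <- function(counts, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  M <- if (is.list(counts) && !is.data.frame(counts))
    do.call(cbind, counts) else as.matrix(counts)
  if (ncol(M) < 2L) stop("need at least two methods")
  if (nrow(M) < 3L) stop("need at least three images")
  sds <- apply(M, 2, stats::sd)
  C <- suppressWarnings(cor(M, method = method))
  C[sds == 0, ] <- NA; C[, sds == 0] <- NA
  diag(C) <- 1
  ok <- sds > 0
  hc <- NULL; dend <- NULL
  if (sum(ok) >= 2L) {
    D <- as.dist(1 - C[ok, ok, drop = FALSE])
    hc <- hclust(D, method = "average")
    dend <- as.dendrogram(hc)
  }
  list(correlation = C, dendrogram = dend, hclust = hc,
       linkage = "average")
}

#' Plot a method-similarity heat map
#'
#' Correlations below 0.5 are rendered black, higher values on a heat
#' ramp.
#'
#' @param sim result of [method_similarity()].
#' @param ... passed to [graphics::image()].
#' @return invisibly, the reordered correlation matrix.
#' @export
plot_method_similarity <- function(sim, ...) {
  C <- sim$correlation
  ord <- if (!is.null(sim$hclust)) sim$hclust$order else seq_len(nrow(C))
  C <- C[ord, ord]
  Cc <- pmax(C, 0.5)                      # below 0.5 -> black
  cols <- c("black", grDevices::heat.colors(49))
  graphics::image(seq_len(nrow(C)), seq_len(ncol(C)), Cc, col = cols,
                  zlim = c(0.5, 1), axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1, seq_len(nrow(C)), rownames(C), las = 2)
  graphics::axis(2, seq_len(ncol(C)), colnames(C), las = 2)
  invisible(C)
}
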