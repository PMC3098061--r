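## Exhaustive grid-search parameter tuning with the F-score as objective.
## Parameters are tuned once for a whole image set, never per image, which
## mirrors how a screen is analysed in practice.

#' Parameter grid
#'
#' Cartesian product of per-parameter value lists.  Infeasible
#' combinations (those rejected by the method's parameter constructor,
#' e.g. BPF cut-offs out of order) are excluded before evaluation, so
#' dependent parameters produce a sparse point cloud rather than a full
#' lattice.
#'
#' @param method_id detector id.
#' @param ... named vectors of candidate values (natural-number parameters
#'   sparse, real-valued ones sampled more densely).
#' @return object of class `param_grid`.
#' @export
param_grid <- function(method_id, ...) {
  method_id <- match.arg(toupper(method_id), .method_ids)
  values <- list(...)
  if (length(values) > 0 &&
      (is.null(names(values)) || any(names(values) == "")))
    stop("all grid axes must be named")
  pts <- if (length(values) == 0) data.frame(row.names = 1)
         else expand.grid(values, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
  feasible <- vapply(seq_len(nrow(pts)), function(k) {
    pl <- as.list(pts[k, , drop = FALSE])
    !inherits(tryCatch(build_params(method_id, pl), error = identity),
              "error")
  }, logical(1))
  structure(list(method_id = method_id, points = pts[feasible, ,
                 drop = FALSE]), class = "param_grid")
}

#' Default parameter grids
#'
#' Small, package-chosen search ranges for each method (size parameters as
#' short integer lists, thresholds as geometric sequences); override with
#' [param_grid()] for serious tuning.
#'
#' @param method_id detector id.
#' @return a `param_grid`.
#' @export
default_grid <- function(method_id) {
  method_id <- match.arg(toupper(method_id), .method_ids)
  switch(method_id,
    BPF = param_grid("BPF", w1 = c(0.02, 0.05), w2 = c(0.1, 0.2),
                     w3 = c(0.5, 0.6), w4 = 0.9),
    FPD = param_grid("FPD", w = c(2, 3), r_pct = c(2, 4, 6, 10, 15),
                     T_s = Inf),
    HD  = param_grid("HD", sigma_L = 1.5,
                     h = c(160, 320, 640, 1280), sigma_M = 4),
    KDE = param_grid("KDE", R = c(1, 2), h = c(0.5, 1, 2),
                     kernel = c("uniform", "gaussian")),
    LC  = param_grid("LC", R = c(3, 4, 6),
                     alpha = c(1.1, 1.2, 1.3, 1.4, 1.5)),
    LEF = param_grid("LEF", th_s = c(4, 8, 12, 16, 20, 24, 32)),
    MGI = param_grid("MGI"),
    MW  = param_grid("MW", J = c(2, 3), l_d = c(0.1, 1, 10, 100)),
    SE  = param_grid("SE", block_size = c(16, 32),
                     th_detect = c(1.5, 2, 3, 4), th_bg = 0,
                     gauss_sigma = 1),
    SPL = param_grid("SPL", alpha = c(1e-3, 1e-4, 1e-5, 1e-6)),
    THE = param_grid("THE", r = c(2, 3, 5)))
}

#' Grid-search parameter tuning
#'
#' Runs the detector with every feasible grid point on all images with the
#' same parameters, pools TP/FP/FN over the set (micro-averaging, robust
#' to empty images where a per-image F is ill-posed), scores once, and
#' returns the arg-max with a deterministic tie-break (first point in grid
#' order).
#'
#' @param images list of [gray_image()].
#' @param refs list of [reference_annotation()] (mask mode required for
#'   `level = "pixel"`), same length as `images`.
#' @param method_id detector id.
#' @param grid a [param_grid()]; defaults to [default_grid()].
#' @param level `"object"` or `"pixel"`.
#' @return object of class `tuning_result`: fields `table` (one row per
#'   grid point with pooled counts and F-score), `best_params`,
#'   `best_fscore`, `level`, `method_id`.
#' @export
grid_search <- function(images, refs, method_id, grid = NULL,
                        level = "object") {
  method_id <- match.arg(toupper(method_id), .method_ids)
  level <- match.arg(level, c("object", "pixel"))
  stopifnot(length(images) >= 1, length(images) == length(refs))
  if (is.null(grid)) grid <- default_grid(method_id)
  stopifnot(inherits(grid, "param_grid"), grid$method_id == method_id)
  pts <- grid$points
  if (nrow(pts) == 0L) stop("empty feasible grid")
  rows <- vector("list", nrow(pts))
  for (k in seq_len(nrow(pts))) {
    pl <- as.list(pts[k, , drop = FALSE])
    tp <- fp <- fn <- 0L
    for (i in seq_along(images)) {
      det <- suppressWarnings(
        suppressMessages(detect_spots(images[[i]], method_id, pl)))
      m <- if (level == "object") match_objects(det, refs[[i]])
      else {
        rep <- pixel_score(det$mask, refs[[i]])
        c(tp = rep$tp, fp = rep$fp, fn = rep$fn)
      }
      tp <- tp + m["tp"]; fp <- fp + m["fp"]; fn <- fn + m["fn"]
    }
    rep <- score(tp, fp, fn, level = level)
    rows[[k]] <- cbind(pts[k, , drop = FALSE],
                       data.frame(tp = rep$tp, fp = rep$fp, fn = rep$fn,
                                  fscore = rep$fscore))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  best <- which.max(tab$fscore)          # first maximum in grid order
  structure(list(table = tab,
                 best_params = as.list(pts[best, , drop = FALSE]),
                 best_fscore = tab$fscore[best],
                 level = level, method_id = method_id),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result %s (%s level): best F = %.4f over %d grid points>\n",
              x$method_id, x$level, x$best_fscore, nrow(x$table)))
  invisible(x)
}

#' Sensitivity surface over two parameters
#'
#' For each combination of the two chosen parameters, the maximum F-score
#' over the remaining parameters (profile maximization), suitable for a
#' heat map.  With a single-parameter method the surface degenerates to a
#' curve.
#'
#' @param result a [grid_search()] result.
#' @param param_x,param_y parameter names present in the grid (`param_y`
#'   may be omitted for 1-parameter methods).
#' @return data.frame with columns `param_x`, (`param_y`,) `fscore`.
#' @export
sensitivity_surface <- function(result, param_x, param_y = NULL) {
  stopifnot(inherits(result, "tuning_result"))
  tab <- result$table
  for (pn in c(param_x, param_y))
    if (!pn %in% names(tab)) stop("unknown parameter name: ", pn)
  keys <- c(param_x, param_y)
  agg <- stats::aggregate(tab$fscore, by = tab[keys], FUN = max)
  names(agg) <- c(keys, "fscore")
  agg
}
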