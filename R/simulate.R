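## Synthetic benchmark scenes with exact ground truth: multi-channel cell
## images (nuclei / cytoplasm / spots on their own channels), focal stacks
## in which objects drift out of focus, and dose plates with a planted
## spots-per-cell profile.

#' Simulation configuration
#'
#' The defaults describe the stated benchmark world: 10 textured elliptical
#' cells with nuclei, 3 subcellular spots per cell rendered as 2-D Gaussian
#' bumps in their own channel, additive Gaussian noise, and a quarter of
#' the spots rendered out of focus with a 3x wider PSF (excluded from the
#' ground truth, since only in-focus objects count as reference objects).
#'
#' @param image_size image side in pixels (square images).
#' @param n_cells number of cells to place (0 with `empty_frame = TRUE`
#'   gives a background-plus-noise frame).
#' @param spots_per_cell fixed count, or length-2 range sampled uniformly.
#' @param spot_sigma length-2 range of in-focus spot Gaussian sigmas (px).
#' @param spot_peak spot peak intensity in the spot channel.
#' @param cell_intensity cytoplasm channel level inside cells.
#' @param nucleus_intensity nucleus channel level inside nuclei.
#' @param background additive background level on all channels.
#' @param noise_sd Gaussian noise sd added per channel.
#' @param texture_amp amplitude of the smooth intra-cell texture.
#' @param blur_fraction fraction of spots rendered out of focus.
#' @param blur_sigma_factor PSF widening factor for out-of-focus spots;
#'   a spot counts as in focus iff its rendered sigma is at most 1.5x its
#'   nominal sigma.
#' @param empty_frame if TRUE no cells or spots are drawn.
#' @param seed RNG seed (R's Mersenne-Twister; recorded in the scene).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(image_size = 128L, n_cells = 10L,
                       spots_per_cell = 3L, spot_sigma = c(1.0, 1.6),
                       spot_peak = 150, cell_intensity = 30,
                       nucleus_intensity = 60, background = 25,
                       noise_sd = 5, texture_amp = 5,
                       blur_fraction = 0.25, blur_sigma_factor = 3,
                       empty_frame = FALSE, seed = 1L) {
  stopifnot(image_size >= 32, n_cells >= 0, all(spot_sigma > 0),
            spot_peak >= 0, background >= 0, noise_sd >= 0,
            blur_fraction >= 0, blur_fraction <= 1, blur_sigma_factor >= 1)
  if (length(spots_per_cell) == 1L)
    spots_per_cell <- rep(spots_per_cell, 2L)
  if (length(spot_sigma) == 1L) spot_sigma <- rep(spot_sigma, 2L)
  structure(list(image_size = as.integer(image_size),
                 n_cells = as.integer(n_cells),
                 spots_per_cell = spots_per_cell,
                 spot_sigma = spot_sigma, spot_peak = spot_peak,
                 cell_intensity = cell_intensity,
                 nucleus_intensity = nucleus_intensity,
                 background = background, noise_sd = noise_sd,
                 texture_amp = texture_amp, blur_fraction = blur_fraction,
                 blur_sigma_factor = blur_sigma_factor,
                 empty_frame = isTRUE(empty_frame), seed = as.integer(seed)),
            class = "sim_config")
}

# mask of an ellipse (0-based center, semi-axes a >= b, angle radians)
.ellipse_mask <- function(n, ctr, a, b, th) {
  x <- matrix(rep(0:(n - 1), n), n, n)    # rows
  dx <- x - ctr[1]; dy <- t(x) - ctr[2]
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

# place non-overlapping cells; bounded retries then error
.place_cells <- function(n, n_cells) {
  cells <- list()
  tries <- 0L
  while (length(cells) < n_cells) {
    if (tries > 200L * max(n_cells, 1L))
      stop("infeasible placement: too many cells for the image size")
    tries <- tries + 1L
    a <- runif(1, 0.09, 0.14) * n
    b <- runif(1, 0.7, 1) * a
    ctr <- runif(2, a, n - 1 - a)
    ok <- TRUE
    for (cl in cells)
      if (sqrt(sum((ctr - cl$ctr)^2)) < 0.95 * (a + cl$a)) { ok <- FALSE; break }
    if (ok) cells[[length(cells) + 1L]] <-
        list(ctr = ctr, a = a, b = b, th = runif(1, 0, pi))
  }
  cells
}

# add a Gaussian bump (peak at 0-based center) to a matrix, truncated 4 sigma
.add_bump <- function(m, ctr, sigma, peak) {
  n1 <- nrow(m); n2 <- ncol(m)
  r <- ceiling(4 * sigma)
  rows <- max(1, round(ctr[1]) + 1 - r):min(n1, round(ctr[1]) + 1 + r)
  cols <- max(1, round(ctr[2]) + 1 - r):min(n2, round(ctr[2]) + 1 + r)
  ri <- matrix(rep(rows - 1, length(cols)), length(rows))
  ci <- t(matrix(rep(cols - 1, length(rows)), length(cols)))
  m[rows, cols] <- m[rows, cols] +
    peak * exp(-((ri - ctr[1])^2 + (ci - ctr[2])^2) / (2 * sigma^2))
  m
}

# core renderer shared by scene/stack/plate generators
.render_scene <- function(cfg, cells, spots) {
  n <- cfg$image_size
  red <- matrix(cfg$background, n, n)     # cytoplasm
  grn <- matrix(cfg$background, n, n)     # spots
  blu <- matrix(cfg$background, n, n)     # nuclei
  for (cl in cells) {
    em <- .ellipse_mask(n, cl$ctr, cl$a, cl$b, cl$th)
    red[em] <- red[em] + cfg$cell_intensity
    nm <- .ellipse_mask(n, cl$ctr, 0.4 * cl$a, 0.4 * cl$b, cl$th)
    blu[nm] <- blu[nm] + cfg$nucleus_intensity
  }
  if (length(cells) > 0 && cfg$texture_amp > 0) {
    tex <- gauss_smooth(matrix(rnorm(n * n), n, n), 3)
    tex <- tex / max(stats::sd(tex), 1e-12) * cfg$texture_amp
    inside <- Reduce(`|`, lapply(cells, function(cl)
      .ellipse_mask(n, cl$ctr, cl$a, cl$b, cl$th)))
    red[inside] <- pmax(red[inside] + tex[inside], 0)
  }
  grn_clean <- grn
  truth_mask <- matrix(0L, n, n)
  if (nrow(spots) > 0) {
    for (k in seq_len(nrow(spots))) {
      s <- spots[k, ]
      sig <- s$sigma * s$blur_factor
      peak <- s$peak * (s$sigma / sig)^2  # out-of-focus spreads intensity
      grn_clean <- .add_bump(grn_clean, c(s$row, s$col), sig, peak)
      if (s$in_focus) {
        single <- .add_bump(matrix(0, n, n), c(s$row, s$col), sig, peak)
        truth_mask[single > 0.5 * peak] <- 1L
      }
    }
  }
  grn <- grn_clean
  if (cfg$noise_sd > 0) {
    red <- pmax(red + matrix(rnorm(n * n, 0, cfg$noise_sd), n, n), 0)
    grn <- pmax(grn + matrix(rnorm(n * n, 0, cfg$noise_sd), n, n), 0)
    blu <- pmax(blu + matrix(rnorm(n * n, 0, cfg$noise_sd), n, n), 0)
  }
  gray <- rgb_to_gray(red, grn, blu)
  tp <- spots[spots$in_focus, c("row", "col"), drop = FALSE]
  n_merge <- if (sum(truth_mask) > 0)
    sum(spots$in_focus) - max(label_components_cpp(truth_mask, 8L)) else 0L
  structure(list(r = red, g = grn, b = blu, gray = gray,
                 truth_mask = binary_mask(truth_mask),
                 truth_points = point_list(tp),
                 spots = spots, n_merged = n_merge, config = cfg),
            class = "sim_scene")
}

#' @export
print.sim_scene <- function(x, ...) {
  cat(sprintf("<sim_scene %dx%d: %d spots (%d in focus), seed %d>\n",
              x$config$image_size, x$config$image_size, nrow(x$spots),
              sum(x$spots$in_focus), x$config$seed))
  invisible(x)
}

# draw spot table for a cell layout
.draw_spots <- function(cfg, cells) {
  spots <- list()
  for (ci in seq_along(cells)) {
    cl <- cells[[ci]]
    k <- if (cfg$spots_per_cell[1] == cfg$spots_per_cell[2])
      cfg$spots_per_cell[1]
    else sample(cfg$spots_per_cell[1]:cfg$spots_per_cell[2], 1)
    for (s in seq_len(k)) {
      repeat {
        u <- runif(1, -1, 1); v <- runif(1, -1, 1)
        if (u^2 + v^2 <= 1) break
      }
      pos <- cl$ctr + c(cos(cl$th) * u * cl$a * 0.9 - sin(cl$th) * v * cl$b * 0.9,
                        sin(cl$th) * u * cl$a * 0.9 + cos(cl$th) * v * cl$b * 0.9)
      blurred <- runif(1) < cfg$blur_fraction
      spots[[length(spots) + 1L]] <- data.frame(
        row = pos[1], col = pos[2],
        sigma = runif(1, cfg$spot_sigma[1], cfg$spot_sigma[2]),
        peak = cfg$spot_peak,
        blur_factor = if (blurred) cfg$blur_sigma_factor else 1,
        cell = ci)
    }
  }
  spots <- if (length(spots)) do.call(rbind, spots) else
    data.frame(row = numeric(0), col = numeric(0), sigma = numeric(0),
               peak = numeric(0), blur_factor = numeric(0),
               cell = integer(0))
  spots$in_focus <- spots$blur_factor <= 1.5
  spots
}

#' Generate one synthetic scene
#'
#' Places non-overlapping elliptical cells with textured cytoplasm and
#' nuclei (each structure class on its own channel), draws spots inside
#' the cells as Gaussian bumps, blurs the configured fraction (emulating
#' out-of-focus objects, which are visible but excluded from the truth),
#' adds background and noise, and records the exact ground truth: spot
#' centers and the mask of pixels where a spot's noiseless contribution
#' exceeds half its peak.  Deterministic under `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a `sim_scene`: channels `r`, `g`, `b`; `gray`
#'   ([gray_image()] via [rgb_to_gray()]); `truth_mask`; `truth_points`;
#'   per-spot metadata `spots`; merge count `n_merged`.
#' @export
generate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  cells <- if (cfg$empty_frame || cfg$n_cells == 0L) list()
           else .place_cells(cfg$image_size, cfg$n_cells)
  spots <- .draw_spots(cfg, cells)
  .render_scene(cfg, cells, spots)
}

#' Generate a focal stack
#'
#' One latent spot field is rendered at `n_frames` focus settings.
#' `focus_profile` gives the per-frame PSF widening factor applied to every
#' spot (1 = nominal focus); frames with a factor above 1.5 contain only
#' out-of-focus objects and have empty truth, emulating stacks in which
#' objects come into focus, persist in a few frames, and vanish again.
#'
#' @param cfg a [sim_config()] (`blur_fraction` is ignored; focus comes
#'   from the profile).
#' @param n_frames number of frames (`>= 1`).
#' @param focus_profile numeric vector of length `n_frames`.
#' @return list of `sim_scene` frames.
#' @export
generate_stack <- function(cfg, n_frames, focus_profile) {
  stopifnot(inherits(cfg, "sim_config"), n_frames >= 1,
            length(focus_profile) == n_frames, all(focus_profile >= 1))
  set.seed(cfg$seed)
  cells <- if (cfg$empty_frame || cfg$n_cells == 0L) list()
           else .place_cells(cfg$image_size, cfg$n_cells)
  cfg0 <- cfg; cfg0$blur_fraction <- 0
  spots <- .draw_spots(cfg0, cells)
  lapply(seq_len(n_frames), function(f) {
    sp <- spots
    if (nrow(sp) > 0) {
      sp$blur_factor <- focus_profile[f]
      sp$in_focus <- focus_profile[f] <= 1.5
    }
    set.seed(cfg$seed + 1000L * f)       # frame-specific noise stream
    .render_scene(cfg, cells, sp)
  })
}

#' Generate a synthetic dose plate
#'
#' Per dose level, `n_images` scenes whose expected spots-per-cell follows
#' the given profile (spot counts per cell drawn Poisson); the nucleus
#' channel is always present so cells can be counted downstream.
#'
#' @param cfg a [sim_config()].
#' @param dose_levels vector of dose labels.
#' @param spots_per_cell_by_dose expected spots per cell at each dose
#'   (same length as `dose_levels`).
#' @param n_images images per dose level.
#' @return list with `scenes` (list of `sim_scene`), `dose` (label per
#'   scene), `truth_counts` (in-focus spots per scene), `cell_counts`.
#' @export
generate_doseplate <- function(cfg, dose_levels, spots_per_cell_by_dose,
                               n_images = 4L) {
  stopifnot(inherits(cfg, "sim_config"),
            length(dose_levels) == length(spots_per_cell_by_dose))
  scenes <- list(); dose <- c()
  for (d in seq_along(dose_levels)) {
    for (i in seq_len(n_images)) {
      ccfg <- cfg
      ccfg$seed <- cfg$seed + 7919L * d + i
      set.seed(ccfg$seed)
      cells <- .place_cells(ccfg$image_size, ccfg$n_cells)
      lambda <- spots_per_cell_by_dose[d]
      spots <- list()
      for (ci in seq_along(cells)) {
        cl <- cells[[ci]]
        for (s in seq_len(rpois(1, lambda))) {
          repeat {
            u <- runif(1, -1, 1); v <- runif(1, -1, 1)
            if (u^2 + v^2 <= 1) break
          }
          pos <- cl$ctr +
            c(cos(cl$th) * u * cl$a * 0.9 - sin(cl$th) * v * cl$b * 0.9,
              sin(cl$th) * u * cl$a * 0.9 + cos(cl$th) * v * cl$b * 0.9)
          blurred <- runif(1) < ccfg$blur_fraction
          spots[[length(spots) + 1L]] <- data.frame(
            row = pos[1], col = pos[2],
            sigma = runif(1, ccfg$spot_sigma[1], ccfg$spot_sigma[2]),
            peak = ccfg$spot_peak,
            blur_factor = if (blurred) ccfg$blur_sigma_factor else 1,
            cell = ci)
        }
      }
      spots <- if (length(spots)) do.call(rbind, spots) else
        data.frame(row = numeric(0), col = numeric(0), sigma = numeric(0),
                   peak = numeric(0), blur_factor = numeric(0),
                   cell = integer(0))
      spots$in_focus <- if (nrow(spots)) spots$blur_factor <= 1.5 else logical(0)
      sc <- .render_scene(ccfg, cells, spots)
      scenes[[length(scenes) + 1L]] <- sc
      dose <- c(dose, dose_levels[d])
    }
  }
  list(scenes = scenes, dose = dose,
       truth_counts = vapply(scenes, function(s) sum(s$spots$in_focus),
                             numeric(1)),
       cell_counts = vapply(scenes, function(s) s$config$n_cells,
                            numeric(1)))
}
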