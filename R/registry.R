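## Uniform front end over the eleven detectors, used by the tuner and the
## CLI.  Parameters are given as a plain named list and validated by each
## method's parameter constructor.

.detector_param_fields <- list(
  BPF = c("w1", "w2", "w3", "w4"),
  FPD = c("w", "r_pct", "T_s", "lambda_n"),
  HD  = c("sigma_L", "h", "s", "sigma_M", "n_samples", "seed"),
  KDE = c("R", "h", "kernel"),
  LC  = c("R", "alpha"),
  LEF = c("th_s", "kernel_size", "inner_radius", "target_mean"),
  MGI = c("d_max", "fraction"),
  MW  = c("J", "l_d"),
  SE  = c("block_size", "th_detect", "th_bg", "gauss_sigma",
          "deblend_nslices", "deblend_min_contrast"),
  SPL = c("alpha", "psf_sigma", "max_iter", "tol"),
  THE = c("r"))

# build the method's parameter object from a plain named list;
# errors signal an infeasible combination
build_params <- function(method_id, params) {
  method_id <- match.arg(toupper(method_id), .method_ids)
  keep <- params[intersect(names(params),
                           .detector_param_fields[[method_id]])]
  switch(method_id,
    BPF = bpf_params(c(keep$w1, keep$w2, keep$w3, keep$w4)),
    FPD = do.call(fpd_params, keep),
    HD  = do.call(hd_params, keep),
    KDE = do.call(kde_params, keep),
    LC  = do.call(lc_params, keep),
    LEF = do.call(lef_params, keep),
    MGI = keep,
    MW  = do.call(mw_params, keep),
    SE  = do.call(se_params, keep),
    SPL = do.call(spl_params, keep),
    THE = do.call(the_params, keep))
}

#' Run a detector by method id
#'
#' @param img a [gray_image()].
#' @param method_id one of BPF, FPD, HD, KDE, LC, LEF, MGI, MW, SE, SPL,
#'   THE (case-insensitive).
#' @param params named list of that method's parameters (see the
#'   `*_params()` constructors); MGI takes none.
#' @param prefilter_sigma optional Gaussian [lowpass_prefilter()] sigma
#'   applied before detection (0 = off, the default).
#' @return a [detection_result()].
#' @export
detect_spots <- function(img, method_id, params = list(),
                         prefilter_sigma = 0) {
  method_id <- match.arg(toupper(method_id), .method_ids)
  img <- as_gray_image(img)
  if (prefilter_sigma > 0) img <- lowpass_prefilter(img, prefilter_sigma)
  p <- build_params(method_id, params)
  switch(method_id,
    BPF = detect_bpf(img, p),
    FPD = detect_fpd(img, p),
    HD  = detect_hd(img, p),
    KDE = detect_kde(img, p),
    LC  = detect_lc(img, p),
    LEF = detect_lef(img, p),
    MGI = do.call(detect_mgi, c(list(img), p)),
    MW  = detect_mw(img, p),
    SE  = detect_se(img, p),
    SPL = detect_spl(img, p),
    THE = detect_the(img, p))
}
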