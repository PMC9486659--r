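#' Train and serialize an estimator (pipeline step)
#'
#' @param scheme preset name (`"two_shell"`, `"hex_ball"`) or a
#'   `dmi_scheme`.
#' @param out_path output estimator JSON file.
#' @param config a [prior_config()].
#' @param quiet suppress the per-parameter training RMSE log.
#' @return the `dmi_estimator`, invisibly.
#' @export
run_train <- function(scheme, out_path, config = prior_config(),
                      quiet = FALSE) {
  t0 <- Sys.time()
  est <- train_estimator(scheme, config)
  write_estimator(est, out_path)
  if (!quiet) {
    message(sprintf("trained order-%d regressor on %d samples in %.1fs",
                    est$degree, est$n_train,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    message("training RMSE: ",
            paste(sprintf("%s=%.4f", names(est$training_rmse),
                          est$training_rmse), collapse = " "))
  }
  invisible(est)
}

#' Fit parameter maps and ADC for a measured volume (pipeline step)
#'
#' @param dwi_path,bval_path,bvec_path the DWI volume and gradient table.
#' @param mask_path brain mask NIfTI.
#' @param estimator_path trained estimator JSON (scheme must match).
#' @param out_dir output directory for the seven NIfTI maps.
#' @param adc_b,adc_tol shell selection for [compute_adc()].
#' @param quiet suppress the runtime log.
#' @return the `dmi_maps` (with `adc` field), invisibly.
#' @export
run_fit <- function(dwi_path, bval_path, bvec_path, mask_path,
                    estimator_path, out_dir, adc_b = 1.0, adc_tol = 0.1,
                    quiet = FALSE) {
  t0 <- Sys.time()
  vol <- read_dwi(dwi_path, bval_path, bvec_path)
  mask <- read_mask(mask_path)
  est <- read_estimator(estimator_path)
  maps <- predict_maps(est, vol, mask)
  maps$fields$adc <- compute_adc(vol, maps$mask, b_target = adc_b,
                                 b_tol = adc_tol)
  write_parameter_maps(maps, out_dir)
  if (!quiet)
    message(sprintf("fitted %d voxels in %.1fs -> %s", sum(maps$mask),
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    out_dir))
  invisible(maps)
}

#' ROC evaluation against the four ground-truth variants (pipeline step)
#'
#' @param maps_dir directory written by [run_fit()] (or
#'   [write_parameter_maps()]) containing `d_ax_intra` and `adc` maps.
#' @param dmi_truth_path,dwi_truth_path ground-truth segmentation NIfTIs.
#' @param brain_mask_path brain mask NIfTI.
#' @param out_csv output CSV report path.
#' @return the evaluation tibble, invisibly.
#' @export
run_evaluate <- function(maps_dir, dmi_truth_path, dwi_truth_path,
                         brain_mask_path, out_csv) {
  maps <- read_parameter_maps(maps_dir)
  if (is.null(maps$fields$adc))
    stop("maps_dir has no adc.nii.gz; run the fit step first", call. = FALSE)
  dmi_t <- read_mask(dmi_truth_path)
  dwi_t <- read_mask(dwi_truth_path)
  brain <- read_mask(brain_mask_path)
  if (sum(dmi_t) == 0 || sum(dwi_t) == 0)
    stop("empty ground-truth mask", call. = FALSE)
  tab <- evaluate_variants(
    contrasts = list(d_ax_intra = maps$fields$d_ax_intra,
                     adc = maps$fields$adc),
    dmi_truth = dmi_t, dwi_truth = dwi_t, brain_mask = brain)
  write_roc_table(tab, out_csv)
  invisible(tab)
}

#' Generate a phantom fixture on disk (pipeline step)
#'
#' @param out_dir output directory.
#' @param seed noise seed.
#' @param scheme_name preset scheme.
#' @param snr b = 0 SNR.
#' @param grid grid side length (isotropic).
#' @return invisibly, the path list from [make_fixture()].
#' @export
run_phantom <- function(out_dir, seed = 1L, scheme_name = "two_shell",
                        snr = 30, grid = 48) {
  cfg <- phantom_config(grid_shape = rep(grid, 3), snr = snr, seed = seed,
                        scheme_name = scheme_name)
  make_fixture(cfg, out_dir)
}
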