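#' Apparent diffusion coefficient map
#'
#' Conventional single-shell ADC from the b = 0 and (by default) b = 1.0
#' ms/µm² frames: `ADC = -(1/b) log(mean(S_b) / mean(S_b0))`, with the
#' arithmetic mean over directions taken before the log (trace-weighted
#' convention). Voxels with a non-positive signal ratio are excluded
#' (set `NA`).
#'
#' @param volume a `dmi_volume`.
#' @param mask 3D 0/1 array.
#' @param b_target shell to use, ms/µm² (default 1.0).
#' @param b_tol tolerance when matching the shell (default 0.1).
#' @return 3D array of ADC in µm²/ms (`NA` outside mask / excluded voxels).
#' @export
compute_adc <- function(volume, mask, b_target = 1.0, b_tol = 0.1) {
  stopifnot(inherits(volume, "dmi_volume"))
  sch <- volume$scheme
  sel <- which(!is_b0(sch) & abs(sch$bvals - b_target) <= b_tol)
  if (!length(sel))
    stop("scheme has no shell near b = ", b_target, " ms/um^2", call. = FALSE)
  b0 <- which(is_b0(sch))
  if (!length(b0)) stop("scheme has no b = 0 frame", call. = FALSE)
  b_eff <- mean(sch$bvals[sel])
  idx <- which(mask > 0)
  dims <- dim(mask)
  Sb <- rowMeans(frames_matrix(volume$data, idx)[, sel, drop = FALSE])
  S0 <- rowMeans(frames_matrix(volume$data, idx)[, b0, drop = FALSE])
  ratio <- Sb / S0
  adc <- rep(NA_real_, length(idx))
  ok <- is.finite(ratio) & ratio > 0
  adc[ok] <- -log(ratio[ok]) / b_eff
  out <- array(NA_real_, dims)
  out[idx] <- adc
  out
}

#' Mean high-b diffusion-weighted image
#'
#' Arithmetic mean over all weightings with b >= `b_min` (the conventional
#' "mean DWI" contrast, e.g. b >= 1.8 ms/µm²).
#'
#' @param volume a `dmi_volume`.
#' @param b_min lower b cutoff, ms/µm².
#' @return 3D array.
#' @export
mean_dwi <- function(volume, b_min = 1.8) {
  sel <- which(volume$scheme$bvals >= b_min - 1e-9)
  if (!length(sel))
    stop("no weightings with b >= ", b_min, " ms/um^2", call. = FALSE)
  d <- volume$data[, , , sel, drop = FALSE]
  apply(d, 1:3, mean)
}
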