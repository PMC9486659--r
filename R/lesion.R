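#' Youden's J statistic
#' @param sens,spec sensitivity and specificity, each in [0, 1].
#' @return `sens + spec - 1` (vectorized).
#' @export
youden <- function(sens, spec) {
  if (any(sens < 0 | sens > 1 | spec < 0 | spec > 1, na.rm = TRUE))
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  sens + spec - 1
}

#' Threshold-based lesion segmentation
#'
#' Infarct-core convention: lesion voxels are those with map value BELOW the
#' threshold (both the ADC < 0.620 µm²/ms guide and the D_ax_intra contrast
#' drop inside the core).
#'
#' @param map 3D array of a scalar contrast.
#' @param tau threshold, map units.
#' @param mask 3D 0/1 array restricting the segmentation.
#' @param direction only `"below"` is defined for infarct contrasts.
#' @return 3D integer 0/1 mask.
#' @export
threshold_segment <- function(map, tau, mask, direction = "below") {
  direction <- match.arg(direction, "below")
  if (!identical(dim(map), dim(mask)))
    stop("map and mask shapes differ", call. = FALSE)
  out <- array(0L, dim(map))
  sel <- which(mask > 0 & !is.na(map) & map < tau)
  out[sel] <- 1L
  out
}

#' Combine two binary masks
#' @param a,b congruent 0/1 arrays.
#' @param mode `"union"` (voxelwise OR) or `"intersection"` (AND).
#' @return 0/1 array.
#' @export
combine_masks <- function(a, b, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (!identical(dim(a), dim(b))) stop("mask shapes differ", call. = FALSE)
  out <- if (mode == "union") (a > 0) | (b > 0) else (a > 0) & (b > 0)
  array(as.integer(out), dim(a))
}

#' Mirror a mask across the x midline
#'
#' Contralateral mirroring on a midline-aligned grid: voxel (x, y, z) maps to
#' (W - 1 - x, y, z) (0-based), i.e. the first array dimension is reversed.
#' An optional clip mask (e.g. brain-without-CSF) is intersected afterwards.
#'
#' @param mask 3D 0/1 array.
#' @param clip_mask optional congruent 0/1 array.
#' @return 0/1 array.
#' @export
mirror_mask <- function(mask, clip_mask = NULL) {
  out <- mask[dim(mask)[1]:1, , , drop = FALSE]
  dim(out) <- dim(mask)
  if (!is.null(clip_mask)) out <- combine_masks(out, clip_mask, "intersection")
  array(as.integer(out > 0), dim(mask))
}

## ---- ROC ----------------------------------------------------------------

# exact empirical ROC on pooled voxel values; positives are scores < tau
roc_from_values <- function(score, truth) {
  ok <- is.finite(score) & !is.na(truth)
  score <- score[ok]; truth <- as.logical(truth[ok])
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0) stop("no lesion voxels in pooled set; sensitivity undefined",
                       call. = FALSE)
  if (n_neg == 0) stop("no background voxels in pooled set", call. = FALSE)
  us <- sort(unique(score))
  K <- length(us)
  taus <- c(-Inf, us, Inf)
  # cumulative counts with score <= us[i]; strictly-below counts at tau =
  # us[i] are the cumulative counts through us[i-1]
  pos_le <- cumsum(tabulate(match(score[truth], us), K))
  neg_le <- cumsum(tabulate(match(score[!truth], us), K))
  pos_lt <- c(0, pos_le[seq_len(K - 1)])
  neg_lt <- c(0, neg_le[seq_len(K - 1)])
  sens <- c(0, pos_lt, n_pos) / n_pos
  fpr <- c(0, neg_lt, n_neg) / n_neg
  spec <- 1 - fpr
  j <- sens + spec - 1
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  jm <- max(j)
  opt_i <- which(j >= jm - 1e-12)[1]  # ties -> lowest threshold
  structure(list(
    curve = tibble::tibble(threshold = taus, sensitivity = sens,
                           specificity = spec, youden = j),
    auc = auc, j_max = jm, optimal_threshold = taus[opt_i],
    sens_at_opt = sens[opt_i], spec_at_opt = spec[opt_i],
    n_pos = n_pos, n_neg = n_neg, direction = "below"),
    class = "dmi_roc")
}

#' Pooled-voxel ROC analysis
#'
#' Pools in-mask voxels across subjects, sweeps every observed value (plus
#' ±Inf) as a "lesion = score below threshold" rule, and reports the exact
#' empirical ROC: AUC by trapezoid (equal to the pairwise concordance
#' probability with ties counted 1/2), the Youden maximum, and the optimal
#' threshold (ties broken toward the lower, more specific threshold).
#'
#' @param score_maps a 3D array or list of per-subject 3D arrays.
#' @param truth_masks congruent 0/1 array(s) marking lesion voxels.
#' @param brain_masks optional congruent 0/1 array(s); voxels outside are
#'   excluded (brain-stripping).
#' @return a `dmi_roc` object; see [glance.dmi_roc()], [autoplot.dmi_roc()].
#' @export
pooled_roc <- function(score_maps, truth_masks, brain_masks = NULL) {
  if (!is.list(score_maps)) score_maps <- list(score_maps)
  if (!is.list(truth_masks)) truth_masks <- list(truth_masks)
  if (!is.null(brain_masks) && !is.list(brain_masks))
    brain_masks <- list(brain_masks)
  stopifnot(length(score_maps) == length(truth_masks))
  sc <- list(); tr <- list()
  for (i in seq_along(score_maps)) {
    m <- score_maps[[i]]; t <- truth_masks[[i]]
    if (!identical(dim(m), dim(t)))
      stop("subject ", i, ": score and truth shapes differ", call. = FALSE)
    keep <- if (is.null(brain_masks)) !is.na(m) else (brain_masks[[i]] > 0) & !is.na(m)
    sc[[i]] <- m[keep]; tr[[i]] <- (t > 0)[keep]
  }
  roc_from_values(unlist(sc), unlist(tr))
}

#' @export
print.dmi_roc <- function(x, ...) {
  cat(sprintf(
    "<dmi_roc> %d lesion / %d background voxels\n  AUC %.4f | Jmax %.4f at threshold %.4g (sens %.3f, spec %.3f)\n",
    x$n_pos, x$n_neg, x$auc, x$j_max, x$optimal_threshold,
    x$sens_at_opt, x$spec_at_opt))
  invisible(x)
}

#' Tidy the ROC curve
#' @param x a `dmi_roc`.
#' @param ... unused.
#' @return tibble of threshold, sensitivity, specificity, youden.
#' @export
tidy.dmi_roc <- function(x, ...) x$curve

#' One-row ROC summary
#' @param x a `dmi_roc`.
#' @param ... unused.
#' @return tibble with auc, j_max, optimal_threshold, sens, spec, counts.
#' @export
glance.dmi_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, j_max = x$j_max,
                 optimal_threshold = x$optimal_threshold,
                 sens = x$sens_at_opt, spec = x$spec_at_opt,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Plot a ROC curve with its Youden-optimal operating point
#' @param object a `dmi_roc`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dmi_roc <- function(object, ...) {
  cv <- object$curve
  opt <- tibble::tibble(fpr = 1 - object$spec_at_opt, tpr = object$sens_at_opt)
  ggplot2::ggplot(cv, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = opt, ggplot2::aes(x = .data$fpr, y = .data$tpr),
                        colour = "red", size = 2) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC %.3f, Jmax %.3f at %.3g",
                                  object$auc, object$j_max,
                                  object$optimal_threshold)) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Descriptive lesion statistics
#'
#' Mean and 5th/95th percentiles (linear-interpolation convention, R type 7)
#' of each parameter map inside the lesion and inside a contralateral region.
#'
#' @param maps a `dmi_maps`.
#' @param lesion 3D 0/1 lesion mask.
#' @param contra 3D 0/1 contralateral mask (e.g. [mirror_mask()] output).
#' @return tibble with columns parameter, region, mean, p5, p95, n_voxels.
#' @export
lesion_statistics <- function(maps, lesion, contra) {
  stopifnot(inherits(maps, "dmi_maps"))
  if (sum(lesion > 0) == 0 || sum(contra > 0) == 0)
    stop("empty lesion or contralateral mask", call. = FALSE)
  one_region <- function(msk, region) {
    idx <- which(msk > 0 & maps$mask > 0)
    purrr::map_dfr(names(maps$fields), function(p) {
      v <- maps$fields[[p]][idx]
      v <- v[!is.na(v)]
      q <- stats::quantile(v, c(0.05, 0.95), names = FALSE, type = 7)
      tibble::tibble(parameter = p, region = region, mean = mean(v),
                     p5 = q[1], p95 = q[2], n_voxels = length(v))
    })
  }
  dplyr::bind_rows(one_region(lesion, "lesion"),
                   one_region(contra, "contralateral"))
}

#' Evaluate segmentation contrasts against ground-truth variants
#'
#' The cross-validation design for infarct-core segmentation: each contrast
#' (D_ax_intra, ADC; lesion = value below threshold) is swept against four
#' ground-truth variants — the DMI-based mask, the DWI-based mask, their
#' intersection and their union.
#'
#' @param contrasts named list of 3D score maps, e.g.
#'   `list(d_ax_intra = ..., adc = ...)`.
#' @param dmi_truth,dwi_truth 0/1 ground-truth masks.
#' @param brain_mask 0/1 mask for brain-stripping.
#' @return tibble with columns ground_truth_variant, contrast, auc, j_max,
#'   optimal_threshold, sens, spec.
#' @export
evaluate_variants <- function(contrasts, dmi_truth, dwi_truth, brain_mask) {
  variants <- list(
    dmi = dmi_truth,
    dwi = dwi_truth,
    intersection = combine_masks(dmi_truth, dwi_truth, "intersection"),
    union = combine_masks(dmi_truth, dwi_truth, "union"))
  purrr::map_dfr(names(variants), function(v) {
    purrr::map_dfr(names(contrasts), function(ct) {
      r <- pooled_roc(contrasts[[ct]], variants[[v]], brain_mask)
      dplyr::mutate(glance(r)[, c("auc", "j_max", "optimal_threshold",
                                  "sens", "spec")],
                    ground_truth_variant = v, contrast = ct, .before = 1)
    })
  })
}

#' Write an evaluation table as CSV
#' @param table tibble from [evaluate_variants()].
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_roc_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}
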