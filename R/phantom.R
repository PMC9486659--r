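#' Digital stroke phantom configuration
#'
#' A spherical "brain" with concentric tissue classes — CSF rim, cortical
#' gray-matter ribbon, white-matter core and a central CSF ventricle — plus a
#' spherical ischemic lesion inside the white matter of one hemisphere.
#' Inside the lesion all three diffusivities are reduced (axial intra-axonal
#' most strongly), the intra-axonal fraction is increased and the
#' extra-axonal and free-water fractions are reduced, the qualitative acute
#' stroke pattern. All tissue parameter values are conventions of this
#' phantom, not measured values; defaults put healthy white matter at
#' D_ax_intra = 2.4 and the lesion at 1.4 µm²/ms so the separating boundary
#' sits near 2 µm²/ms, and ADC at roughly 0.74 (WM), 0.65 (GM) and 0.45
#' (lesion) µm²/ms around the conventional 0.620 infarct guide.
#'
#' @param grid_shape integer triple, voxel grid (default 48^3).
#' @param brain_radius,csf_rim,gm_ribbon geometry in voxels: brain sphere
#'   radius, rim thickness, ribbon thickness.
#' @param ventricle_radius central CSF sphere radius.
#' @param lesion_center,lesion_radius lesion sphere (voxel coordinates;
#'   default offset into the +x hemisphere).
#' @param tissues named list of per-tissue parameter lists (fields of
#'   [microstructure_params()] plus `kappa`); defaults described above.
#' @param snr b = 0 signal-to-noise ratio of the synthetic acquisition.
#' @param seed integer seed (mandatory; drives the noise only — the
#'   geometry and truth masks are deterministic).
#' @param scheme_name preset scheme for [phantom_dataset()].
#' @param s0 b = 0 intensity scale.
#' @return a `dmi_phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(48, 48, 48),
                           brain_radius = 20, csf_rim = 2, gm_ribbon = 4,
                           ventricle_radius = 4,
                           lesion_center = NULL, lesion_radius = 5,
                           tissues = default_tissues(),
                           snr = 30, seed = 1L,
                           scheme_name = "two_shell", s0 = 1000) {
  grid_shape <- as.integer(grid_shape)
  ctr <- (grid_shape + 1) / 2
  if (is.null(lesion_center)) lesion_center <- ctr + c(7, 0, 0)
  if (sqrt(sum((lesion_center - ctr)^2)) + lesion_radius >
      brain_radius - csf_rim - gm_ribbon + 1e-9)
    stop("lesion must lie inside the white-matter core", call. = FALSE)
  for (tn in c("wm", "gm", "csf", "lesion")) {
    tp <- tissues[[tn]]
    if (is.null(tp)) stop("missing tissue spec: ", tn, call. = FALSE)
    do.call(microstructure_params, tp[DMI_PARAMS])  # validates the override
  }
  if (is.null(seed)) stop("seed is mandatory", call. = FALSE)
  structure(list(grid_shape = grid_shape, brain_radius = brain_radius,
                 csf_rim = csf_rim, gm_ribbon = gm_ribbon,
                 ventricle_radius = ventricle_radius,
                 lesion_center = lesion_center, lesion_radius = lesion_radius,
                 tissues = tissues, snr = snr, seed = as.integer(seed),
                 scheme_name = scheme_name, s0 = s0),
            class = "dmi_phantom_config")
}

#' Default phantom tissue parameters (convention values)
#' @return named list of tissue parameter lists.
#' @export
default_tissues <- function() {
  list(
    wm = list(v_intra = 0.45, v_extra = 0.45, v_csf = 0.10,
              d_ax_intra = 2.4, d_ax_extra = 1.2, d_rad_extra = 0.5,
              kappa = 64),
    gm = list(v_intra = 0.35, v_extra = 0.55, v_csf = 0.10,
              d_ax_intra = 2.0, d_ax_extra = 1.0, d_rad_extra = 0.5,
              kappa = 4),
    csf = list(v_intra = 0, v_extra = 0, v_csf = 1,
               d_ax_intra = 3.0, d_ax_extra = 3.0, d_rad_extra = 1.5,
               kappa = 0),
    lesion = list(v_intra = 0.65, v_extra = 0.30, v_csf = 0.05,
                  d_ax_intra = 1.4, d_ax_extra = 0.7, d_rad_extra = 0.3,
                  kappa = 64))
}

# tissue label codes
PHANTOM_LABELS <- c(background = 0L, csf_rim = 1L, gm = 2L, wm = 3L,
                    ventricle = 4L, lesion = 5L)

label_to_tissue <- c("csf", "gm", "wm", "csf", "lesion")  # codes 1..5

#' Generate the stroke phantom
#'
#' Deterministic given the config: builds the tissue label map, the
#' ground-truth parameter fields (with a one-voxel partial-volume layer at
#' tissue boundaries mixing the two neighboring tissues 50/50, so that ROC
#' tests see non-separable voxels), the lesion truth mask and the brain mask.
#'
#' @param config a [phantom_config()].
#' @return list with `param_field` (arrays for [simulate_volume()]),
#'   `labels` (3D integer tissue codes), `lesion_mask`, `brain_mask`,
#'   `csf_mask`, `truth_maps` (a `dmi_maps` of the noiseless ground-truth
#'   parameters), and `config`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "dmi_phantom_config"))
  gs <- config$grid_shape
  ctr <- (gs + 1) / 2
  co <- arrayInd(seq_len(prod(gs)), gs)
  r <- sqrt((co[, 1] - ctr[1])^2 + (co[, 2] - ctr[2])^2 + (co[, 3] - ctr[3])^2)
  labels <- array(PHANTOM_LABELS[["background"]], gs)
  wm_radius <- config$brain_radius - config$csf_rim - config$gm_ribbon
  labels[r <= config$brain_radius] <- PHANTOM_LABELS[["csf_rim"]]
  labels[r <= config$brain_radius - config$csf_rim] <- PHANTOM_LABELS[["gm"]]
  labels[r <= wm_radius] <- PHANTOM_LABELS[["wm"]]
  labels[r <= config$ventricle_radius] <- PHANTOM_LABELS[["ventricle"]]
  rl <- sqrt((co[, 1] - config$lesion_center[1])^2 +
               (co[, 2] - config$lesion_center[2])^2 +
               (co[, 3] - config$lesion_center[3])^2)
  lesion <- array(as.integer(rl <= config$lesion_radius &
                               labels == PHANTOM_LABELS[["wm"]]), gs)
  labels[lesion > 0] <- PHANTOM_LABELS[["lesion"]]
  brain <- array(as.integer(labels > 0), gs)
  csf_mask <- array(as.integer(labels %in% PHANTOM_LABELS[c("csf_rim", "ventricle")]), gs)

  tiss_mat <- t(vapply(label_to_tissue, function(tn) {
    tp <- config$tissues[[tn]]
    c(tp$v_intra, tp$v_extra, tp$v_csf, tp$d_ax_intra, tp$d_ax_extra,
      tp$d_rad_extra, tp$kappa)
  }, numeric(7)))
  colnames(tiss_mat) <- c(DMI_PARAMS, "kappa")

  idx <- which(brain > 0)
  lab <- labels[idx]
  P <- tiss_mat[lab, , drop = FALSE]

  # one-voxel partial-volume layer: voxels with a 6-neighbor of a different
  # (in-brain) tissue get the 50/50 mix of own and modal neighbor tissue
  nb_lab <- neighbor_mode_label(labels, idx)
  mix <- which(nb_lab > 0 & nb_lab != lab)
  if (length(mix)) {
    P[mix, ] <- 0.5 * P[mix, , drop = FALSE] +
      0.5 * tiss_mat[nb_lab[mix], , drop = FALSE]
  }

  param_field <- lapply(seq_len(ncol(P)), function(j) {
    a <- array(NA_real_, gs); a[idx] <- P[, j]; a
  })
  names(param_field) <- colnames(P)
  param_field$mu_x <- array(0, gs); param_field$mu_y <- array(0, gs)
  param_field$mu_z <- array(1, gs)

  fields <- param_field[DMI_PARAMS]
  truth_maps <- parameter_maps(fields, brain, check = TRUE)
  list(param_field = param_field, labels = labels, lesion_mask = lesion,
       brain_mask = brain, csf_mask = csf_mask, truth_maps = truth_maps,
       config = config)
}

# modal different-label among 6-neighbors, 0 where none differs / background
neighbor_mode_label <- function(labels, idx) {
  gs <- dim(labels)
  co <- arrayInd(idx, gs)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  nb <- matrix(0L, length(idx), 6)
  for (s in seq_len(6)) {
    cc <- sweep(co, 2, shifts[s, ], "+")
    ok <- cc[, 1] >= 1 & cc[, 1] <= gs[1] & cc[, 2] >= 1 & cc[, 2] <= gs[2] &
      cc[, 3] >= 1 & cc[, 3] <= gs[3]
    lin <- rep(NA_integer_, length(idx))
    lin[ok] <- (cc[ok, 3] - 1L) * gs[1] * gs[2] + (cc[ok, 2] - 1L) * gs[1] + cc[ok, 1]
    v <- rep(0L, length(idx))
    v[ok] <- labels[lin[ok]]
    nb[, s] <- v
  }
  own <- labels[idx]
  out <- integer(length(idx))
  differs <- nb != own & nb > 0
  any_diff <- rowSums(differs) > 0
  for (i in which(any_diff)) {
    tb <- table(nb[i, differs[i, ]])
    out[i] <- as.integer(names(tb)[which.max(tb)])
  }
  out
}

#' Add Rician noise to a DWI volume
#'
#' Magnitude-MRI noise: `S' = sqrt((S + n1)^2 + n2^2)` with independent
#' Gaussian channels of standard deviation `s0 / snr`, where s0 is the
#' volume's b = 0 intensity scale. Deterministic given `seed`.
#'
#' @param volume a `dmi_volume`.
#' @param snr b = 0 SNR, > 0 (use `Inf` for a no-op).
#' @param seed integer seed.
#' @param s0 intensity scale; default: mean b = 0 intensity over non-zero
#'   voxels.
#' @return a `dmi_volume`.
#' @export
add_rician_noise <- function(volume, snr, seed, s0 = NULL) {
  stopifnot(inherits(volume, "dmi_volume"))
  if (is.na(snr) || snr <= 0) stop("snr must be > 0", call. = FALSE)
  if (is.infinite(snr)) return(volume)
  if (is.null(s0)) {
    b0d <- volume$data[, , , is_b0(volume$scheme), drop = FALSE]
    s0 <- mean(b0d[b0d > 0])
  }
  sigma <- s0 / snr
  d <- volume$data
  noisy <- with_seed(seed, {
    n1 <- array(stats::rnorm(length(d), sd = sigma), dim(d))
    n2 <- array(stats::rnorm(length(d), sd = sigma), dim(d))
    sqrt((d + n1)^2 + n2^2)
  })
  dwi_volume(noisy, volume$scheme, volume$voxel_size)
}

#' Simulate the complete phantom acquisition
#'
#' [generate_phantom()] -> [simulate_volume()] -> [add_rician_noise()].
#' @param config a [phantom_config()].
#' @return list: everything from [generate_phantom()] plus `volume` (noisy
#'   `dmi_volume`), `noiseless` (noise-free `dmi_volume`) and `scheme`.
#' @export
phantom_dataset <- function(config = phantom_config()) {
  ph <- generate_phantom(config)
  scheme <- preset_scheme(config$scheme_name)
  clean <- simulate_volume(ph$param_field, scheme, s0 = config$s0,
                           mask = ph$brain_mask)
  noisy <- add_rician_noise(clean, config$snr, seed = config$seed,
                            s0 = config$s0)
  c(ph, list(volume = noisy, noiseless = clean, scheme = scheme))
}

#' Morphological perturbation of a mask (synthetic rater variability)
#'
#' One-step 6-neighborhood erosion or dilation, used to derive imperfect
#' "manual" ground-truth variants from the phantom truth.
#'
#' @param mask 3D 0/1 array.
#' @param op `"erode"` or `"dilate"`.
#' @param within optional 0/1 array bounding a dilation (e.g. brain mask).
#' @return 0/1 array.
#' @export
perturb_mask <- function(mask, op = c("erode", "dilate"), within = NULL) {
  op <- match.arg(op)
  gs <- dim(mask)
  m <- mask > 0
  shifted <- function(s) {
    out <- array(FALSE, gs)
    src <- list(seq_len(gs[1]), seq_len(gs[2]), seq_len(gs[3]))
    dst <- src
    for (a in 1:3) {
      if (s[a] == 1) { dst[[a]] <- 2:gs[a]; src[[a]] <- 1:(gs[a] - 1) }
      if (s[a] == -1) { dst[[a]] <- 1:(gs[a] - 1); src[[a]] <- 2:gs[a] }
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  acc <- m
  for (s in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
    acc <- if (op == "dilate") acc | shifted(s) else acc & shifted(s)
  }
  if (op == "dilate" && !is.null(within)) acc <- acc & (within > 0)
  array(as.integer(acc), gs)
}

#' Write a complete phantom fixture to disk
#'
#' Writes the NIfTI volume, FSL gradient table, truth masks, tissue labels,
#' noiseless truth parameter maps and a JSON config echo — a full input set
#' for an end-to-end pipeline run.
#'
#' @param config a [phantom_config()].
#' @param out_dir output directory.
#' @return invisibly, named list of written paths.
#' @export
make_fixture <- function(config, out_dir) {
  ds <- phantom_dataset(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vs <- ds$volume$voxel_size
  paths <- list(
    dwi = file.path(out_dir, "dwi.nii.gz"),
    bval = file.path(out_dir, "dwi.bval"),
    bvec = file.path(out_dir, "dwi.bvec"),
    brain_mask = file.path(out_dir, "brain_mask.nii.gz"),
    lesion_truth = file.path(out_dir, "lesion_truth.nii.gz"),
    csf_mask = file.path(out_dir, "csf_mask.nii.gz"),
    labels = file.path(out_dir, "tissue_labels.nii.gz"),
    truth_maps = file.path(out_dir, "truth_maps"),
    config = file.path(out_dir, "phantom_config.json"))
  write_dwi(ds$volume, paths$dwi, paths$bval, paths$bvec)
  write_mask(ds$brain_mask, paths$brain_mask, vs)
  write_mask(ds$lesion_mask, paths$lesion_truth, vs)
  write_mask(ds$csf_mask, paths$csf_mask, vs)
  write_nifti_array(array(as.double(ds$labels), dim(ds$labels)), paths$labels, vs)
  write_parameter_maps(ds$truth_maps, paths$truth_maps)
  cfg <- unclass(config)
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
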