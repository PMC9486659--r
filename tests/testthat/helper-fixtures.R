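# Shared fixtures, built lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

two_shell <- function() cached("two_shell", preset_scheme("two_shell"))
hex_ball <- function() cached("hex_ball", preset_scheme("hex_ball"))

# a quick estimator for plumbing tests (small but valid training set)
quick_estimator <- function() {
  cached("quick_estimator",
         train_estimator(two_shell(), prior_config(n_samples = 2000, seed = 7)))
}

# the reference estimator used by the heavier recovery/acceptance checks
full_estimator <- function() {
  cached("full_estimator",
         train_estimator(two_shell(), prior_config(n_samples = 20000, seed = 11)))
}

# small phantom for plumbing tests (not the acceptance conditions)
small_phantom_config <- function(seed = 3, scheme_name = "two_shell") {
  phantom_config(grid_shape = c(24, 24, 24), brain_radius = 10, csf_rim = 1,
                 gm_ribbon = 2, ventricle_radius = 2,
                 lesion_center = c(16.5, 12.5, 12.5), lesion_radius = 3,
                 snr = 30, seed = seed, scheme_name = scheme_name)
}

small_phantom <- function() cached("small_phantom",
                                   phantom_dataset(small_phantom_config()))

# the default-conditions phantom of the end-to-end acceptance checks
default_phantom <- function() cached("default_phantom",
                                     phantom_dataset(phantom_config(seed = 1)))

# random rotation matrix (uniform via QR of a Gaussian matrix)
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_d) %*% diag(sign(diag(qr.R(qr_d))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# canonical WM-like single-voxel parameter set
wm_params <- function() microstructure_params(0.45, 0.45, 0.10, 2.4, 1.2, 0.5)
csf_params <- function() microstructure_params(0, 0, 1, 3, 3, 1.5)

# build a dmi_volume where every in-mask voxel carries the given per-frame
# signal vector (scaled by s0)
uniform_volume <- function(signals, scheme, dims = c(4, 4, 4), s0 = 1) {
  data <- array(0, c(dims, length(scheme)))
  for (f in seq_along(signals)) data[, , , f] <- signals[f] * s0
  dwi_volume(data, scheme, voxel_size = c(1.5, 1.5, 5))
}

full_mask <- function(dims = c(4, 4, 4)) array(1L, dims)

# analytic spherical mean of the stick compartment exp(-b d t^2)
stick_spherical_mean <- function(bd) {
  ifelse(bd <= 0, 1, sqrt(pi / (4 * bd)) * pracma::erf(sqrt(bd)))
}

# analytic spherical mean of a full parameter set at one b
analytic_spherical_mean <- function(params, b) {
  with(params,
       v_intra * stick_spherical_mean(b * d_ax_intra) +
         v_extra * exp(-b * d_rad_extra) *
           stick_spherical_mean(b * (d_ax_extra - d_rad_extra)) +
         v_csf * exp(-b * 3))
}
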