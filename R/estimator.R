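#' Prior configuration for the simulation-trained estimator
#'
#' The training prior spans the biophysical range of the standard model:
#' flat Dirichlet(1,1,1) on the fraction simplex; uniform diffusivities
#' `d_ax_intra`, `d_ax_extra` on [0, 3] µm²/ms and `d_rad_extra` on
#' [0, 1.5] µm²/ms, rejection-sampled under the branch constraint
#' `d_ax_intra > d_ax_extra + 2 * d_rad_extra`; uniform Watson dispersion
#' (log-spaced kappa) and uniform random mean directions as mesostructure
#' nuisance; SNR marginalized uniformly over `snr_range` (defined at b = 0).
#' The prior is deliberately generic — not adapted to stroke tissue.
#'
#' @param n_samples number of training samples (>= 10 x 20 polynomial terms).
#' @param d_ax_intra_range,d_ax_extra_range,d_rad_extra_range diffusivity
#'   ranges, µm²/ms.
#' @param kappa_range Watson concentration range (sampled log-uniformly,
#'   with 0 mapped from the lower bound if it is 0).
#' @param snr_range b = 0 SNR range for Rician training noise; use
#'   `c(Inf, Inf)` for noiseless training.
#' @param seed integer RNG seed (mandatory: the estimator is deterministic).
#' @return a `dmi_prior` list.
#' @export
prior_config <- function(n_samples = 20000,
                         d_ax_intra_range = c(0, 3),
                         d_ax_extra_range = c(0, 3),
                         d_rad_extra_range = c(0, 1.5),
                         kappa_range = c(0, 64),
                         snr_range = c(15, 60),
                         seed = 1L) {
  rng <- list(d_ax_intra_range, d_ax_extra_range, d_rad_extra_range)
  for (r in rng) {
    if (length(r) != 2L || r[1] < 0 || r[2] > 3 || r[1] >= r[2])
      stop("diffusivity ranges must be increasing and within [0, 3]", call. = FALSE)
  }
  if (d_ax_intra_range[2] <= d_ax_extra_range[1])
    stop("empty admissible region under the branch constraint", call. = FALSE)
  if (n_samples < 200)
    stop("n_samples must be at least 10x the 20 polynomial terms", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 d_ax_intra_range = d_ax_intra_range,
                 d_ax_extra_range = d_ax_extra_range,
                 d_rad_extra_range = d_rad_extra_range,
                 kappa_range = kappa_range, snr_range = snr_range,
                 seed = as.integer(seed)),
            class = "dmi_prior")
}

#' Sample the biophysical prior
#'
#' Rejection sampling under `d_ax_intra > d_ax_extra + 2 * d_rad_extra`;
#' deterministic given `config$seed`.
#'
#' @param config a [prior_config()].
#' @return tibble with one row per sample: fractions, diffusivities, Watson
#'   `kappa`, mean direction `mu_x, mu_y, mu_z`, and `snr`. Attribute
#'   `"acceptance_rate"` records the fraction of raw draws accepted.
#' @export
sample_prior <- function(config) {
  stopifnot(inherits(config, "dmi_prior"))
  n <- config$n_samples
  out <- with_seed(config$seed, {
    acc_num <- 0; acc_den <- 0
    draws <- list()
    got <- 0L
    while (got < n) {
      m <- max(2L * (n - got), 1000L)
      dai <- stats::runif(m, config$d_ax_intra_range[1], config$d_ax_intra_range[2])
      dae <- stats::runif(m, config$d_ax_extra_range[1], config$d_ax_extra_range[2])
      dre <- stats::runif(m, config$d_rad_extra_range[1], config$d_rad_extra_range[2])
      ok <- dai > dae + 2 * dre
      acc_num <- acc_num + sum(ok); acc_den <- acc_den + m
      if (any(ok)) {
        k <- which(ok)[seq_len(min(sum(ok), n - got))]
        draws[[length(draws) + 1L]] <- cbind(dai[k], dae[k], dre[k])
        got <- got + length(k)
      }
      if (acc_den > 1e7 && acc_num == 0)
        stop("admissible region appears empty", call. = FALSE)
    }
    D <- do.call(rbind, draws)
    # flat Dirichlet(1,1,1) via normalized exponentials
    E <- matrix(stats::rexp(3 * n), n, 3)
    V <- E / rowSums(E)
    # log-uniform kappa (lower bound 0 maps to exactly 0 with prob of its cell)
    klo <- max(config$kappa_range[1], 0.25)
    kap <- exp(stats::runif(n, log(klo), log(max(config$kappa_range[2], klo + 1e-6))))
    if (config$kappa_range[1] <= 0) {
      kap[stats::runif(n) < 0.15] <- 0   # include truly uniform ODFs
    }
    mu <- matrix(stats::rnorm(3 * n), n, 3)
    mu <- mu / sqrt(rowSums(mu^2))
    snr <- if (all(is.infinite(config$snr_range))) rep(Inf, n)
           else stats::runif(n, config$snr_range[1], config$snr_range[2])
    tb <- tibble::tibble(
      v_intra = V[, 1], v_extra = V[, 2], v_csf = V[, 3],
      d_ax_intra = D[, 1], d_ax_extra = D[, 2], d_rad_extra = D[, 3],
      kappa = kap, mu_x = mu[, 1], mu_y = mu[, 2], mu_z = mu[, 3], snr = snr)
    attr(tb, "acceptance_rate") <- acc_num / acc_den
    tb
  })
  out
}

# run code under a temporary RNG state (restores any prior state after)
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Build a simulated training set
#'
#' For each prior sample: noiseless dispersed signals on the scheme, Rician
#' noise at the sample's SNR (sigma = s0/snr, s0 = 1), then the same feature
#' computation used at inference time.
#'
#' @param samples tibble from [sample_prior()].
#' @param scheme a `dmi_scheme`.
#' @param noise_seed seed for the training noise (separate from the prior
#'   seed so the two sources of randomness are independent).
#' @return list with `features` (n x 3 matrix), `targets` (n x 6 matrix in
#'   [DMI_PARAMS] order), `valid` (logical; rows with degenerate noisy b0).
#' @export
build_training_set <- function(samples, scheme, noise_seed = 2L) {
  theta <- as.list(samples[c(DMI_PARAMS, "kappa", "mu_x", "mu_y", "mu_z")])
  S <- batch_signals(theta, scheme)
  snr <- samples$snr
  if (any(is.finite(snr))) {
    sigma <- ifelse(is.finite(snr), 1 / snr, 0)
    S <- with_seed(noise_seed, rician_matrix(S, sigma))
  }
  ft <- features_from_signals(S, scheme)
  targets <- as.matrix(samples[DMI_PARAMS])
  list(features = ft$features, targets = targets, valid = ft$valid)
}

# Rician corruption of a signal matrix, per-row sigma (0 = noiseless)
rician_matrix <- function(S, sigma) {
  n <- nrow(S); Fm <- ncol(S)
  sg <- matrix(sigma, n, Fm)
  sqrt((S + matrix(stats::rnorm(n * Fm), n, Fm) * sg)^2 +
         (matrix(stats::rnorm(n * Fm), n, Fm) * sg)^2)
}

## ---- polynomial regressor ----------------------------------------------

# full cubic monomial expansion of 3 features: 20 columns incl. intercept
poly_expand3 <- function(X) {
  x1 <- X[, 1]; x2 <- X[, 2]; x3 <- X[, 3]
  cbind(1, x1, x2, x3,
        x1 * x1, x1 * x2, x1 * x3, x2 * x2, x2 * x3, x3 * x3,
        x1 * x1 * x1, x1 * x1 * x2, x1 * x1 * x3,
        x1 * x2 * x2, x1 * x2 * x3, x1 * x3 * x3,
        x2 * x2 * x2, x2 * x2 * x3, x2 * x3 * x3, x3 * x3 * x3)
}

#' Fit the order-3 polynomial regressor
#'
#' Ridge-stabilized least squares of each standard-model parameter on the
#' full cubic expansion (20 terms) of the standardized feature triple. This
#' regressor, trained on prior simulations, approximates the Bayesian
#' posterior-mean estimator of the parameters given the features.
#'
#' @param features n x 3 feature matrix.
#' @param targets n x 6 target matrix ([DMI_PARAMS] order).
#' @param degree polynomial degree, fixed at 3.
#' @param ridge ridge penalty on standardized, non-intercept terms.
#' @param scheme the scheme the features came from (fingerprint is embedded;
#'   prediction refuses a different scheme).
#' @return a `dmi_estimator` with coefficients, standardization constants,
#'   per-parameter training RMSE and the scheme.
#' @export
fit_regressor <- function(features, targets, degree = 3, ridge = 1e-6,
                          scheme = NULL) {
  stopifnot(degree == 3)
  features <- as.matrix(features); targets <- as.matrix(targets)
  stopifnot(nrow(features) == nrow(targets), ncol(features) == 3L,
            ncol(targets) == 6L)
  ok <- stats::complete.cases(features) & stats::complete.cases(targets)
  features <- features[ok, , drop = FALSE]; targets <- targets[ok, , drop = FALSE]
  mu <- colMeans(features)
  sd <- apply(features, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  Z <- sweep(sweep(features, 2, mu), 2, sd, "/")
  X <- poly_expand3(Z)
  XtX <- crossprod(X)
  pen <- diag(c(0, rep(ridge, ncol(X) - 1L))) * nrow(X)
  if (ridge <= 0 && rcond(XtX) < 1e-14)
    stop("rank-deficient polynomial design; use a positive ridge", call. = FALSE)
  beta <- solve(XtX + pen, crossprod(X, targets))
  pred <- X %*% beta
  rmse <- sqrt(colMeans((pred - targets)^2))
  names(rmse) <- DMI_PARAMS
  colnames(beta) <- DMI_PARAMS
  structure(list(degree = 3L, coefficients = beta,
                 feature_mean = mu, feature_sd = sd,
                 training_rmse = rmse, n_train = nrow(X),
                 scheme = scheme,
                 fingerprint = if (!is.null(scheme)) scheme_fingerprint(scheme) else NA_character_),
            class = "dmi_estimator")
}

#' @export
print.dmi_estimator <- function(x, ...) {
  cat(sprintf("<dmi_estimator> order-%d polynomial, %d terms, trained on %d samples\n",
              x$degree, nrow(x$coefficients), x$n_train))
  if (!is.na(x$fingerprint)) cat("  scheme:", x$fingerprint, "\n")
  cat("  training RMSE:",
      paste(sprintf("%s=%.3f", names(x$training_rmse), x$training_rmse),
            collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.dmi_estimator <- function(x, ...) {
  terms <- c("1", "f1", "f2", "f3",
             "f1^2", "f1.f2", "f1.f3", "f2^2", "f2.f3", "f3^2",
             "f1^3", "f1^2.f2", "f1^2.f3", "f1.f2^2", "f1.f2.f3",
             "f1.f3^2", "f2^3", "f2^2.f3", "f2.f3^2", "f3^3")
  tibble::as_tibble(x$coefficients) |>
    dplyr::mutate(term = terms, .before = 1) |>
    tidyr::pivot_longer(-"term", names_to = "parameter", values_to = "estimate")
}

#' @export
glance.dmi_estimator <- function(x, ...) {
  tibble::tibble(degree = x$degree, n_terms = nrow(x$coefficients),
                 n_train = x$n_train,
                 rmse_v_intra = x$training_rmse[["v_intra"]],
                 rmse_d_ax_intra = x$training_rmse[["d_ax_intra"]],
                 scheme = x$fingerprint)
}

# raw (unclipped) predictions for a feature matrix
predict_raw <- function(estimator, features) {
  Z <- sweep(sweep(as.matrix(features), 2, estimator$feature_mean), 2,
             estimator$feature_sd, "/")
  poly_expand3(Z) %*% estimator$coefficients
}

#' Predict features -> parameters (table interface)
#'
#' @param object a `dmi_estimator`.
#' @param features matrix or tibble with the three feature columns.
#' @param ... unused.
#' @return tibble of the six post-processed parameters (fractions clipped to
#'   [0,1] and renormalized to the simplex; diffusivities clipped to [0,3]).
#' @export
predict.dmi_estimator <- function(object, features, ...) {
  ft <- as.matrix(as.data.frame(features)[, c("f0_inner", "f0_outer", "p2")])
  raw <- predict_raw(object, ft)
  tibble::as_tibble(as.data.frame(postprocess_params(raw)))
}

# fractions: clip [0,1] then renormalize; diffusivities: clip [0,3]
postprocess_params <- function(raw) {
  V <- pmin(pmax(raw[, 1:3, drop = FALSE], 0), 1)
  s <- rowSums(V)
  deg <- s <= 0
  V[deg, ] <- 1 / 3
  s[deg] <- 1
  V <- V / s
  D <- pmin(pmax(raw[, 4:6, drop = FALSE], 0), 3)
  out <- cbind(V, D)
  colnames(out) <- DMI_PARAMS
  out
}

#' Predict parameter maps for a volume
#'
#' @param estimator a trained `dmi_estimator` (scheme must match the
#'   volume's scheme).
#' @param volume a `dmi_volume`.
#' @param mask 3D 0/1 processing mask.
#' @return a `dmi_maps` (no ADC field; see [compute_adc()]).
#' @export
predict_maps <- function(estimator, volume, mask) {
  stopifnot(inherits(estimator, "dmi_estimator"), inherits(volume, "dmi_volume"))
  if (is.null(estimator$scheme) ||
      !schemes_equal(estimator$scheme, volume$scheme))
    stop("estimator was trained for a different acquisition scheme (",
         estimator$fingerprint, ")", call. = FALSE)
  ft <- compute_features(volume, mask)
  vm <- attr(ft, "valid_mask")
  dims <- dim(mask)
  fields <- lapply(DMI_PARAMS, function(p) array(NA_real_, dims))
  names(fields) <- DMI_PARAMS
  if (nrow(ft)) {
    raw <- predict_raw(estimator, as.matrix(ft[, c("f0_inner", "f0_outer", "p2")]))
    pp <- postprocess_params(raw)
    idx <- which(vm > 0)
    for (p in DMI_PARAMS) fields[[p]][idx] <- pp[, p]
  }
  parameter_maps(fields, vm, voxel_size = volume$voxel_size, check = FALSE)
}

#' Importance-sampling posterior-mean reference estimator
#'
#' The slow Bayesian reference the polynomial regressor approximates:
#' E[theta | f] estimated by weighting prior samples with a Gaussian kernel
#' in feature space, `w_i = exp(-sum_j (f_j - f_ij)^2 / (2 sigma_j^2))`,
#' where `f_ij` are noiseless features of prior sample i. Intended for
#' validation, not for mapping volumes.
#'
#' @param feature length-3 feature vector (or 3-column matrix of queries).
#' @param config a [prior_config()]; `n_samples` is used as the Monte-Carlo
#'   size (>= 1e4 recommended).
#' @param noise_sigma length-3 feature noise scale (see
#'   [estimate_feature_noise()]).
#' @param scheme the acquisition scheme.
#' @param prior_features optional precomputed list(samples, features) to
#'   reuse across queries.
#' @return tibble of posterior-mean parameters, one row per query.
#' @export
posterior_mean_oracle <- function(feature, config, noise_sigma, scheme,
                                  prior_features = NULL) {
  if (is.null(prior_features)) prior_features <- oracle_prior_features(config, scheme)
  Fq <- rbind(feature)
  th <- as.matrix(prior_features$samples[DMI_PARAMS])
  FF <- prior_features$features
  sig <- rep_len(noise_sigma, 3)
  out <- matrix(NA_real_, nrow(Fq), 6)
  for (q in seq_len(nrow(Fq))) {
    s <- sig
    repeat {
      d2 <- ((FF[, 1] - Fq[q, 1]) / s[1])^2 + ((FF[, 2] - Fq[q, 2]) / s[2])^2 +
        ((FF[, 3] - Fq[q, 3]) / s[3])^2
      w <- exp(-d2 / 2)
      if (sum(w) > 0) break
      warning("all importance weights underflow; widening sigma", call. = FALSE)
      s <- s * 2
    }
    out[q, ] <- colSums(th * w) / sum(w)
  }
  colnames(out) <- DMI_PARAMS
  tibble::as_tibble(as.data.frame(out))
}

#' Precompute noiseless prior features for the oracle
#' @param config a [prior_config()].
#' @param scheme a `dmi_scheme`.
#' @return list(samples, features).
#' @export
oracle_prior_features <- function(config, scheme) {
  samples <- sample_prior(config)
  theta <- as.list(samples[c(DMI_PARAMS, "kappa", "mu_x", "mu_y", "mu_z")])
  S <- batch_signals(theta, scheme)
  ft <- features_from_signals(S, scheme)
  list(samples = samples, features = ft$features)
}

#' Empirical feature-noise scale at a given SNR
#'
#' Simulates repeated Rician-noisy acquisitions of representative prior
#' samples and returns the per-feature standard deviation of the feature
#' error — the `noise_sigma` the posterior-mean oracle needs.
#'
#' @param scheme a `dmi_scheme`.
#' @param snr b = 0 SNR.
#' @param n_params number of representative parameter draws.
#' @param n_rep noisy repetitions per draw.
#' @param seed RNG seed.
#' @return length-3 numeric vector of feature SDs.
#' @export
estimate_feature_noise <- function(scheme, snr, n_params = 50, n_rep = 40,
                                   seed = 99L) {
  cfg <- prior_config(n_samples = max(200, n_params), seed = seed)
  samples <- sample_prior(cfg)[seq_len(n_params), ]
  theta <- as.list(samples[c(DMI_PARAMS, "kappa", "mu_x", "mu_y", "mu_z")])
  S <- batch_signals(theta, scheme)
  clean <- features_from_signals(S, scheme)$features
  devs <- with_seed(seed + 1L, {
    reps <- lapply(seq_len(n_rep), function(r) {
      ft <- features_from_signals(rician_matrix(S, 1 / snr), scheme)$features
      ft - clean
    })
    do.call(rbind, reps)
  })
  apply(devs, 2, stats::sd)
}

## ---- serialization ------------------------------------------------------

#' Write a trained estimator to a versioned JSON file
#' @param estimator a `dmi_estimator`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_estimator <- function(estimator, path) {
  obj <- list(
    format = "dmipipe-estimator", version = 1L,
    degree = estimator$degree,
    coefficients = unname(estimator$coefficients),
    parameter_names = DMI_PARAMS,
    feature_mean = estimator$feature_mean,
    feature_sd = estimator$feature_sd,
    training_rmse = unname(estimator$training_rmse),
    n_train = estimator$n_train,
    fingerprint = estimator$fingerprint,
    scheme = list(name = estimator$scheme$name,
                  bvals = estimator$scheme$bvals,
                  bvecs = unname(estimator$scheme$bvecs),
                  shell_ids = estimator$scheme$shell_ids))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read an estimator written by [write_estimator()]
#' @param path JSON file.
#' @return a `dmi_estimator`.
#' @export
read_estimator <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "dmipipe-estimator"))
    stop("not a dmipipe estimator file: ", path, call. = FALSE)
  sch <- acquisition_scheme(obj$scheme$bvals, obj$scheme$bvecs,
                            obj$scheme$shell_ids)
  sch$name <- obj$scheme$name
  beta <- as.matrix(obj$coefficients)
  colnames(beta) <- obj$parameter_names
  rmse <- as.numeric(obj$training_rmse)
  names(rmse) <- obj$parameter_names
  structure(list(degree = as.integer(obj$degree), coefficients = beta,
                 feature_mean = as.numeric(obj$feature_mean),
                 feature_sd = as.numeric(obj$feature_sd),
                 training_rmse = rmse, n_train = as.integer(obj$n_train),
                 scheme = sch, fingerprint = obj$fingerprint),
            class = "dmi_estimator")
}

#' Train an estimator for a scheme in one call
#'
#' [sample_prior()] -> [build_training_set()] -> [fit_regressor()].
#' @param scheme a `dmi_scheme` or preset name.
#' @param config a [prior_config()].
#' @param noise_seed seed for the training noise.
#' @return a `dmi_estimator`.
#' @export
train_estimator <- function(scheme, config = prior_config(),
                            noise_seed = config$seed + 1000L) {
  if (is.character(scheme)) scheme <- preset_scheme(scheme)
  samples <- sample_prior(config)
  ts <- build_training_set(samples, scheme, noise_seed = noise_seed)
  fit_regressor(ts$features[ts$valid, , drop = FALSE],
                ts$targets[ts$valid, , drop = FALSE], scheme = scheme)
}
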