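test_that("prior sampling is reproducible, admissible and on the simplex", {
  cfg <- prior_config(n_samples = 1000, seed = 123)
  s1 <- sample_prior(cfg)
  s2 <- sample_prior(cfg)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 1000)
  expect_lt(max(abs(s1$v_intra + s1$v_extra + s1$v_csf - 1)), 1e-12)
  expect_true(all(s1$d_ax_intra > s1$d_ax_extra + 2 * s1$d_rad_extra))
  expect_true(all(s1$d_ax_intra <= 3 & s1$d_rad_extra <= 1.5))
  expect_lt(max(abs(sqrt(s1$mu_x^2 + s1$mu_y^2 + s1$mu_z^2) - 1)), 1e-9)
})

test_that("constraint rejection rate matches a brute-force Monte-Carlo estimate", {
  cfg <- prior_config(n_samples = 20000, seed = 42)
  acc <- attr(sample_prior(cfg), "acceptance_rate")
  # independent oracle: plain uniform draws over the diffusivity box
  set.seed(777)
  m <- 2e5
  ok <- stats::runif(m, 0, 3) > stats::runif(m, 0, 3) + 2 * stats::runif(m, 0, 1.5)
  p_hat <- mean(ok)
  n_draws <- 20000 / acc  # approximate raw-draw count behind `acc`
  se <- sqrt(p_hat * (1 - p_hat) * (1 / m + 1 / n_draws))
  expect_lt(abs(acc - p_hat), 3 * se)
})

test_that("training set aligns rows and honors the noiseless closed forms", {
  sch <- two_shell()
  cfg <- prior_config(n_samples = 300, snr_range = c(Inf, Inf), seed = 5)
  samples <- sample_prior(cfg)
  # plant a pure-CSF sample in row 1
  samples[1, c("v_intra", "v_extra", "v_csf")] <- list(0, 0, 1)
  ts <- build_training_set(samples, sch)
  expect_equal(nrow(ts$features), 300)
  expect_equal(nrow(ts$targets), 300)
  expect_equal(unname(ts$features[1, 1]), exp(-3), tolerance = 1e-9)
  expect_equal(unname(ts$features[1, 2]), exp(-6), tolerance = 1e-9)
  expect_lt(ts$features[1, 3], 1e-9)
  expect_equal(unname(ts$targets[1, "v_csf"]), 1)
})

test_that("noiseless spherical-mean features depend on kappa only through p2", {
  sch <- two_shell()
  cfg <- prior_config(n_samples = 200, snr_range = c(Inf, Inf), seed = 8)
  samples <- sample_prior(cfg)
  twins <- samples[rep(1:20, 2), ]
  twins$kappa <- c(rep(0, 20), rep(1e6, 20))
  ts <- build_training_set(twins, sch)
  d_f0 <- abs(ts$features[1:20, 1:2] - ts$features[21:40, 1:2])
  expect_lt(max(d_f0), 1e-2)  # limited by direction-sampling aliasing
  # anisotropic microstructure must move p2 between the two extremes
  aniso <- twins$d_ax_intra[1:20] * twins$v_intra[1:20] > 0.5
  expect_true(any(ts$features[21:40, 3][aniso] -
                    ts$features[1:20, 3][aniso] > 0.01))
})

test_that("polynomial regressor recovers a realizable cubic exactly", {
  set.seed(31)
  X <- matrix(stats::runif(3 * 2000), ncol = 3)
  # a known cubic in the (standardized) features, built through the same
  # expansion the regressor uses
  Z <- scale(X)
  P <- dmipipe:::poly_expand3(Z)
  beta_true <- matrix(stats::rnorm(20 * 6, sd = 0.3), 20, 6)
  Y <- P %*% beta_true
  est <- fit_regressor(X, Y, ridge = 1e-10)
  pred <- dmipipe:::predict_raw(est, X)
  expect_lt(sqrt(mean((pred - Y)^2)), 1e-6)
  # constant target -> intercept-only fit
  Yc <- matrix(rep(c(0.2, 0.3, 0.5, 2, 1, 0.4), each = 2000), 2000, 6)
  est_c <- fit_regressor(X, Yc, ridge = 1e-10)
  expect_lt(max(abs(dmipipe:::predict_raw(est_c, X) - Yc)), 1e-8)
})

test_that("degenerate designs need the ridge", {
  X <- cbind(rep(0.5, 500), rep(0.2, 500), stats::runif(500))
  Y <- matrix(stats::runif(500 * 6), 500, 6)
  expect_error(fit_regressor(X, Y, ridge = 0), "rank-deficient")
  expect_s3_class(fit_regressor(X, Y, ridge = 1e-6), "dmi_estimator")
})

test_that("estimator serialization round-trips and is seed-deterministic", {
  est <- quick_estimator()
  td <- withr::local_tempdir()
  p1 <- file.path(td, "e1.json"); p2 <- file.path(td, "e2.json")
  write_estimator(est, p1)
  back <- read_estimator(p1)
  set.seed(2); Fq <- matrix(stats::runif(30, 0.05, 0.9), 10, 3,
                            dimnames = list(NULL, c("f0_inner", "f0_outer", "p2")))
  expect_equal(predict(back, as.data.frame(Fq)), predict(est, as.data.frame(Fq)),
               tolerance = 1e-12)
  # retraining with the same seeds reproduces the file bit-exactly
  est2 <- train_estimator(two_shell(), prior_config(n_samples = 2000, seed = 7))
  write_estimator(est2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("predicted maps respect the simplex contract and scheme guard", {
  est <- quick_estimator()
  ds <- small_phantom()
  maps <- predict_maps(est, ds$volume, ds$brain_mask)
  idx <- which(maps$mask > 0)
  expect_gt(length(idx), 100)
  fr <- maps$fields$v_intra[idx] + maps$fields$v_extra[idx] +
    maps$fields$v_csf[idx]
  expect_lt(max(abs(fr - 1)), 1e-6)
  for (p in c("d_ax_intra", "d_ax_extra", "d_rad_extra")) {
    expect_true(all(maps$fields[[p]][idx] >= 0 & maps$fields[[p]][idx] <= 3))
  }
  # all-background mask -> empty maps
  empty <- predict_maps(est, ds$volume, array(0L, dim(ds$brain_mask)))
  expect_equal(sum(empty$mask), 0)
  # scheme mismatch is refused
  vol_hex <- dwi_volume(array(1, c(2, 2, 2, 33)), hex_ball())
  expect_error(predict_maps(est, vol_hex, array(1L, c(2, 2, 2))),
               "different acquisition scheme")
})

test_that("posterior-mean oracle behaves at an identifiable corner", {
  sch <- two_shell()
  pf <- cached("oracle_pf_small",
               oracle_prior_features(prior_config(n_samples = 20000, seed = 5), sch))
  f_csf <- c(exp(-3), exp(-6), 0)
  post <- posterior_mean_oracle(f_csf, prior_config(n_samples = 1000, seed = 5),
                                noise_sigma = c(0.005, 0.005, 0.01),
                                sch, prior_features = pf)
  expect_gt(post$v_csf, 0.9)
  # halving the Monte-Carlo size moves the estimate by little
  pf_half <- list(samples = pf$samples[1:10000, ],
                  features = pf$features[1:10000, ])
  post_half <- posterior_mean_oracle(f_csf, prior_config(n_samples = 1000, seed = 5),
                                     noise_sigma = c(0.005, 0.005, 0.01),
                                     sch, prior_features = pf_half)
  expect_lt(abs(post$v_csf - post_half$v_csf), 0.05)
  # underflow protection widens sigma with a warning instead of failing
  w <- testthat::capture_warnings(
    res <- posterior_mean_oracle(c(5, 5, 5),
                                 prior_config(n_samples = 1000, seed = 5),
                                 noise_sigma = c(0.02, 0.02, 0.02), sch,
                                 prior_features = pf_half))
  expect_true(any(grepl("widening", w)))
  expect_true(all(is.finite(as.numeric(res[1, ]))))
})

test_that("predicted v_csf is monotone along a noiseless free-water ramp", {
  est <- full_estimator()
  sch <- two_shell()
  vc_grid <- seq(0.05, 0.95, by = 0.1)
  theta <- list(
    v_intra = (1 - vc_grid) * 0.5, v_extra = (1 - vc_grid) * 0.5,
    v_csf = vc_grid,
    d_ax_intra = rep(2.4, length(vc_grid)),
    d_ax_extra = rep(1.2, length(vc_grid)),
    d_rad_extra = rep(0.5, length(vc_grid)),
    kappa = rep(16, length(vc_grid)),
    mu_x = rep(0, length(vc_grid)), mu_y = rep(0, length(vc_grid)),
    mu_z = rep(1, length(vc_grid)))
  S <- dmipipe:::batch_signals(theta, sch)
  ft <- dmipipe:::features_from_signals(S, sch)$features
  pred <- predict(est, as.data.frame(ft))
  expect_true(all(diff(pred$v_csf) > -0.02))
  expect_gt(stats::cor(pred$v_csf, vc_grid), 0.95)
})
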