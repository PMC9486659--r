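test_that("single-fiber signal honors its closed forms", {
  p <- wm_params()
  g <- c(0, 0, 1); n <- c(0, 0, 1)
  expect_equal(single_fiber_signal(p, 0, g, n), 1.0, tolerance = 1e-12)
  # pure free water: isotropic mono-exponential at D = 3
  expect_equal(single_fiber_signal(csf_params(), 1.0, g, n), exp(-3),
               tolerance = 1e-9)
  # stick gives no perpendicular attenuation
  p_stick <- microstructure_params(1, 0, 0, 2.4, 0, 0)
  expect_equal(single_fiber_signal(p_stick, 2.0, c(1, 0, 0), c(0, 0, 1)), 1.0,
               tolerance = 1e-12)
  expect_error(single_fiber_signal(p, 1, c(0, 0, 2), n), "unit norm")
})

test_that("signal is a convex combination, bounded and monotone in b", {
  set.seed(5)
  bgrid <- seq(0, 2, by = 0.25)
  for (i in 1:20) {
    v <- as.numeric(stats::rexp(3)); v <- v / sum(v)
    dre <- stats::runif(1, 0, 1.5)
    dae <- stats::runif(1, 0, 3)
    dai <- stats::runif(1, 0, 3)
    p <- microstructure_params(v[1], v[2], v[3], dai, dae, dre)
    g <- random_rotation()[, 1]; n <- random_rotation()[, 2]
    s <- single_fiber_signal(p, bgrid, g, n)
    expect_true(all(s > 0 & s <= 1))
    expect_true(all(diff(s) <= 1e-12))
  }
})

test_that("single-fiber signal is rotationally equivariant", {
  p <- wm_params()
  g <- c(1, 0, 0); n <- c(0.6, 0, 0.8)
  set.seed(11)
  base <- single_fiber_signal(p, 1.5, g, n)
  for (i in 1:10) {
    R <- random_rotation()
    expect_equal(single_fiber_signal(p, 1.5, as.numeric(R %*% g),
                                     as.numeric(R %*% n)),
                 base, tolerance = 1e-12)
  }
})

test_that("dispersed signal reduces to its analytic limits", {
  p <- wm_params()
  gset <- rbind(c(0, 0, 1), c(1, 0, 0), c(0.6, 0, 0.8))
  # kappa -> inf: coherent single fiber
  geo_c <- fiber_geometry(c(0, 0, 1), 1e6)
  expect_equal(dispersed_signal(p, geo_c, 1.0, gset),
               single_fiber_signal(p, 1.0, gset, c(0, 0, 1)),
               tolerance = 1e-4)
  # kappa = 0: spherical mean, independent of gradient direction
  geo_u <- fiber_geometry(c(0, 0, 1), 0)
  s <- dispersed_signal(p, geo_u, 2.0, gset)
  expect_lt(diff(range(s)), 1e-10)
  expect_equal(s[1], analytic_spherical_mean(p, 2.0), tolerance = 1e-8)
  # normalization survives dispersion
  expect_equal(dispersed_signal(p, fiber_geometry(c(0, 1, 0), 3), 0, gset),
               rep(1, 3), tolerance = 1e-12)
  expect_error(fiber_geometry(c(0, 0, 1), -1), ">= 0")
})

test_that("dispersed signal matches brute-force spherical quadrature", {
  # independent oracle: dense Gauss-Legendre x azimuth grid over the Watson ODF
  p <- wm_params()
  kappa <- 7
  mu <- c(0, 0.6, 0.8)
  g <- c(0.9, 0, sqrt(1 - 0.81))
  gl <- pracma::gaussLegendre(80, -1, 1)
  phi <- seq(0, 2 * pi, length.out = 161)[-161]
  nodes <- do.call(rbind, lapply(seq_along(gl$x), function(i) {
    r <- sqrt(1 - gl$x[i]^2)
    cbind(r * cos(phi), r * sin(phi), gl$x[i])
  }))
  wts <- rep(gl$w, each = length(phi)) * (2 * pi / length(phi))
  wat <- exp(kappa * (nodes %*% mu)^2)
  sig <- single_fiber_signal_rows <- sapply(seq_len(nrow(nodes)), function(i)
    single_fiber_signal(p, 1.7, g, nodes[i, ]))
  oracle <- sum(wts * wat * sig) / sum(wts * wat)
  expect_equal(dispersed_signal(p, fiber_geometry(mu, kappa), 1.7, g), oracle,
               tolerance = 1e-6)
})

test_that("simulate_volume reproduces per-voxel dispersed signals", {
  sch <- two_shell()
  dims <- c(3, 3, 2)
  n <- prod(dims)
  set.seed(9)
  vi <- stats::runif(n, 0.2, 0.6); vc <- stats::runif(n, 0.05, 0.3)
  field <- list(
    v_intra = array(vi, dims), v_extra = array(1 - vi - vc, dims),
    v_csf = array(vc, dims),
    d_ax_intra = array(stats::runif(n, 2, 2.8), dims),
    d_ax_extra = array(stats::runif(n, 0.5, 1), dims),
    d_rad_extra = array(stats::runif(n, 0.1, 0.4), dims),
    kappa = array(stats::runif(n, 0, 20), dims),
    mu_x = array(0, dims), mu_y = array(0, dims), mu_z = array(1, dims))
  vol <- simulate_volume(field, sch, s0 = 500)
  # b0 frames are exactly s0
  expect_equal(max(abs(vol$data[, , , is_b0(sch)] - 500)), 0, tolerance = 1e-9)
  # element-wise oracle via dispersed_signal
  for (v in c(1, 9, 18)) {
    co <- arrayInd(v, dims)
    p <- microstructure_params(field$v_intra[v], field$v_extra[v],
                               field$v_csf[v], field$d_ax_intra[v],
                               field$d_ax_extra[v], field$d_rad_extra[v])
    geo <- fiber_geometry(c(0, 0, 1), field$kappa[v])
    nz <- which(!is_b0(sch))
    want <- 500 * dispersed_signal(p, geo, sch$bvals[nz], sch$bvecs[nz, ])
    got <- vol$data[co[1], co[2], co[3], nz]
    expect_equal(got, want, tolerance = 1e-12)
  }
  # uniform pure CSF: closed form at the b = 2 shell
  csf_field <- list(
    v_intra = array(0, dims), v_extra = array(0, dims), v_csf = array(1, dims),
    d_ax_intra = array(3, dims), d_ax_extra = array(3, dims),
    d_rad_extra = array(1.5, dims), kappa = array(0, dims),
    mu_x = array(0, dims), mu_y = array(0, dims), mu_z = array(1, dims))
  vol_csf <- simulate_volume(csf_field, sch, s0 = 100)
  b2 <- which(round(sch$bvals, 6) == 2)
  expect_equal(as.numeric(vol_csf$data[, , , b2]),
               rep(100 * exp(-6), n * length(b2)), tolerance = 1e-9)
})
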