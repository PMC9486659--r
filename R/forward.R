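#' Standard-model microstructure parameters for one voxel
#'
#' The three-compartment "standard model" of white matter: an intra-axonal
#' stick (1-D diffusion along the fiber), an extra-axonal zeppelin (axially
#' symmetric tensor) and an isotropic free-water ball with diffusivity fixed
#' at 3 µm²/ms. Fractions live on the unit simplex; diffusivities are bounded
#' by the free-water value.
#'
#' @param v_intra,v_extra,v_csf compartment volume fractions (sum to 1).
#' @param d_ax_intra intra-axonal axial diffusivity (µm²/ms).
#' @param d_ax_extra extra-axonal axial diffusivity (µm²/ms).
#' @param d_rad_extra extra-axonal radial diffusivity (µm²/ms).
#' @return a `dmi_params` list.
#' @export
microstructure_params <- function(v_intra, v_extra, v_csf,
                                  d_ax_intra, d_ax_extra, d_rad_extra) {
  v <- c(v_intra, v_extra, v_csf)
  if (any(v < -1e-12)) stop("negative volume fraction", call. = FALSE)
  if (abs(sum(v) - 1) > 1e-9)
    stop("volume fractions must sum to 1 (tol 1e-9)", call. = FALSE)
  d <- c(d_ax_intra, d_ax_extra, d_rad_extra)
  if (any(d < 0) || any(d > 3))
    stop("diffusivities must lie in [0, 3] um^2/ms", call. = FALSE)
  structure(list(v_intra = v_intra, v_extra = v_extra, v_csf = v_csf,
                 d_ax_intra = d_ax_intra, d_ax_extra = d_ax_extra,
                 d_rad_extra = d_rad_extra, d_csf = D_CSF),
            class = "dmi_params")
}

# free-water (CSF) diffusivity, fixed by the model
D_CSF <- 3.0

#' Is a parameter set admissible under the estimation prior?
#'
#' The degeneracy-breaking branch constraint of the standard model:
#' `d_ax_intra > d_ax_extra + 2 * d_rad_extra`.
#' @param params a `dmi_params` (or list with the named diffusivities).
#' @return logical.
#' @export
prior_admissible <- function(params) {
  params$d_ax_intra > params$d_ax_extra + 2 * params$d_rad_extra
}

#' Single-fiber (coherent) standard-model signal
#'
#' Normalized signal of one perfectly aligned fiber population:
#' \deqn{S = v_i e^{-b D_{a,i} (g\cdot n)^2}
#'        + v_e e^{-b D_{r,e} - b (D_{a,e}-D_{r,e})(g\cdot n)^2}
#'        + v_c e^{-b D_{csf}}}
#' so that S(b = 0) = 1.
#'
#' @param params a `dmi_params`.
#' @param b b-value(s), ms/µm².
#' @param g gradient direction, unit 3-vector or matrix of rows.
#' @param n fiber direction, unit 3-vector.
#' @return numeric vector of signals, one per (b, g) pair.
#' @export
single_fiber_signal <- function(params, b, g, n) {
  g <- rbind(g)
  nb <- max(length(b), nrow(g))
  b <- rep_len(b, nb)
  if (nrow(g) == 1L && nb > 1L) g <- g[rep(1L, nb), , drop = FALSE]
  nz <- b > B0_THRESHOLD   # b = 0 frames carry a zero direction vector
  if (any(abs(sqrt(rowSums(g[nz, , drop = FALSE]^2)) - 1) > 1e-6))
    stop("gradient direction g must have unit norm", call. = FALSE)
  if (abs(sqrt(sum(n^2)) - 1) > 1e-6)
    stop("fiber direction n must have unit norm", call. = FALSE)
  ct2 <- as.numeric(g %*% n)^2
  ct2[!nz] <- 0
  with(params,
       v_intra * exp(-b * d_ax_intra * ct2) +
       v_extra * exp(-b * d_rad_extra - b * (d_ax_extra - d_rad_extra) * ct2) +
       v_csf * exp(-b * d_csf))
}

#' Fiber geometry (mesostructure nuisance)
#'
#' Watson orientation distribution: axially symmetric around `mean_direction`
#' with concentration `dispersion_kappa` (0 = uniform, large = coherent
#' single fiber). The invariant features are insensitive to this geometry by
#' design; the training prior spans it as a nuisance.
#'
#' @param mean_direction unit 3-vector.
#' @param dispersion_kappa Watson concentration, >= 0.
#' @return a `dmi_geometry` list.
#' @export
fiber_geometry <- function(mean_direction = c(0, 0, 1), dispersion_kappa = Inf) {
  mu <- as.numeric(mean_direction)
  nrm <- sqrt(sum(mu^2))
  if (abs(nrm - 1) > 1e-6) stop("mean_direction must have unit norm", call. = FALSE)
  if (is.na(dispersion_kappa) || dispersion_kappa < 0)
    stop("dispersion_kappa must be >= 0", call. = FALSE)
  structure(list(mean_direction = mu / nrm, dispersion_kappa = dispersion_kappa),
            class = "dmi_geometry")
}

## ---- Legendre machinery -----------------------------------------------

# default truncation order of the even Legendre series; at b*D <= 6 the
# truncation error of the worst-case stick kernel is ~1e-6
LMAX_DEFAULT <- 20L

# Even-order Legendre polynomial values: matrix length(x) x (lmax/2 + 1)
# columns l = 0, 2, ..., lmax. Bonnet recursion.
legendre_even <- function(x, lmax = LMAX_DEFAULT) {
  x <- as.numeric(x)
  P <- matrix(0, length(x), lmax + 1L)
  P[, 1] <- 1
  if (lmax >= 1) P[, 2] <- x
  if (lmax >= 2) for (l in 1:(lmax - 1L))
    P[, l + 2L] <- ((2 * l + 1) * x * P[, l + 1L] - l * P[, l]) / (l + 1)
  P[, seq(1L, lmax + 1L, by = 2L), drop = FALSE]
}

# cached Gauss-Legendre rule on [-1, 1]
gl_rule <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
    cache[[key]]
  }
})

# Watson Legendre means w_l(kappa) = E[P_l(t)] under density ∝ exp(kappa t^2)
# on [-1, 1], even l up to lmax. Moderate kappa: Gauss-Legendre on the
# (e^-kappa scaled) density. Large kappa: substitute u = kappa (1 - t^2) and
# use Gauss-Laguerre (the density's boundary layer at |t| = 1).
watson_legendre <- function(kappa, lmax = LMAX_DEFAULT) {
  if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  if (!is.finite(kappa) || kappa > 1e8) return(rep(1, lmax / 2 + 1))
  if (kappa <= 400) {
    gl <- gl_rule(200)
    w <- exp(kappa * (gl$x^2 - 1)) * gl$w
    P <- legendre_even(gl$x, lmax)
    as.numeric(crossprod(w, P) / sum(w))
  } else {
    qa <- gauss_laguerre_60()
    keep <- qa$x < kappa
    t <- sqrt(1 - qa$x[keep] / kappa)
    w <- qa$w[keep] / t
    P <- legendre_even(t, lmax)
    as.numeric(crossprod(w, P) / sum(w))
  }
}

gauss_laguerre_60 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- pracma::gaussLaguerre(60)
    cache
  }
})

# Vectorized Watson means for many kappas: n x (lmax/2+1) matrix.
watson_legendre_matrix <- function(kappas, lmax = LMAX_DEFAULT) {
  t(vapply(kappas, watson_legendre, numeric(lmax / 2 + 1L), lmax = lmax))
}

# Legendre series coefficients c_l(b) of the single-fiber kernel
# K(t) = v_i e^{-b Dai t^2} + v_e e^{-b Dre - b(Dae-Dre) t^2} + v_c e^{-3b},
# with c_l = (2l+1)/2 * int_{-1}^{1} K(t) P_l(t) dt, so that
# K(t) = sum_l c_l P_l(t). Vectorized over parameter rows: returns
# n x (lmax/2+1) for one b.
kernel_legendre <- function(b, vi, ve, vc, dai, dae, dre,
                            lmax = LMAX_DEFAULT, n_leg = 64L) {
  gl <- gl_rule(n_leg)
  t2 <- gl$x^2
  # n x n_leg kernel values
  K <- vi * exp(-b * outer(dai, t2)) +
    ve * exp(-b * dre - b * outer(dae - dre, t2)) +
    vc * exp(-3 * b)
  P <- legendre_even(gl$x, lmax)
  lev <- seq(0L, lmax, 2L)
  (K %*% (gl$w * P)) * rep((2 * lev + 1) / 2, each = nrow(K))
}

#' Orientation-dispersed standard-model signal
#'
#' Signal of a Watson-dispersed fiber population: the spherical convolution
#' of the single-fiber kernel with the Watson orientation distribution,
#' evaluated by an even-order Legendre expansion (Funk–Hecke): the kernel's
#' Legendre coefficients (Gauss–Legendre quadrature, `n_leg` nodes) are
#' damped by the Watson Legendre means and re-summed at cos(angle(g, µ)).
#' Reduces to [single_fiber_signal()] as kappa grows and to the spherical
#' mean at kappa = 0.
#'
#' @param params a `dmi_params`.
#' @param geometry a [fiber_geometry()].
#' @param b b-value(s), ms/µm².
#' @param g unit gradient direction(s), vector or matrix of rows (recycled
#'   against `b`).
#' @param lmax even Legendre truncation order (default 20).
#' @param n_leg quadrature nodes for the kernel coefficients (default 64).
#' @return numeric signal vector.
#' @export
dispersed_signal <- function(params, geometry, b, g,
                             lmax = LMAX_DEFAULT, n_leg = 64L) {
  stopifnot(inherits(geometry, "dmi_geometry"))
  g <- rbind(g)
  nb <- max(length(b), nrow(g))
  b <- rep_len(b, nb)
  if (nrow(g) == 1L && nb > 1L) g <- g[rep(1L, nb), , drop = FALSE]
  nz <- b > B0_THRESHOLD   # b = 0 frames carry a zero direction vector
  if (any(abs(sqrt(rowSums(g[nz, , drop = FALSE]^2)) - 1) > 1e-6))
    stop("gradient direction g must have unit norm", call. = FALSE)
  wl <- watson_legendre(geometry$dispersion_kappa, lmax)
  ct <- as.numeric(g %*% geometry$mean_direction)
  ct[!nz] <- 0
  P <- legendre_even(ct, lmax)
  out <- numeric(nb)
  for (ub in unique(b)) {
    sel <- which(b == ub)
    cl <- kernel_legendre(ub, params$v_intra, params$v_extra, params$v_csf,
                          params$d_ax_intra, params$d_ax_extra,
                          params$d_rad_extra, lmax, n_leg)
    out[sel] <- as.numeric(P[sel, , drop = FALSE] %*% (as.numeric(cl) * wl))
  }
  out
}

## ---- batch forward simulation ------------------------------------------

# Noiseless normalized signals for a batch of parameter/geometry samples on a
# scheme. `theta`: data frame/list with columns v_intra, v_extra, v_csf,
# d_ax_intra, d_ax_extra, d_rad_extra, kappa, mu_x, mu_y, mu_z.
# Returns n x n_frames matrix. Chunked to bound memory.
batch_signals <- function(theta, scheme, lmax = LMAX_DEFAULT, n_leg = 64L,
                          chunk = 5000L) {
  n <- length(theta$v_intra)
  Fm <- length(scheme)
  out <- matrix(0, n, Fm)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    out[s:e, ] <- batch_signals_chunk(lapply(theta, `[`, s:e), scheme, lmax, n_leg)
  }
  out
}

batch_signals_chunk <- function(th, scheme, lmax, n_leg) {
  n <- length(th$v_intra)
  bv <- scheme$bvals
  G <- scheme$bvecs
  mu <- cbind(th$mu_x, th$mu_y, th$mu_z)
  ct <- mu %*% t(G)                       # n x F cos(angle)
  ct[, is_b0(scheme)] <- 0                # direction irrelevant at b = 0
  WL <- watson_legendre_matrix(th$kappa, lmax)   # n x L
  L <- ncol(WL)
  S <- matrix(0, n, length(bv))
  ub <- unique(bv)
  # Legendre coefficient stack per unique b: n x L each
  CL <- lapply(ub, function(b)
    kernel_legendre(b, th$v_intra, th$v_extra, th$v_csf,
                    th$d_ax_intra, th$d_ax_extra, th$d_rad_extra, lmax, n_leg))
  names(CL) <- as.character(ub)
  bidx <- match(bv, ub)
  # P_l(ct) accumulated by recursion over all orders, even ones consumed
  Pprev <- matrix(1, n, length(bv))  # P_0
  Pcur <- ct                         # P_1
  acc <- matrix(0, n, length(bv))
  li <- 1L
  # l = 0 term
  for (f in seq_along(bv)) acc[, f] <- CL[[bidx[f]]][, 1L] * WL[, 1L]
  for (l in 1:(lmax - 1L)) {
    Pnext <- ((2 * l + 1) * ct * Pcur - l * Pprev) / (l + 1)
    if ((l + 1L) %% 2L == 0L) {
      li <- li + 1L
      for (f in seq_along(bv))
        acc[, f] <- acc[, f] + CL[[bidx[f]]][, li] * WL[, li] * Pnext[, f]
    }
    Pprev <- Pcur; Pcur <- Pnext
  }
  acc
}

theta_from_params <- function(params, geometry) {
  list(v_intra = params$v_intra, v_extra = params$v_extra, v_csf = params$v_csf,
       d_ax_intra = params$d_ax_intra, d_ax_extra = params$d_ax_extra,
       d_rad_extra = params$d_rad_extra,
       kappa = geometry$dispersion_kappa,
       mu_x = geometry$mean_direction[1], mu_y = geometry$mean_direction[2],
       mu_z = geometry$mean_direction[3])
}

#' Simulate a noiseless DWI volume from per-voxel parameter fields
#'
#' @param param_field list of 3D arrays named as in [parameter_maps()] plus
#'   `kappa`, `mu_x`, `mu_y`, `mu_z` (fiber geometry per voxel).
#' @param scheme a `dmi_scheme`.
#' @param s0 b = 0 intensity scale.
#' @param mask optional 3D 0/1 array; voxels outside are zero-signal.
#' @param voxel_size mm triple.
#' @return a `dmi_volume` of noiseless signals `s0 * S`.
#' @export
simulate_volume <- function(param_field, scheme, s0 = 1000, mask = NULL,
                            voxel_size = c(1.5, 1.5, 5)) {
  need <- c(DMI_PARAMS, "kappa", "mu_x", "mu_y", "mu_z")
  if (!all(need %in% names(param_field)))
    stop("param_field must contain: ", paste(need, collapse = ", "), call. = FALSE)
  dims <- dim(param_field[[1]])
  for (f in param_field) if (!identical(dim(f), dims))
    stop("param_field arrays have mismatched shapes", call. = FALSE)
  if (is.null(mask)) mask <- array(1L, dims)
  idx <- which(mask > 0)
  theta <- lapply(param_field[need], function(f) as.numeric(f[idx]))
  names(theta) <- c(DMI_PARAMS, "kappa", "mu_x", "mu_y", "mu_z")
  S <- batch_signals(theta, scheme)
  data <- array(0, c(dims, length(scheme)))
  nvox <- prod(dims)
  for (f in seq_len(length(scheme)))
    data[idx + (f - 1L) * nvox] <- s0 * S[, f]
  dwi_volume(data, scheme, voxel_size = voxel_size)
}
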