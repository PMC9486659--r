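#' Real spherical-harmonic basis of orders 0 and 2
#'
#' Orthonormal real spherical harmonics evaluated at unit directions:
#' columns `(Y00, Y2-2, Y2-1, Y20, Y21, Y22)` with
#' Y00 = 1/(2 sqrt(pi)), Y2m the standard real quadratic harmonics
#' (xy, yz, 3z^2-1, xz, x^2-y^2 up to normalization). With this
#' normalization the fitted `c00 * Y00` is the least-squares estimate of the
#' spherical-mean signal.
#'
#' @param dirs n x 3 matrix of unit vectors.
#' @return n x 6 design matrix.
#' @export
sh_basis <- function(dirs) {
  dirs <- rbind(dirs)
  x <- dirs[, 1]; y <- dirs[, 2]; z <- dirs[, 3]
  cbind(
    rep(0.5 / sqrt(pi), nrow(dirs)),
    0.5 * sqrt(15 / pi) * x * y,
    0.5 * sqrt(15 / pi) * y * z,
    0.25 * sqrt(5 / pi) * (3 * z^2 - 1),
    0.5 * sqrt(15 / pi) * x * z,
    0.25 * sqrt(15 / pi) * (x^2 - y^2)
  )
}

Y00 <- 0.5 / sqrt(pi)

#' Least-squares spherical-harmonic fit (orders 0 and 2)
#'
#' @param signals numeric vector (one shell's signals), or matrix with one
#'   row per voxel and one column per direction.
#' @param directions matching n x 3 unit direction matrix.
#' @param max_order fixed at 2 (argument kept for clarity).
#' @return coefficient vector `c(c00, c2m...)` (or matrix, rows = voxels).
#'   The spherical-mean estimate is `c00 * 0.5/sqrt(pi)`.
#' @export
fit_sh <- function(signals, directions, max_order = 2) {
  stopifnot(max_order == 2)
  directions <- rbind(directions)
  one_row <- is.null(dim(signals))
  S <- rbind(signals)
  if (ncol(S) != nrow(directions))
    stop("signals and directions length mismatch", call. = FALSE)
  if (nrow(directions) < 6L)
    stop("at least 6 directions are required for an order-2 SH fit",
         call. = FALSE)
  B <- sh_basis(directions)
  if (rcond(crossprod(B)) < 1e-10)
    stop("SH design is ill-conditioned for this direction set", call. = FALSE)
  C <- S %*% sh_projector(directions)
  if (one_row) as.numeric(C) else C
}

# projection matrix B (B'B)^-1: signals %*% proj gives SH coefficients
sh_projector <- function(directions) {
  B <- sh_basis(directions)
  B %*% solve(crossprod(B))
}

# order-0-only projector (mean estimate) for radial bins too sparse for l=2
sh_projector_l0 <- function(directions) {
  matrix(1 / (nrow(rbind(directions)) * Y00), nrow(rbind(directions)), 1)
}

#' Rotation-invariant signal features of one scheme
#'
#' The three order-<=2 rotation- and mesostructure-invariant features the
#' estimator consumes:
#' \describe{
#'   \item{f0_inner}{spherical-mean signal of the inner radial bin,
#'     normalized by the mean b = 0 signal;}
#'   \item{f0_outer}{same for the outer radial bin;}
#'   \item{p2}{the l = 2 rotational power `sqrt(sum(c2m^2))` of the SH fit
#'     on the outer bin (b0-normalized signals).}
#' }
#' For a two-shell scheme the bins are the shells; for the hexagonal q-ball
#' scheme weightings are split at b = 1.0 ms/µm². The features are exactly
#' invariant under a joint rotation of the gradient set because each l-block
#' of the SH fit transforms orthogonally.
#'
#' @param volume a `dmi_volume`.
#' @param mask 3D 0/1 array (processing mask).
#' @return tibble with voxel indices `x, y, z` and columns `f0_inner`,
#'   `f0_outer`, `p2`; attribute `"valid_mask"` carries the possibly reduced
#'   mask (voxels with non-positive b = 0 mean are dropped).
#' @export
compute_features <- function(volume, mask) {
  stopifnot(inherits(volume, "dmi_volume"))
  dims <- dim(volume$data)[1:3]
  if (!identical(dim(mask), dims)) stop("mask shape mismatch", call. = FALSE)
  idx <- which(mask > 0)
  S <- frames_matrix(volume$data, idx)
  res <- features_from_signals(S, volume$scheme)
  keep <- res$valid
  vm <- array(0L, dims)
  vm[idx[keep]] <- 1L
  co <- arrayInd(idx[keep], dims)
  out <- tibble::tibble(x = co[, 1], y = co[, 2], z = co[, 3],
                        f0_inner = res$features[keep, 1],
                        f0_outer = res$features[keep, 2],
                        p2 = res$features[keep, 3])
  attr(out, "valid_mask") <- vm
  out
}

# extract voxels x frames matrix from a 4D array at linear voxel indices
frames_matrix <- function(data4d, idx) {
  dims <- dim(data4d)
  nvox <- prod(dims[1:3])
  Fm <- dims[4]
  m <- matrix(0, length(idx), Fm)
  for (f in seq_len(Fm)) m[, f] <- data4d[idx + (f - 1) * nvox]
  m
}

# radial bin membership: list(inner, outer) of frame indices
radial_bins <- function(scheme) {
  b0 <- is_b0(scheme)
  b <- scheme$bvals
  shells <- sort(unique(round(b[!b0], 6)))
  if (length(shells) < 2L)
    stop("scheme needs at least two distinguishable radial bins", call. = FALSE)
  if (length(shells) == 2L) {
    inner <- which(!b0 & round(b, 6) == shells[1])
    outer <- which(!b0 & round(b, 6) == shells[2])
  } else {
    inner <- which(!b0 & b <= 1.0)
    outer <- which(!b0 & b > 1.0)
  }
  if (!length(inner) || !length(outer))
    stop("empty radial bin; cannot form features", call. = FALSE)
  list(inner = inner, outer = outer)
}

# Shared feature computation: signals = n x F matrix (raw intensities),
# returns list(features = n x 3, valid = logical n). Used identically at
# training and inference time.
features_from_signals <- function(signals, scheme) {
  b0 <- is_b0(scheme)
  if (!any(b0)) stop("scheme has no b = 0 frame", call. = FALSE)
  bins <- radial_bins(scheme)
  s0 <- rowMeans(signals[, b0, drop = FALSE])
  valid <- is.finite(s0) & s0 > 0
  Sn <- signals / ifelse(valid, s0, 1)
  f0_of_bin <- function(fr) {
    dirs <- scheme$bvecs[fr, , drop = FALSE]
    if (length(fr) >= 6L) {
      P <- sh_projector(dirs)
      (Sn[, fr, drop = FALSE] %*% P[, 1, drop = FALSE]) * Y00
    } else {
      rowMeans(Sn[, fr, drop = FALSE])
    }
  }
  f0_inner <- as.numeric(f0_of_bin(bins$inner))
  f0_outer <- as.numeric(f0_of_bin(bins$outer))
  dirs_out <- scheme$bvecs[bins$outer, , drop = FALSE]
  C <- Sn[, bins$outer, drop = FALSE] %*% sh_projector(dirs_out)
  p2 <- sqrt(rowSums(C[, 2:6, drop = FALSE]^2))
  list(features = cbind(f0_inner = f0_inner, f0_outer = f0_outer, p2 = p2),
       valid = valid)
}
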