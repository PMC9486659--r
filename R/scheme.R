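#' Diffusion acquisition scheme
#'
#' An acquisition scheme is the list of diffusion weightings of one protocol:
#' a b-value (internal units ms/µm²; 1000 s/mm² = 1.0 ms/µm²), a unit gradient
#' direction per weighting (the zero vector for b = 0 frames), and an integer
#' shell/radial-bin label (-1 for b = 0).
#'
#' @param bvals numeric vector of b-values in ms/µm² (>= 0).
#' @param bvecs numeric matrix, one row per weighting, 3 columns; rows for
#'   non-zero b must have unit norm (tolerance 1e-6), b = 0 rows must be zero.
#' @param shell_ids optional integer shell label per weighting (-1 for b = 0).
#'   If omitted, labels are assigned by ranking the distinct non-zero b-values.
#'
#' @return An object of class `dmi_scheme`: a list with elements `bvals`,
#'   `bvecs`, `shell_ids`, `name`.
#' @export
acquisition_scheme <- function(bvals, bvecs, shell_ids = NULL) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != length(bvals) || ncol(bvecs) != 3L)
    stop("bvecs must be a length(bvals) x 3 matrix", call. = FALSE)
  if (any(bvals < 0)) stop("negative b-value", call. = FALSE)
  b0 <- bvals <= B0_THRESHOLD
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(abs(nrm[!b0] - 1) > 1e-6))
    stop("non-b0 gradient directions must have unit norm (tol 1e-6)", call. = FALSE)
  bvecs[b0, ] <- 0
  if (is.null(shell_ids)) {
    shell_ids <- rep(-1L, length(bvals))
    if (any(!b0)) {
      ub <- sort(unique(round(bvals[!b0], 6)))
      shell_ids[!b0] <- match(round(bvals[!b0], 6), ub)
    }
  }
  structure(list(bvals = bvals, bvecs = unname(bvecs),
                 shell_ids = as.integer(shell_ids), name = "custom"),
            class = "dmi_scheme")
}

# b-values at or below this (ms/µm², i.e. 50 s/mm²) are classed as b = 0,
# absorbing vendor rounding of nominally unweighted frames.
B0_THRESHOLD <- 0.05

#' @export
print.dmi_scheme <- function(x, ...) {
  b0 <- is_b0(x)
  shells <- sort(unique(round(x$bvals[!b0], 3)))
  cat(sprintf("<dmi_scheme '%s'> %d frames (%d b=0, %d weighted); b shells: %s ms/um^2\n",
              x$name, length(x$bvals), sum(b0), sum(!b0),
              paste(shells, collapse = ", ")))
  invisible(x)
}

#' @export
length.dmi_scheme <- function(x) length(x$bvals)

#' Logical index of b = 0 frames of a scheme
#' @param scheme a `dmi_scheme`.
#' @return logical vector over frames.
#' @export
is_b0 <- function(scheme) scheme$bvals <= B0_THRESHOLD

#' Deterministic point set on the unit sphere (golden-spiral construction)
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Interleave b=0 frames: one leading b=0 and one after every complete group
# of `every` weightings (none after a trailing partial group).
interleave_b0 <- function(bvals, bvecs, shell_ids, every = 6L) {
  n <- length(bvals)
  out_b <- 0; out_v <- matrix(0, 1, 3); out_s <- -1L
  i <- 1L
  while (i <= n) {
    j <- min(i + every - 1L, n)
    out_b <- c(out_b, bvals[i:j])
    out_v <- rbind(out_v, bvecs[i:j, , drop = FALSE])
    out_s <- c(out_s, shell_ids[i:j])
    if (j - i + 1L == every) {  # b0 only after a complete group
      out_b <- c(out_b, 0); out_v <- rbind(out_v, c(0, 0, 0)); out_s <- c(out_s, -1L)
    }
    i <- j + 1L
  }
  list(bvals = out_b, bvecs = out_v, shell_ids = as.integer(out_s))
}

#' Preset acquisition schemes
#'
#' Two protocol presets:
#' \describe{
#'   \item{`"two_shell"`}{30 directions per shell at b = 1.0 and 2.0 ms/µm²
#'     (golden-spiral point sets), with a b = 0 frame leading the series and
#'     after every 6th weighting.}
#'   \item{`"hex_ball"`}{28 weightings whose q-vectors are the 28 innermost
#'     non-origin points of an FCC (hexagonal close packing) lattice, scaled
#'     so the outermost shell sits at b = 2.0 ms/µm² (b scales with |q|²,
#'     giving shells at 2/3, 4/3 and 2.0), plus interleaved b = 0 frames
#'     (33 frames in total). Shell labels 1 (inner, b <= 1.0) and 2 (outer).}
#' }
#' The exact direction sets are conventions: the estimator is trained per
#' scheme, so only self-consistency between training and inference matters.
#'
#' @param name `"two_shell"` or `"hex_ball"`.
#' @return a [acquisition_scheme()] object.
#' @examples
#' preset_scheme("two_shell")
#' preset_scheme("hex_ball")
#' @export
preset_scheme <- function(name = c("two_shell", "hex_ball")) {
  name <- match.arg(name)
  if (name == "two_shell") {
    dirs <- fibonacci_sphere(30)
    bvals <- c(rep(1.0, 30), rep(2.0, 30))
    bvecs <- rbind(dirs, dirs)
    sid <- c(rep(1L, 30), rep(2L, 30))
  } else {
    q <- hex_ball_qvectors(28)
    r <- sqrt(rowSums(q^2))
    bvals <- 2.0 * (r / max(r))^2
    bvecs <- q / r
    sid <- ifelse(bvals <= 1.0, 1L, 2L)
  }
  parts <- interleave_b0(bvals, bvecs, sid)
  sch <- acquisition_scheme(parts$bvals, parts$bvecs, parts$shell_ids)
  sch$name <- name
  sch
}

# The 28 innermost non-origin FCC lattice points, ordered deterministically by
# (radius, x, y, z). FCC primitive vectors (0,.5,.5), (.5,0,.5), (.5,.5,0).
hex_ball_qvectors <- function(n = 28) {
  rng <- -4:4
  idx <- as.matrix(expand.grid(i = rng, j = rng, k = rng))
  A <- rbind(c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  pts <- idx %*% A
  r <- sqrt(rowSums(pts^2))
  keep <- r > 1e-9
  pts <- pts[keep, , drop = FALSE]; r <- r[keep]
  ord <- order(round(r, 9), round(pts[, 1], 9), round(pts[, 2], 9), round(pts[, 3], 9))
  pts[ord[seq_len(n)], , drop = FALSE]
}

#' Read an FSL-style gradient table
#'
#' @param bval_path path to a whitespace-separated 1 x N b-value file
#'   (s/mm²; converted to ms/µm²; values <= 50 s/mm² are classed as b = 0).
#' @param bvec_path path to the matching 3 x N direction file.
#' @return a [acquisition_scheme()] object.
#' @export
read_gradient_table <- function(bval_path, bvec_path) {
  bv <- scan(bval_path, quiet = TRUE)
  if (any(bv < 0)) stop("negative b-value in ", bval_path, call. = FALSE)
  vec <- as.matrix(utils::read.table(bvec_path))
  if (nrow(vec) != 3L)
    stop("bvec file must have 3 rows (FSL dialect): ", bvec_path, call. = FALSE)
  if (ncol(vec) != length(bv))
    stop("bval/bvec length mismatch: ", length(bv), " vs ", ncol(vec), call. = FALSE)
  b_int <- bv / 1000  # s/mm^2 -> ms/um^2, exact for integer inputs
  g <- t(vec)
  nrm <- sqrt(rowSums(g^2))
  nz <- b_int > B0_THRESHOLD & nrm > 0
  g[nz, ] <- g[nz, ] / nrm[nz]
  acquisition_scheme(b_int, g)
}

#' Write an FSL-style gradient table
#' @param scheme a `dmi_scheme`.
#' @param bval_path,bvec_path output paths.
#' @return invisibly, the two paths.
#' @export
write_gradient_table <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals * 1000, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  m <- t(scheme$bvecs)
  lines <- apply(m, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10, scientific = FALSE), collapse = " "))
  writeLines(lines, bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Scheme fingerprint
#'
#' A short deterministic identifier of a scheme (frame count, b = 0 count and
#' a checksum over b-values and directions), embedded in trained estimators to
#' prevent silent cross-protocol use.
#' @param scheme a `dmi_scheme`.
#' @return character scalar.
#' @export
scheme_fingerprint <- function(scheme) {
  chk <- sum(round(scheme$bvals, 6) * seq_along(scheme$bvals)) +
    sum(round(scheme$bvecs, 6) * matrix(seq_len(3 * nrow(scheme$bvecs)) %% 97 + 1,
                                        nrow(scheme$bvecs), 3))
  sprintf("%s/n%d/b0_%d/chk%.6f", scheme$name, length(scheme$bvals),
          sum(is_b0(scheme)), chk)
}

# strict structural equality used by predict-time guards
schemes_equal <- function(a, b, tol = 1e-6) {
  length(a$bvals) == length(b$bvals) &&
    max(abs(a$bvals - b$bvals)) <= tol &&
    max(abs(a$bvecs - b$bvecs)) <= tol
}
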