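#' Read a 4D diffusion-weighted volume with its gradient table
#'
#' @param image_path NIfTI image (.nii or .nii.gz), 4th dimension = weighting.
#' @param bval_path,bvec_path FSL-style gradient table files; see
#'   [read_gradient_table()].
#' @return a `dmi_volume`: list with `data` (4D array, intensities >= 0),
#'   `scheme` ([acquisition_scheme()]), `voxel_size` (mm triple).
#' @export
read_dwi <- function(image_path, bval_path, bvec_path) {
  img <- RNifti::readNifti(image_path)
  scheme <- read_gradient_table(bval_path, bvec_path)
  arr <- array(as.numeric(img), dim(img))  # plain array, header dropped
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 4L)
    stop("expected a 4D image, got ", length(dim(arr)), "D", call. = FALSE)
  if (dim(arr)[4] != length(scheme))
    stop("image has ", dim(arr)[4], " volumes but gradient table has ",
         length(scheme), " entries", call. = FALSE)
  vs <- RNifti::pixdim(img)[1:3]
  dwi_volume(arr, scheme, voxel_size = vs)
}

#' Construct a DWI volume object
#' @param data 4D array (x, y, z, weighting), non-negative intensities.
#' @param scheme matching `dmi_scheme`.
#' @param voxel_size mm triple.
#' @return a `dmi_volume`.
#' @export
dwi_volume <- function(data, scheme, voxel_size = c(1.5, 1.5, 5)) {
  stopifnot(inherits(scheme, "dmi_scheme"))
  if (length(dim(data)) != 4L || dim(data)[4] != length(scheme))
    stop("4th dimension of data must equal the scheme length", call. = FALSE)
  if (min(data) < 0) stop("negative signal intensities", call. = FALSE)
  structure(list(data = data, scheme = scheme,
                 voxel_size = as.numeric(voxel_size)),
            class = "dmi_volume")
}

#' @export
print.dmi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dmi_volume> %dx%dx%d voxels, %d frames, voxel %.2gx%.2gx%.2g mm\n",
              d[1], d[2], d[3], d[4],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  print(x$scheme)
  invisible(x)
}

#' Write a DWI volume and its gradient table
#' @param volume a `dmi_volume`.
#' @param image_path,bval_path,bvec_path output paths.
#' @return invisibly, the image path.
#' @export
write_dwi <- function(volume, image_path, bval_path, bvec_path) {
  write_nifti_array(volume$data, image_path, volume$voxel_size)
  write_gradient_table(volume$scheme, bval_path, bvec_path)
  invisible(image_path)
}

write_nifti_array <- function(arr, path, voxel_size = c(1, 1, 1)) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  img <- RNifti::asNifti(arr)
  # pixdim replacement must match the image dimensionality exactly
  RNifti::pixdim(img) <- c(voxel_size[1:3], rep(1, length(dim(arr)) - 3L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary voxel mask
#' @param path NIfTI file; values are binarised at 0.5.
#' @return 3D integer array of 0/1.
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) dim(arr) <- dim(arr)[1:3]
  array(as.integer(arr > 0.5), dim(arr))
}

#' Write a binary voxel mask
#' @param mask 3D array of 0/1 (or logical).
#' @param path output NIfTI path.
#' @param voxel_size mm triple.
#' @return invisibly, the path.
#' @export
write_mask <- function(mask, path, voxel_size = c(1.5, 1.5, 5)) {
  m <- array(as.integer(mask > 0.5), dim(mask))
  write_nifti_array(m, path, voxel_size)
}

# canonical parameter order used throughout
DMI_PARAMS <- c("v_intra", "v_extra", "v_csf",
                "d_ax_intra", "d_ax_extra", "d_rad_extra")

#' Construct parameter maps
#'
#' A `dmi_maps` object holds the six standard-model parameter fields
#' (volume fractions `v_intra`, `v_extra`, `v_csf`; diffusivities
#' `d_ax_intra`, `d_ax_extra`, `d_rad_extra`, µm²/ms) and optionally `adc`,
#' each a 3D array on a common grid. Voxels outside the processing mask
#' are `NA`.
#'
#' @param fields named list of 3D arrays (the six parameters, optional `adc`).
#' @param mask 3D 0/1 array marking valid voxels.
#' @param voxel_size mm triple.
#' @param check validate fraction simplex and diffusivity range inside mask.
#' @return a `dmi_maps` object.
#' @export
parameter_maps <- function(fields, mask, voxel_size = c(1.5, 1.5, 5),
                           check = TRUE) {
  stopifnot(all(DMI_PARAMS %in% names(fields)))
  dims <- dim(fields[[1]])
  for (f in fields) stopifnot(identical(dim(f), dims))
  stopifnot(identical(dim(mask), dims))
  if (check) {
    idx <- which(mask > 0)
    if (length(idx)) {
      fr <- fields$v_intra[idx] + fields$v_extra[idx] + fields$v_csf[idx]
      if (max(abs(fr - 1)) > 1e-6)
        stop("volume fractions do not sum to 1 inside the mask", call. = FALSE)
      for (p in DMI_PARAMS) {
        v <- fields[[p]][idx]
        if (min(v) < -1e-9 || max(v) > 3 + 1e-9)
          stop("parameter ", p, " outside [0, 3] inside the mask", call. = FALSE)
      }
    }
  }
  structure(list(fields = fields, mask = mask,
                 voxel_size = as.numeric(voxel_size)),
            class = "dmi_maps")
}

#' @export
print.dmi_maps <- function(x, ...) {
  d <- dim(x$fields[[1]])
  cat(sprintf("<dmi_maps> %dx%dx%d, %d voxels in mask, fields: %s\n",
              d[1], d[2], d[3], sum(x$mask > 0),
              paste(names(x$fields), collapse = ", ")))
  invisible(x)
}

#' Tidy a parameter-map set into a voxel table
#' @param x a `dmi_maps`.
#' @param ... unused.
#' @return tibble with columns x, y, z and one column per field (masked
#'   voxels only).
#' @export
tidy.dmi_maps <- function(x, ...) {
  idx <- which(x$mask > 0)
  co <- arrayInd(idx, dim(x$mask))
  vals <- lapply(x$fields, function(f) f[idx])
  tibble::as_tibble(c(list(x = co[, 1], y = co[, 2], z = co[, 3]), vals))
}

#' Write parameter maps as one NIfTI per parameter
#' @param maps a `dmi_maps`.
#' @param out_dir output directory (created if missing).
#' @return invisibly, character vector of written paths.
#' @export
write_parameter_maps <- function(maps, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  paths <- character(0)
  for (nm in names(maps$fields)) {
    p <- file.path(out_dir, paste0(nm, ".nii.gz"))
    arr <- maps$fields[[nm]]
    arr[is.na(arr)] <- 0
    write_nifti_array(arr, p, maps$voxel_size)
    paths <- c(paths, p)
  }
  pm <- file.path(out_dir, "processing_mask.nii.gz")
  write_mask(maps$mask, pm, maps$voxel_size)
  invisible(c(paths, pm))
}

#' Read parameter maps written by [write_parameter_maps()]
#' @param dir directory containing the per-parameter NIfTI files.
#' @return a `dmi_maps`.
#' @export
read_parameter_maps <- function(dir) {
  mask <- read_mask(file.path(dir, "processing_mask.nii.gz"))
  nms <- DMI_PARAMS
  adc_path <- file.path(dir, "adc.nii.gz")
  if (file.exists(adc_path)) nms <- c(nms, "adc")
  fields <- lapply(nms, function(nm) {
    img <- RNifti::readNifti(file.path(dir, paste0(nm, ".nii.gz")))
    arr <- array(as.numeric(img), dim(img))
    arr[mask == 0] <- NA_real_
    arr
  })
  names(fields) <- nms
  vs <- RNifti::pixdim(RNifti::readNifti(file.path(dir, paste0(nms[1], ".nii.gz"))))[1:3]
  parameter_maps(fields, mask, voxel_size = vs, check = FALSE)
}
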