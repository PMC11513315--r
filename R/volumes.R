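#' Voxel volume container
#'
#' A `voxel_volume` is a plain 3D numeric array carrying its physical voxel
#' spacing in millimetres. It is the carrier for T1-like intensities, binary
#' masks, class maps and bias fields. Physical coordinates follow the voxel
#' lattice convention used throughout the package: the centre of voxel
#' `(i, j, k)` (1-based array index) sits at `((i,j,k) - 1) * spacing_mm`,
#' i.e. 0-based voxel indices scaled by the spacing, with axes x = left-right,
#' y = anterior-posterior, z = inferior-superior.
#'
#' @param values 3D numeric array.
#' @param spacing_mm Positive numeric length-3 voxel size in mm (default 1 mm
#'   isotropic).
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing_mm = c(1, 1, 1)) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 strictly positive values")
  structure(values, spacing_mm = spacing_mm, class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<voxel_volume> %d x %d x %d, spacing %s mm, range [%g, %g]\n",
              d[1], d[2], d[3],
              paste(signif(vol_spacing(x), 4), collapse = " x "),
              min(x), max(x)))
  invisible(x)
}

#' Voxel spacing of a volume
#' @param vol A `voxel_volume` or `tensor_volume`.
#' @return Numeric length-3 spacing in mm.
#' @export
vol_spacing <- function(vol) {
  sp <- attr(vol, "spacing_mm")
  if (is.null(sp)) sp <- c(1, 1, 1)
  sp
}

#' Volume of a single voxel in cubic millimetres
#' @param vol A `voxel_volume` or `tensor_volume`.
#' @export
voxel_mm3 <- function(vol) prod(vol_spacing(vol))

# Strip class/attrs down to a plain array (RNifti and arithmetic helpers).
as_plain_array <- function(vol) {
  a <- unclass(vol)
  attr(a, "spacing_mm") <- NULL
  a
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; returns 1 when both masks are empty.
#'
#' @param a,b Binary volumes/arrays of identical shape.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  a <- as_plain_array(a) > 0
  b <- as_plain_array(b) > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Diffusion tensor volume container
#'
#' Stores one symmetric 3x3 diffusion tensor per voxel as a 4D array whose
#' fourth dimension holds the six unique components in the order
#' `(Dxx, Dxy, Dxz, Dyy, Dyz, Dzz)`, units mm^2/s. The same lattice
#' convention as [voxel_volume()] applies.
#'
#' @param components 4D numeric array with `dim[4] == 6`.
#' @param spacing_mm Positive length-3 voxel size in mm.
#' @return An object of class `tensor_volume`.
#' @export
tensor_volume <- function(components, spacing_mm = c(1, 1, 1)) {
  if (length(dim(components)) != 4L || dim(components)[4] != 6L)
    stop("`components` must be a 4D array with 6 tensor components")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 strictly positive values")
  structure(components, spacing_mm = spacing_mm, class = "tensor_volume")
}

#' @export
print.tensor_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<tensor_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(signif(vol_spacing(x), 4), collapse = " x ")))
  invisible(x)
}

# Index of each unique component within the (xx, xy, xz, yy, yz, zz) layout.
TENSOR_COMP <- c(xx = 1L, xy = 2L, xz = 3L, yy = 4L, yz = 5L, zz = 6L)

#' Extract the 3x3 tensor at one voxel
#' @param tensors A `tensor_volume`.
#' @param i,j,k 1-based voxel indices.
#' @return Symmetric 3x3 matrix.
#' @export
tensor_at <- function(tensors, i, j, k) {
  v <- tensors[i, j, k, ]
  matrix(c(v[1], v[2], v[3],
           v[2], v[4], v[5],
           v[3], v[5], v[6]), 3, 3)
}

#' Read a volume from a NIfTI-1 file
#'
#' 3D files become [voxel_volume()] objects; 4D files with 6 components on
#' the fourth axis become [tensor_volume()] objects.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @export
read_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf(
                    "'%s' is not a readable NIfTI file: %s",
                    path, conditionMessage(e)), call. = FALSE))
  arr <- as.array(img)
  sp <- RNifti::pixdim(img)[seq_len(min(3L, length(dim(arr))))]
  if (length(dim(arr)) == 4L && dim(arr)[4] == 6L)
    return(tensor_volume(arr, spacing_mm = sp))
  if (length(dim(arr)) != 3L)
    stop(sprintf("'%s' is neither a 3D volume nor a 6-component tensor file",
                 path))
  voxel_volume(arr, spacing_mm = sp)
}

#' Write a volume to a NIfTI-1 file
#'
#' The voxel spacing is encoded in the NIfTI pixdim/affine. Binary masks and
#' label maps should be written with `datatype = "uint8"`.
#'
#' @param vol A `voxel_volume` or `tensor_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type, e.g. `"auto"`, `"uint8"`, `"float"`,
#'   `"double"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "auto") {
  arr <- as_plain_array(vol)
  img <- RNifti::asNifti(arr)
  pd <- RNifti::pixdim(img)
  sp <- vol_spacing(vol)
  pd[seq_len(min(3L, length(pd)))] <- sp[seq_len(min(3L, length(pd)))]
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# Check that two volumes share grid shape (first three dims) and spacing;
# errors naming both roles when they do not.
check_aligned <- function(a, b, name_a = "volume", name_b = "mask") {
  da <- dim(a)[1:3]; db <- dim(b)[1:3]
  if (!identical(da, db))
    stop(sprintf("%s (%s) and %s (%s) have different grid shapes",
                 name_a, paste(da, collapse = "x"),
                 name_b, paste(db, collapse = "x")))
  if (max(abs(vol_spacing(a) - vol_spacing(b))) > 1e-6)
    stop(sprintf("%s and %s have different voxel spacings", name_a, name_b))
  invisible(TRUE)
}

# Physical mm coordinate of the centre of each voxel along one axis.
axis_coords_mm <- function(n, spacing) (seq_len(n) - 1) * spacing
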