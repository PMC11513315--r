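#' Spherical region of interest on a voxel lattice
#'
#' A voxel belongs to the ROI iff its physical centre lies within
#' `diameter_mm / 2` of `center_mm` (Euclidean distance in mm, so
#' anisotropic voxels are handled correctly). The default 5 mm diameter
#' matches the standard ALPS protocol.
#'
#' @param center_mm Physical centre (mm, length 3) in the volume's frame
#'   (voxel `(i,j,k)` centre at `((i,j,k)-1) * spacing`).
#' @param diameter_mm Sphere diameter in mm (default 5).
#' @param geometry A `voxel_volume`/`tensor_volume`, or a list with
#'   `shape` and `spacing_mm`.
#' @return Binary [voxel_volume()]; errors if no voxel centre falls inside
#'   the sphere.
#' @export
make_sphere_roi <- function(center_mm, diameter_mm = 5, geometry) {
  if (is.list(geometry) && !is.null(geometry$shape)) {
    shape <- as.integer(geometry$shape)
    sp <- geometry$spacing_mm
  } else {
    shape <- dim(geometry)[1:3]
    sp <- vol_spacing(geometry)
  }
  if (length(sp) == 1L) sp <- rep(sp, 3)
  if (diameter_mm <= max(sp))
    warning("ROI diameter is not larger than the largest voxel dimension")
  r2 <- (diameter_mm / 2)^2
  dx2 <- (axis_coords_mm(shape[1], sp[1]) - center_mm[1])^2
  dy2 <- (axis_coords_mm(shape[2], sp[2]) - center_mm[2])^2
  dz2 <- (axis_coords_mm(shape[3], sp[3]) - center_mm[3])^2
  inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r2
  if (!any(inside))
    stop("sphere contains no voxel centre (outside the grid?)")
  voxel_volume(array(as.integer(inside), dim = shape), sp)
}

# Principal eigenvector (unit, largest eigenvalue) of the tensor at each
# ROI voxel. Returns list(lin = linear indices kept, vec = 3 x n matrix,
# skipped = count of non-finite tensors).
principal_directions <- function(tensors, roi) {
  d <- dim(tensors)[1:3]
  lin <- which(as_plain_array(roi) > 0)
  nvox <- prod(d)
  comp <- as_plain_array(tensors)
  vec <- matrix(NA_real_, 3, length(lin))
  ok <- logical(length(lin))
  for (i in seq_along(lin)) {
    v6 <- comp[lin[i] + (0:5) * nvox]
    if (any(!is.finite(v6))) next
    M <- matrix(c(v6[1], v6[2], v6[3],
                  v6[2], v6[4], v6[5],
                  v6[3], v6[5], v6[6]), 3, 3)
    e <- eigen(M, symmetric = TRUE)
    vec[, i] <- e$vectors[, 1]
    ok[i] <- TRUE
  }
  list(lin = lin[ok], vec = vec[, ok, drop = FALSE],
       skipped = sum(!ok))
}

# Dominant-axis label for unit vectors: 1 projection (z), 2 association
# (y), 3 subcortical (x); ties broken in the order z > y > x.
dominant_axis_label <- function(vec) {
  az <- abs(vec[3, ]); ay <- abs(vec[2, ]); ax <- abs(vec[1, ])
  ifelse(az >= ay & az >= ax, 1L, ifelse(ay >= ax, 2L, 3L))
}

#' Classify ROI voxels into fiber populations by principal diffusion
#' direction
#'
#' Each ROI voxel's tensor is diagonalized; the voxel is labelled
#' projection fiber if the absolute z-component of the principal
#' eigenvector is largest, association fiber if the y-component is largest,
#' subcortical fiber if the x-component is largest. Exact ties are broken
#' in the order z > y > x. Voxels with non-finite tensors are skipped and
#' counted in `qc`.
#'
#' @param tensors A [tensor_volume()].
#' @param roi Binary [voxel_volume()] (nonempty).
#' @return List: `labels` ([voxel_volume()], 0 outside ROI, 1 projection,
#'   2 association, 3 subcortical) and `qc` (per-class counts, skipped).
#' @export
classify_fiber_voxels <- function(tensors, roi) {
  check_aligned(tensors, roi, "tensors", "roi")
  if (!any(as_plain_array(roi) > 0)) stop("roi is empty")
  pd <- principal_directions(tensors, roi)
  lab <- array(0L, dim = dim(tensors)[1:3])
  if (length(pd$lin) > 0)
    lab[pd$lin] <- dominant_axis_label(pd$vec)
  counts <- tabulate(lab[lab > 0], nbins = 3)
  list(labels = voxel_volume(lab, vol_spacing(tensors)),
       qc = list(n_projection = counts[1], n_association = counts[2],
                 n_subcortical = counts[3], n_skipped = pd$skipped))
}

#' Select one representative voxel per fiber class on a shared x-axis
#'
#' Restricted to x-indices where both a projection and an association voxel
#' occur inside the ROI, picks for each class the voxel with the maximum
#' orientation -- by default the largest absolute principal-eigenvector
#' component along that class's axis (`orientation = "component"`), or the
#' largest fractional anisotropy (`orientation = "fa"`). Diffusivities are
#' read as raw tensor diagonal entries in scanner axes at the selected
#' voxels: `Dxproj`/`Dyproj` at the projection voxel, `Dxassoc`/`Dzassoc`
#' at the association voxel.
#'
#' @param labels Label [voxel_volume()] from [classify_fiber_voxels()].
#' @param tensors A [tensor_volume()].
#' @param roi Binary [voxel_volume()].
#' @param orientation `"component"` (default) or `"fa"`.
#' @return List with `Dxproj`, `Dyproj`, `Dxassoc`, `Dzassoc` (mm^2/s) and
#'   `voxels`: the 1-based array indices of the two selected voxels.
#' @export
select_fiber_representatives <- function(labels, tensors, roi,
                                         orientation = c("component", "fa")) {
  orientation <- match.arg(orientation)
  check_aligned(labels, tensors, "labels", "tensors")
  d <- dim(tensors)[1:3]
  nvox <- prod(d)
  comp <- as_plain_array(tensors)
  lab <- as_plain_array(labels)
  lin_p <- which(lab == 1L & as_plain_array(roi) > 0)
  lin_a <- which(lab == 2L & as_plain_array(roi) > 0)
  co_p <- arrayInd(lin_p, d); co_a <- arrayInd(lin_a, d)
  shared_x <- intersect(co_p[, 1], co_a[, 1])
  if (length(lin_p) == 0) stop("no projection-fiber voxel in the ROI")
  if (length(lin_a) == 0) stop("no association-fiber voxel in the ROI")
  if (length(shared_x) == 0)
    stop(paste("no x-index holds both a projection and an association",
               "fiber voxel"))
  keep_p <- co_p[, 1] %in% shared_x
  keep_a <- co_a[, 1] %in% shared_x
  lin_p <- lin_p[keep_p]; lin_a <- lin_a[keep_a]

  score <- function(lin, axis_row) {
    vapply(lin, function(l) {
      v6 <- comp[l + (0:5) * nvox]
      M <- matrix(c(v6[1], v6[2], v6[3],
                    v6[2], v6[4], v6[5],
                    v6[3], v6[5], v6[6]), 3, 3)
      if (orientation == "fa") {
        ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
        mb <- mean(ev)
        sqrt(3 / 2) * sqrt(sum((ev - mb)^2)) / sqrt(sum(ev^2))
      } else {
        abs(eigen(M, symmetric = TRUE)$vectors[axis_row, 1])
      }
    }, 0)
  }
  best_p <- lin_p[which.max(score(lin_p, 3L))]
  best_a <- lin_a[which.max(score(lin_a, 2L))]
  read6 <- function(l) comp[l + (0:5) * nvox]
  tp <- read6(best_p); ta <- read6(best_a)
  list(Dxproj = tp[TENSOR_COMP["xx"]], Dyproj = tp[TENSOR_COMP["yy"]],
       Dxassoc = ta[TENSOR_COMP["xx"]], Dzassoc = ta[TENSOR_COMP["zz"]],
       voxels = list(projection = arrayInd(best_p, d)[1, ],
                     association = arrayInd(best_a, d)[1, ]))
}

#' ALPS region-of-interest descriptor
#'
#' @param center_mm Physical ROI centre (mm).
#' @param diameter_mm Sphere diameter (default 5 mm).
#' @param hemisphere Annotation only (default `"left"`, the conventional
#'   side); does not change the computation.
#' @return An object of class `alps_roi`.
#' @export
alps_roi <- function(center_mm, diameter_mm = 5, hemisphere = "left") {
  structure(list(center_mm = as.numeric(center_mm),
                 diameter_mm = diameter_mm, hemisphere = hemisphere),
            class = "alps_roi")
}

#' Compute the DTI-ALPS index
#'
#' Composes the spherical ROI, principal-direction fiber classification and
#' shared-x representative selection, then applies the index formula
#' `ALPS = mean(Dxproj, Dxassoc) / mean(Dyproj, Dzassoc)`: the ratio of
#' x-axis (perivascular-direction) diffusivity in fibers running
#' perpendicular to x, over their own principal-perpendicular
#' diffusivities. The index is 1 for isotropic diffusion and rises with
#' preferential diffusion along the perivascular axis; it is invariant to a
#' global rescaling of the tensor field.
#'
#' @param tensors A [tensor_volume()].
#' @param roi An [alps_roi()] (or list with `center_mm`, `diameter_mm`).
#' @param orientation Passed to [select_fiber_representatives()].
#' @return An object of class `alps_result`: `diffusivities` (the four
#'   directional diffusivities and selected voxels), `index`, `qc` (fiber
#'   counts in the ROI), `roi`.
#' @export
compute_alps <- function(tensors, roi, orientation = "component") {
  if (!inherits(roi, "alps_roi"))
    roi <- alps_roi(roi$center_mm,
                    if (is.null(roi$diameter_mm)) 5 else roi$diameter_mm,
                    if (is.null(roi$hemisphere)) "left" else roi$hemisphere)
  roi_mask <- make_sphere_roi(roi$center_mm, roi$diameter_mm, tensors)
  cls <- classify_fiber_voxels(tensors, roi_mask)
  diff <- select_fiber_representatives(cls$labels, tensors, roi_mask,
                                       orientation = orientation)
  idx <- mean(c(diff$Dxproj, diff$Dxassoc)) /
    mean(c(diff$Dyproj, diff$Dzassoc))
  structure(list(diffusivities = diff, index = idx, qc = cls$qc, roi = roi),
            class = "alps_result")
}

#' @export
print.alps_result <- function(x, ...) {
  d <- x$diffusivities
  cat(sprintf(paste0("<alps_result> index %.3f  (Dxproj %.2e, Dxassoc %.2e,",
                     " Dyproj %.2e, Dzassoc %.2e mm^2/s)\n"),
              x$index, d$Dxproj, d$Dxassoc, d$Dyproj, d$Dzassoc))
  invisible(x)
}
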