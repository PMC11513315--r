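# Separable 3D Gaussian smoothing by banded row-normalized convolution
# matrices along each axis; edge effects handled by the row normalization.
gaussian_smooth_3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  if (length(sigma_vox) == 1L) sigma_vox <- rep(sigma_vox, 3)
  smooth_axis <- function(a, axis) {
    s <- sigma_vox[axis]
    if (s <= 0) return(a)
    n <- dim(a)[axis]
    K <- stats::dnorm(outer(seq_len(n), seq_len(n), `-`), sd = s)
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = n)
    out <- array(K %*% m, dim = dim(ap))
    aperm(out, order(perm))
  }
  for (axis in 1:3) arr <- smooth_axis(arr, axis)
  arr
}

#' Estimate a multiplicative bias field inside a mask
#'
#' A deliberately simple intensity-inhomogeneity estimator: in-mask voxels
#' are provisionally split into three intensity classes by 1D k-means
#' (quantile-initialized, deterministic), each voxel's class-mean log
#' intensity is subtracted from its own log intensity, and the residuals are
#' smoothed by a heavy Gaussian kernel (normalized convolution, so only
#' in-mask voxels contribute). The exponentiated smooth residual,
#' renormalized to mean 1 over the mask, is the estimated field; dividing
#' the image by it yields the corrected volume. Removing the provisional
#' class means first keeps the estimate near 1 on bias-free images even
#' though the tissue classes are spatially structured.
#'
#' @param t1 Intensity [voxel_volume()].
#' @param mask Binary [voxel_volume()] aligned with `t1`.
#' @param scale_mm Smoothing kernel SD in mm (default 12); must be large
#'   compared with the voxel size.
#' @param n_classes Provisional intensity classes (default 3).
#' @return A [voxel_volume()] bias field (1 outside the mask's support).
#' @export
estimate_bias_field <- function(t1, mask, scale_mm = 12, n_classes = 3L) {
  check_aligned(t1, mask, "t1", "mask")
  m <- as_plain_array(mask) > 0
  if (!any(m)) stop("mask is empty")
  vals <- as_plain_array(t1)[m]
  if (all(vals == 0)) stop("all-zero intensities in mask")
  ok <- m
  ok[m] <- vals > 0
  x <- as_plain_array(t1)[ok]

  qs <- unique(stats::quantile(x, probs = (seq_len(n_classes) - 0.5) /
                                 n_classes))
  if (length(qs) > 1L) {
    km <- suppressWarnings(stats::kmeans(x, centers = matrix(qs),
                                         iter.max = 50))
    class_mean <- as.numeric(km$centers)[km$cluster]
  } else {
    class_mean <- rep(mean(x), length(x))   # effectively a single class
  }
  resid <- log(x) - log(class_mean)

  sp <- vol_spacing(t1)
  sigma_vox <- scale_mm / sp
  num <- array(0, dim = dim(ok)); num[ok] <- resid
  den <- array(0, dim = dim(ok)); den[ok] <- 1
  num_s <- gaussian_smooth_3d(num, sigma_vox)
  den_s <- gaussian_smooth_3d(den, sigma_vox)
  logf <- array(0, dim = dim(ok))
  supported <- den_s > 1e-8
  logf[supported] <- num_s[supported] / den_s[supported]
  field <- exp(logf)
  field <- field / mean(field[m])
  field[!supported] <- 1
  voxel_volume(field, sp)
}

# Label 26-connected components of a binary 3D mask. Returns an integer
# array: 0 outside, component id inside. Adjacency is built explicitly and
# handed to igraph's component search.
label_components_26 <- function(mask) {
  d <- dim(mask)
  lin <- which(mask > 0)
  lab <- array(0L, dim = d)
  nv <- length(lin)
  if (nv == 0L) return(lab)
  id_of <- array(0L, dim = d)
  id_of[lin] <- seq_len(nv)
  co <- arrayInd(lin, d)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  offsets <- offsets[offsets[, 1] > 0 |
                     (offsets[, 1] == 0 & offsets[, 2] > 0) |
                     (offsets[, 1] == 0 & offsets[, 2] == 0 &
                      offsets[, 3] > 0), , drop = FALSE]
  edges <- vector("list", nrow(offsets))
  for (r in seq_len(nrow(offsets))) {
    nb <- sweep(co, 2, offsets[r, ], `+`)
    inb <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
           nb[, 2] >= 1 & nb[, 2] <= d[2] &
           nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(inb)) next
    nb_id <- id_of[nb[inb, , drop = FALSE]]
    src <- seq_len(nv)[inb]
    keep <- nb_id > 0L
    if (any(keep))
      edges[[r]] <- cbind(src[keep], nb_id[keep])
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  if (!is.null(em) && nrow(em) > 0)
    g <- igraph::add_edges(g, t(em))
  comp <- igraph::components(g)
  lab[lin] <- as.integer(comp$membership)
  lab
}

#' Rule-based cleanup of a candidate choroid-plexus mask
#'
#' Stands in for expert manual refinement with two explicit rules: drop
#' 26-connected components smaller than `min_component_vox` voxels (flow
#' artifacts / noise specks), and, when a ventricle boundary shell is
#' supplied, drop CP voxels lying on that 1-voxel inner boundary
#' (wall-contamination rule). The operation is idempotent.
#'
#' @param mask Binary [voxel_volume()].
#' @param min_component_vox Minimum surviving component size (default 5).
#' @param boundary_shell Optional binary [voxel_volume()]: the inner boundary
#'   shell of the ventricle mask (see [ventricle_shell()]).
#' @return Cleaned binary [voxel_volume()].
#' @export
refine_mask <- function(mask, min_component_vox = 5L, boundary_shell = NULL) {
  m <- as_plain_array(mask) > 0
  if (!is.null(boundary_shell)) {
    check_aligned(mask, boundary_shell, "mask", "boundary_shell")
    m <- m & !(as_plain_array(boundary_shell) > 0)
  }
  lab <- label_components_26(m)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < min_component_vox)
    if (length(drop) > 0) m[lab %in% drop] <- FALSE
  }
  voxel_volume(array(as.integer(m), dim = dim(m)), vol_spacing(mask))
}

#' Inner boundary shell of a binary mask
#'
#' The 1-voxel-thick layer of in-mask voxels with at least one face
#' neighbour outside the mask (or on the grid edge) -- where ventricular-wall
#' partial-volume voxels live.
#'
#' @param mask Binary [voxel_volume()].
#' @return Binary [voxel_volume()] of the shell.
#' @export
ventricle_shell <- function(mask) {
  sh <- inner_shell(as_plain_array(mask) > 0)
  voxel_volume(array(as.integer(sh), dim = dim(sh)), vol_spacing(mask))
}

#' TIV-normalized volume of a binary mask
#'
#' @param cp_mask Binary [voxel_volume()].
#' @param tiv_mm3 Total intracranial volume in mm^3 (> 0).
#' @return List `mm3` (voxel count times voxel volume) and `pct`
#'   (`100 * mm3 / tiv_mm3`); both 0 for an empty mask.
#' @export
compute_normalized_volume <- function(cp_mask, tiv_mm3) {
  if (!is.numeric(tiv_mm3) || tiv_mm3 <= 0) stop("tiv_mm3 must be > 0")
  mm3 <- sum(as_plain_array(cp_mask) > 0) * voxel_mm3(cp_mask)
  list(mm3 = mm3, pct = 100 * mm3 / tiv_mm3)
}

#' Segment the choroid plexus inside a lateral-ventricle mask
#'
#' Fits a K-class Gaussian mixture ([fit_gmm_em()]) to the in-mask voxel
#' intensities and assigns each in-mask voxel to its maximum-a-posteriori
#' component. Tissue identity follows the T1 intensity convention: the
#' lowest-mean component is CSF (darkest), the middle component is choroid
#' plexus, the highest is ventricular wall / partial volume (brightest).
#' The candidate CP mask is then cleaned by [refine_mask()] (small-component
#' removal plus the boundary-shell rule) and its volume normalized by the
#' supplied total intracranial volume.
#'
#' When the fitted components are not separated (minimum pairwise
#' `|mu_i - mu_j| / sqrt((v_i + v_j)/2)` below `options$min_separation`,
#' default 2), the intensity histogram does not support distinct tissue
#' classes: the CP class is treated as absent, a warning is raised, and
#' `qc$degenerate` is set.
#'
#' @param t1 Intensity [voxel_volume()] (bias-corrected, or use
#'   `options$bias_correct = TRUE`).
#' @param ventricle_mask Binary [voxel_volume()] aligned with `t1`.
#' @param tiv_mm3 Total intracranial volume in mm^3.
#' @param options Named list overriding: `K` (3), `init` ("quantile"),
#'   `tol` (1e-6), `max_iter` (500), `seed` (NULL), `min_component_vox` (5),
#'   `use_boundary_shell` (TRUE), `min_separation` (2),
#'   `bias_correct` (FALSE), `bias_scale_mm` (12).
#' @return An object of class `cp_segmentation`: `cp_mask`, `class_map`
#'   (0 outside, 1 CSF, 2 CP, 3 wall for K = 3), `cp_volume_mm3`,
#'   `cp_volume_pct`, `model` (the fitted `gmm`), and `qc` (per-class voxel
#'   counts before cleanup, voxels removed by cleanup, convergence flag,
#'   iterations, degeneracy flag).
#' @export
segment_cp <- function(t1, ventricle_mask, tiv_mm3, options = list()) {
  opt <- utils::modifyList(list(K = 3L, init = "quantile", tol = 1e-6,
                                max_iter = 500L, seed = NULL,
                                min_component_vox = 5L,
                                use_boundary_shell = TRUE,
                                min_separation = 2,
                                bias_correct = FALSE, bias_scale_mm = 12),
                           options)
  check_aligned(t1, ventricle_mask, "t1", "ventricle_mask")
  if (tiv_mm3 <= 0) stop("tiv_mm3 must be > 0")
  m <- as_plain_array(ventricle_mask) > 0
  if (!any(m)) stop("ventricle mask is empty")

  if (isTRUE(opt$bias_correct)) {
    field <- estimate_bias_field(t1, ventricle_mask,
                                 scale_mm = opt$bias_scale_mm)
    t1 <- voxel_volume(as_plain_array(t1) / as_plain_array(field),
                       vol_spacing(t1))
  }

  x <- as_plain_array(t1)[m]
  model <- fit_gmm_em(x, K = opt$K, init = opt$init, tol = opt$tol,
                      max_iter = opt$max_iter, seed = opt$seed)

  labels <- gmm_map(model, x)
  class_map <- array(0L, dim = dim(m))
  class_map[m] <- labels
  counts <- tabulate(labels, nbins = model$K)

  # CP = middle-mean component; with K != 3 the middle component
  # ceiling(K/2)... only K >= 3 has a wall class above and CSF below.
  cp_class <- if (model$K >= 3L) 2L else model$K

  sep <- Inf
  if (model$K >= 2L) {
    pr <- utils::combn(model$K, 2)
    sep <- min(abs(model$means[pr[1, ]] - model$means[pr[2, ]]) /
               sqrt((model$variances[pr[1, ]] + model$variances[pr[2, ]]) / 2))
  }
  degenerate <- is.finite(sep) && sep < opt$min_separation

  sp <- vol_spacing(t1)
  if (degenerate) {
    warning("mixture components are not separated; ",
            "treating the CP class as absent")
    cp_raw <- array(0L, dim = dim(m))
  } else {
    cp_raw <- array(as.integer(class_map == cp_class), dim = dim(m))
  }
  cp_raw <- voxel_volume(cp_raw, sp)
  shell <- if (isTRUE(opt$use_boundary_shell))
    ventricle_shell(ventricle_mask) else NULL
  cp_mask <- refine_mask(cp_raw, opt$min_component_vox, shell)

  vol <- compute_normalized_volume(cp_mask, tiv_mm3)
  structure(list(
    cp_mask = cp_mask,
    class_map = voxel_volume(class_map, sp),
    cp_volume_mm3 = vol$mm3,
    cp_volume_pct = vol$pct,
    model = model,
    qc = list(class_counts = counts,
              removed_vox = sum(as_plain_array(cp_raw)) -
                sum(as_plain_array(cp_mask)),
              converged = model$converged,
              iterations = model$iterations,
              degenerate = degenerate,
              min_separation = sep)),
    class = "cp_segmentation")
}

#' @export
print.cp_segmentation <- function(x, ...) {
  cat(sprintf("<cp_segmentation> CP volume %.1f mm^3 (%.3f%% of TIV), %s\n",
              x$cp_volume_mm3, x$cp_volume_pct,
              if (x$qc$degenerate) "DEGENERATE mixture"
              else sprintf("EM %s in %d iterations",
                           if (x$qc$converged) "converged" else "stopped",
                           x$qc$iterations)))
  invisible(x)
}
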