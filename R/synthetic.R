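#' Specification of a T1-like ventricle phantom
#'
#' Describes a synthetic T1 volume containing a pair of ellipsoidal lateral
#' ventricles. Voxel intensities inside the ventricle mask come from a
#' three-class Gaussian mixture: CSF (darkest), choroid plexus (intermediate)
#' and ventricular wall (brightest, the partial-volume shell at the mask
#' boundary) -- the T1 intensity ordering the segmentation relies on. The
#' choroid plexus occupies `cp_fraction` of the ventricle voxels as one
#' compact blob per ventricle at its posterior (+y) pole.
#'
#' @param grid_shape Integer length-3 voxel counts per axis.
#' @param spacing_mm Voxel size in mm (length 3 or scalar).
#' @param tiv_mm3 Total intracranial volume (mm^3) used to normalize the CP
#'   volume; a pipeline input, not derived from the grid.
#' @param ventricle_centers_mm List of two length-3 physical centres (mm); by
#'   default the two ellipsoids sit 11 mm left/right of the grid centre.
#' @param semi_axes_mm Ellipsoid semi-axes (mm), shared by both ventricles.
#' @param cp_fraction Target fraction of ventricle voxels assigned to CP,
#'   in (0, 1).
#' @param class_params Named list `csf`, `cp`, `wall`, each `c(mean, sd)` of
#'   the class intensity Gaussian; means must be strictly ordered
#'   csf < cp < wall and sds strictly positive.
#' @param bias_amplitude Peak multiplicative deviation of the smooth bias
#'   field in `[0, 1)`; 0 disables the bias field.
#' @param seed RNG seed; identical specs produce bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 44L, 24L),
                         spacing_mm = c(1, 1, 1),
                         tiv_mm3 = 64000,
                         ventricle_centers_mm = NULL,
                         semi_axes_mm = c(8, 16, 6),
                         cp_fraction = 0.25,
                         class_params = list(csf  = c(mean = 30, sd = 3),
                                             cp   = c(mean = 55, sd = 3),
                                             wall = c(mean = 80, sd = 3)),
                         bias_amplitude = 0,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- if (length(spacing_mm) == 1L) rep(spacing_mm, 3) else
    as.numeric(spacing_mm)
  if (is.null(ventricle_centers_mm)) {
    ctr <- (grid_shape - 1) / 2 * spacing_mm
    ventricle_centers_mm <- list(ctr - c(11, 0, 0), ctr + c(11, 0, 0))
  }
  spec <- structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                         tiv_mm3 = tiv_mm3,
                         ventricle_centers_mm = ventricle_centers_mm,
                         semi_axes_mm = as.numeric(semi_axes_mm),
                         cp_fraction = cp_fraction,
                         class_params = class_params,
                         bias_amplitude = bias_amplitude,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(grid_shape) != 3L || any(grid_shape < 4L))
      stop("grid_shape must be 3 integers >= 4")
    if (any(spacing_mm <= 0)) stop("spacing_mm must be positive")
    if (!(cp_fraction > 0 && cp_fraction < 1))
      stop("cp_fraction must lie in (0, 1)")
    mus <- vapply(class_params[c("csf", "cp", "wall")], `[[`, 0, "mean")
    sds <- vapply(class_params[c("csf", "cp", "wall")], `[[`, 0, "sd")
    if (any(sds <= 0)) stop("class sds must be strictly positive")
    if (!(mus[1] < mus[2] && mus[2] < mus[3]))
      stop("class means must satisfy csf < cp < wall")
    if (bias_amplitude < 0 || bias_amplitude >= 1)
      stop("bias_amplitude must lie in [0, 1)")
    vent_mm3 <- length(ventricle_centers_mm) *
      4 / 3 * pi * prod(semi_axes_mm)
    if (tiv_mm3 <= vent_mm3)
      stop("tiv_mm3 must exceed the ventricle volume")
  })
  invisible(spec)
}

# Rasterize the ellipsoid pair; returns integer array: 0 outside,
# e = index of the ellipsoid containing the voxel (first wins on overlap).
rasterize_ventricles <- function(spec) {
  d <- spec$grid_shape; sp <- spec$spacing_mm
  if (any(spec$semi_axes_mm < 2 * sp))
    stop("degenerate ellipsoid: every semi-axis must span >= 2 voxels")
  xs <- axis_coords_mm(d[1], sp[1])
  ys <- axis_coords_mm(d[2], sp[2])
  zs <- axis_coords_mm(d[3], sp[3])
  lab <- array(0L, dim = d)
  ax <- spec$semi_axes_mm
  for (e in rev(seq_along(spec$ventricle_centers_mm))) {
    ctr <- spec$ventricle_centers_mm[[e]]
    qx <- ((xs - ctr[1]) / ax[1])^2
    qy <- ((ys - ctr[2]) / ax[2])^2
    qz <- ((zs - ctr[3]) / ax[3])^2
    q <- outer(outer(qx, qy, `+`), qz, `+`)
    lab[q <= 1] <- e
  }
  lab
}

# 6-neighbour shift: TRUE where `mask` has an out-of-mask face neighbour
# (or touches the grid edge) -- the 1-voxel inner boundary shell.
inner_shell <- function(mask) {
  m <- mask > 0
  d <- dim(m)
  core <- array(TRUE, dim = d)
  shift_and <- function(axis, by) {
    out <- array(FALSE, dim = d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[axis]
    if (by == 1L) { idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n }
    else          { idx_dst[[axis]] <- 2:n;       idx_src[[axis]] <- 1:(n - 1) }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (axis in 1:3) for (by in c(1L, -1L))
    core <- core & shift_and(axis, by)
  m & !core
}

#' Simulate a smooth multiplicative bias field
#'
#' Builds a sum of a few broad Gaussian bumps with random centres and signs,
#' recentres it to mean zero over the grid, rescales its peak to 1, and maps
#' it to `1 + amplitude * g`. The result is strictly positive, has grid mean
#' exactly 1 and `max |field - 1|` exactly `amplitude` (or the constant-1
#' field when `amplitude = 0`).
#'
#' @param shape Grid shape (3 integers).
#' @param spacing_mm Voxel spacing in mm.
#' @param amplitude Peak deviation, `0 <= amplitude < 1`.
#' @param seed RNG seed.
#' @param n_bumps Number of Gaussian bumps (default 4).
#' @return A [voxel_volume()] bias field.
#' @export
simulate_bias_field <- function(shape, spacing_mm = c(1, 1, 1), amplitude,
                                seed = 1L, n_bumps = 4L) {
  shape <- as.integer(shape)
  spacing_mm <- if (length(spacing_mm) == 1L) rep(spacing_mm, 3) else
    as.numeric(spacing_mm)
  if (amplitude < 0 || amplitude >= 1)
    stop("amplitude must lie in [0, 1)")
  if (amplitude == 0)
    return(voxel_volume(array(1, dim = shape), spacing_mm))
  extent <- (shape - 1) * spacing_mm
  set.seed(seed)
  g <- array(0, dim = shape)
  xs <- axis_coords_mm(shape[1], spacing_mm[1])
  ys <- axis_coords_mm(shape[2], spacing_mm[2])
  zs <- axis_coords_mm(shape[3], spacing_mm[3])
  for (b in seq_len(n_bumps)) {
    ctr <- stats::runif(3, 0, extent)
    width <- stats::runif(1, 0.25, 0.5) * max(extent)
    sgn <- sample(c(-1, 1), 1)
    gx <- exp(-((xs - ctr[1])^2) / (2 * width^2))
    gy <- exp(-((ys - ctr[2])^2) / (2 * width^2))
    gz <- exp(-((zs - ctr[3])^2) / (2 * width^2))
    g <- g + sgn * outer(outer(gx, gy), gz)
  }
  g <- g - mean(g)
  peak <- max(abs(g))
  if (peak > 0) g <- g / peak
  voxel_volume(1 + amplitude * g, spacing_mm)
}

#' Generate a T1 ventricle phantom with ground truth
#'
#' Rasterizes the ellipsoid pair of `spec`, carves the 1-voxel inner boundary
#' shell as the wall class, places a compact choroid-plexus blob at the
#' posterior pole of each ventricle occupying `cp_fraction` of ventricle
#' voxels (to within rounding), fills the remaining interior with CSF, draws
#' intensities i.i.d. per class, and optionally multiplies by a simulated
#' bias field (seeded from `spec$seed + 1`).
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `t1`, `ventricle_mask`, `true_cp_mask` (all
#'   [voxel_volume()]), and `truth`: per-class voxel counts, true CP volume in
#'   mm^3 and as a percentage of `tiv_mm3`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  ell <- rasterize_ventricles(spec)
  vent <- ell > 0L
  n_vent <- sum(vent)
  if (n_vent == 0L) stop("ventricle geometry rasterizes to zero voxels")
  shell <- inner_shell(vent)
  interior <- vent & !shell

  k_total <- round(spec$cp_fraction * n_vent)
  if (k_total < 1L) stop("cp_fraction too small: no CP voxel fits")

  # split CP voxels across ellipsoids proportionally (largest remainder)
  n_ell <- length(spec$ventricle_centers_mm)
  int_counts <- vapply(seq_len(n_ell),
                       function(e) sum(interior & ell == e), 0L)
  quota <- k_total * int_counts / sum(int_counts)
  k_e <- floor(quota)
  rem <- k_total - sum(k_e)
  if (rem > 0) {
    o <- order(quota - k_e, decreasing = TRUE)
    k_e[o[seq_len(rem)]] <- k_e[o[seq_len(rem)]] + 1
  }
  if (any(k_e > int_counts))
    stop(sprintf(paste0("cp_fraction %.3f incompatible with geometry: ",
                        "CP region cannot fit inside the ventricle interior"),
                 spec$cp_fraction))

  sp <- spec$spacing_mm
  cp <- array(FALSE, dim = spec$grid_shape)
  for (e in seq_len(n_ell)) {
    if (k_e[e] == 0L) next
    idx <- which(interior & ell == e)
    co <- arrayInd(idx, spec$grid_shape)
    mm <- sweep(co - 1, 2, sp, `*`)
    # posterior pole: centroid of the max-y slab of this ventricle's interior
    pole <- colMeans(mm[mm[, 2] == max(mm[, 2]), , drop = FALSE])
    d2 <- colSums((t(mm) - pole)^2)
    keep <- idx[order(d2, idx)[seq_len(k_e[e])]]
    cp[keep] <- TRUE
  }

  class_map <- array(0L, dim = spec$grid_shape)
  class_map[interior] <- 1L           # CSF
  class_map[cp] <- 2L                 # choroid plexus
  class_map[shell] <- 3L              # ventricular wall

  set.seed(spec$seed)
  t1 <- array(0, dim = spec$grid_shape)
  for (cls in 1:3) {
    nm <- c("csf", "cp", "wall")[cls]
    p <- spec$class_params[[nm]]
    n_cls <- sum(class_map == cls)
    t1[class_map == cls] <- stats::rnorm(n_cls, p[["mean"]], p[["sd"]])
  }
  if (spec$bias_amplitude > 0) {
    field <- simulate_bias_field(spec$grid_shape, sp, spec$bias_amplitude,
                                 seed = spec$seed + 1L)
    t1 <- t1 * as_plain_array(field)
  }

  vox <- prod(sp)
  counts <- c(csf = sum(class_map == 1L), cp = sum(class_map == 2L),
              wall = sum(class_map == 3L))
  truth <- list(class_counts = counts,
                n_ventricle_vox = n_vent,
                cp_vox = unname(counts["cp"]),
                cp_mm3 = unname(counts["cp"]) * vox,
                cp_pct = 100 * unname(counts["cp"]) * vox / spec$tiv_mm3,
                per_ventricle_cp_vox = k_e)
  list(t1 = voxel_volume(t1, sp),
       ventricle_mask = voxel_volume(array(as.integer(vent),
                                           dim = spec$grid_shape), sp),
       true_cp_mask = voxel_volume(array(as.integer(cp),
                                         dim = spec$grid_shape), sp),
       class_map = voxel_volume(class_map, sp),
       truth = truth)
}

#' Phantom spec realizing a target normalized CP volume
#'
#' Computes the `cp_fraction` that makes the phantom's true CP volume equal
#' `cp_pct` percent of `tiv_mm3` on the rasterized ventricle geometry of
#' `base` (exact up to one-voxel rounding). This is the per-subject
#' "phantomize" hook used by the end-to-end pipeline.
#'
#' @param cp_pct Target TIV-normalized CP volume, percent.
#' @param base A [phantom_spec()] providing geometry and intensity model.
#' @param seed Seed for this subject's intensity draw.
#' @return A [phantom_spec()] with the adjusted `cp_fraction`.
#' @export
phantom_spec_for_cp_pct <- function(cp_pct, base = phantom_spec(),
                                    seed = base$seed) {
  if (cp_pct <= 0) stop("cp_pct must be positive")
  n_vent <- sum(rasterize_ventricles(base) > 0L)
  vox <- prod(base$spacing_mm)
  frac <- cp_pct / 100 * base$tiv_mm3 / (n_vent * vox)
  if (frac >= 1)
    stop("target cp_pct exceeds what the ventricle geometry can hold")
  base$cp_fraction <- frac
  base$seed <- as.integer(seed)
  validate_phantom_spec(base)
  base
}

#' Specification of a diffusion-tensor phantom
#'
#' Two disjoint axis-aligned boxes emulate the fiber geometry at the ALPS
#' region of interest: projection fibers (principal diffusivity along z,
#' superior-inferior) and association fibers (along y,
#' anterior-posterior), embedded in an isotropic background. The boxes must
#' share at least one x-index so that representative voxels of both fiber
#' classes can be read on the same x-axis. Tensors are diagonal; optional
#' noise is added to the three diagonal components (negative draws redrawn).
#'
#' @param grid_shape Voxel counts per axis (default 20^3).
#' @param spacing_mm Voxel size in mm.
#' @param proj_region,assoc_region Lists with 1-based inclusive index ranges
#'   `x`, `y`, `z` (each `c(lo, hi)`).
#' @param proj_tensor Diagonal `(Dxx, Dyy, Dzz)` in mm^2/s for projection
#'   voxels; `Dzz` must be strictly maximal.
#' @param assoc_tensor Diagonal for association voxels; `Dyy` strictly
#'   maximal.
#' @param background_d Isotropic background diffusivity (mm^2/s).
#' @param noise_sd SD of additive Gaussian noise on diagonal components.
#' @param seed RNG seed.
#' @return An object of class `tensor_phantom_spec`.
#' @export
tensor_phantom_spec <- function(grid_shape = c(20L, 20L, 20L),
                                spacing_mm = c(1, 1, 1),
                                proj_region = list(x = c(4L, 17L),
                                                   y = c(4L, 9L),
                                                   z = c(4L, 17L)),
                                assoc_region = list(x = c(4L, 17L),
                                                    y = c(12L, 17L),
                                                    z = c(4L, 17L)),
                                proj_tensor = c(1.2e-3, 0.6e-3, 1.8e-3),
                                assoc_tensor = c(1.2e-3, 1.8e-3, 0.6e-3),
                                background_d = 0.8e-3,
                                noise_sd = 0,
                                seed = 1L) {
  spec <- structure(list(grid_shape = as.integer(grid_shape),
                         spacing_mm = if (length(spacing_mm) == 1L)
                           rep(spacing_mm, 3) else as.numeric(spacing_mm),
                         proj_region = proj_region,
                         assoc_region = assoc_region,
                         proj_tensor = as.numeric(proj_tensor),
                         assoc_tensor = as.numeric(assoc_tensor),
                         background_d = background_d,
                         noise_sd = noise_sd, seed = as.integer(seed)),
                    class = "tensor_phantom_spec")
  validate_tensor_phantom_spec(spec)
  spec
}

region_empty <- function(r) any(vapply(r, function(v) v[2] < v[1], TRUE))

validate_tensor_phantom_spec <- function(spec) {
  with(spec, {
    if (any(proj_tensor <= 0) || any(assoc_tensor <= 0) || background_d <= 0)
      stop("all diffusivities must be strictly positive")
    if (!(proj_tensor[3] > max(proj_tensor[1:2])))
      stop("proj_tensor must have Dzz strictly maximal")
    if (!(assoc_tensor[2] > max(assoc_tensor[c(1, 3)])))
      stop("assoc_tensor must have Dyy strictly maximal")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    pe <- region_empty(proj_region); ae <- region_empty(assoc_region)
    if (!pe && !ae) {
      overlap <- all(vapply(c("x", "y", "z"), function(axis) {
        a <- proj_region[[axis]]; b <- assoc_region[[axis]]
        a[1] <= b[2] && b[1] <= a[2]
      }, TRUE))
      if (overlap) stop("proj_region and assoc_region overlap")
      if (max(proj_region$x[1], assoc_region$x[1]) >
          min(proj_region$x[2], assoc_region$x[2]))
        stop("proj_region and assoc_region share no x-index")
    }
  })
  invisible(spec)
}

region_voxels <- function(r, shape) {
  if (region_empty(r)) return(integer(0))
  ix <- r$x[1]:r$x[2]; iy <- r$y[1]:r$y[2]; iz <- r$z[1]:r$z[2]
  if (min(ix, iy, iz) < 1L || r$x[2] > shape[1] || r$y[2] > shape[2] ||
      r$z[2] > shape[3])
    stop("region exceeds grid bounds")
  co <- as.matrix(expand.grid(i = ix, j = iy, k = iz))
  co[, 1] + (co[, 2] - 1L) * shape[1] + (co[, 3] - 1L) * shape[1] * shape[2]
}

# draw additive diagonal noise, redrawing until base + noise > 0
draw_positive_noise <- function(base, n, sd) {
  x <- stats::rnorm(n, 0, sd)
  bad <- which(base + x <= 0)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), 0, sd)
    bad <- bad[base + x[bad] <= 0]
  }
  x
}

#' Generate a diffusion-tensor phantom with ground truth
#'
#' @param spec A [tensor_phantom_spec()].
#' @return List with `tensors` ([tensor_volume()]), `labels` (a
#'   [voxel_volume()]: 0 background, 1 projection, 2 association) and
#'   `truth`: the noise-free diagonals `Dxproj`, `Dyproj`, `Dxassoc`,
#'   `Dzassoc` and the ALPS `index` they imply.
#' @export
generate_tensor_phantom <- function(spec) {
  validate_tensor_phantom_spec(spec)
  d <- spec$grid_shape
  comp <- array(0, dim = c(d, 6L))
  comp[, , , TENSOR_COMP["xx"]] <- spec$background_d
  comp[, , , TENSOR_COMP["yy"]] <- spec$background_d
  comp[, , , TENSOR_COMP["zz"]] <- spec$background_d
  labels <- array(0L, dim = d)
  nvox <- prod(d)
  set.seed(spec$seed)
  fill <- function(lin, diag3, comp) {
    for (a in 1:3) {
      slot <- TENSOR_COMP[c("xx", "yy", "zz")[a]]
      vals <- rep(diag3[a], length(lin))
      if (spec$noise_sd > 0)
        vals <- vals + draw_positive_noise(vals, length(lin), spec$noise_sd)
      comp[lin + (slot - 1L) * nvox] <- vals
    }
    comp
  }
  lin_p <- region_voxels(spec$proj_region, d)
  lin_a <- region_voxels(spec$assoc_region, d)
  comp <- fill(lin_p, spec$proj_tensor, comp)
  comp <- fill(lin_a, spec$assoc_tensor, comp)
  labels[lin_p] <- 1L
  labels[lin_a] <- 2L
  truth <- list(Dxproj = spec$proj_tensor[1], Dyproj = spec$proj_tensor[2],
                Dxassoc = spec$assoc_tensor[1], Dzassoc = spec$assoc_tensor[3])
  truth$index <- mean(c(truth$Dxproj, truth$Dxassoc)) /
    mean(c(truth$Dyproj, truth$Dzassoc))
  list(tensors = tensor_volume(comp, spec$spacing_mm),
       labels = voxel_volume(labels, spec$spacing_mm),
       truth = truth)
}

#' Tensor phantom spec realizing a target ALPS index
#'
#' Holds the perpendicular diffusivities fixed at `d_perp` and sets the
#' x-axis diffusivity of both fiber classes to `index * d_perp`, so the
#' noise-free phantom's true ALPS index equals `index` exactly. Requires
#' `0 < index < d_fiber / d_perp` to preserve the strict principal-axis
#' ordering of each fiber class.
#'
#' @param index Target ALPS index.
#' @param base A [tensor_phantom_spec()] providing geometry.
#' @param d_perp Diffusivity along y (projection) and z (association),
#'   mm^2/s.
#' @param d_fiber Principal-axis diffusivity of each fiber class, mm^2/s.
#' @param seed Seed for this subject's noise draw.
#' @return A [tensor_phantom_spec()].
#' @export
tensor_spec_for_alps <- function(index, base = tensor_phantom_spec(),
                                 d_perp = 0.6e-3, d_fiber = 1.8e-3,
                                 seed = base$seed) {
  if (index <= 0 || index * d_perp >= d_fiber)
    stop("index must lie in (0, d_fiber/d_perp)")
  base$proj_tensor <- c(index * d_perp, d_perp, d_fiber)
  base$assoc_tensor <- c(index * d_perp, d_fiber, d_perp)
  base$seed <- as.integer(seed)
  validate_tensor_phantom_spec(base)
  base
}

#' Specification of a simulated two-group cohort
#'
#' Per-subject measured quantities are drawn directly from group-level
#' normal models: normalized CP volume (percent of TIV) and the
#' word-list-recognition z-score from a bivariate normal with correlation
#' `cp_wrecog_cor`, the remaining neuropsychological subtest z-scores from
#' independent normals, and the ALPS index from its own group normal.
#'
#' @param n_per_group Named counts `c(esrd = ..., control = ...)`, each >= 2.
#' @param cp_mean_pct,cp_sd_pct Named group means/SDs of CP volume percent.
#' @param alps_mean,alps_sd Named group means/SDs of the ALPS index.
#' @param domain_means,domain_sds Named lists (per group) of named subtest
#'   mean/SD vectors; subtest names must match [cerad_subtests()].
#' @param cp_wrecog_cor Named per-group correlation between CP percent and
#'   the word-list-recognition z-score, each in (-1, 1).
#' @param seed RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group, cp_mean_pct, cp_sd_pct,
                        alps_mean, alps_sd,
                        domain_means, domain_sds, cp_wrecog_cor,
                        seed = 1L) {
  groups <- names(n_per_group)
  spec <- structure(list(groups = groups,
                         n_per_group = n_per_group,
                         cp_mean_pct = cp_mean_pct, cp_sd_pct = cp_sd_pct,
                         alps_mean = alps_mean, alps_sd = alps_sd,
                         domain_means = domain_means, domain_sds = domain_sds,
                         cp_wrecog_cor = cp_wrecog_cor,
                         seed = as.integer(seed)),
                    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (any(spec$n_per_group < 2)) stop("n_per_group must be >= 2 per group")
  if (any(c(unlist(spec$cp_sd_pct), unlist(spec$alps_sd)) <= 0))
    stop("all SDs must be strictly positive")
  for (g in spec$groups) {
    if (any(spec$domain_sds[[g]] <= 0))
      stop("all subtest SDs must be strictly positive")
    r <- spec$cp_wrecog_cor[[g]]
    if (abs(r) >= 1)
      stop("cp_wrecog_cor implies a non-positive-definite covariance")
  }
  invisible(spec)
}

#' Names of the CERAD-K subtests carried by cohort tables
#' @return Character vector of subtest column names.
#' @export
cerad_subtests <- function() {
  c("verbal_fluency", "trail_making_b", "stroop", "boston_naming",
    "word_list_memory", "word_list_recall", "word_list_recognition",
    "constructional_recall", "mmse_kc")
}

#' Study-calibrated default cohort specification
#'
#' Group models matching the printed case-control summaries: ESRD (n = 40)
#' vs healthy controls (n = 42); normalized CP volume means 2.514 vs 2.190
#' percent (preset `"section3"`; the alternative abstract presentation
#' 1.392 vs 1.138 is available as preset `"abstract"`); ALPS index
#' 1.470 +- 0.239 vs 1.641 +- 0.266; ESRD subtest z-score means/SDs from the
#' published neuropsychology table; CP-percent vs word-list-recognition
#' correlation -0.428 in the ESRD group. CP-percent SDs (0.45 / 0.40) are a
#' package calibration choice (the source tables print no SD); controls get
#' standard-normal subtest scores with zero CP correlation.
#'
#' @param preset `"section3"` (default) or `"abstract"` CP-volume means.
#' @param seed RNG seed.
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(preset = c("section3", "abstract"),
                                seed = 1L) {
  preset <- match.arg(preset)
  cp_means <- switch(preset,
                     section3 = c(esrd = 2.514, control = 2.190),
                     abstract = c(esrd = 1.392, control = 1.138))
  esrd_means <- c(verbal_fluency = -0.67, trail_making_b = -0.58,
                  stroop = -0.96, boston_naming = 0.25,
                  word_list_memory = -0.03, word_list_recall = -0.16,
                  word_list_recognition = 0.11, constructional_recall = -0.37,
                  mmse_kc = 0.24)
  esrd_sds <- c(verbal_fluency = 0.94, trail_making_b = 0.94,
                stroop = 1.14, boston_naming = 0.86,
                word_list_memory = 1.08, word_list_recall = 1.12,
                word_list_recognition = 0.93, constructional_recall = 0.95,
                mmse_kc = 0.89)
  ctrl_means <- stats::setNames(rep(0, length(esrd_means)), names(esrd_means))
  ctrl_sds <- stats::setNames(rep(1, length(esrd_means)), names(esrd_means))
  cohort_spec(n_per_group = c(esrd = 40L, control = 42L),
              cp_mean_pct = cp_means,
              cp_sd_pct = c(esrd = 0.45, control = 0.40),
              alps_mean = c(esrd = 1.470, control = 1.641),
              alps_sd = c(esrd = 0.239, control = 0.266),
              domain_means = list(esrd = esrd_means, control = ctrl_means),
              domain_sds = list(esrd = esrd_sds, control = ctrl_sds),
              cp_wrecog_cor = c(esrd = -0.428, control = 0),
              seed = seed)
}

#' Simulate a cohort table
#'
#' Subjects are drawn group by group in the order of `spec$groups`. Per
#' subject the draw order is fixed (two standard normals for the bivariate
#' CP/word-recognition pair, then the remaining subtests in
#' [cerad_subtests()] order, then the ALPS index), so a given seed always
#' yields the same table. The bivariate pair uses the Cholesky transform
#' `w = rho * z1 + sqrt(1 - rho^2) * z2`. The derived cognitive-impairment
#' flag applies [classify_impairment()] to each subject's subtests.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame with columns `id`, `group`, `cp_pct`, `alps`, the
#'   nine subtest z-scores, and logical `impaired`, in that order.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  subtests <- cerad_subtests()
  set.seed(spec$seed)
  rows <- list()
  sid <- 0L
  for (g in spec$groups) {
    n <- spec$n_per_group[[g]]
    rho <- spec$cp_wrecog_cor[[g]]
    mu <- spec$domain_means[[g]]; sdv <- spec$domain_sds[[g]]
    for (s in seq_len(n)) {
      sid <- sid + 1L
      z1 <- stats::rnorm(1); z2 <- stats::rnorm(1)
      cp <- spec$cp_mean_pct[[g]] + spec$cp_sd_pct[[g]] * z1
      wrec <- mu[["word_list_recognition"]] +
        sdv[["word_list_recognition"]] * (rho * z1 + sqrt(1 - rho^2) * z2)
      others <- setdiff(subtests, "word_list_recognition")
      zz <- stats::setNames(stats::rnorm(length(others), mu[others],
                                         sdv[others]), others)
      alps <- stats::rnorm(1, spec$alps_mean[[g]], spec$alps_sd[[g]])
      rec <- c(list(id = sprintf("S%03d", sid), group = g,
                    cp_pct = cp, alps = alps),
               as.list(c(zz, word_list_recognition = wrec)[subtests]))
      rows[[sid]] <- as.data.frame(rec, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$impaired <- vapply(seq_len(nrow(tab)), function(i) {
    classify_impairment(unlist(tab[i, subtests]))$impaired
  }, TRUE)
  rownames(tab) <- NULL
  tab
}

#' Write / read a cohort table as tab-separated values
#' @param cohort Data.frame from [generate_cohort()] (or same columns).
#' @param path Output TSV path.
#' @return `path` invisibly / the cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
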