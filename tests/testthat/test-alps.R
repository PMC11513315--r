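test_that("spherical ROI matches brute-force lattice enumeration", {
  geom <- list(shape = c(21, 21, 21), spacing_mm = c(1, 1, 1))
  roi <- make_sphere_roi(c(10, 10, 10), 5, geom)
  # brute force: integer offsets with squared norm <= 2.5^2
  count <- sum(outer(outer((-10:10)^2, (-10:10)^2, `+`), (-10:10)^2, `+`)
               <= 6.25)
  expect_identical(sum(unclass(roi)), count)
  expect_identical(sum(unclass(roi)), 81L)
  # discretized volume close to the continuous sphere volume
  expect_lt(abs(sum(unclass(roi)) - 4 / 3 * pi * 2.5^3),
            0.35 * 4 / 3 * pi * 2.5^3)

  tiny <- make_sphere_roi(c(5, 5, 5), 1.01, geom)
  expect_identical(sum(unclass(tiny)), 1L)
  expect_error(make_sphere_roi(c(100, 100, 100), 5, geom), "no voxel")
})

test_that("anisotropic spacing uses physical distances", {
  geom <- list(shape = c(21, 21, 9), spacing_mm = c(1, 1, 2.25))
  roi <- make_sphere_roi(c(10, 10, 9), 5, geom)
  co <- which(unclass(roi) > 0, arr.ind = TRUE)
  mm <- sweep(co - 1, 2, c(1, 1, 2.25), `*`)
  d <- sqrt(colSums((t(mm) - c(10, 10, 9))^2))
  expect_true(all(d <= 2.5))
  expect_gt(length(unique(co[, 3])), 1)   # spans slices despite 2.25 mm
})

test_that("fiber classification follows the principal axis with z>y>x ties", {
  shape <- c(5, 5, 5)
  roi <- voxel_volume(array(1L, dim = shape))
  proj <- uniform_tensor_volume(shape, 1e-4, 2e-4, 9e-4)
  expect_identical(unique(as.vector(
    unclass(classify_fiber_voxels(proj, roi)$labels))), 1L)
  assoc <- uniform_tensor_volume(shape, 1e-4, 9e-4, 2e-4)
  expect_identical(unique(as.vector(
    unclass(classify_fiber_voxels(assoc, roi)$labels))), 2L)
  subc <- uniform_tensor_volume(shape, 9e-4, 1e-4, 2e-4)
  expect_identical(unique(as.vector(
    unclass(classify_fiber_voxels(subc, roi)$labels))), 3L)
  iso <- uniform_tensor_volume(shape, 5e-4, 5e-4, 5e-4)
  expect_identical(unique(as.vector(
    unclass(classify_fiber_voxels(iso, roi)$labels))), 1L)  # tie -> z
})

test_that("non-finite tensors are skipped with a qc note", {
  shape <- c(4, 4, 4)
  tv <- uniform_tensor_volume(shape, 1e-4, 2e-4, 9e-4)
  tv[1, 1, 1, 1] <- NA
  roi <- voxel_volume(array(1L, dim = shape))
  cls <- classify_fiber_voxels(tv, roi)
  expect_identical(cls$qc$n_skipped, 1L)
  expect_identical(unclass(cls$labels)[1, 1, 1], 0L)
})

test_that("representative selection maximizes orientation on a shared x-axis", {
  shape <- c(6, 6, 6)
  comp <- array(0, dim = c(shape, 6))
  # helper: symmetric tensor from eigenvalues and a rotation about x
  tilted <- function(theta, lambda = c(2e-4, 3e-4, 9e-4)) {
    R <- rbind(c(1, 0, 0),
               c(0, cos(theta), -sin(theta)),
               c(0, sin(theta), cos(theta)))
    M <- R %*% diag(lambda) %*% t(R)
    c(M[1, 1], M[1, 2], M[1, 3], M[2, 2], M[2, 3], M[3, 3])
  }
  # two projection candidates at x = 3: |v_z| = cos(8deg) vs cos(26deg)
  comp[3, 2, 2, ] <- tilted(8 * pi / 180)
  comp[3, 2, 4, ] <- tilted(26 * pi / 180)
  # one association voxel at the same x
  comp[3, 5, 3, ] <- c(1.1e-3, 0, 0, 1.8e-3, 0, 0.6e-3)
  tv <- tensor_volume(comp)
  roi <- voxel_volume(array(1L, dim = shape))
  cls <- classify_fiber_voxels(tv, roi)
  # background zero tensors are "projection" by tie rule but carry Dxx = 0;
  # restrict the ROI to the constructed voxels
  roi2 <- array(0L, dim = shape)
  roi2[3, 2, 2] <- 1L; roi2[3, 2, 4] <- 1L; roi2[3, 5, 3] <- 1L
  roi2 <- voxel_volume(roi2)
  cls2 <- classify_fiber_voxels(tv, roi2)
  rep <- select_fiber_representatives(cls2$labels, tv, roi2)
  expect_identical(rep$voxels$projection, c(3L, 2L, 2L))  # larger |v_z|
  expect_identical(rep$voxels$association, c(3L, 5L, 3L))
  expect_identical(rep$Dxassoc, 1.1e-3)
})

test_that("selection errors name the missing ingredient", {
  shape <- c(6, 6, 6)
  proj_only <- uniform_tensor_volume(shape, 1e-4, 2e-4, 9e-4)
  roi <- voxel_volume(array(1L, dim = shape))
  lab <- classify_fiber_voxels(proj_only, roi)$labels
  expect_error(select_fiber_representatives(lab, proj_only, roi),
               "association")
  # both classes present but never on the same x-index
  comp <- array(0, dim = c(shape, 6))
  comp[2, 2, 2, c(1, 4, 6)] <- c(1e-4, 2e-4, 9e-4)
  comp[4, 4, 4, c(1, 4, 6)] <- c(1e-4, 9e-4, 2e-4)
  roi3 <- array(0L, dim = shape); roi3[2, 2, 2] <- 1L; roi3[4, 4, 4] <- 1L
  roi3 <- voxel_volume(roi3)
  tv <- tensor_volume(comp)
  lab3 <- classify_fiber_voxels(tv, roi3)$labels
  expect_error(select_fiber_representatives(lab3, tv, roi3), "x-index")
})

test_that("the index follows the closed form on the two-fiber phantom", {
  tp <- generate_tensor_phantom(tensor_phantom_spec(seed = 1))
  roi <- alps_roi(pipeline_config()$roi_center_mm)
  res <- compute_alps(tp$tensors, roi)
  expect_equal(res$index, 2.0)
  d <- res$diffusivities
  expect_identical(c(d$Dxproj, d$Dyproj, d$Dxassoc, d$Dzassoc),
                   c(1.2e-3, 0.6e-3, 1.2e-3, 0.6e-3))
  expect_identical(res$index,
                   mean(c(d$Dxproj, d$Dxassoc)) /
                     mean(c(d$Dyproj, d$Dzassoc)))
})

test_that("an isotropic field with forced labels gives index exactly 1", {
  shape <- c(8, 8, 8)
  iso <- uniform_tensor_volume(shape, 7e-4, 7e-4, 7e-4)
  lab <- array(0L, dim = shape)
  lab[3, 2:4, 3] <- 1L
  lab[3, 6:7, 3] <- 2L
  roi <- voxel_volume(array(1L, dim = shape))
  rep <- select_fiber_representatives(voxel_volume(lab), iso, roi)
  idx <- mean(c(rep$Dxproj, rep$Dxassoc)) / mean(c(rep$Dyproj, rep$Dzassoc))
  expect_identical(idx, 1)
})

test_that("the index is invariant to global tensor rescaling", {
  tp <- generate_tensor_phantom(tensor_phantom_spec(noise_sd = 2e-5,
                                                    seed = 77))
  roi <- alps_roi(pipeline_config()$roi_center_mm)
  base <- compute_alps(tp$tensors, roi)
  for (c in c(0.5, 3)) {
    scaled <- tensor_volume(unclass(tp$tensors) * c,
                            vol_spacing(tp$tensors))
    res <- compute_alps(scaled, roi)
    expect_equal(res$index, base$index, tolerance = 1e-12)
    expect_identical(res$diffusivities$voxels, base$diffusivities$voxels)
  }
})

test_that("the computed index is noise-consistent and deterministic", {
  spec0 <- tensor_phantom_spec()
  noise <- 0.05 * min(spec0$proj_tensor, spec0$assoc_tensor)
  roi <- alps_roi(pipeline_config()$roi_center_mm)
  idx <- vapply(1:200, function(r) {
    tp <- generate_tensor_phantom(tensor_phantom_spec(noise_sd = noise,
                                                      seed = 400 + r))
    compute_alps(tp$tensors, roi)$index
  }, 0)
  expect_lt(abs(median(idx) - 2.0), 0.05 * 2.0)

  tp <- generate_tensor_phantom(tensor_phantom_spec(noise_sd = noise,
                                                    seed = 42))
  r1 <- compute_alps(tp$tensors, roi)
  r2 <- compute_alps(tp$tensors, roi)
  expect_identical(r1, r2)
})
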