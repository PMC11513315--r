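test_that("bias field is smooth, mean-one and amplitude-bounded", {
  f0 <- simulate_bias_field(c(16, 16, 8), c(1, 1, 1), amplitude = 0, seed = 3)
  expect_true(all(f0 == 1))

  f <- simulate_bias_field(c(24, 24, 12), c(1, 1, 2), amplitude = 0.2,
                           seed = 11)
  expect_true(all(f >= 0.8 - 1e-12) && all(f <= 1.2 + 1e-12))
  expect_lt(abs(mean(f) - 1), 0.01)
  expect_gt(max(abs(f - 1)), 0.19)    # peak reaches the amplitude

  f2 <- simulate_bias_field(c(24, 24, 12), c(1, 1, 2), amplitude = 0.2,
                            seed = 11)
  expect_identical(as.vector(f), as.vector(f2))
  expect_error(simulate_bias_field(c(8, 8, 8), amplitude = -0.1, seed = 1))
})

test_that("phantom truth obeys the normalization arithmetic and mask algebra", {
  spec <- small_phantom_spec(seed = 5, cp_fraction = 0.10)
  ph <- generate_phantom(spec)
  tr <- ph$truth
  n_vent <- tr$n_ventricle_vox
  # cp count hits the requested fraction to within one voxel of rounding
  expect_lte(abs(tr$cp_vox - spec$cp_fraction * n_vent), 1)
  # pct is exactly 100 * mm3 / tiv, mm3 exactly count * voxel volume
  expect_identical(tr$cp_mm3, tr$cp_vox * voxel_mm3(ph$t1))
  expect_equal(tr$cp_pct, 100 * tr$cp_mm3 / spec$tiv_mm3)
  # mask algebra: CP inside ventricle, class counts partition the mask
  vent <- as.logical(unclass(ph$ventricle_mask))
  cp <- as.logical(unclass(ph$true_cp_mask))
  expect_true(all(vent[cp]))
  expect_identical(sum(tr$class_counts), sum(vent))
  # CP blob is 26-connected within each ventricle (contiguous, 2 ventricles)
  lab <- cpalps:::label_components_26(unclass(ph$true_cp_mask))
  expect_lte(max(lab), 2)
})

test_that("noise-free limit reproduces the class means and phantoms are deterministic", {
  spec <- small_phantom_spec(seed = 2, sds = c(1e-9, 1e-9, 1e-9))
  ph <- generate_phantom(spec)
  cp <- as.logical(unclass(ph$true_cp_mask))
  expect_equal(max(abs(unclass(ph$t1)[cp] - 55)), 0, tolerance = 1e-6)

  ph2 <- generate_phantom(small_phantom_spec(seed = 2,
                                             sds = c(1e-9, 1e-9, 1e-9)))
  expect_identical(as.vector(ph$t1), as.vector(ph2$t1))
})

test_that("phantom generation rejects impossible geometry", {
  expect_error(generate_phantom(small_phantom_spec(cp_fraction = 0.95)),
               "incompatible|cannot fit")
  expect_error(phantom_spec(cp_fraction = 0))
  expect_error(phantom_spec(class_params = list(csf = c(mean = 50, sd = 3),
                                                cp = c(mean = 40, sd = 3),
                                                wall = c(mean = 80, sd = 3))))
  spec <- phantom_spec(semi_axes_mm = c(1.5, 16, 6))
  expect_error(generate_phantom(spec), "degenerate")
  expect_error(phantom_spec(tiv_mm3 = 5000), "tiv")
})

test_that("tensor phantom truth matches the closed-form index", {
  spec <- tensor_phantom_spec(seed = 4)
  tp <- generate_tensor_phantom(spec)
  expect_equal(tp$truth$index, 2.0)
  # labelled voxels carry the spec diagonals verbatim (noise-free)
  lab <- unclass(tp$labels)
  comp <- unclass(tp$tensors)
  nv <- prod(dim(lab))
  lp <- which(lab == 1L)[1]
  expect_identical(comp[lp], spec$proj_tensor[1])
  expect_identical(comp[lp + 5 * nv], spec$proj_tensor[3])
})

test_that("tensor noise averages out and keeps diagonals positive", {
  spec <- tensor_phantom_spec(noise_sd = 1e-5, seed = 9)
  tp <- generate_tensor_phantom(spec)
  lab <- unclass(tp$labels); comp <- unclass(tp$tensors)
  nv <- prod(dim(lab))
  lin <- which(lab == 1L)
  expect_gte(length(lin), 1000)
  for (a in c(1, 4, 6)) {
    vals <- comp[lin + (a - 1) * nv]
    truth <- spec$proj_tensor[match(a, c(1, 4, 6))]
    expect_lt(abs(mean(vals) - truth), 3 * 1e-5 / sqrt(length(lin)))
    expect_true(all(vals > 0))
  }
})

test_that("overlapping fiber regions are rejected", {
  expect_error(tensor_phantom_spec(
    proj_region = list(x = c(4, 17), y = c(4, 12), z = c(4, 17)),
    assoc_region = list(x = c(4, 17), y = c(10, 17), z = c(4, 17))),
    "overlap")
})

test_that("cohort generator is deterministic with the documented layout", {
  spec <- default_cohort_spec(seed = 21)
  a <- generate_cohort(spec)
  b <- generate_cohort(default_cohort_spec(seed = 21))
  expect_identical(a, b)
  expect_identical(names(a)[1:4], c("id", "group", "cp_pct", "alps"))
  expect_identical(names(a)[5:13], cerad_subtests())
  expect_identical(names(a)[14], "impaired")
  expect_identical(as.integer(table(a$group)[c("esrd", "control")]),
                   c(40L, 42L))
})

test_that("zero configured correlation yields near-zero sample correlation", {
  spec <- default_cohort_spec(seed = 33)
  spec$cp_wrecog_cor[["esrd"]] <- 0
  spec$n_per_group <- c(esrd = 10000L, control = 2L)
  co <- generate_cohort(spec)
  cases <- co[co$group == "esrd", ]
  expect_lt(abs(cor(cases$cp_pct, cases$word_list_recognition)), 0.05)
})

test_that("identical group models give nominal Welch type-I error", {
  spec <- default_cohort_spec(seed = 0)
  for (f in c("cp_mean_pct", "cp_sd_pct", "alps_mean", "alps_sd"))
    spec[[f]]["esrd"] <- spec[[f]]["control"]
  spec$n_per_group <- c(esrd = 20L, control = 20L)
  rej <- vapply(seq_len(1000), function(r) {
    spec$seed <- 5000L + r
    co <- generate_cohort(spec)
    welch_t_test(co$alps[co$group == "esrd"],
                 co$alps[co$group == "control"])$p_value < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.075)
})

test_that("calibrated cohort recovers the configured group means", {
  spec <- default_cohort_spec()
  sums <- matrix(0, 1000, 4)
  for (r in seq_len(1000)) {
    spec$seed <- 100L + r
    co <- generate_cohort(spec)
    e <- co$group == "esrd"
    sums[r, ] <- c(mean(co$cp_pct[e]), mean(co$cp_pct[!e]),
                   mean(co$alps[e]), mean(co$alps[!e]))
  }
  gm <- colMeans(sums)
  sem <- c(0.45 / sqrt(1000 * 40), 0.40 / sqrt(1000 * 42),
           0.239 / sqrt(1000 * 40), 0.266 / sqrt(1000 * 42))
  target <- c(2.514, 2.190, 1.470, 1.641)
  expect_true(all(abs(gm - target) <= 2 * sem))
})

test_that("cohort tables round-trip through TSV", {
  co <- generate_cohort(default_cohort_spec(seed = 8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_identical(names(back), names(co))
  expect_equal(back$cp_pct, co$cp_pct, tolerance = 1e-12)
  expect_identical(back$impaired, co$impaired)
})
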