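test_that("the impairment rule applies the strict -1.5 / two-domain cut", {
  base <- setNames(rep(0, 9), cerad_subtests())

  r <- classify_impairment(base)
  expect_false(r$impaired)
  expect_identical(r$affected_domains, character(0))

  two <- base; two["verbal_fluency"] <- -2.0; two["word_list_recall"] <- -1.6
  r2 <- classify_impairment(two)
  expect_true(r2$impaired)
  expect_setequal(r2$affected_domains, c("frontal_executive", "verbal_memory"))

  one <- base; one["mmse_kc"] <- -3.0
  expect_false(classify_impairment(one)$impaired)  # one domain is not enough

  boundary <- base; boundary["stroop"] <- -1.5; boundary["mmse_kc"] <- -1.5
  r4 <- classify_impairment(boundary)               # strictly below required
  expect_false(r4$impaired)
  expect_identical(r4$affected_domains, character(0))

  # one subtest below the cut affects its whole domain
  part <- base; part["word_list_memory"] <- -1.51; part["stroop"] <- -1.51
  expect_true(classify_impairment(part)$impaired)
})

test_that("missing domains are skipped with a warning", {
  partial <- setNames(rep(-2, 3), c("verbal_fluency", "boston_naming",
                                    "mmse_kc"))
  expect_warning(r <- classify_impairment(partial), "verbal_memory")
  expect_identical(r$n_domains_evaluated, 3L)
  expect_true(r$impaired)
  expect_error(suppressWarnings(classify_impairment(c(mmse_kc = -2))),
               "2 domains")
})

test_that("prevalence is the exact percentage of impaired subjects", {
  expect_identical(impairment_prevalence(c(rep(TRUE, 29), rep(FALSE, 11))),
                   72.5)
  expect_identical(impairment_prevalence(rep(FALSE, 10)), 0)
  expect_error(impairment_prevalence(logical(0)), "empty")
})

test_that("Welch test matches its formulas and swap symmetry", {
  expect_identical(welch_t_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  set.seed(12)
  x <- rnorm(15, 0, 1); y <- rnorm(20, 0.8, 1.6)
  got <- welch_t_test(x, y)
  ora <- oracle_welch(x, y)
  expect_equal(got$statistic, ora$t, tolerance = 1e-10)
  expect_equal(got$df, ora$df, tolerance = 1e-10)
  expect_equal(got$p_value, ora$p, tolerance = 1e-8)

  swapped <- welch_t_test(y, x)
  expect_equal(swapped$statistic, -got$statistic, tolerance = 1e-12)
  expect_equal(swapped$p_value, got$p_value, tolerance = 1e-12)

  # degenerate equal-constant convention
  expect_identical(welch_t_test(rep(2, 5), rep(2, 7))$p_value, 1)
})

test_that("summary-statistic Welch equals the sample variant and the oracle", {
  set.seed(7)
  x <- rnorm(12, 1, 0.5); y <- rnorm(18, 1.4, 0.9)
  a <- welch_t_test(x, y)
  b <- welch_t_test_summary(mean(x), sd(x), length(x),
                            mean(y), sd(y), length(y))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_equal(a$df, b$df, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)

  # the published group summaries give a clearly significant difference
  pub <- welch_t_test_summary(1.470, 0.239, 40, 1.641, 0.266, 42)
  expect_lt(pub$p_value, 0.01)
  expect_equal(pub$p_value, oracle_t_p(pub$statistic, pub$df),
               tolerance = 1e-6)
})

test_that("chi-square test matches the direct formula and is transpose-safe", {
  prop <- matrix(c(10, 20, 30, 60), 2, 2)   # perfectly proportional
  r <- chi_square_test(prop)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)

  sex <- matrix(c(19, 21, 20, 22), 2, 2, byrow = FALSE)
  got <- chi_square_test(sex)
  ora <- oracle_chisq(sex)
  expect_equal(got$statistic, ora$stat, tolerance = 1e-10)
  expect_equal(got$p_value, ora$p, tolerance = 1e-8)
  expect_gt(got$p_value, 0.9)
  expect_equal(chi_square_test(t(sex))$statistic, got$statistic,
               tolerance = 1e-12)

  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2, 2)), "marginal")
  expect_error(chi_square_test(matrix(c(1.5, 2, 3, 4), 2, 2)), "integer")
  # Yates correction is available but changes the statistic
  expect_lt(chi_square_test(matrix(c(5, 9, 12, 4), 2, 2),
                            correct = TRUE)$statistic,
            chi_square_test(matrix(c(5, 9, 12, 4), 2, 2))$statistic)
})

test_that("Pearson correlation handles exact linear relations and errors", {
  x <- c(1, 2.5, 3, 4.2, 7)
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_corr(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(pearson_corr(x, rep(2, 5)), "constant")
  expect_error(pearson_corr(c(1, 2), c(3, 4)), "n >= 3")
})

test_that("all test statistics match brute-force oracles on random inputs", {
  set.seed(99)
  for (r in 1:50) {
    x <- rnorm(sample(4:12, 1), rnorm(1), runif(1, 0.3, 2))
    y <- rnorm(sample(4:12, 1), rnorm(1), runif(1, 0.3, 2))
    got <- welch_t_test(x, y); ora <- oracle_welch(x, y)
    expect_equal(got$statistic, ora$t, tolerance = 1e-8)
    expect_equal(got$p_value, ora$p, tolerance = 1e-8)

    n <- min(length(x), length(y))
    pc <- pearson_corr(x[1:n], y[1:n]); po <- oracle_pearson(x[1:n], y[1:n])
    expect_equal(pc$r, po$r, tolerance = 1e-8)
    expect_equal(pc$p_value, po$p, tolerance = 1e-8)

    tab <- matrix(sample(3:30, 4, replace = TRUE), 2, 2)
    gc <- chi_square_test(tab); oc <- oracle_chisq(tab)
    expect_equal(gc$statistic, oc$stat, tolerance = 1e-8)
    expect_equal(gc$p_value, oc$p, tolerance = 1e-8)
  }
})

test_that("sample correlations concentrate around the configured rho", {
  rho <- -0.428
  hit <- vapply(1:500, function(r) {
    set.seed(7000 + r)
    z1 <- rnorm(200); z2 <- rnorm(200)
    x <- z1
    y <- rho * z1 + sqrt(1 - rho^2) * z2
    abs(pearson_corr(x, y)$r - rho) <= 0.15
  }, TRUE)
  expect_gte(mean(hit), 0.90)
})

test_that("run_study reproduces the analysis table layout", {
  co <- generate_cohort(default_cohort_spec(seed = 15))
  rep <- run_study(co)
  expect_s3_class(rep, "cp_study_report")
  expect_identical(unname(rep$n), c(40L, 42L))
  expect_identical(rep$comparisons$cp_pct$test, "welch_t")
  expect_identical(nrow(rep$correlations), 9L)
  expect_identical(rep$impairment$prevalence_pct,
                   100 * rep$impairment$n_impaired / 40)
  # BH adjustment is opt-in and adds a column
  rep2 <- run_study(co, adjust = "BH")
  expect_true("p_adj_bh" %in% names(rep2$correlations))
  expect_true(all(rep2$correlations$p_adj_bh >=
                    rep2$correlations$p_value - 1e-12))
  expect_output(print(rep), "DTI-ALPS index")
})

test_that("run_study rejects degenerate groups", {
  co <- generate_cohort(default_cohort_spec(seed = 1))
  expect_error(run_study(co, case_group = "nope"), "absent")
  co1 <- co[c(which(co$group == "esrd")[1], which(co$group == "control")), ]
  expect_error(run_study(co1), "single subject")
})

test_that("null cohorts give uniform comparison p-values", {
  spec <- default_cohort_spec(seed = 0)
  for (f in c("cp_mean_pct", "cp_sd_pct", "alps_mean", "alps_sd"))
    spec[[f]]["esrd"] <- spec[[f]]["control"]
  spec$n_per_group <- c(esrd = 20L, control = 20L)
  pvals <- vapply(1:500, function(r) {
    spec$seed <- 9000L + r
    co <- generate_cohort(spec)
    welch_t_test(co$cp_pct[co$group == "esrd"],
                 co$cp_pct[co$group == "control"])$p_value
  }, 0)
  ks <- max(abs(sort(pvals) - (seq_along(pvals) - 0.5) / length(pvals)))
  expect_lt(ks, 0.1)
})

test_that("the calibrated cohort shows the expected group direction", {
  spec <- default_cohort_spec()
  dir_ok <- vapply(1:200, function(r) {
    spec$seed <- 300L + r
    co <- generate_cohort(spec)
    mean(co$cp_pct[co$group == "esrd"]) >
      mean(co$cp_pct[co$group == "control"])
  }, TRUE)
  expect_gte(mean(dir_ok), 0.95)
})
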