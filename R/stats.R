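#' CERAD-K domain structure
#'
#' Mapping of the nine subtest z-score columns onto the five cognitive
#' domains used by the impairment rule: frontal/executive (verbal fluency,
#' trail-making B, Stroop), language (modified Boston Naming), verbal
#' memory (word-list memory / recall / recognition), visual memory
#' (constructional recall) and global cognition (MMSE-KC).
#'
#' @return Named list of subtest-name character vectors.
#' @export
cerad_domains <- function() {
  list(frontal_executive = c("verbal_fluency", "trail_making_b", "stroop"),
       language = "boston_naming",
       verbal_memory = c("word_list_memory", "word_list_recall",
                         "word_list_recognition"),
       visual_memory = "constructional_recall",
       global = "mmse_kc")
}

#' Classify cognitive impairment from domain z-scores
#'
#' A domain is affected iff any of its subtest z-scores falls strictly
#' below `threshold` (default -1.5, i.e. more than 1.5 SD below the
#' normative mean); a subject is impaired iff at least `min_affected`
#' domains are affected (default 2: "more than one domain"). A score of
#' exactly -1.5 is therefore not abnormal. Domains with no subtest present
#' are skipped with a warning.
#'
#' @param scores Named numeric vector of subtest z-scores (names as in
#'   [cerad_subtests()]), or any subset covering at least 2 domains.
#' @param threshold Abnormality cut-point on the z-scale.
#' @param min_affected Minimum number of affected domains for impairment.
#' @param domains Domain-to-subtest mapping (default [cerad_domains()]).
#' @return List: `impaired` (logical), `affected_domains` (character),
#'   `n_domains_evaluated`.
#' @export
classify_impairment <- function(scores, threshold = -1.5, min_affected = 2L,
                                domains = cerad_domains()) {
  scores <- unlist(scores)
  if (any(!is.finite(scores))) stop("z-scores must be finite")
  present <- lapply(domains, function(st) st[st %in% names(scores)])
  missing <- names(domains)[vapply(present, length, 0L) == 0L]
  if (length(missing) > 0) {
    warning(sprintf("no subtest present for domain(s): %s; skipped",
                    paste(missing, collapse = ", ")))
    present <- present[vapply(present, length, 0L) > 0L]
  }
  if (length(present) < 2L)
    stop("need subtests from at least 2 domains")
  affected <- names(present)[vapply(present, function(st)
    any(scores[st] < threshold), TRUE)]
  list(impaired = length(affected) >= min_affected,
       affected_domains = affected,
       n_domains_evaluated = length(present))
}

#' Impairment prevalence in percent
#' @param impaired Logical vector of per-subject impairment flags.
#' @return `100 * sum(impaired) / length(impaired)`.
#' @export
impairment_prevalence <- function(impaired) {
  if (length(impaired) == 0) stop("empty cohort")
  100 * sum(impaired) / length(impaired)
}

comparison_result <- function(test, statistic, df, p_value, ...) {
  structure(c(list(test = test, statistic = unname(statistic),
                   df = unname(df), p_value = unname(p_value)),
              list(...)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s> statistic %.4f, df %.2f, p = %.4g\n",
              x$test, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Two-sample t test (Welch by default)
#'
#' Compares two independent samples; by default the Welch unequal-variance
#' statistic with Welch-Satterthwaite degrees of freedom (set
#' `var_equal = TRUE` for the pooled-variance Student variant). When both
#' samples have zero variance and equal means the comparison is vacuous and
#' `t = 0, p = 1` is returned by convention.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param var_equal Use the pooled-variance Student t instead of Welch.
#' @return A `comparison_result` with group means, SDs and sizes.
#' @export
welch_t_test <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per group")
  ms <- c(mean(x), mean(y)); sds <- c(stats::sd(x), stats::sd(y))
  if (all(sds == 0)) {
    if (ms[1] == ms[2])
      return(comparison_result("welch_t", 0, length(x) + length(y) - 2, 1,
                               means = ms, sds = sds,
                               ns = c(length(x), length(y))))
    stop("both groups have zero variance with different means")
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  comparison_result(if (var_equal) "student_t" else "welch_t",
                    tt$statistic, tt$parameter, tt$p.value,
                    means = ms, sds = sds, ns = c(length(x), length(y)))
}

#' @describeIn welch_t_test Welch test from group summary statistics
#'   (means, SDs, sizes); algebraically identical to the sample variant.
#' @param mean_x,sd_x,n_x,mean_y,sd_y,n_y Group summaries.
#' @export
welch_t_test_summary <- function(mean_x, sd_x, n_x, mean_y, sd_y, n_y) {
  if (n_x < 2 || n_y < 2) stop("need n >= 2 per group")
  if (sd_x < 0 || sd_y < 0) stop("SDs must be nonnegative")
  vx <- sd_x^2 / n_x; vy <- sd_y^2 / n_y
  if (vx + vy == 0) {
    if (mean_x == mean_y)
      return(comparison_result("welch_t", 0, n_x + n_y - 2, 1,
                               means = c(mean_x, mean_y),
                               sds = c(sd_x, sd_y), ns = c(n_x, n_y)))
    stop("both groups have zero variance with different means")
  }
  tstat <- (mean_x - mean_y) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (n_x - 1) + vy^2 / (n_y - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  comparison_result("welch_t", tstat, df, p,
                    means = c(mean_x, mean_y), sds = c(sd_x, sd_y),
                    ns = c(n_x, n_y))
}

#' Pearson chi-square test on a contingency table
#'
#' Without continuity correction by default (set `correct = TRUE` for the
#' Yates-corrected variant).
#'
#' @param tab Matrix of nonnegative integer counts (2x2 for the study's
#'   sex-by-group comparison).
#' @param correct Apply the Yates continuity correction.
#' @return A `comparison_result` carrying the observed table.
#' @export
chi_square_test <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has a zero marginal")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  comparison_result("chi_square", ct$statistic, ct$parameter, ct$p.value,
                    observed = tab)
}

#' Pearson correlation with two-sided t-based p-value
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List `r`, `p_value`, `n`, `df`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       df = unname(ct$parameter))
}

#' Run the full case-control statistical analysis on a cohort table
#'
#' Reproduces the study's analysis surface on any cohort table with the
#' columns produced by [generate_cohort()]:
#' \itemize{
#'   \item patient-vs-control comparison of normalized CP volume percent
#'     and of the ALPS index (Welch t by default);
#'   \item the cognitive-impairment rule applied per patient, and the
#'     impairment prevalence;
#'   \item within-patients comparison of CP percent between impaired and
#'     unimpaired subjects;
#'   \item Pearson correlation of CP percent against every subtest z-score
#'     within the patient group.
#' }
#' P-values are reported raw (per-test alpha, as in the source analysis);
#' `adjust = "BH"` additionally reports Benjamini-Hochberg adjusted
#' correlation p-values, clearly flagged as an extension.
#'
#' @param cohort Data.frame with columns `group`, `cp_pct`, `alps` and the
#'   subtest z-score columns ([cerad_subtests()]).
#' @param case_group,control_group Group labels (defaults `"esrd"`,
#'   `"control"`).
#' @param var_equal Use Student instead of Welch comparisons.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return An object of class `cp_study_report`.
#' @export
run_study <- function(cohort, case_group = "esrd",
                      control_group = "control", var_equal = FALSE,
                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  for (g in c(case_group, control_group)) {
    n <- sum(cohort$group == g)
    if (n == 0) stop(sprintf("group '%s' absent from cohort", g))
    if (n < 2) stop(sprintf("group '%s' has a single subject", g))
  }
  cases <- cohort[cohort$group == case_group, , drop = FALSE]
  ctrls <- cohort[cohort$group == control_group, , drop = FALSE]

  cmp_cp <- welch_t_test(cases$cp_pct, ctrls$cp_pct, var_equal = var_equal)
  cmp_alps <- welch_t_test(cases$alps, ctrls$alps, var_equal = var_equal)

  subtests <- intersect(cerad_subtests(), names(cohort))
  impaired <- vapply(seq_len(nrow(cases)), function(i)
    classify_impairment(unlist(cases[i, subtests]))$impaired, TRUE)
  prevalence <- impairment_prevalence(impaired)

  cmp_impaired <- NULL
  if (sum(impaired) >= 2 && sum(!impaired) >= 2)
    cmp_impaired <- welch_t_test(cases$cp_pct[impaired],
                                 cases$cp_pct[!impaired],
                                 var_equal = var_equal)

  cors <- do.call(rbind, lapply(subtests, function(st) {
    ct <- tryCatch(pearson_corr(cases$cp_pct, cases[[st]]),
                   error = function(e) list(r = NA_real_,
                                            p_value = NA_real_,
                                            n = nrow(cases)))
    data.frame(subtest = st, r = ct$r, p_value = ct$p_value, n = ct$n)
  }))
  if (adjust == "BH")
    cors$p_adj_bh <- stats::p.adjust(cors$p_value, method = "BH")

  structure(list(
    groups = c(case = case_group, control = control_group),
    n = c(case = nrow(cases), control = nrow(ctrls)),
    comparisons = list(cp_pct = cmp_cp, alps = cmp_alps,
                       cp_pct_impaired_vs_not = cmp_impaired),
    impairment = list(n_impaired = sum(impaired),
                      prevalence_pct = prevalence,
                      flags = impaired),
    correlations = cors,
    settings = list(test = if (var_equal) "student_t" else "welch_t",
                    adjust = adjust)),
    class = "cp_study_report")
}

#' @export
print.cp_study_report <- function(x, ...) {
  fmt_cmp <- function(nm, cmp) {
    if (is.null(cmp)) return(sprintf("  %-28s (not computable)\n", nm))
    sprintf("  %-28s %.3f vs %.3f   t = %6.3f, df = %5.1f, p = %.4g\n",
            nm, cmp$means[1], cmp$means[2], cmp$statistic, cmp$df,
            cmp$p_value)
  }
  cat(sprintf("Case-control study report (%s n=%d vs %s n=%d; %s)\n",
              x$groups["case"], x$n["case"], x$groups["control"],
              x$n["control"], x$settings$test))
  cat(fmt_cmp("CP volume (% of TIV)", x$comparisons$cp_pct))
  cat(fmt_cmp("DTI-ALPS index", x$comparisons$alps))
  cat(sprintf("  cognitive impairment: %d/%d cases (%.1f%%)\n",
              x$impairment$n_impaired, x$n["case"],
              x$impairment$prevalence_pct))
  cat(fmt_cmp("CP% impaired vs not (cases)",
              x$comparisons$cp_pct_impaired_vs_not))
  cat("  correlations of CP% with subtest z-scores (cases):\n")
  for (i in seq_len(nrow(x$correlations)))
    cat(sprintf("    %-24s r = %6.3f, p = %.4g\n",
                x$correlations$subtest[i], x$correlations$r[i],
                x$correlations$p_value[i]))
  invisible(x)
}
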