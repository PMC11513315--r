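#' Derive a per-subject RNG seed from a master seed
#'
#' Deterministic splitting rule
#' `(master + 104729 * index) mod 2147483647` (the prime 104729 strides the
#' 31-bit seed space), so a subject's phantom is reproducible in isolation
#' and independent of cohort size.
#'
#' @param master_seed Integer master seed.
#' @param index 1-based subject index.
#' @return Integer seed in `[0, 2^31 - 2]`.
#' @export
subject_seed <- function(master_seed, index) {
  m <- 2147483647
  as.integer((as.numeric(master_seed) %% m + 104729 * as.numeric(index)) %% m)
}

#' Default end-to-end pipeline configuration
#'
#' @param seed Master seed.
#' @param preset Cohort calibration preset (see [default_cohort_spec()]).
#' @param n_per_group Optional named override of group sizes.
#' @param stages Character subset of `c("segment", "alps")`: which measured
#'   quantities are produced by running phantoms through the pipeline
#'   (otherwise the simulated target value is carried through directly).
#' @param phantom_base A [phantom_spec()] giving the T1 phantom geometry.
#' @param tensor_base A [tensor_phantom_spec()] giving the tensor geometry.
#' @param roi_center_mm ALPS ROI centre; default sits between the two fiber
#'   boxes of `tensor_base` on their shared x-range.
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, preset = "section3",
                            n_per_group = NULL,
                            stages = c("segment", "alps"),
                            phantom_base = phantom_spec(),
                            tensor_base = tensor_phantom_spec(),
                            roi_center_mm = NULL,
                            out_dir = NULL) {
  if (is.null(roi_center_mm)) {
    sp <- tensor_base$spacing_mm
    mid <- function(axis) {
      lo <- max(tensor_base$proj_region[[axis]][1],
                tensor_base$assoc_region[[axis]][1])
      hi <- min(tensor_base$proj_region[[axis]][2],
                tensor_base$assoc_region[[axis]][2])
      (mean(c(lo, hi)) - 1)
    }
    gap_y <- mean(c(tensor_base$proj_region$y, tensor_base$assoc_region$y))
    roi_center_mm <- c(mid("x") * sp[1], (gap_y - 1) * sp[2],
                       mid("z") * sp[3])
  }
  structure(list(seed = as.integer(seed), preset = preset,
                 n_per_group = n_per_group, stages = stages,
                 phantom_base = phantom_base, tensor_base = tensor_base,
                 roi_center_mm = roi_center_mm, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `seed`, `preset`, `n_per_group` (mapping of
#' group label to count), `stages` (list), `out_dir`; phantom/tensor
#' geometry keys under `phantom` / `tensor` override the corresponding
#' [phantom_spec()] / [tensor_phantom_spec()] arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pb <- do.call(phantom_spec, if (is.null(y$phantom)) list() else y$phantom)
  tb <- do.call(tensor_phantom_spec,
                if (is.null(y$tensor)) list() else y$tensor)
  pipeline_config(seed = if (is.null(y$seed)) 1L else y$seed,
                  preset = if (is.null(y$preset)) "section3" else y$preset,
                  n_per_group = if (is.null(y$n_per_group)) NULL else
                    unlist(y$n_per_group),
                  stages = if (is.null(y$stages))
                    c("segment", "alps") else unlist(y$stages),
                  phantom_base = pb, tensor_base = tb,
                  out_dir = y$out_dir)
}

stage_try <- function(stage, subject, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed for subject %s: %s", stage, subject,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full simulation-to-statistics pipeline
#'
#' Draws a cohort of subject-level target values from the calibrated group
#' models, realizes each subject as phantoms (a T1 ventricle phantom whose
#' true CP fraction matches the subject's target CP percent; a noise-free
#' tensor phantom whose true ALPS index matches the target), measures both
#' quantities by actually running [segment_cp()] and [compute_alps()], and
#' feeds the measured cohort table to [run_study()]. Stages omitted from
#' `config$stages` pass the simulated target through unmeasured. Every
#' subject's phantom uses [subject_seed()], so the whole run is
#' reproducible from `config$seed` alone.
#'
#' @param config A `pipeline_config` (or YAML path, see
#'   [read_pipeline_config()]).
#' @return List: `cohort` (targets plus measured values), `report`
#'   (the [run_study()] output) and `manifest` (config echo, seeds,
#'   package version). When `config$out_dir` is set, `cohort.tsv`,
#'   `report.json` and `manifest.json` are written there.
#' @export
run_all <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cspec <- default_cohort_spec(preset = config$preset, seed = config$seed)
  if (!is.null(config$n_per_group))
    cspec$n_per_group[names(config$n_per_group)] <-
      as.integer(config$n_per_group)
  validate_cohort_spec(cspec)
  targets <- generate_cohort(cspec)

  n <- nrow(targets)
  measured_cp <- targets$cp_pct
  measured_alps <- targets$alps
  # geometry is shared by all subjects: rasterize the ventricles once
  pbase <- config$phantom_base
  if ("segment" %in% config$stages) {
    n_vent <- sum(rasterize_ventricles(pbase) > 0L)
    vent_mm3 <- n_vent * prod(pbase$spacing_mm)
  }
  for (i in seq_len(n)) {
    sseed <- subject_seed(config$seed, i)
    sid <- targets$id[i]
    if ("segment" %in% config$stages) {
      seg <- stage_try("segment", sid, {
        sp <- pbase
        sp$cp_fraction <- targets$cp_pct[i] / 100 * pbase$tiv_mm3 / vent_mm3
        sp$seed <- sseed
        validate_phantom_spec(sp)
        ph <- generate_phantom(sp)
        segment_cp(ph$t1, ph$ventricle_mask, pbase$tiv_mm3)
      })
      measured_cp[i] <- seg$cp_volume_pct
    }
    if ("alps" %in% config$stages) {
      res <- stage_try("alps", sid, {
        tp <- generate_tensor_phantom(tensor_spec_for_alps(
          targets$alps[i], base = config$tensor_base, seed = sseed))
        compute_alps(tp$tensors, alps_roi(config$roi_center_mm))
      })
      measured_alps[i] <- res$index
    }
  }

  cohort <- targets
  cohort$cp_pct_target <- targets$cp_pct
  cohort$alps_target <- targets$alps
  cohort$cp_pct <- measured_cp
  cohort$alps <- measured_alps

  report <- stage_try("stats", "(cohort)", run_study(cohort))
  manifest <- list(seed = config$seed, preset = config$preset,
                   n_per_group = as.list(cspec$n_per_group),
                   stages = config$stages,
                   subject_seeds = vapply(seq_len(n), subject_seed,
                                          0L, master_seed = config$seed),
                   roi_center_mm = config$roi_center_mm,
                   package_version =
                     as.character(utils::packageVersion("cpalps")))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(config$out_dir, "cohort.tsv"))
    jsonlite::write_json(report_to_list(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(cohort = cohort, report = report, manifest = manifest)
}

# Flatten a cp_study_report into JSON-friendly plain lists.
report_to_list <- function(report) {
  cmp_list <- function(cmp) {
    if (is.null(cmp)) return(NULL)
    list(test = cmp$test, statistic = cmp$statistic, df = cmp$df,
         p_value = cmp$p_value, means = cmp$means, sds = cmp$sds,
         ns = cmp$ns)
  }
  list(groups = as.list(report$groups), n = as.list(report$n),
       comparisons = lapply(report$comparisons, cmp_list),
       impairment = list(n_impaired = report$impairment$n_impaired,
                         prevalence_pct = report$impairment$prevalence_pct),
       correlations = report$correlations,
       settings = report$settings)
}
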