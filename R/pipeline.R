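#' Extract texture features for every patient and operator of a cohort
#'
#' Computes the FWC map of each patient's Dixon pair and extracts the
#' 36-feature filtration-histogram set under each operator's ROI.
#'
#' @param cohort A [simulate_cohort()] / [read_cohort()] object.
#' @param ssf_mm Spatial scale factors (mm).
#' @param n_bins Entropy histogram bins.
#' @return Long feature tibble with `patient_id`, `operator_id`,
#'   `ssf_mm`, `statistic`, `feature`, `value`, `roi_pixel_count`.
#' @export
cohort_features <- function(cohort, ssf_mm = c(0, 2, 3, 4, 5, 6),
                            n_bins = 64L) {
  ids <- cohort$clinical$patient_id
  purrr::map2_dfr(cohort$patients, ids, function(p, id) {
    fmap <- compute_fwc_map(p$dixon)
    dplyr::bind_rows(
      extract_feature_set(fmap, p$mask_op1, ssf_mm, n_bins,
                          patient_id = id, operator_id = "1"),
      extract_feature_set(fmap, p$mask_op2, ssf_mm, n_bins,
                          patient_id = id, operator_id = "2")
    )
  })
}

#' Run the full FWC radiomics analysis
#'
#' Executes the four statistical stages on a cohort (in memory or a
#' directory written by [write_cohort()]):
#' \enumerate{
#'   \item inter-operator ICC QC: features with ICC <= 0.75 dropped,
#'     survivors averaged across operators;
#'   \item Spearman screening of retained features against the six
#'     functional imaging metrics with BH false discovery control;
#'   \item optimal-cutpoint Kaplan-Meier screening of retained features
#'     and functional metrics, then forward-stepwise Cox modelling of
#'     the best univariately significant marker of each family
#'     (texture, FDG uptake, ADC) and their pairwise interactions;
#'   \item mutation association for the most significant prognostic
#'     texture marker's groups (smallest log-rank p; ties broken by
#'     coarsest SSF, then alphabetical statistic).
#' }
#'
#' @param cohort A cohort object or a cohort directory path.
#' @param fdr_q BH false discovery rate (default 0.1).
#' @param icc_threshold ICC retention threshold (default 0.75).
#' @param min_group_frac Minimum group fraction for cutpoint search.
#' @param alpha Significance level for survival/Cox stages.
#' @param ssf_mm,n_bins Texture configuration.
#' @param features Optional precomputed [cohort_features()] table.
#' @return An `fwc_analysis` object: list with `icc`, `correlations`,
#'   `survival`, `cox`, `mutations`, `best_texture_marker`, `config`.
#' @export
run_full_analysis <- function(cohort, fdr_q = 0.1, icc_threshold = 0.75,
                              min_group_frac = 0.1, alpha = 0.05,
                              ssf_mm = c(0, 2, 3, 4, 5, 6), n_bins = 64L,
                              features = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  clinical <- cohort$clinical
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_fwctex(sprintf("stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   "fwctex_stage_failure")
    })
  }

  if (is.null(features)) {
    features <- stage("texture", cohort_features(cohort, ssf_mm, n_bins))
  }
  icc <- stage("icc-qc", qc_filter_features(
    dplyr::filter(features, .data$operator_id == "1"),
    dplyr::filter(features, .data$operator_id == "2"),
    threshold = icc_threshold
  ))
  correlations <- stage("correlation", correlation_screen(
    icc$averaged, clinical, q = fdr_q
  ))

  # survival stage: retained texture features + functional metrics
  wide <- tidyr::pivot_wider(icc$averaged, names_from = "feature",
                             values_from = "value")
  surv_dat <- dplyr::inner_join(wide, clinical, by = "patient_id")
  texture_markers <- setdiff(names(wide), "patient_id")
  functional_markers <- intersect(
    c("suv_max", "suv_mean", "tlg", "adc_mean", "adc_skewness",
      "adc_kurtosis"),
    names(clinical)
  )
  surv <- stage("survival", survival_screen(
    surv_dat, c(texture_markers, functional_markers),
    min_group_frac = min_group_frac, alpha = alpha
  ))

  # multivariate stage: the best univariately significant marker of each
  # family (texture, FDG uptake, ADC) plus their pairwise interactions
  sig <- dplyr::filter(surv, .data$significant)
  families <- list(
    texture = texture_markers,
    fdg = intersect(c("suv_max", "suv_mean", "tlg"), functional_markers),
    adc = intersect(c("adc_mean", "adc_skewness", "adc_kurtosis"),
                    functional_markers)
  )
  best_per_family <- purrr::map_chr(families, function(mk) {
    rows <- dplyr::filter(sig, .data$marker %in% mk)
    if (nrow(rows) == 0) NA_character_
    else rows$marker[which.min(rows$p)]
  })
  cox_markers <- unname(best_per_family[!is.na(best_per_family)])
  cox <- NULL
  if (length(cox_markers) > 0) {
    sel <- dplyr::filter(sig, .data$marker %in% cox_markers)
    dich <- surv_dat["patient_id"]
    dich$os_months <- surv_dat$os_months
    dich$event <- surv_dat$event
    for (i in seq_len(nrow(sel))) {
      g <- prognostic_group(surv_dat[[sel$marker[i]]], sel$threshold[i],
                            sel$direction[i])
      dich[[sel$marker[i]]] <- as.integer(g == "poor")
    }
    cox <- stage("cox", cox_forward_selection(
      dich, sel$marker, include_interactions = TRUE, alpha_enter = alpha
    ))
  }

  # mutation stage on the best texture marker's prognostic groups
  best_texture <- surv |>
    dplyr::filter(.data$marker %in% texture_markers, !is.na(.data$p)) |>
    dplyr::mutate(
      ssf = as.numeric(sub("^.*_ssf", "", .data$marker)),
      statistic = sub("_ssf.*$", "", .data$marker)
    ) |>
    dplyr::arrange(.data$p, dplyr::desc(.data$ssf), .data$statistic)
  mutations <- NULL
  best_marker <- NA_character_
  if (nrow(best_texture) > 0 && nrow(cohort$mutations) > 0) {
    bm <- best_texture[1, ]
    best_marker <- bm$marker
    groups <- tibble::tibble(
      patient_id = surv_dat$patient_id,
      group = as.character(prognostic_group(surv_dat[[bm$marker]],
                                            bm$threshold, bm$direction))
    )
    profiled_groups <- unique(groups$group[groups$patient_id %in%
                                             cohort$mutations$patient_id])
    if (length(profiled_groups) == 2L) {
      mutations <- stage("mutation", mutation_association(
        cohort$mutations, groups
      ))
    } else {
      message("mutation stage skipped: all profiled patients fall in one ",
              "prognostic group")
    }
  }

  structure(
    list(
      features = features, icc = icc, correlations = correlations,
      survival = surv, cox = cox, mutations = mutations,
      best_texture_marker = best_marker,
      config = list(fdr_q = fdr_q, icc_threshold = icc_threshold,
                    min_group_frac = min_group_frac, alpha = alpha,
                    ssf_mm = ssf_mm, entropy_bins = n_bins)
    ),
    class = "fwc_analysis"
  )
}

#' @export
print.fwc_analysis <- function(x, ...) {
  cat("<fwc_analysis>\n")
  cat(sprintf("  QC: %d/%d features retained (ICC > %.2f)\n",
              sum(x$icc$features$retained), nrow(x$icc$features),
              x$config$icc_threshold))
  cat(sprintf("  Correlation: %d BH-significant tests at q = %.2g\n",
              sum(x$correlations$bh_significant, na.rm = TRUE),
              x$config$fdr_q))
  cat(sprintf("  Survival: %d/%d markers significant at alpha = %.2g\n",
              sum(x$survival$significant, na.rm = TRUE), nrow(x$survival),
              x$config$alpha))
  if (!is.null(x$cox)) {
    cat(sprintf("  Cox: %d term(s) included\n", nrow(x$cox$included)))
  }
  if (!is.null(x$mutations)) {
    cat(sprintf("  Mutations (%s): medians %.3g vs %.3g, p = %.4g\n",
                x$best_texture_marker,
                x$mutations$count_test$median_good,
                x$mutations$count_test$median_poor,
                x$mutations$count_test$p))
  }
  invisible(x)
}

#' Write all analysis reports to a directory
#'
#' Emits `features.csv`, `icc_report.csv`, `correlations.csv`,
#' `survival.csv`, `cox_report.json`, `mutations_report.json` and
#' `analysis_config.json`.
#'
#' @param analysis An [run_full_analysis()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_reports <- function(analysis, dir) {
  stopifnot(inherits(analysis, "fwc_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(analysis$features, file.path(dir, "features.csv"))
  readr::write_csv(analysis$icc$features, file.path(dir, "icc_report.csv"))
  readr::write_csv(tibble::as_tibble(analysis$correlations),
                   file.path(dir, "correlations.csv"))
  readr::write_csv(tibble::as_tibble(analysis$survival),
                   file.path(dir, "survival.csv"))
  if (!is.null(analysis$cox)) {
    jsonlite::write_json(
      list(included = analysis$cox$included,
           excluded = analysis$cox$excluded,
           n = analysis$cox$n, n_events = analysis$cox$n_events),
      file.path(dir, "cox_report.json"), auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(analysis$mutations)) {
    jsonlite::write_json(
      list(best_texture_marker = analysis$best_texture_marker,
           count_test = analysis$mutations$count_test,
           per_gene = analysis$mutations$per_gene),
      file.path(dir, "mutations_report.json"), auto_unbox = TRUE,
      digits = NA
    )
  }
  jsonlite::write_json(analysis$config, file.path(dir, "analysis_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the whole simulate-to-reports workflow
#'
#' Simulates a cohort (unless `cohort_dir` already holds one and
#' `simulate = FALSE`), writes it to disk, runs [run_full_analysis()],
#' writes all reports, and returns a checksummed artifact manifest.
#'
#' @param out_dir Output directory (cohort under `cohort/`, reports
#'   under `reports/`).
#' @param config A [cohort_config()] (ignored when `simulate = FALSE`).
#' @param simulate Generate a fresh cohort (default TRUE).
#' @param ... Passed to [run_full_analysis()].
#' @return A list with `analysis` and `manifest` (tibble: `file`,
#'   `md5`).
#' @export
run_pipeline <- function(out_dir, config = cohort_config(),
                         simulate = TRUE, ...) {
  cohort_dir <- file.path(out_dir, "cohort")
  if (simulate) {
    cohort <- simulate_cohort(config)
    write_cohort(cohort, cohort_dir)
  }
  if (!file.exists(file.path(cohort_dir, "clinical.csv"))) {
    abort_fwctex("analysis stage: clinical.csv not found in cohort directory",
                 "fwctex_stage_failure")
  }
  analysis <- run_full_analysis(cohort_dir, ...)
  report_dir <- file.path(out_dir, "reports")
  write_reports(analysis, report_dir)
  files <- sort(c(list.files(cohort_dir, full.names = TRUE),
                  list.files(report_dir, full.names = TRUE)))
  manifest <- tibble::tibble(
    file = sub(paste0("^", out_dir, "/?"), "", files),
    md5 = unname(tools::md5sum(files))
  )
  list(analysis = analysis, manifest = manifest)
}
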