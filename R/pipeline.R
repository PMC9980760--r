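# Orchestration: cohort summary, score-performance grids, administrative
# grids, and the end-to-end pipeline runner.

SCORE_CUTOFFS <- tibble::tibble(
  score = c("sofa", "news", "news", "sirs", "qsofa"),
  cutoff = c(2, 5, 7, 2, 2)
)

#' Severity-score performance for a mortality endpoint
#'
#' Evaluates each instrument at its clinical cut-off (SOFA >= 2, NEWS >= 5,
#' NEWS >= 7, SIRS >= 2, qSOFA >= 2) against a mortality endpoint among
#' admissions with infection: 2x2 counts, sensitivity/specificity/PPV/NPV
#' with 95% CIs, plus the empirical AUROC of the score across all its values
#' (DeLong confidence interval).
#'
#' @param labels tibble from [label_cohort()].
#' @param endpoint which mortality endpoint is the truth: 30-day from
#'   infection onset (default), 30-day from admission, or in-hospital.
#' @param cutoffs tibble with columns `score`, `cutoff` overriding the
#'   clinical defaults.
#' @param ci_method passed to [accuracy_stats()].
#' @return list with `grid` (one row per score/cut-off) and `auroc` (one row
#'   per instrument, across all values).
#' @export
score_performance <- function(labels,
                              endpoint = c("mortality_30d_onset",
                                           "mortality_30d_admission",
                                           "in_hospital_death"),
                              cutoffs = SCORE_CUTOFFS,
                              ci_method = "clopper-pearson") {
  endpoint <- match.arg(endpoint)
  inf <- labels[labels$category != "no_infection", , drop = FALSE]
  if (nrow(inf) == 0) stop_invalid("no admissions with infection")
  truth <- inf[[endpoint]]
  score_col <- c(sofa = "max_sofa", news = "news", sirs = "sirs",
                 qsofa = "qsofa")

  rows <- lapply(seq_len(nrow(cutoffs)), function(i) {
    sc <- cutoffs$score[i]
    co <- cutoffs$cutoff[i]
    vals <- inf[[score_col[[sc]]]]
    t <- two_by_two(vals >= co, truth)
    st <- accuracy_stats(t, ci_method = ci_method)
    wide <- stats::setNames(
      as.list(c(rbind(st$estimate, st$conf_low, st$conf_high))),
      paste0(rep(st$statistic, each = 3), c("", "_low", "_high"))
    )
    tibble::tibble(score = sc, cutoff = co, n_infected = nrow(inf),
                   n_positive = t$tp + t$fp,
                   deaths_above = t$tp, deaths_below = t$fn,
                   tp = t$tp, fp = t$fp, fn = t$fn, tn = t$tn, !!!wide)
  })

  auroc <- dplyr::bind_rows(lapply(unique(cutoffs$score), function(sc) {
    vals <- inf[[score_col[[sc]]]]
    if (!any(truth) || all(truth)) {
      return(tibble::tibble(score = sc, auroc = NA_real_,
                            auroc_low = NA_real_, auroc_high = NA_real_))
    }
    ci <- auroc_ci(vals, truth)
    tibble::tibble(score = sc, auroc = ci$auroc, auroc_low = ci$conf_low,
                   auroc_high = ci$conf_high)
  }))

  list(grid = dplyr::bind_rows(rows), auroc = auroc)
}

#' Pairwise DeLong comparisons of the severity-score AUROCs
#'
#' @param labels tibble from [label_cohort()].
#' @param reference_score instrument to compare the others against.
#' @inheritParams score_performance
#' @return tibble with `score`, both AUROCs, `z` and `p_value`.
#' @export
compare_score_aurocs <- function(labels, reference_score = "sofa",
                                 endpoint = "mortality_30d_onset") {
  inf <- labels[labels$category != "no_infection", , drop = FALSE]
  truth <- inf[[endpoint]]
  score_col <- c(sofa = "max_sofa", news = "news", sirs = "sirs",
                 qsofa = "qsofa")
  ref <- inf[[score_col[[reference_score]]]]
  others <- setdiff(names(score_col), reference_score)
  dplyr::bind_rows(lapply(others, function(sc) {
    dt <- delong_test(inf[[score_col[[sc]]]], ref, truth)
    tibble::tibble(score = sc, reference = reference_score,
                   auroc = dt$auroc_a$auroc, auroc_ref = dt$auroc_b$auroc,
                   z = dt$z, p_value = dt$p_value)
  }))
}

#' Cohort summary by sepsis category
#'
#' Descriptive counts and medians per labelled category: admissions, age,
#' length of stay, critical-care admission, blood-culture sampling and
#' positivity, and the mortality endpoints.
#'
#' @param cohort an `ehr_cohort` or compatible list of tibbles.
#' @param labels tibble from [label_cohort()].
#' @return tibble with one row per category plus a cohort-wide row.
#' @export
summarise_cohort <- function(cohort, labels) {
  adm <- dplyr::inner_join(cohort$admissions,
                           labels[, c("admission_id", "category",
                                      "mortality_30d_onset",
                                      "mortality_30d_admission",
                                      "in_hospital_death",
                                      "critical_care_48h")],
                           by = "admission_id")
  cult <- cohort$cultures |>
    dplyr::group_by(.data$admission_id) |>
    dplyr::summarise(sampled = TRUE,
                     positive = any(.data$result == "positive"),
                     .groups = "drop")
  adm <- dplyr::left_join(adm, cult, by = "admission_id")
  adm$sampled[is.na(adm$sampled)] <- FALSE
  adm$positive[is.na(adm$positive)] <- FALSE
  adm$los_days <- as.numeric(difftime(adm$discharge_time, adm$admit_time,
                                      units = "days"))
  adm$cc_any <- adm$admission_id %in%
    cohort$episodes$admission_id[cohort$episodes$unit_type == "critical_care"]

  one <- function(d, label) {
    tibble::tibble(
      group = label, n = nrow(d),
      age_median = stats::median(d$age),
      los_median_days = stats::median(d$los_days),
      critical_care = sum(d$cc_any),
      critical_care_48h = sum(d$critical_care_48h),
      blood_culture = sum(d$sampled),
      positive_culture = sum(d$positive),
      in_hospital_deaths = sum(d$in_hospital_death),
      deaths_30d_admission = sum(d$mortality_30d_admission),
      deaths_30d_onset = sum(d$mortality_30d_onset)
    )
  }
  dplyr::bind_rows(
    one(adm, "all"),
    lapply(levels(adm$category), function(lv) {
      one(adm[adm$category == lv, , drop = FALSE], lv)
    })
  )
}

#' Pipeline configuration
#'
#' @param params [cohort_params()] for the simulation stage (ignored when a
#'   cohort is passed to [run_pipeline()] directly).
#' @param window_h acuity window half-width, hours.
#' @param sofa_threshold Sepsis-3 organ-dysfunction threshold.
#' @param baseline_mode critical-care SOFA baseline rule.
#' @param endpoint mortality endpoint for the score grid.
#' @param reference reference definition for the administrative grid:
#'   Sepsis-3 label, or infection with NEWS >= 7.
#' @param ci_method confidence-interval method.
#' @param news7_cutoff NEWS cut-off used by the `infection_news7` reference.
#' @param code_lists code lists from [default_code_lists()].
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(params = cohort_params(),
                            window_h = 48,
                            sofa_threshold = 2,
                            baseline_mode = "min_pre",
                            endpoint = "mortality_30d_onset",
                            reference = c("sepsis3", "infection_news7"),
                            ci_method = "clopper-pearson",
                            news7_cutoff = 7,
                            code_lists = default_code_lists(),
                            seed = 1L) {
  reference <- match.arg(reference)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Simulate (unless a cohort is supplied), filter, score, label, and
#' evaluate: produces the cohort summary, the severity-score performance
#' grid for the chosen mortality endpoint, the administrative-data grid
#' against the chosen reference, ROC curves, and run metadata (config hash
#' and seed) for reproducibility.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-built `ehr_cohort`; when absent one is
#'   generated from `config$params` with `config$seed`.
#' @return list with elements `cohort_summary`, `score_grid`, `score_auroc`,
#'   `delong`, `admin_grid`, `roc`, `labels`, `exclusions`, `meta`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    params <- config$params
    params$seed <- config$seed
    cohort <- generate_cohort(params)
  }

  filt <- apply_eligibility_filters(cohort$admissions)
  kept <- filt$admissions$admission_id
  sub <- function(tb) tb[tb$admission_id %in% kept, , drop = FALSE]
  cohort_f <- cohort
  cohort_f$admissions <- filt$admissions
  for (nm in c("episodes", "vitals", "labs", "cultures", "antibiotics",
               "codes")) {
    cohort_f[[nm]] <- sub(cohort[[nm]])
  }

  labels <- label_cohort(cohort_f, window_h = config$window_h,
                         sofa_threshold = config$sofa_threshold,
                         baseline_mode = config$baseline_mode)

  perf <- score_performance(labels, endpoint = config$endpoint,
                            ci_method = config$ci_method)
  delong <- compare_score_aurocs(labels, endpoint = config$endpoint)

  ind <- build_indicators(cohort_f$codes, cohort_f$cultures,
                          labels$admission_id, lists = config$code_lists)
  reference <- if (config$reference == "sepsis3") {
    labels$category == "sepsis"
  } else {
    labels$category != "no_infection" & labels$news >= config$news7_cutoff
  }
  admin <- evaluate_indicators(ind, reference, ci_method = config$ci_method)

  inf <- labels[labels$category != "no_infection", , drop = FALSE]
  truth <- inf[[config$endpoint]]
  roc <- if (any(truth) && !all(truth)) {
    dplyr::bind_rows(lapply(
      c(sofa = "max_sofa", news = "news", sirs = "sirs", qsofa = "qsofa"),
      function(cl) roc_curve(inf[[cl]], truth)), .id = "score")
  } else {
    tibble::tibble()
  }

  list(
    cohort_summary = summarise_cohort(cohort_f, labels),
    score_grid = perf$grid,
    score_auroc = perf$auroc,
    delong = delong,
    admin_grid = admin,
    roc = roc,
    labels = labels,
    exclusions = filt$exclusions,
    meta = list(seed = config$seed,
                config_hash = rlang::hash(config),
                endpoint = config$endpoint,
                reference = config$reference,
                n_analysed = nrow(labels))
  )
}

#' Bundled reference 2x2 counts
#'
#' The package ships the confusion counts of a published single-centre
#' evaluation cohort (958 admissions, 630 with infection, 78 thirty-day
#' deaths from onset among the infected; 347 Sepsis-3 sepsis): severity
#' scores at their clinical cut-offs against 30-day mortality, and the seven
#' administrative indicators against the Sepsis-3 reference. They are used
#' as fixed inputs for validating the accuracy statistics.
#'
#' @return `reference_score_counts()`: tibble of score/cut-off rows with
#'   `tp`, `fp`, `fn`, `tn`; `reference_admin_counts()`: tibble of indicator
#'   rows with the same columns.
#' @export
reference_score_counts <- function() {
  tibble::tibble(
    score = c("sofa", "news", "news", "sirs", "qsofa"),
    cutoff = c(2, 5, 7, 2, 2),
    tp = c(65, 66, 53, 70, 33),
    fp = c(282, 270, 147, 335, 55),
    fn = c(13, 12, 25, 8, 45),
    tn = c(270, 282, 405, 217, 497)
  )
}

#' @rdname reference_score_counts
#' @export
reference_admin_counts <- function() {
  tibble::tibble(
    indicator = c("infection_code", "sepsis_code", "infection_or_sepsis_code",
                  "blood_culture", "positive_blood_culture",
                  "code_or_culture", "code_and_culture"),
    tp = c(226, 27, 243, 229, 26, 303, 169),
    fp = c(198, 15, 210, 250, 16, 313, 147),
    fn = c(121, 320, 104, 118, 321, 44, 178),
    tn = c(413, 596, 401, 361, 595, 298, 464)
  )
}

#' Recompute the reference performance grids from the bundled counts
#'
#' @param ci_method confidence-interval method.
#' @return list with `scores` and `admin` tibbles carrying full-precision
#'   statistics, CIs and (for the administrative grid) binary AUROCs.
#' @export
reproduce_reference_grids <- function(ci_method = "clopper-pearson") {
  sc <- reference_score_counts()
  score_rows <- lapply(seq_len(nrow(sc)), function(i) {
    t <- two_by_two_counts(sc$tp[i], sc$fp[i], sc$fn[i], sc$tn[i])
    st <- accuracy_stats(t, ci_method = ci_method)
    wide <- stats::setNames(
      as.list(c(rbind(st$estimate, st$conf_low, st$conf_high))),
      paste0(rep(st$statistic, each = 3), c("", "_low", "_high"))
    )
    tibble::tibble(score = sc$score[i], cutoff = sc$cutoff[i], !!!wide)
  })
  ad <- reference_admin_counts()
  admin_rows <- lapply(seq_len(nrow(ad)), function(i) {
    t <- two_by_two_counts(ad$tp[i], ad$fp[i], ad$fn[i], ad$tn[i])
    st <- accuracy_stats(t, ci_method = ci_method)
    au <- binary_auroc(t)
    wide <- stats::setNames(
      as.list(c(rbind(st$estimate, st$conf_low, st$conf_high))),
      paste0(rep(st$statistic, each = 3), c("", "_low", "_high"))
    )
    tibble::tibble(indicator = ad$indicator[i], !!!wide,
                   auroc = au$auroc, auroc_low = au$conf_low,
                   auroc_high = au$conf_high)
  })
  list(scores = dplyr::bind_rows(score_rows),
       admin = dplyr::bind_rows(admin_rows))
}
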