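# Sepsis-3 phenotyping: infection onset, +/-48h acuity windows, worst-per-24h
# SOFA, and the three-way label {no_infection, infection_no_sepsis, sepsis}.
#
# Window conventions: the acuity window is [onset - 48h, onset + 48h), split
# for SOFA into four 24h periods [-48, -24), [-24, 0), [0, 24), [24, 48)
# relative to onset; the left edge of the first period is inclusive and the
# +48h edge exclusive.

SEPSIS_CATEGORIES <- c("no_infection", "infection_no_sepsis", "sepsis")

#' Onset of infection
#'
#' The earlier of the first blood culture and the first antibiotic dose.
#'
#' @param culture_times,antibiotic_times `POSIXct` vectors (either may be
#'   empty, not both).
#' @return a single `POSIXct` timestamp.
#' @export
#' @examples
#' infection_onset(as.POSIXct("2015-11-02 10:00", tz = "UTC"),
#'                 as.POSIXct("2015-11-02 12:00", tz = "UTC"))
infection_onset <- function(culture_times, antibiotic_times) {
  all_t <- c(culture_times, antibiotic_times)
  all_t <- all_t[!is.na(all_t)]
  if (length(all_t) == 0) {
    stop_invalid("no blood cultures or antibiotics: infection onset undefined")
  }
  out <- min(all_t)
  tz <- attr(culture_times, "tzone")
  if (is.null(tz) || !nzchar(tz)) tz <- attr(antibiotic_times, "tzone")
  if (!is.null(tz) && nzchar(tz)) attr(out, "tzone") <- tz
  out
}

# hours from onset, and the 24h period index (-2, -1, 0, 1) for in-window rows
window_period <- function(time, onset, window_h = 48) {
  dt <- as.numeric(difftime(time, onset, units = "hours"))
  p <- floor(dt / 24)
  p[dt < -window_h | dt >= window_h] <- NA_integer_
  p
}

# NEWS/qSOFA/SIRS for each vitals row, with the nearest in-window WCC attached
score_observations <- function(vitals, labs) {
  if (nrow(vitals) == 0) {
    vitals$news <- integer()
    vitals$qsofa <- integer()
    vitals$wcc <- numeric()
    vitals$sirs <- integer()
    return(vitals)
  }
  wcc <- labs[labs$analyte == "wcc", c("admission_id", "time", "value")]
  out <- vitals
  out$news <- news_score(
    resp_rate = vitals$resp_rate, spo2 = vitals$spo2,
    on_oxygen = vitals$on_oxygen, temp = vitals$temp, sbp = vitals$sbp,
    heart_rate = vitals$heart_rate, avpu = vitals$avpu
  )
  out$qsofa <- qsofa_score(resp_rate = vitals$resp_rate, sbp = vitals$sbp,
                           gcs = vitals$gcs, avpu = vitals$avpu)
  out$wcc <- nearest_value(vitals$admission_id, vitals$time, wcc)
  out$sirs <- sirs_score(temp = vitals$temp, heart_rate = vitals$heart_rate,
                         resp_rate = vitals$resp_rate, wcc = out$wcc)
  out
}

# for each (id, time) query, the lab value at the nearest timestamp of the
# same admission (NA when that admission has none)
nearest_value <- function(id, time, lab_tbl) {
  if (nrow(lab_tbl) == 0) return(rep(NA_real_, length(id)))
  split_lab <- split(seq_len(nrow(lab_tbl)), lab_tbl$admission_id)
  out <- rep(NA_real_, length(id))
  for (g in split(seq_along(id), id)) {
    rows <- split_lab[[as.character(id[g[1]])]]
    if (is.null(rows)) next
    lt <- lab_tbl$time[rows]
    lv <- lab_tbl$value[rows]
    idx <- vapply(time[g], function(tt) {
      which.min(abs(as.numeric(difftime(lt, tt, units = "secs"))))
    }, integer(1))
    out[g] <- lv[idx]
  }
  out
}

#' Severity scores at the point of highest acuity
#'
#' Scores NEWS, qSOFA and SIRS at (a) the vitals observation nearest to
#' infection onset and (b) the observation with the highest NEWS in the 48h
#' before or after onset; the highest-NEWS values are the ones used in
#' analyses. Ties on NEWS are broken by the earliest timestamp. An empty
#' window yields all-zero scores with a warning.
#'
#' @param vitals tibble of vitals observations for one admission (columns
#'   `time`, `resp_rate`, `spo2`, `on_oxygen`, `temp`, `sbp`, `dbp`,
#'   `heart_rate`, `avpu`, `gcs`; missing columns treated as absent).
#' @param labs tibble of laboratory results for one admission (columns
#'   `time`, `analyte`, `value`); only `wcc` rows are used here.
#' @param onset infection onset (`POSIXct`).
#' @param window_h half-width of the acuity window in hours (default 48).
#' @return one-row tibble: `news`, `qsofa`, `sirs` (highest acuity),
#'   `news_nearest`, `qsofa_nearest`, `sirs_nearest`, `acuity_time`,
#'   `n_obs_window`.
#' @export
highest_acuity_scores <- function(vitals, labs, onset, window_h = 48) {
  vitals <- normalise_vitals(vitals)
  labs <- normalise_labs(labs)
  dt <- as.numeric(difftime(vitals$time, onset, units = "hours"))
  win <- vitals[dt >= -window_h & dt < window_h, , drop = FALSE]
  if (nrow(win) == 0) {
    warning("no vitals observations within the acuity window; scores set to 0",
            call. = FALSE)
    return(tibble::tibble(news = 0L, qsofa = 0L, sirs = 0L,
                          news_nearest = 0L, qsofa_nearest = 0L,
                          sirs_nearest = 0L,
                          acuity_time = as.POSIXct(NA), n_obs_window = 0L))
  }
  sc <- score_observations(win, labs)
  peak <- sc[order(-sc$news, sc$time), , drop = FALSE][1, ]
  near <- sc[order(abs(as.numeric(difftime(sc$time, onset, units = "secs"))),
                   sc$time), , drop = FALSE][1, ]
  tibble::tibble(news = peak$news, qsofa = peak$qsofa, sirs = peak$sirs,
                 news_nearest = near$news, qsofa_nearest = near$qsofa,
                 sirs_nearest = near$sirs,
                 acuity_time = peak$time, n_obs_window = nrow(win))
}

VITAL_COLS <- c("resp_rate", "spo2", "on_oxygen", "temp", "sbp", "dbp",
                "heart_rate", "avpu", "gcs")

normalise_vitals <- function(vitals) {
  if (is.null(vitals) || nrow(vitals) == 0) {
    vitals <- tibble::tibble(time = as.POSIXct(character()))
  }
  for (cl in VITAL_COLS) {
    if (!cl %in% names(vitals)) {
      vitals[[cl]] <- if (cl == "avpu") NA_character_
                      else if (cl == "on_oxygen") NA else NA_real_
    }
  }
  if (!"admission_id" %in% names(vitals)) vitals$admission_id <- 1L
  vitals
}

normalise_labs <- function(labs) {
  if (is.null(labs) || nrow(labs) == 0) {
    labs <- tibble::tibble(admission_id = integer(),
                           time = as.POSIXct(character()),
                           analyte = character(), value = numeric())
  }
  if (!"admission_id" %in% names(labs)) labs$admission_id <- 1L
  labs
}

# worst (most deranged) value per admission x period for every SOFA input;
# vectorised over many admissions at once
worst_by_period_table <- function(vitals, labs, onsets, window_h = 48) {
  vitals <- dplyr::inner_join(vitals, onsets, by = "admission_id")
  vitals$period <- window_period(vitals$time, vitals$onset, window_h)
  vitals <- vitals[!is.na(vitals$period), , drop = FALSE]
  vitals$map <- mean_arterial_pressure(vitals$sbp, vitals$dbp)
  avpu_rank <- c(A = 1L, V = 2L, P = 3L, U = 4L)

  worst_vit <- vitals |>
    dplyr::group_by(.data$admission_id, .data$period) |>
    dplyr::summarise(
      spo2 = min_or_na(.data$spo2),
      on_oxygen = any(!is.na(.data$on_oxygen) & .data$on_oxygen),
      map = min_or_na(.data$map),
      gcs = min_or_na(.data$gcs),
      avpu = worst_avpu(.data$avpu, avpu_rank),
      .groups = "drop"
    )

  labs <- dplyr::inner_join(labs, onsets, by = "admission_id")
  labs$period <- window_period(labs$time, labs$onset, window_h)
  labs <- labs[!is.na(labs$period), , drop = FALSE]

  lab_wide <- labs |>
    dplyr::filter(.data$analyte %in% c("platelets", "bilirubin", "creatinine")) |>
    tidyr::pivot_wider(id_cols = c("admission_id", "period", "time"),
                       names_from = "analyte", values_from = "value",
                       values_fn = mean)
  for (cl in c("platelets", "bilirubin", "creatinine")) {
    if (!cl %in% names(lab_wide)) lab_wide[[cl]] <- NA_real_
  }
  worst_lab <- lab_wide |>
    dplyr::group_by(.data$admission_id, .data$period) |>
    dplyr::summarise(
      platelets = min_or_na(.data$platelets),
      bilirubin = max_or_na(.data$bilirubin),
      creatinine = max_or_na(.data$creatinine),
      .groups = "drop"
    )

  # blood gases: pair PaO2 and FiO2 drawn at the same timestamp, keep the
  # gas with the lowest ratio in each period
  gas <- labs |>
    dplyr::filter(.data$analyte %in% c("pao2", "fio2")) |>
    tidyr::pivot_wider(id_cols = c("admission_id", "period", "time"),
                       names_from = "analyte", values_from = "value",
                       values_fn = mean)
  if (!"pao2" %in% names(gas)) gas$pao2 <- NA_real_
  if (!"fio2" %in% names(gas)) gas$fio2 <- NA_real_
  worst_gas <- gas |>
    dplyr::filter(!is.na(.data$pao2) & !is.na(.data$fio2)) |>
    dplyr::mutate(pf = .data$pao2 / .data$fio2) |>
    dplyr::group_by(.data$admission_id, .data$period) |>
    dplyr::slice_min(.data$pf, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("admission_id", "period", "pao2", "fio2")

  grid <- tidyr::expand_grid(admission_id = onsets$admission_id,
                             period = -2L:1L)
  grid |>
    dplyr::left_join(worst_vit, by = c("admission_id", "period")) |>
    dplyr::left_join(worst_lab, by = c("admission_id", "period")) |>
    dplyr::left_join(worst_gas, by = c("admission_id", "period")) |>
    dplyr::mutate(on_oxygen = !is.na(.data$on_oxygen) & .data$on_oxygen)
}

min_or_na <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
max_or_na <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
worst_avpu <- function(x, rank_map) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_character_)
  names(rank_map)[max(rank_map[x])]
}

# SOFA components + total for each row of a worst-by-period table
sofa_for_periods <- function(wt) {
  # a blood gas, when present in the period, takes precedence over SpO2
  spo2_eff <- ifelse(!is.na(wt$pao2) & !is.na(wt$fio2), NA_real_, wt$spo2)
  sofa_score(pao2 = wt$pao2, fio2 = wt$fio2, spo2 = spo2_eff,
             on_oxygen = wt$on_oxygen, platelets = wt$platelets,
             bilirubin = wt$bilirubin, map = wt$map, gcs = wt$gcs,
             avpu = wt$avpu, creatinine = wt$creatinine)
}

#' Worst-per-24h-period SOFA scores around infection onset
#'
#' Splits the 48h before and after onset into four 24h periods, takes the
#' directionally worst value of each SOFA input within each period (lowest
#' platelets, MAP, SpO2, PaO2/FiO2 and GCS; highest bilirubin and
#' creatinine), and scores SOFA per period. Periods with no data score 0.
#'
#' @inheritParams highest_acuity_scores
#' @return tibble with one row per period (`period` = -2, -1, 0, 1 in 24h
#'   units from onset), the six component scores and `total`.
#' @export
worst_sofa_by_period <- function(vitals, labs, onset, window_h = 48) {
  vitals <- normalise_vitals(vitals)
  labs <- normalise_labs(labs)
  id <- vitals$admission_id[1] %||% 1L
  if (is.na(id)) id <- 1L
  onsets <- tibble::tibble(admission_id = id, onset = onset)
  wt <- worst_by_period_table(vitals, labs, onsets, window_h)
  dplyr::bind_cols(wt["period"], sofa_for_periods(wt))
}

#' Sepsis-3 classification
#'
#' Ward patients: sepsis when the maximum per-period SOFA is at least the
#' threshold (baseline assumed zero). Patients in critical care within the
#' acuity window: sepsis when the rise in SOFA (maximum over all periods
#' minus a pre-onset baseline) is at least the threshold.
#'
#' @param infected logical; documented infection with antibiotics.
#' @param max_sofa maximum per-period SOFA over the four periods.
#' @param delta_sofa SOFA rise relative to the pre-onset baseline.
#' @param critical_care_48h logical; in critical care within the window.
#' @param sofa_threshold the Sepsis-3 organ-dysfunction threshold (default 2).
#' @return factor with levels `no_infection`, `infection_no_sepsis`, `sepsis`.
#' @export
classify_sepsis <- function(infected, max_sofa, delta_sofa,
                            critical_care_48h, sofa_threshold = 2) {
  septic <- ifelse(critical_care_48h, delta_sofa >= sofa_threshold,
                   max_sofa >= sofa_threshold)
  out <- ifelse(!infected, "no_infection",
                ifelse(septic, "sepsis", "infection_no_sepsis"))
  factor(out, levels = SEPSIS_CATEGORIES)
}

# baseline for the critical-care delta rule; empty periods count 0
sofa_baseline <- function(pre_totals, mode = c("min_pre", "first_pre", "zero")) {
  mode <- match.arg(mode)
  switch(mode,
         min_pre = min(pre_totals),
         first_pre = pre_totals[1],
         zero = 0)
}

#' Mortality endpoints
#'
#' @param death_time `POSIXct` or `NA` for survivors.
#' @param onset infection onset (`NA` when no infection).
#' @param admit_time,discharge_time admission interval.
#' @return tibble of logicals: `mortality_30d_onset` (death within 720h of
#'   onset, inclusive), `mortality_30d_admission`, `in_hospital_death`.
#' @export
mortality_endpoints <- function(death_time, onset, admit_time, discharge_time) {
  if (any(!is.na(death_time) & death_time < admit_time)) {
    stop_invalid("death date before admission")
  }
  within <- function(ref) {
    !is.na(death_time) & !is.na(ref) &
      as.numeric(difftime(death_time, ref, units = "hours")) <= 720
  }
  tibble::tibble(
    mortality_30d_onset = within(onset),
    mortality_30d_admission = within(admit_time),
    in_hospital_death = !is.na(death_time) & death_time <= discharge_time
  )
}

#' Label a cohort with Sepsis-3 categories and analysis scores
#'
#' Runs the full phenotyping pipeline over a cohort: locates infection onset
#' (first blood culture or first antibiotic dose) for admissions flagged as
#' infected, extracts the highest-acuity NEWS/qSOFA/SIRS in the +/-48h
#' window, computes worst-per-24h-period SOFA, applies the ward and
#' critical-care Sepsis-3 rules, and attaches mortality endpoints.
#'
#' @param cohort an `ehr_cohort` (see [generate_cohort()]) or a list with
#'   tibbles `admissions`, `episodes`, `vitals`, `labs`, `cultures`,
#'   `antibiotics`.
#' @param window_h acuity window half-width, hours.
#' @param sofa_threshold Sepsis-3 organ-dysfunction threshold.
#' @param baseline_mode baseline for the critical-care SOFA rise:
#'   `"min_pre"` (minimum of the two pre-onset periods, default),
#'   `"first_pre"`, or `"zero"`.
#' @return tibble with one row per admission: `admission_id`, `category`,
#'   `onset`, `max_sofa`, `delta_sofa`, `critical_care_48h`, highest-acuity
#'   scores (`news`, `qsofa`, `sirs`), nearest-onset scores, and the three
#'   mortality endpoints.
#' @export
label_cohort <- function(cohort, window_h = 48, sofa_threshold = 2,
                         baseline_mode = c("min_pre", "first_pre", "zero")) {
  baseline_mode <- match.arg(baseline_mode)
  adm <- cohort$admissions

  # onset for infected admissions
  ev <- dplyr::bind_rows(
    cohort$cultures[, c("admission_id", "time")],
    cohort$antibiotics[, c("admission_id", "time")]
  )
  onsets <- ev |>
    dplyr::group_by(.data$admission_id) |>
    dplyr::summarise(onset = min(.data$time), .groups = "drop")
  onsets <- onsets[onsets$admission_id %in%
                     adm$admission_id[adm$infection], , drop = FALSE]
  n_missing <- sum(adm$infection) - nrow(onsets)
  if (n_missing > 0) {
    warning(n_missing, " infected admission(s) with no cultures or ",
            "antibiotics; treated as undated infection with zero scores",
            call. = FALSE)
  }

  # highest-acuity NEWS/qSOFA/SIRS (vectorised across admissions)
  vit <- dplyr::inner_join(normalise_vitals(cohort$vitals), onsets,
                           by = "admission_id")
  dt <- as.numeric(difftime(vit$time, vit$onset, units = "hours"))
  vit <- vit[dt >= -window_h & dt < window_h, , drop = FALSE]
  sc <- score_observations(vit, normalise_labs(cohort$labs))
  acuity <- sc |>
    dplyr::group_by(.data$admission_id) |>
    dplyr::arrange(dplyr::desc(.data$news), .data$time, .by_group = TRUE) |>
    dplyr::summarise(news = .data$news[1], qsofa = .data$qsofa[1],
                     sirs = .data$sirs[1], n_obs_window = dplyr::n(),
                     .groups = "drop")
  nearest <- sc |>
    dplyr::mutate(adist = abs(as.numeric(
      difftime(.data$time, .data$onset, units = "secs")))) |>
    dplyr::group_by(.data$admission_id) |>
    dplyr::arrange(.data$adist, .data$time, .by_group = TRUE) |>
    dplyr::summarise(news_nearest = .data$news[1],
                     qsofa_nearest = .data$qsofa[1],
                     sirs_nearest = .data$sirs[1], .groups = "drop")

  # per-period SOFA and the ward / critical-care decision quantities
  wt <- worst_by_period_table(normalise_vitals(cohort$vitals),
                              normalise_labs(cohort$labs), onsets, window_h)
  wt$total <- sofa_for_periods(wt)$total
  sofa_summ <- wt |>
    dplyr::group_by(.data$admission_id) |>
    dplyr::summarise(
      max_sofa = max(.data$total),
      baseline = sofa_baseline(.data$total[.data$period < 0][
        order(.data$period[.data$period < 0])], baseline_mode),
      .groups = "drop"
    ) |>
    dplyr::mutate(delta_sofa = .data$max_sofa - .data$baseline)

  # critical care within the window
  cc <- dplyr::inner_join(
    cohort$episodes[cohort$episodes$unit_type == "critical_care", ,
                    drop = FALSE],
    onsets, by = "admission_id"
  )
  cc_ids <- unique(cc$admission_id[
    cc$start < cc$onset + hours(window_h) & cc$end >= cc$onset - hours(window_h)
  ])

  out <- adm[, c("admission_id", "admit_time", "discharge_time",
                 "death_time", "infection")] |>
    dplyr::left_join(onsets, by = "admission_id") |>
    dplyr::left_join(acuity, by = "admission_id") |>
    dplyr::left_join(nearest, by = "admission_id") |>
    dplyr::left_join(sofa_summ, by = "admission_id")

  zero_cols <- c("news", "qsofa", "sirs", "news_nearest", "qsofa_nearest",
                 "sirs_nearest", "max_sofa", "delta_sofa")
  infected_no_obs <- out$infection &
    (is.na(out$n_obs_window) | out$n_obs_window == 0)
  if (any(infected_no_obs & !is.na(out$onset))) {
    warning(sum(infected_no_obs & !is.na(out$onset)),
            " infected admission(s) with no vitals in the acuity window; ",
            "scores set to 0", call. = FALSE)
  }
  for (cl in zero_cols) out[[cl]][is.na(out[[cl]])] <- 0L
  out$n_obs_window[is.na(out$n_obs_window)] <- 0L
  out$critical_care_48h <- out$admission_id %in% cc_ids & out$infection

  out$category <- classify_sepsis(out$infection, out$max_sofa,
                                  out$delta_sofa, out$critical_care_48h,
                                  sofa_threshold)
  ends <- mortality_endpoints(out$death_time, out$onset, out$admit_time,
                              out$discharge_time)
  out <- dplyr::bind_cols(out, ends)
  out$baseline <- NULL
  out
}
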