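# shared fixture builders: tiny hand-constructed admissions for the
# labelling module, built in code at test time

ts <- function(x) as.POSIXct(x, tz = "UTC")

# one admission with vitals/labs placed relative to an onset timestamp;
# offsets in hours
mini_admission <- function(onset = ts("2015-11-02 10:00:00"),
                           vitals_offsets_h = numeric(),
                           vitals = list(),
                           labs_offsets_h = numeric(),
                           labs_analyte = character(),
                           labs_value = numeric(),
                           admit_offset_h = -30, los_h = 200,
                           critical_care = FALSE,
                           death_offset_h = NA) {
  admit <- onset + hours(admit_offset_h)
  v <- tibble::tibble(
    admission_id = 1L,
    time = onset + hours(vitals_offsets_h),
    resp_rate = vitals$resp_rate %||% rep(NA_real_, length(vitals_offsets_h)),
    spo2 = vitals$spo2 %||% rep(NA_real_, length(vitals_offsets_h)),
    on_oxygen = vitals$on_oxygen %||% rep(NA, length(vitals_offsets_h)),
    temp = vitals$temp %||% rep(NA_real_, length(vitals_offsets_h)),
    sbp = vitals$sbp %||% rep(NA_real_, length(vitals_offsets_h)),
    dbp = vitals$dbp %||% rep(NA_real_, length(vitals_offsets_h)),
    heart_rate = vitals$heart_rate %||% rep(NA_real_, length(vitals_offsets_h)),
    avpu = vitals$avpu %||% rep(NA_character_, length(vitals_offsets_h)),
    gcs = vitals$gcs %||% rep(NA_real_, length(vitals_offsets_h))
  )
  l <- tibble::tibble(
    admission_id = 1L,
    time = onset + hours(labs_offsets_h),
    analyte = labs_analyte,
    value = labs_value
  )
  ep <- tibble::tibble(
    admission_id = 1L,
    ward = if (critical_care) "CCU" else "W01",
    unit_type = if (critical_care) "critical_care" else "ward",
    start = admit, end = admit + hours(los_h)
  )
  list(
    admissions = tibble::tibble(
      admission_id = 1L, patient_id = 1L, admit_time = admit,
      discharge_time = admit + hours(los_h),
      death_time = if (is.na(death_offset_h)) ts(NA) else {
        onset + hours(death_offset_h)
      },
      maternity = FALSE, infection = TRUE,
      true_category = factor("sepsis",
                             levels = c("no_infection", "infection_no_sepsis",
                                        "sepsis")),
      true_onset = onset
    ),
    episodes = ep,
    vitals = v,
    labs = l,
    cultures = tibble::tibble(admission_id = integer(),
                              time = ts(character()), result = character()),
    antibiotics = tibble::tibble(admission_id = 1L, time = onset,
                                 route = "IV"),
    codes = tibble::tibble(admission_id = integer(), code = character())
  )
}

hours <- function(h) h * 3600
`%||%` <- function(a, b) if (is.null(a)) b else a

# stratified bootstrap variance of the empirical AUROC
bootstrap_auc_var <- function(scores, labels, n_boot = 1e4) {
  cases <- scores[labels]
  ctrls <- scores[!labels]
  aucs <- replicate(n_boot, {
    empirical_auroc(c(sample(cases, replace = TRUE),
                      sample(ctrls, replace = TRUE)),
                    c(rep(TRUE, length(cases)), rep(FALSE, length(ctrls))))
  })
  stats::var(aucs)
}
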