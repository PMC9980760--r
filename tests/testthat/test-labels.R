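# Infection onset, acuity windows, worst-per-period SOFA, and the Sepsis-3
# classification rules.

test_that("infection onset is the earliest of culture and antibiotic", {
  c1 <- ts("2015-11-02 10:00:00")
  a1 <- ts("2015-11-02 12:00:00")
  expect_equal(infection_onset(c1, a1), c1)
  expect_equal(infection_onset(as.POSIXct(character()), a1), a1)
  expect_error(infection_onset(as.POSIXct(character()),
                               as.POSIXct(character())),
               class = "sepsisperf_invalid_input")
})

test_that("highest-acuity scores take the maximal NEWS in the window", {
  onset <- ts("2015-11-02 10:00:00")
  # two observations: NEWS 4 (rr 22, sbp 95) then NEWS 7 (rr 25, spo2 93,
  # hr 115) — the later, higher one is used
  adm <- mini_admission(
    onset = onset,
    vitals_offsets_h = c(-2, 6),
    vitals = list(resp_rate = c(22, 25), sbp = c(95, 120),
                  spo2 = c(97, 93), heart_rate = c(75, 115))
  )
  hs <- highest_acuity_scores(adm$vitals, adm$labs, onset)
  expect_equal(hs$news, 7L)
  expect_equal(hs$news_nearest, 4L)  # the -2h observation is nearer onset
  expect_equal(hs$acuity_time, onset + hours(6))

  # single observation: its scores verbatim
  adm1 <- mini_admission(onset = onset, vitals_offsets_h = 1,
                         vitals = list(resp_rate = 22, sbp = 95))
  hs1 <- highest_acuity_scores(adm1$vitals, adm1$labs, onset)
  expect_equal(hs1$news, 4L)
  expect_equal(hs1$qsofa, 2L)

  # NEWS ties broken by the earlier timestamp
  admt <- mini_admission(onset = onset, vitals_offsets_h = c(3, 12),
                         vitals = list(resp_rate = c(25, 25)))
  hst <- highest_acuity_scores(admt$vitals, admt$labs, onset)
  expect_equal(hst$acuity_time, onset + hours(3))
})

test_that("observations outside the 48h window never influence the scores", {
  onset <- ts("2015-11-02 10:00:00")
  adm <- mini_admission(
    onset = onset,
    vitals_offsets_h = c(-49, 48, 10),
    vitals = list(resp_rate = c(35, 35, 18))
  )
  hs <- highest_acuity_scores(adm$vitals, adm$labs, onset)
  expect_equal(hs$news, 0L)  # only the in-window normal observation counts
  expect_equal(hs$n_obs_window, 1L)
  # the -48h edge is inclusive, the +48h edge exclusive
  adm_edge <- mini_admission(onset = onset, vitals_offsets_h = -48,
                             vitals = list(resp_rate = 25))
  expect_equal(highest_acuity_scores(adm_edge$vitals, adm_edge$labs,
                                     onset)$news, 3L)
  # empty window: zero scores with a warning
  adm0 <- mini_admission(onset = onset, vitals_offsets_h = -60,
                         vitals = list(resp_rate = 30))
  expect_warning(hs0 <- highest_acuity_scores(adm0$vitals, adm0$labs, onset),
                 "no vitals")
  expect_equal(hs0$news, 0L)
})

test_that("worst-per-period SOFA picks directional extremes per 24h period", {
  onset <- ts("2015-11-02 10:00:00")
  # platelets 140 in period -1, 90 in period 0 -> coagulation 1 then 2
  adm <- mini_admission(
    onset = onset,
    labs_offsets_h = c(-10, 5, 8),
    labs_analyte = c("platelets", "platelets", "platelets"),
    labs_value = c(140, 90, 200)
  )
  w <- worst_sofa_by_period(adm$vitals, adm$labs, onset)
  expect_equal(w$period, -2:1)
  expect_equal(w$coagulation, c(0L, 1L, 2L, 0L))
  expect_equal(max(w$total), 2L)
  # empty periods score 0
  expect_equal(w$total[w$period == -2], 0L)
  expect_equal(w$total[w$period == 1], 0L)

  # identical data in all periods -> identical scores
  adm2 <- mini_admission(
    onset = onset,
    labs_offsets_h = c(-36, -12, 12, 36),
    labs_analyte = rep("creatinine", 4),
    labs_value = rep(200, 4)
  )
  w2 <- worst_sofa_by_period(adm2$vitals, adm2$labs, onset)
  expect_equal(w2$total, rep(2L, 4))

  # directional extremes: lowest SpO2, highest bilirubin within a period
  adm3 <- mini_admission(
    onset = onset,
    vitals_offsets_h = c(1, 2),
    vitals = list(spo2 = c(96, 92)),
    labs_offsets_h = c(1, 2),
    labs_analyte = c("bilirubin", "bilirubin"),
    labs_value = c(10, 40)
  )
  w3 <- worst_sofa_by_period(adm3$vitals, adm3$labs, onset)
  p0 <- w3[w3$period == 0, ]
  expect_equal(p0$respiration, 1L)
  expect_equal(p0$liver, 2L)
})

test_that("a blood gas in the period takes precedence over SpO2", {
  onset <- ts("2015-11-02 10:00:00")
  adm <- mini_admission(
    onset = onset,
    vitals_offsets_h = 1, vitals = list(spo2 = 88),
    labs_offsets_h = c(2, 2),
    labs_analyte = c("pao2", "fio2"),
    labs_value = c(12, 0.21)
  )
  w <- worst_sofa_by_period(adm$vitals, adm$labs, onset)
  expect_equal(w$respiration[w$period == 0], 0L)  # normal gas wins over SpO2
})

test_that("ward and critical-care Sepsis-3 rules classify correctly", {
  lv <- c("no_infection", "infection_no_sepsis", "sepsis")
  expect_equal(as.character(classify_sepsis(TRUE, 2, 2, FALSE)), "sepsis")
  expect_equal(as.character(classify_sepsis(TRUE, 1, 1, FALSE)),
               "infection_no_sepsis")
  expect_equal(as.character(classify_sepsis(FALSE, 5, 5, FALSE)),
               "no_infection")
  # critical care: the rise matters, not the absolute score
  expect_equal(as.character(classify_sepsis(TRUE, 4, 1, TRUE)),
               "infection_no_sepsis")
  expect_equal(as.character(classify_sepsis(TRUE, 4, 2, TRUE)), "sepsis")
  expect_equal(levels(classify_sepsis(TRUE, 2, 2, FALSE)), lv)
})

test_that("critical-care delta uses the configured pre-onset baseline", {
  onset <- ts("2015-11-02 10:00:00")
  # period -2: SOFA 3 (creatinine 320); period -1: SOFA 2 (creatinine 200);
  # period 0: SOFA 4 (creatinine 450) -> min_pre baseline 2, delta 2
  adm <- mini_admission(
    onset = onset, critical_care = TRUE,
    vitals_offsets_h = 0,  # one all-missing observation anchors the window
    labs_offsets_h = c(-36, -12, 6),
    labs_analyte = rep("creatinine", 3),
    labs_value = c(320, 200, 450)
  )
  coh <- adm
  lab_min <- label_cohort(coh, baseline_mode = "min_pre")
  expect_equal(lab_min$max_sofa, 4L)
  expect_equal(lab_min$delta_sofa, 2L)
  expect_true(lab_min$critical_care_48h)
  expect_equal(as.character(lab_min$category), "sepsis")
  # first_pre baseline = 3 -> delta 1 -> no sepsis
  lab_first <- label_cohort(coh, baseline_mode = "first_pre")
  expect_equal(lab_first$delta_sofa, 1L)
  expect_equal(as.character(lab_first$category), "infection_no_sepsis")
  # zero baseline -> delta = max
  lab_zero <- label_cohort(coh, baseline_mode = "zero")
  expect_equal(lab_zero$delta_sofa, 4L)
})

test_that("delta rule matches brute-force enumeration of period scores", {
  onset <- ts("2015-11-02 10:00:00")
  set.seed(33)
  for (i in 1:20) {
    creat <- sample(c(80, 120, 200, 320, 460), 4, replace = TRUE)
    adm <- mini_admission(
      onset = onset, critical_care = TRUE,
      vitals_offsets_h = 0,
      labs_offsets_h = c(-36, -12, 6, 30),
      labs_analyte = rep("creatinine", 4),
      labs_value = creat
    )
    lab <- label_cohort(adm, baseline_mode = "min_pre")
    per_score <- sofa_score(creatinine = creat)$total
    delta <- max(per_score) - min(per_score[1:2])
    expect_equal(lab$delta_sofa, delta)
    expect_equal(as.character(lab$category),
                 if (delta >= 2) "sepsis" else "infection_no_sepsis")
  }
})

test_that("mortality endpoints use inclusive 30-day windows", {
  onset <- ts("2015-11-02 10:00:00")
  admit <- onset - hours(30)
  dis <- admit + hours(100)
  m29 <- mortality_endpoints(onset + hours(29 * 24), onset, admit, dis)
  expect_true(m29$mortality_30d_onset)
  expect_false(m29$in_hospital_death)
  m31 <- mortality_endpoints(onset + hours(31 * 24), onset, admit, dis)
  expect_false(m31$mortality_30d_onset)
  # exactly onset + 720h counts
  m720 <- mortality_endpoints(onset + hours(720), onset, admit, dis)
  expect_true(m720$mortality_30d_onset)
  mna <- mortality_endpoints(as.POSIXct(NA), onset, admit, dis)
  expect_false(any(unlist(mna)))
  expect_error(mortality_endpoints(admit - hours(1), onset, admit, dis),
               class = "sepsisperf_invalid_input")
})

test_that("labels partition the cohort and are time-translation invariant", {
  coh <- generate_cohort(cohort_params(n_admissions = 150, seed = 12,
                                       maternity_rate = 0, short_stay_rate = 0))
  lab <- label_cohort(coh)
  expect_equal(nrow(lab), 150)
  expect_equal(sum(table(lab$category)), 150)
  expect_false(anyNA(lab$category))

  shift <- hours(24 * 365)
  coh2 <- coh
  coh2$admissions$admit_time <- coh2$admissions$admit_time + shift
  coh2$admissions$discharge_time <- coh2$admissions$discharge_time + shift
  coh2$admissions$death_time <- coh2$admissions$death_time + shift
  coh2$admissions$true_onset <- coh2$admissions$true_onset + shift
  for (nm in c("vitals", "labs", "cultures", "antibiotics")) {
    coh2[[nm]]$time <- coh2[[nm]]$time + shift
  }
  coh2$episodes$start <- coh2$episodes$start + shift
  coh2$episodes$end <- coh2$episodes$end + shift
  lab2 <- label_cohort(coh2)
  expect_equal(as.character(lab2$category), as.character(lab$category))
  expect_equal(lab2$max_sofa, lab$max_sofa)
  expect_equal(lab2$news, lab$news)
  expect_equal(lab2$mortality_30d_onset, lab$mortality_30d_onset)
})

test_that("classification error vanishes as generator noise shrinks", {
  coh <- generate_cohort(cohort_params(n_admissions = 400, seed = 99,
                                       maternity_rate = 0,
                                       short_stay_rate = 0))
  lab <- label_cohort(coh)
  truth <- as.character(coh$admissions$true_category)
  err <- mean(as.character(lab$category) != truth)
  expect_lt(err, 0.05)
})
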