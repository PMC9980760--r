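# Severity-score engines: published band tables, boundary exactness,
# substitution rules, and the structural invariants.

test_that("NEWS reproduces the published band table, including boundaries", {
  expect_equal(news_score(resp_rate = 18, spo2 = 97, on_oxygen = FALSE,
                          temp = 36.8, sbp = 120, heart_rate = 75,
                          avpu = "A"), 0L)
  # every parameter in its maximal band: the maximum attainable NEWS
  expect_equal(news_score(resp_rate = 25, spo2 = 90, on_oxygen = TRUE,
                          temp = 35.0, sbp = 88, heart_rate = 135,
                          avpu = "P"), 20L)
  expect_equal(news_score(resp_rate = 22, sbp = 95), 4L)

  # band boundaries at value, value - eps, value + eps
  e <- 0.01
  bands <- list(
    list(arg = "resp_rate", cuts = c(8, 11, 20, 24),
         pts = c(3, 1, 0, 2, 3)),
    list(arg = "spo2", cuts = c(91, 93, 95), pts = c(3, 2, 1, 0)),
    list(arg = "temp", cuts = c(35, 36, 38, 39), pts = c(3, 1, 0, 1, 2)),
    list(arg = "sbp", cuts = c(90, 100, 110, 219), pts = c(3, 2, 1, 0, 3)),
    list(arg = "heart_rate", cuts = c(40, 50, 90, 110, 130),
         pts = c(3, 1, 0, 1, 2, 3))
  )
  for (b in bands) {
    for (i in seq_along(b$cuts)) {
      cut <- b$cuts[i]
      at <- do.call(news_score, stats::setNames(list(cut), b$arg))
      below <- do.call(news_score, stats::setNames(list(cut - e), b$arg))
      above <- do.call(news_score, stats::setNames(list(cut + e), b$arg))
      expect_equal(at, b$pts[i], info = paste(b$arg, "at", cut))
      expect_equal(below, b$pts[i], info = paste(b$arg, "just below", cut))
      expect_equal(above, b$pts[i + 1], info = paste(b$arg, "just above", cut))
    }
  }
  expect_equal(news_score(avpu = "A"), 0L)
  expect_equal(news_score(avpu = "V"), 3L)
  expect_equal(news_score(on_oxygen = TRUE), 2L)
})

test_that("SIRS criteria use strict inequalities at the quoted thresholds", {
  expect_equal(sirs_score(wcc = 13, heart_rate = 95, resp_rate = 22,
                          temp = 38.5), 4L)
  expect_equal(sirs_score(wcc = 8, heart_rate = 80, resp_rate = 16,
                          temp = 37.0), 0L)
  expect_equal(sirs_score(temp = 35.8), 1L)
  # thresholds themselves do not score (strict < / >)
  expect_equal(sirs_score(wcc = 4), 0L)
  expect_equal(sirs_score(wcc = 12), 0L)
  expect_equal(sirs_score(wcc = 3.9), 1L)
  expect_equal(sirs_score(wcc = 12.1), 1L)
  expect_equal(sirs_score(heart_rate = 90), 0L)
  expect_equal(sirs_score(heart_rate = 90.5), 1L)
  expect_equal(sirs_score(resp_rate = 20), 0L)
  expect_equal(sirs_score(resp_rate = 20.5), 1L)
  expect_equal(sirs_score(temp = 36), 0L)
  expect_equal(sirs_score(temp = 38), 0L)
  expect_equal(sirs_score(temp = 38.1), 1L)
})

test_that("qSOFA boundaries are inclusive and AVPU substitutes for GCS", {
  expect_equal(qsofa_score(resp_rate = 22, sbp = 100, avpu = "A"), 2L)
  expect_equal(qsofa_score(resp_rate = 21.9, sbp = 100.1, avpu = "A"), 0L)
  expect_equal(qsofa_score(), 0L)
  expect_equal(qsofa_score(resp_rate = 30, sbp = 80, avpu = "V"), 3L)
  # GCS takes precedence over AVPU when both present
  expect_equal(qsofa_score(gcs = 14, avpu = "U"), 0L)
  expect_equal(qsofa_score(gcs = 13), 1L)
  expect_equal(qsofa_score(avpu = "V"), 1L)
})

test_that("SOFA respiratory component applies the SpO2 substitution bands", {
  expect_equal(sofa_respiration_points(spo2 = 93), 1L)
  expect_equal(sofa_respiration_points(spo2 = 90), 2L)
  expect_equal(sofa_respiration_points(spo2 = 96), 0L)
  expect_equal(sofa_respiration_points(spo2 = 91), 1L)
  expect_equal(sofa_respiration_points(spo2 = 94), 1L)
  expect_equal(sofa_respiration_points(spo2 = 95), 0L)
  expect_equal(sofa_respiration_points(spo2 = 90.9), 2L)
})

test_that("blood gas takes precedence and scores by PaO2/FiO2 in mmHg", {
  # PaO2 12 kPa on air: ratio 12 * 7.50062 / 0.21 = 428 mmHg -> 0 points
  expect_equal(sofa_respiration_points(pao2 = 12, fio2 = 0.21), 0L)
  # 10 kPa / 0.21 -> 357 mmHg -> 1
  expect_equal(sofa_respiration_points(pao2 = 10, fio2 = 0.21), 1L)
  # 10 kPa / 0.30 -> 250 mmHg -> 2 (no support needed)
  expect_equal(sofa_respiration_points(pao2 = 10, fio2 = 0.30), 2L)
  # 10 kPa / 0.60 -> 125 mmHg -> 3 only with support
  expect_equal(sofa_respiration_points(pao2 = 10, fio2 = 0.60,
                                       on_oxygen = TRUE), 3L)
  expect_equal(sofa_respiration_points(pao2 = 10, fio2 = 0.60,
                                       on_oxygen = FALSE), 2L)
  # 6 kPa / 0.60 -> 75 mmHg -> 4 with support
  expect_equal(sofa_respiration_points(pao2 = 6, fio2 = 0.60,
                                       on_oxygen = TRUE), 4L)
  # gas beats the SpO2 substitution when both are present
  expect_equal(sofa_respiration_points(pao2 = 12, fio2 = 0.21, spo2 = 88), 0L)
  expect_error(sofa_respiration_points(fio2 = 0.1),
               class = "sepsisperf_invalid_input")
})

test_that("CNS component bands GCS, mapping AVPU to a surrogate when absent", {
  expect_equal(sofa_cns_points(gcs = 15), 0L)
  expect_equal(sofa_cns_points(gcs = 14), 1L)
  expect_equal(sofa_cns_points(gcs = 13), 1L)
  expect_equal(sofa_cns_points(gcs = 12), 2L)
  expect_equal(sofa_cns_points(gcs = 10), 2L)
  expect_equal(sofa_cns_points(gcs = 9), 3L)
  expect_equal(sofa_cns_points(gcs = 6), 3L)
  expect_equal(sofa_cns_points(gcs = 5), 4L)
  # surrogate GCS: A = 15, V = 13, P = 8, U = 3
  expect_equal(sofa_cns_points(avpu = "A"), 0L)
  expect_equal(sofa_cns_points(avpu = "V"), 1L)
  expect_equal(sofa_cns_points(avpu = "P"), 3L)
  expect_equal(sofa_cns_points(avpu = "U"), 4L)
  # recorded GCS wins over AVPU
  expect_equal(sofa_cns_points(gcs = 14, avpu = "U"), 1L)
  expect_equal(sofa_cns_points(), 0L)
})

test_that("SOFA components band correctly and sum to the total", {
  s <- sofa_score(platelets = 90, bilirubin = 40, map = 65, avpu = "A",
                  creatinine = 100, spo2 = 96)
  expect_equal(s$coagulation, 2L)
  expect_equal(s$liver, 2L)
  expect_equal(s$cardiovascular, 1L)
  expect_equal(s$cns, 0L)
  expect_equal(s$renal, 0L)
  expect_equal(s$respiration, 0L)
  expect_equal(s$total, 5L)

  expect_equal(sofa_score()$total, 0L)
  expect_equal(sofa_score(spo2 = 90)$total, 2L)

  # band boundaries per component
  expect_equal(sofa_score(platelets = 150)$coagulation, 0L)
  expect_equal(sofa_score(platelets = 149.9)$coagulation, 1L)
  expect_equal(sofa_score(platelets = 99)$coagulation, 2L)
  expect_equal(sofa_score(platelets = 49)$coagulation, 3L)
  expect_equal(sofa_score(platelets = 19)$coagulation, 4L)
  expect_equal(sofa_score(bilirubin = 19.9)$liver, 0L)
  expect_equal(sofa_score(bilirubin = 20)$liver, 1L)
  expect_equal(sofa_score(bilirubin = 33)$liver, 2L)
  expect_equal(sofa_score(bilirubin = 102)$liver, 3L)
  expect_equal(sofa_score(bilirubin = 204.5)$liver, 4L)
  expect_equal(sofa_score(creatinine = 109)$renal, 0L)
  expect_equal(sofa_score(creatinine = 110)$renal, 1L)
  expect_equal(sofa_score(creatinine = 171)$renal, 2L)
  expect_equal(sofa_score(creatinine = 300)$renal, 3L)
  expect_equal(sofa_score(creatinine = 441)$renal, 4L)
  expect_equal(sofa_score(map = 70)$cardiovascular, 0L)
  expect_equal(sofa_score(map = 69.9)$cardiovascular, 1L)
})

test_that("MAP derives from SBP/DBP; DBP absent scores cardiovascular 0", {
  expect_equal(mean_arterial_pressure(120, 60), 80)
  expect_equal(sofa_score(sbp = 90, dbp = 50)$cardiovascular, 1L)  # MAP 63.3
  expect_equal(sofa_score(sbp = 80)$cardiovascular, 0L)
})

test_that("vasopressor and urine-output inputs extend the bands when given", {
  expect_equal(sofa_score(map = 80, vasopressor = "low")$cardiovascular, 2L)
  expect_equal(sofa_score(map = 60, vasopressor = "high")$cardiovascular, 4L)
  expect_equal(sofa_score(urine_output = 450)$renal, 3L)
  expect_equal(sofa_score(urine_output = 150)$renal, 4L)
  expect_equal(sofa_score(creatinine = 120, urine_output = 150)$renal, 4L)
})

test_that("out-of-range physiological values are rejected", {
  expect_error(news_score(spo2 = 101), class = "sepsisperf_invalid_input")
  expect_error(news_score(resp_rate = -2), class = "sepsisperf_invalid_input")
  expect_error(qsofa_score(gcs = 16), class = "sepsisperf_invalid_input")
  expect_error(news_score(avpu = "X"), class = "sepsisperf_invalid_input")
  expect_error(sofa_score(vasopressor = "huge"),
               class = "sepsisperf_invalid_input")
})

test_that("all-missing input scores 0 on all four instruments", {
  expect_equal(news_score(), 0L)
  expect_equal(sirs_score(), 0L)
  expect_equal(qsofa_score(), 0L)
  expect_equal(sofa_score()$total, 0L)
})

random_vitals <- function(n) {
  tibble::tibble(
    resp_rate = sample(c(NA, 4:45), n, replace = TRUE),
    spo2 = sample(c(NA, 75:100), n, replace = TRUE),
    on_oxygen = sample(c(NA, TRUE, FALSE), n, replace = TRUE),
    temp = sample(c(NA, seq(33, 41, 0.1)), n, replace = TRUE),
    sbp = sample(c(NA, 60:240), n, replace = TRUE),
    dbp = sample(c(NA, 30:120), n, replace = TRUE),
    heart_rate = sample(c(NA, 30:180), n, replace = TRUE),
    avpu = sample(c(NA, "A", "V", "P", "U"), n, replace = TRUE),
    gcs = sample(c(NA, 3:15), n, replace = TRUE),
    wcc = sample(c(NA, seq(1, 30, 0.5)), n, replace = TRUE),
    platelets = sample(c(NA, 5:400), n, replace = TRUE),
    bilirubin = sample(c(NA, 2:300), n, replace = TRUE),
    creatinine = sample(c(NA, 40:600), n, replace = TRUE)
  )
}

test_that("scores stay in range over randomised inputs", {
  set.seed(421)
  v <- random_vitals(2000)
  news <- news_score(v$resp_rate, v$spo2, v$on_oxygen, v$temp, v$sbp,
                     v$heart_rate, v$avpu)
  expect_true(all(news >= 0 & news <= 20))
  sirs <- sirs_score(v$temp, v$heart_rate, v$resp_rate, v$wcc)
  expect_true(all(sirs >= 0 & sirs <= 4))
  qs <- qsofa_score(v$resp_rate, v$sbp, v$gcs, v$avpu)
  expect_true(all(qs >= 0 & qs <= 3))
  s <- sofa_score(spo2 = v$spo2, on_oxygen = v$on_oxygen,
                  platelets = v$platelets, bilirubin = v$bilirubin,
                  sbp = v$sbp, dbp = v$dbp, gcs = v$gcs, avpu = v$avpu,
                  creatinine = v$creatinine)
  expect_true(all(s$total >= 0 & s$total <= 24))
  comp <- as.matrix(s[, 1:6])
  expect_true(all(comp >= 0 & comp <= 4))
  expect_equal(s$total, as.integer(rowSums(comp)))
})

test_that("worsening any single parameter never decreases a score", {
  set.seed(77)
  v <- random_vitals(300)
  # NEWS: push each parameter one step toward its worst value
  base <- news_score(v$resp_rate, v$spo2, v$on_oxygen, v$temp, v$sbp,
                     v$heart_rate, v$avpu)
  worse_news <- list(
    news_score(pmax(v$resp_rate, 40), v$spo2, v$on_oxygen, v$temp, v$sbp,
               v$heart_rate, v$avpu),
    news_score(v$resp_rate, pmin(v$spo2, 85), v$on_oxygen, v$temp, v$sbp,
               v$heart_rate, v$avpu),
    news_score(v$resp_rate, v$spo2, TRUE, v$temp, v$sbp, v$heart_rate,
               v$avpu),
    news_score(v$resp_rate, v$spo2, v$on_oxygen, v$temp, pmin(v$sbp, 85),
               v$heart_rate, v$avpu),
    news_score(v$resp_rate, v$spo2, v$on_oxygen, v$temp, v$sbp,
               pmax(v$heart_rate, 135), v$avpu),
    news_score(v$resp_rate, v$spo2, v$on_oxygen, v$temp, v$sbp,
               v$heart_rate, "U")
  )
  for (w in worse_news) expect_true(all(w >= base))

  qs_base <- qsofa_score(v$resp_rate, v$sbp, v$gcs, v$avpu)
  expect_true(all(qsofa_score(pmax(v$resp_rate, 25), v$sbp, v$gcs,
                              v$avpu) >= qs_base))
  expect_true(all(qsofa_score(v$resp_rate, pmin(v$sbp, 95), v$gcs,
                              v$avpu) >= qs_base))
  expect_true(all(qsofa_score(v$resp_rate, v$sbp, pmin(v$gcs, 10),
                              v$avpu) >= qs_base))

  sofa_base <- sofa_score(spo2 = v$spo2, platelets = v$platelets,
                          bilirubin = v$bilirubin, creatinine = v$creatinine)$total
  expect_true(all(sofa_score(spo2 = pmin(v$spo2, 90),
                             platelets = v$platelets,
                             bilirubin = v$bilirubin,
                             creatinine = v$creatinine)$total >= sofa_base))
  expect_true(all(sofa_score(spo2 = v$spo2, platelets = pmin(v$platelets, 15),
                             bilirubin = v$bilirubin,
                             creatinine = v$creatinine)$total >= sofa_base))
})
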