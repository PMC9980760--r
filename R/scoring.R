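# Severity scoring: NEWS (RCP 2012), SIRS, qSOFA, SOFA.
#
# All scorers are vectorised over their physiological arguments and follow the
# missing-as-normal convention: an absent (NA) parameter contributes 0 points,
# so an observation with every field missing scores 0 on all four instruments.

#' National Early Warning Score (NEWS, RCP 2012)
#'
#' Aggregate early-warning score over seven physiological parameters:
#' respiratory rate, oxygen saturation, supplemental oxygen, temperature,
#' systolic blood pressure, heart rate and level of consciousness (AVPU).
#' Each parameter scores 0-3 (supplemental oxygen 0 or 2); the total ranges
#' 0-20. Missing parameters score 0 (missing-as-normal).
#'
#' @param resp_rate respiratory rate, breaths/min.
#' @param spo2 peripheral oxygen saturation, percent (0-100).
#' @param on_oxygen logical; receiving supplemental oxygen.
#' @param temp temperature, degrees Celsius.
#' @param sbp systolic blood pressure, mmHg.
#' @param heart_rate heart rate, beats/min.
#' @param avpu consciousness level, one of `"A"`, `"V"`, `"P"`, `"U"`.
#' @param breakdown if `TRUE`, return a tibble with per-parameter points and
#'   the total; otherwise an integer vector of totals.
#' @return integer vector of NEWS totals (0-20), or a tibble when
#'   `breakdown = TRUE`.
#' @export
#' @examples
#' news_score(resp_rate = 22, sbp = 95)                     # 4
#' news_score(resp_rate = 25, spo2 = 90, on_oxygen = TRUE,
#'            temp = 35, sbp = 88, heart_rate = 135, avpu = "P") # 20
news_score <- function(resp_rate = NULL, spo2 = NULL, on_oxygen = NULL,
                       temp = NULL, sbp = NULL, heart_rate = NULL,
                       avpu = NULL, breakdown = FALSE) {
  n <- common_length(resp_rate, spo2, on_oxygen, temp, sbp, heart_rate, avpu)
  resp_rate  <- rep_arg(resp_rate, n)
  spo2       <- rep_arg(spo2, n)
  on_oxygen  <- rep_arg(on_oxygen, n)
  temp       <- rep_arg(temp, n)
  sbp        <- rep_arg(sbp, n)
  heart_rate <- rep_arg(heart_rate, n)
  avpu       <- check_avpu(rep_arg(avpu, n))

  check_range(resp_rate, "respiratory rate", 0, 150)
  check_range(spo2, "SpO2", 0, 100)
  check_range(temp, "temperature", 20, 45)
  check_range(sbp, "systolic BP", 0, 350)
  check_range(heart_rate, "heart rate", 0, 350)

  pts_rr <- band0(resp_rate,
                  resp_rate <= 8 ~ 3L, resp_rate <= 11 ~ 1L, resp_rate <= 20 ~ 0L,
                  resp_rate <= 24 ~ 2L, TRUE ~ 3L)
  pts_spo2 <- band0(spo2,
                    spo2 <= 91 ~ 3L, spo2 <= 93 ~ 2L, spo2 <= 95 ~ 1L, TRUE ~ 0L)
  pts_o2 <- ifelse(!is.na(on_oxygen) & on_oxygen, 2L, 0L)
  pts_temp <- band0(temp,
                    temp <= 35 ~ 3L, temp <= 36 ~ 1L, temp <= 38 ~ 0L,
                    temp <= 39 ~ 1L, TRUE ~ 2L)
  pts_sbp <- band0(sbp,
                   sbp <= 90 ~ 3L, sbp <= 100 ~ 2L, sbp <= 110 ~ 1L,
                   sbp <= 219 ~ 0L, TRUE ~ 3L)
  pts_hr <- band0(heart_rate,
                  heart_rate <= 40 ~ 3L, heart_rate <= 50 ~ 1L,
                  heart_rate <= 90 ~ 0L, heart_rate <= 110 ~ 1L,
                  heart_rate <= 130 ~ 2L, TRUE ~ 3L)
  pts_avpu <- ifelse(!is.na(avpu) & avpu != "A", 3L, 0L)

  total <- pts_rr + pts_spo2 + pts_o2 + pts_temp + pts_sbp + pts_hr + pts_avpu
  if (!breakdown) return(as.integer(total))
  tibble::tibble(
    resp_rate = pts_rr, spo2 = pts_spo2, supplemental_o2 = pts_o2,
    temp = pts_temp, sbp = pts_sbp, heart_rate = pts_hr, avpu = pts_avpu,
    total = as.integer(total)
  )
}

# vectorised banding: first TRUE formula wins, NA input scores 0
band0 <- function(x, ...) {
  rules <- list(...)
  out <- rep(0L, length(x))
  done <- is.na(x)
  for (r in rules) {
    cond <- eval(r[[2]], envir = environment(r))
    pts <- eval(r[[3]], envir = environment(r))
    if (isTRUE(cond)) cond <- rep(TRUE, length(x))
    hit <- !done & !is.na(cond) & cond
    out[hit] <- pts
    done <- done | hit
  }
  out
}

#' Systemic Inflammatory Response Syndrome (SIRS) criteria
#'
#' One point for each of: white cell count < 4 or > 12 (x10^9/L), heart rate
#' > 90 beats/min, respiratory rate > 20 breaths/min, temperature < 36 or
#' > 38 degrees C. Inequalities are strict. Missing parameters score 0.
#'
#' @inheritParams news_score
#' @param wcc white cell count, x10^9/L.
#' @return integer vector, 0-4.
#' @export
#' @examples
#' sirs_score(wcc = 13, heart_rate = 95, resp_rate = 22, temp = 38.5) # 4
#' sirs_score(temp = 35.8)                                            # 1
sirs_score <- function(temp = NULL, heart_rate = NULL, resp_rate = NULL,
                       wcc = NULL) {
  n <- common_length(temp, heart_rate, resp_rate, wcc)
  temp       <- rep_arg(temp, n)
  heart_rate <- rep_arg(heart_rate, n)
  resp_rate  <- rep_arg(resp_rate, n)
  wcc        <- rep_arg(wcc, n)
  check_range(temp, "temperature", 20, 45)
  check_range(heart_rate, "heart rate", 0, 350)
  check_range(resp_rate, "respiratory rate", 0, 150)
  check_range(wcc, "white cell count", 0, 500)

  crit <- function(x) ifelse(is.na(x), FALSE, x)
  as.integer(
    crit(wcc < 4 | wcc > 12) + crit(heart_rate > 90) +
      crit(resp_rate > 20) + crit(temp < 36 | temp > 38)
  )
}

#' quick SOFA (qSOFA)
#'
#' One point for each of: respiratory rate >= 22 breaths/min, systolic BP
#' <= 100 mmHg, and altered mentation (GCS <= 13, or AVPU other than alert
#' when GCS is unavailable). Missing parameters score 0.
#'
#' @inheritParams news_score
#' @param gcs Glasgow Coma Scale, integer 3-15. Takes precedence over AVPU.
#' @return integer vector, 0-3.
#' @export
#' @examples
#' qsofa_score(resp_rate = 22, sbp = 100, avpu = "A") # 2 (boundaries inclusive)
#' qsofa_score(resp_rate = 30, sbp = 80, avpu = "V")  # 3
qsofa_score <- function(resp_rate = NULL, sbp = NULL, gcs = NULL, avpu = NULL) {
  n <- common_length(resp_rate, sbp, gcs, avpu)
  resp_rate <- rep_arg(resp_rate, n)
  sbp       <- rep_arg(sbp, n)
  gcs       <- rep_arg(gcs, n)
  avpu      <- check_avpu(rep_arg(avpu, n))
  check_range(resp_rate, "respiratory rate", 0, 150)
  check_range(sbp, "systolic BP", 0, 350)
  check_range(gcs, "GCS", 3, 15)

  crit <- function(x) ifelse(is.na(x), FALSE, x)
  mentation <- ifelse(!is.na(gcs), gcs <= 13, !is.na(avpu) & avpu != "A")
  as.integer(crit(resp_rate >= 22) + crit(sbp <= 100) + mentation)
}

#' SOFA respiratory component with SpO2 substitution
#'
#' When an arterial blood gas is available (both `pao2` and `fio2` present)
#' the component is scored on the PaO2/FiO2 ratio in mmHg (< 400 -> 1,
#' < 300 -> 2, < 200 -> 3, < 100 -> 4; 3-4 additionally require respiratory
#' support, proxied by the supplemental-oxygen flag). PaO2 in kPa is converted
#' at 7.50062 mmHg/kPa. Without a blood gas, SpO2 substitutes: 91-94% scores
#' 1, below 91% scores 2, 95% and above scores 0. Neither available scores 0.
#'
#' @param pao2 arterial oxygen partial pressure, kPa.
#' @param fio2 inspired oxygen fraction, 0.21-1.0.
#' @param spo2 oxygen saturation, percent.
#' @param on_oxygen logical; respiratory support in place (needed for
#'   blood-gas scores 3-4).
#' @return integer vector, 0-4.
#' @export
#' @examples
#' sofa_respiration_points(spo2 = 93) # 1
#' sofa_respiration_points(spo2 = 90) # 2
#' sofa_respiration_points(pao2 = 10, fio2 = 0.6, on_oxygen = TRUE) # 3
sofa_respiration_points <- function(pao2 = NULL, fio2 = NULL, spo2 = NULL,
                                    on_oxygen = NULL) {
  n <- common_length(pao2, fio2, spo2, on_oxygen)
  pao2      <- rep_arg(pao2, n)
  fio2      <- rep_arg(fio2, n)
  spo2      <- rep_arg(spo2, n)
  on_oxygen <- rep_arg(on_oxygen, n)
  check_range(pao2, "PaO2", 0, 100)
  check_range(fio2, "FiO2", 0.21, 1.0)
  check_range(spo2, "SpO2", 0, 100)

  kpa_to_mmhg <- 7.50062
  pf <- pao2 * kpa_to_mmhg / fio2
  support <- !is.na(on_oxygen) & on_oxygen

  gas <- !is.na(pf)
  gas_pts <- band0(pf,
                   pf < 100 & support ~ 4L, pf < 200 & support ~ 3L,
                   pf < 300 ~ 2L, pf < 400 ~ 1L, TRUE ~ 0L)
  sub_pts <- band0(spo2, spo2 < 91 ~ 2L, spo2 <= 94 ~ 1L, TRUE ~ 0L)
  as.integer(ifelse(gas, gas_pts, sub_pts))
}

# surrogate GCS values for AVPU levels when GCS is unrecorded
.zadravecz_gcs <- c(A = 15, V = 13, P = 8, U = 3)

#' SOFA central nervous system component from GCS or AVPU
#'
#' GCS bands: 15 -> 0, 13-14 -> 1, 10-12 -> 2, 6-9 -> 3, below 6 -> 4. When
#' GCS is absent, AVPU is mapped to a surrogate GCS (A = 15, V = 13, P = 8,
#' U = 3) and banded identically. Both absent scores 0.
#'
#' @inheritParams qsofa_score
#' @param surrogate named numeric vector mapping AVPU levels to surrogate GCS;
#'   override to use a different published mapping.
#' @return integer vector, 0-4.
#' @export
#' @examples
#' sofa_cns_points(gcs = 14)    # 1
#' sofa_cns_points(avpu = "P")  # 3
sofa_cns_points <- function(gcs = NULL, avpu = NULL,
                            surrogate = c(A = 15, V = 13, P = 8, U = 3)) {
  n <- common_length(gcs, avpu)
  gcs  <- rep_arg(gcs, n)
  avpu <- check_avpu(rep_arg(avpu, n))
  check_range(gcs, "GCS", 3, 15)

  eff <- ifelse(!is.na(gcs), gcs, unname(surrogate[avpu]))
  band0(eff, eff >= 15 ~ 0L, eff >= 13 ~ 1L, eff >= 10 ~ 2L,
        eff >= 6 ~ 3L, TRUE ~ 4L)
}

#' Mean arterial pressure from systolic and diastolic pressure
#'
#' `MAP = DBP + (SBP - DBP) / 3`. Returns `NA` when either pressure is
#' missing, in which case the SOFA cardiovascular component scores 0
#' (missing-as-normal).
#'
#' @param sbp,dbp systolic and diastolic blood pressure, mmHg.
#' @return numeric vector of MAP, mmHg.
#' @export
mean_arterial_pressure <- function(sbp, dbp) {
  dbp + (sbp - dbp) / 3
}

#' Sequential Organ Failure Assessment (SOFA)
#'
#' Six organ components, each 0-4, summed to a 0-24 total. Inputs are the
#' directionally worst values over a 24-hour period (lowest platelets, MAP,
#' SpO2, PaO2/FiO2 and GCS; highest bilirubin and creatinine). Missing
#' components score 0.
#'
#' Bands: coagulation, platelets x10^9/L (< 150 -> 1, < 100 -> 2, < 50 -> 3,
#' < 20 -> 4); liver, bilirubin umol/L (20-32 -> 1, 33-101 -> 2,
#' 102-204 -> 3, > 204 -> 4); cardiovascular, MAP < 70 mmHg -> 1, with
#' vasopressor support (if recorded) scoring 2-4 regardless of MAP; renal,
#' creatinine umol/L (110-170 -> 1, 171-299 -> 2, 300-440 -> 3, > 440 -> 4)
#' or daily urine output mL (< 500 -> 3, < 200 -> 4), whichever is worse;
#' respiration via [sofa_respiration_points()]; CNS via [sofa_cns_points()].
#'
#' @inheritParams sofa_respiration_points
#' @inheritParams qsofa_score
#' @param platelets platelet count, x10^9/L.
#' @param bilirubin total bilirubin, umol/L.
#' @param map mean arterial pressure, mmHg; alternatively give `sbp` and
#'   `dbp` and it is derived.
#' @param sbp,dbp systolic/diastolic BP, mmHg (used only when `map` absent).
#' @param creatinine serum creatinine, umol/L.
#' @param urine_output 24-h urine volume, mL (optional).
#' @param vasopressor one of `"none"`, `"low"` (score 2), `"medium"` (3),
#'   `"high"` (4); dose categories per the critical-care scoring table.
#'   Defaults to absent, capping the cardiovascular component at 1.
#' @return tibble with one row per observation: the six component scores
#'   (`respiration`, `coagulation`, `liver`, `cardiovascular`, `cns`,
#'   `renal`) and `total`.
#' @export
#' @examples
#' sofa_score(platelets = 90, bilirubin = 40, map = 65, avpu = "A",
#'            creatinine = 100, spo2 = 96)$total # 5
#' sofa_score(spo2 = 90)$total                   # 2
sofa_score <- function(pao2 = NULL, fio2 = NULL, spo2 = NULL, on_oxygen = NULL,
                       platelets = NULL, bilirubin = NULL,
                       map = NULL, sbp = NULL, dbp = NULL,
                       gcs = NULL, avpu = NULL,
                       creatinine = NULL, urine_output = NULL,
                       vasopressor = NULL) {
  n <- common_length(pao2, fio2, spo2, on_oxygen, platelets, bilirubin,
                     map, sbp, dbp, gcs, avpu, creatinine, urine_output,
                     vasopressor)
  platelets    <- rep_arg(platelets, n)
  bilirubin    <- rep_arg(bilirubin, n)
  map          <- rep_arg(map, n)
  sbp          <- rep_arg(sbp, n)
  dbp          <- rep_arg(dbp, n)
  creatinine   <- rep_arg(creatinine, n)
  urine_output <- rep_arg(urine_output, n)
  vasopressor  <- rep_arg(vasopressor, n, default = NA_character_)
  check_range(platelets, "platelets", 0, 5000)
  check_range(bilirubin, "bilirubin", 0, 2000)
  check_range(creatinine, "creatinine", 0, 5000)
  check_range(urine_output, "urine output", 0, 20000)

  resp <- sofa_respiration_points(pao2 = rep_arg(pao2, n),
                                  fio2 = rep_arg(fio2, n),
                                  spo2 = rep_arg(spo2, n),
                                  on_oxygen = rep_arg(on_oxygen, n))

  coag <- band0(platelets, platelets < 20 ~ 4L, platelets < 50 ~ 3L,
                platelets < 100 ~ 2L, platelets < 150 ~ 1L, TRUE ~ 0L)

  liver <- band0(bilirubin, bilirubin > 204 ~ 4L, bilirubin >= 102 ~ 3L,
                 bilirubin >= 33 ~ 2L, bilirubin >= 20 ~ 1L, TRUE ~ 0L)

  if (all(is.na(map))) map <- mean_arterial_pressure(sbp, dbp)
  vaso_pts <- dplyr::case_when(
    is.na(vasopressor) | vasopressor == "none" ~ 0L,
    vasopressor == "low" ~ 2L,
    vasopressor == "medium" ~ 3L,
    vasopressor == "high" ~ 4L,
    TRUE ~ NA_integer_
  )
  if (anyNA(vaso_pts)) stop_invalid("invalid vasopressor category")
  cardio <- pmax(band0(map, map < 70 ~ 1L, TRUE ~ 0L), vaso_pts)

  cns <- sofa_cns_points(gcs = rep_arg(gcs, n), avpu = rep_arg(avpu, n))

  renal_cr <- band0(creatinine, creatinine > 440 ~ 4L, creatinine >= 300 ~ 3L,
                    creatinine >= 171 ~ 2L, creatinine >= 110 ~ 1L, TRUE ~ 0L)
  renal_uo <- band0(urine_output, urine_output < 200 ~ 4L,
                    urine_output < 500 ~ 3L, TRUE ~ 0L)
  renal <- pmax(renal_cr, renal_uo)

  tibble::tibble(
    respiration = as.integer(resp), coagulation = as.integer(coag),
    liver = as.integer(liver), cardiovascular = as.integer(cardio),
    cns = as.integer(cns), renal = as.integer(renal),
    total = as.integer(resp + coag + liver + cardio + cns + renal)
  )
}
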