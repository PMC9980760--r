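# Synthetic EHR cohort generator.
#
# Emulates the statistical structure the analysis assumes: a cohort
# oversampled for infection (blood-culture-matched design), with
# category-conditional mortality, culture sampling/positivity, ICD-10 coding
# probabilities, and vitals/labs trajectories that peak at infection onset
# and drive realistic severity-score distributions. Latent truth
# (true_category, true_onset) is carried alongside the observables so
# recovery can be tested end-to-end.

#' Parameters for the synthetic cohort generator
#'
#' Defaults encode the cohort structure of a blood-culture-matched UK
#' district-general-hospital population: 65.7% infection prevalence, 55.1%
#' of infected meeting Sepsis-3, category-conditional 30-day mortality
#' (19.9% / 5.3% / 4.0%), blood-culture sampling (66.0% / 70.3% / 15.5%)
#' and positivity, and explicit-sepsis coding sensitivity of 7.8%.
#'
#' @param n_admissions number of admissions to generate.
#' @param infection_prevalence proportion treated for infection.
#' @param sepsis_given_infection proportion of infected meeting Sepsis-3.
#' @param mortality_30d named proportions (30-day mortality from admission)
#'   per category.
#' @param culture_sampling named proportions with a blood culture taken.
#' @param culture_positive named proportions positive among sampled (true
#'   pathogen growth, not contamination).
#' @param contamination_rate proportion of sampled cultures growing
#'   contaminants (counted as sampled, never positive).
#' @param sepsis_code_rate named probability of an explicit sepsis ICD-10
#'   code per category.
#' @param infection_code_rate named probability of at least one infection
#'   ICD-10 code per category.
#' @param critical_care named probability of a critical-care episode.
#' @param los_median_days,los_sigma lognormal length-of-stay parameters per
#'   category (median in days; sigma on the log scale).
#' @param maternity_rate,short_stay_rate rates of admissions excluded by the
#'   eligibility filters (maternity units; discharge or death within 24h).
#' @param obs_gap_h range of hours between consecutive vitals observations.
#' @param pulse_tau_h time constant (hours) of the exponential derangement
#'   pulse around infection onset.
#' @param seed integer seed; all domains draw from named substreams of it.
#' @return a `cohort_params` list.
#' @export
cohort_params <- function(
    n_admissions = 958,
    infection_prevalence = 0.657,
    sepsis_given_infection = 0.551,
    mortality_30d = c(sepsis = 0.199, infection_no_sepsis = 0.053,
                      no_infection = 0.040),
    culture_sampling = c(sepsis = 0.660, infection_no_sepsis = 0.703,
                         no_infection = 0.155),
    culture_positive = c(sepsis = 0.1135, infection_no_sepsis = 0.0804,
                         no_infection = 0),
    contamination_rate = 0.05,
    sepsis_code_rate = c(sepsis = 0.078, infection_no_sepsis = 0.0246,
                         no_infection = 0.0246),
    infection_code_rate = c(sepsis = 0.651, infection_no_sepsis = 0.45,
                            no_infection = 0.215),
    critical_care = c(sepsis = 0.153, infection_no_sepsis = 0.060,
                      no_infection = 0.067),
    los_median_days = c(sepsis = 5.8, infection_no_sepsis = 3.9,
                        no_infection = 3.8),
    los_sigma = 0.78,
    maternity_rate = 0.02,
    short_stay_rate = 0.04,
    obs_gap_h = c(4, 8),
    pulse_tau_h = 30,
    seed = 1L) {
  p <- as.list(environment())
  for (nm in c("infection_prevalence", "sepsis_given_infection",
               "mortality_30d", "culture_sampling", "culture_positive",
               "contamination_rate", "sepsis_code_rate",
               "infection_code_rate", "critical_care")) {
    if (any(p[[nm]] < 0 | p[[nm]] > 1)) {
      stop_invalid(nm, " must be a proportion in [0, 1]")
    }
  }
  if (p$n_admissions < 2) stop_invalid("n_admissions must be at least 2")
  structure(p, class = "cohort_params")
}

# deterministic substream seed from the master seed and a domain name,
# kept below 2^31 so adding a generator domain never perturbs the others
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 997L
  (abs(as.integer(seed)) %% 1000000L) * 1000L + h
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(substream_seed(seed, name))
  expr
}

#' Generate a synthetic EHR cohort
#'
#' Draws a latent sepsis category per admission, then generates admission
#' intervals, ward and critical-care episodes, vitals every 4-8 hours with a
#' category-conditional derangement pulse peaking at infection onset,
#' daily laboratory results, antibiotic administrations, blood-culture
#' sampling and results, ICD-10 discharge codes and death dates, all with
#' the configured conditional probabilities. Reproducible given the seed.
#'
#' @param params a [cohort_params()] object.
#' @return an `ehr_cohort`: list of tibbles `admissions` (with latent
#'   `true_category` and `true_onset`), `episodes`, `vitals`, `labs`,
#'   `cultures`, `antibiotics`, `codes`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_params(n_admissions = 50, seed = 7))
#' names(coh)
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  n <- p$n_admissions
  t0 <- as.POSIXct("2015-10-01 00:00:00", tz = "UTC")

  adm <- with_substream(p$seed, "admissions", {
    cat_lv <- SEPSIS_CATEGORIES
    infected <- stats::runif(n) < p$infection_prevalence
    septic <- infected & stats::runif(n) < p$sepsis_given_infection
    category <- factor(ifelse(!infected, "no_infection",
                              ifelse(septic, "sepsis", "infection_no_sepsis")),
                       levels = cat_lv)
    maternity <- stats::runif(n) < p$maternity_rate
    short <- !maternity & stats::runif(n) < p$short_stay_rate
    los_h <- ifelse(
      short,
      stats::runif(n, 4, 20),
      pmax(26, exp(stats::rnorm(n, log(p$los_median_days[as.character(category)] * 24),
                                p$los_sigma)))
    )
    admit <- t0 + stats::runif(n, 0, 182 * 24) * 3600
    cc <- !short & stats::runif(n) < p$critical_care[as.character(category)]
    tibble::tibble(
      admission_id = seq_len(n),
      patient_id = seq_len(n),
      admit_time = admit,
      los_h = los_h,
      discharge_time = admit + los_h * 3600,
      maternity = maternity,
      age = pmin(100, pmax(16, round(stats::rnorm(
        n, c(sepsis = 71, infection_no_sepsis = 64,
             no_infection = 64)[as.character(category)], 16)))),
      sex = ifelse(stats::runif(n) < 0.54, "F", "M"),
      ward = paste0("W", sprintf("%02d", sample.int(10, n, replace = TRUE))),
      has_cc = cc,
      true_category = category,
      infection = infected & !short,
      true_onset = as.POSIXct(NA)
    )
  })
  # short stays carry no infection episode (no time for the workup)
  adm$true_category[adm$los_h < 24] <- "no_infection"

  adm <- with_substream(p$seed, "onset", {
    inf <- adm$infection
    onset_off <- stats::runif(nrow(adm), 2, 36)
    onset <- adm$admit_time + pmin(onset_off, adm$los_h - 4) * 3600
    adm$true_onset[inf] <- onset[inf]
    adm
  })

  # deaths shorten the stay, so they are drawn before the clinical streams
  adm <- with_substream(p$seed, "deaths", build_deaths(adm, p))
  episodes <- with_substream(p$seed, "episodes", build_episodes(adm))
  vitals <- with_substream(p$seed, "vitals", build_vitals(adm, p))
  labs <- with_substream(p$seed, "labs", build_labs(adm, p))
  cultures <- with_substream(p$seed, "cultures", build_cultures(adm, p))
  antibiotics <- with_substream(p$seed, "antibiotics", build_antibiotics(adm))
  codes <- with_substream(p$seed, "codes", build_codes(adm, p))

  antibiotics <- antibiotics[
    antibiotics$time <= adm$discharge_time[match(antibiotics$admission_id,
                                                 adm$admission_id)], ,
    drop = FALSE]

  structure(list(
    admissions = adm[, c("admission_id", "patient_id", "admit_time",
                         "discharge_time", "death_time", "maternity", "age",
                         "sex", "ward", "infection", "true_category",
                         "true_onset")],
    episodes = episodes, vitals = vitals, labs = labs,
    cultures = cultures, antibiotics = antibiotics, codes = codes,
    params = p
  ), class = "ehr_cohort")
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat("Synthetic EHR cohort:", nrow(x$admissions), "admissions\n")
  cat("  categories:", paste(names(table(x$admissions$true_category)),
                             table(x$admissions$true_category),
                             collapse = ", ", sep = " = "), "\n")
  cat("  vitals:", nrow(x$vitals), "observations; labs:", nrow(x$labs),
      "results; cultures:", nrow(x$cultures), "\n")
  invisible(x)
}

build_episodes <- function(adm) {
  ward_ep <- tibble::tibble(
    admission_id = adm$admission_id, ward = adm$ward, unit_type = "ward",
    start = adm$admit_time, end = adm$discharge_time
  )
  cc_rows <- which(adm$has_cc)
  if (length(cc_rows) == 0) return(ward_ep)
  a <- adm[cc_rows, ]
  inf <- a$infection
  # infected critical-care patients move to the unit around onset;
  # others at a random point of the stay
  rel_start <- numeric(nrow(a))
  rel_start[inf] <- as.numeric(difftime(a$true_onset[inf], a$admit_time[inf],
                                        units = "hours")) +
    stats::runif(sum(inf), -12, 36)
  rel_start[!inf] <- stats::runif(sum(!inf), 0, pmax(1, a$los_h[!inf] - 24))
  rel_start <- pmax(0, pmin(rel_start, a$los_h - 6))
  dur <- pmin(stats::runif(nrow(a), 48, 144), a$los_h - rel_start)
  cc_ep <- tibble::tibble(
    admission_id = a$admission_id, ward = "CCU", unit_type = "critical_care",
    start = a$admit_time + rel_start * 3600,
    end = a$admit_time + (rel_start + dur) * 3600
  )
  dplyr::bind_rows(ward_ep, cc_ep) |> dplyr::arrange(.data$admission_id)
}

# per-admission derangement magnitudes; interpolation toward the deranged
# value follows the pulse exp(-|t - onset| / tau)
derangement_profile <- function(adm) {
  n <- nrow(adm)
  cat <- as.character(adm$true_category)
  draw <- function(mu, sd) {
    m <- c(sepsis = mu[1], infection_no_sepsis = mu[2], no_infection = 0)[cat]
    s <- c(sepsis = sd[1], infection_no_sepsis = sd[2], no_infection = 0)[cat]
    stats::rnorm(n, m, s) * (cat != "no_infection")
  }
  # mild-infection derangements stay subclinical: febrile/tachycardic
  # responses without organ dysfunction, so SpO2 and blood-pressure
  # depressions are kept well clear of the SOFA bands
  tibble::tibble(
    d_rr = pmax(0, draw(c(12, 4), c(3, 2))),
    d_spo2 = pmax(0, draw(c(9, 0.8), c(1.2, 0.4))),
    d_temp = draw(c(1.8, 1.2), c(0.5, 0.5)),
    d_sbp = pmax(0, draw(c(32, 8), c(8, 4))),
    d_dbp = pmax(0, draw(c(15, 2), c(5, 1))),
    d_hr = pmax(0, draw(c(32, 12), c(8, 5)))
  )
}

pulse_at <- function(time, onset, tau_h) {
  dt <- abs(as.numeric(difftime(time, onset, units = "hours")))
  out <- exp(-dt / tau_h)
  out[is.na(out)] <- 0
  out
}

build_vitals <- function(adm, p) {
  gap_mid <- mean(p$obs_gap_h)
  n_obs <- pmax(2L, ceiling(adm$los_h / gap_mid) + 1L)
  idx <- rep(seq_len(nrow(adm)), n_obs)
  gaps <- stats::runif(length(idx), p$obs_gap_h[1], p$obs_gap_h[2])
  first <- !duplicated(idx)
  gaps[first] <- stats::runif(sum(first), 0, 2)
  rel_h <- stats::ave(gaps, idx, FUN = cumsum)
  keep <- rel_h <= adm$los_h[idx]
  idx <- idx[keep]
  rel_h <- rel_h[keep]

  a <- adm[idx, ]
  prof <- derangement_profile(adm)[idx, ]
  time <- a$admit_time + rel_h * 3600
  pl <- pulse_at(time, a$true_onset, p$pulse_tau_h)
  m <- length(idx)

  rr <- pmax(6, stats::rnorm(m, 16, 1.5) + prof$d_rr * pl)
  spo2 <- pmin(100, stats::rnorm(m, 97, 0.6) - prof$d_spo2 * pl)
  temp <- stats::rnorm(m, 36.8, 0.3) + prof$d_temp * pl
  sbp <- pmax(55, stats::rnorm(m, 126, 10) - prof$d_sbp * pl)
  dbp <- pmax(35, stats::rnorm(m, 75, 6) - prof$d_dbp * pl)
  dbp <- pmin(dbp, sbp - 12)
  hr <- pmax(35, stats::rnorm(m, 78, 8) + prof$d_hr * pl)

  septic <- a$true_category == "sepsis"
  u <- stats::runif(m)
  avpu <- rep("A", m)
  avpu[septic & u < 0.30 * pl] <- "V"
  avpu[septic & u < 0.08 * pl] <- "P"
  gcs_recorded <- stats::runif(m) < 0.25
  gcs <- ifelse(gcs_recorded,
                c(A = 15, V = 14, P = 9, U = 3)[avpu], NA_real_)
  on_ox <- stats::runif(m) < ifelse(septic, 0.6 * pl,
                                    ifelse(a$infection, 0.15 * pl, 0.02))

  tibble::tibble(
    admission_id = a$admission_id, time = time,
    resp_rate = round(rr), spo2 = round(spo2), on_oxygen = on_ox,
    temp = round(temp, 1), sbp = round(sbp), dbp = round(dbp),
    heart_rate = round(hr), avpu = avpu, gcs = gcs
  ) |> dplyr::arrange(.data$admission_id, .data$time)
}

# laboratory baselines and category-conditional deranged targets
LAB_MODEL <- list(
  platelets  = list(base = c(260, 40), sepsis = c(110, 30), inf = c(245, 40)),
  creatinine = list(base = c(76, 13),  sepsis = c(190, 50), inf = c(80, 13)),
  bilirubin  = list(base = c(10, 4),   sepsis = c(28, 10),  inf = c(10, 4)),
  wcc        = list(base = c(8, 1.8),  sepsis = c(17, 4),   inf = c(13, 3))
)

build_labs <- function(adm, p) {
  n_days <- pmax(1L, pmin(10L, ceiling(adm$los_h / 24)))
  idx <- rep(seq_len(nrow(adm)), n_days)
  day <- unlist(lapply(n_days, seq_len)) - 1L
  a <- adm[idx, ]
  time <- a$admit_time + (day * 24 + stats::runif(length(idx), 6, 10)) * 3600
  keep <- time < a$discharge_time
  idx <- idx[keep]; a <- a[keep, ]; time <- time[keep]
  pl <- pulse_at(time, a$true_onset, p$pulse_tau_h)
  m <- length(idx)
  cat <- as.character(a$true_category)

  one_analyte <- function(analyte) {
    md <- LAB_MODEL[[analyte]]
    target_mu <- ifelse(cat == "sepsis", md$sepsis[1],
                        ifelse(cat == "infection_no_sepsis", md$inf[1],
                               md$base[1]))
    target_sd <- ifelse(cat == "sepsis", md$sepsis[2],
                        ifelse(cat == "infection_no_sepsis", md$inf[2],
                               md$base[2]))
    mu <- md$base[1] + (target_mu - md$base[1]) * pl
    sd <- md$base[2] + (target_sd - md$base[2]) * pl
    tibble::tibble(admission_id = a$admission_id, time = time,
                   analyte = analyte,
                   value = pmax(0.1, stats::rnorm(m, mu, sd)))
  }
  out <- dplyr::bind_rows(lapply(names(LAB_MODEL), one_analyte))

  # arterial blood gases for critical-care admissions only; hypoxaemia and
  # the oxygen requirement track the derangement pulse so gases away from
  # onset are room-air normals (PaO2/FiO2 well above 400 mmHg)
  cc <- a$has_cc
  if (any(cc)) {
    sep_cc <- cat[cc] == "sepsis"
    pl_cc <- pl[cc]
    pao2 <- stats::rnorm(sum(cc), 12.8 - ifelse(sep_cc, 4.6, 0) * pl_cc,
                         0.8 + 0.7 * sep_cc * pl_cc)
    fio2 <- 0.21 + ifelse(sep_cc, 0.3, 0.02) * pl_cc +
      abs(stats::rnorm(sum(cc), 0, 0.01))
    gas <- tibble::tibble(
      admission_id = rep(a$admission_id[cc], 2),
      time = rep(time[cc], 2),
      analyte = rep(c("pao2", "fio2"), each = sum(cc)),
      value = c(pmax(4, pao2), pmin(1, pmax(0.21, fio2)))
    )
    out <- dplyr::bind_rows(out, gas)
  }
  dplyr::arrange(out, .data$admission_id, .data$time)
}

build_cultures <- function(adm, p) {
  cat <- as.character(adm$true_category)
  sampled <- stats::runif(nrow(adm)) < p$culture_sampling[cat]
  a <- adm[sampled, ]
  cat_s <- cat[sampled]
  # infected admissions are cultured at onset; others at a random point
  rel <- pmin(stats::runif(nrow(a), 4, pmax(5, a$los_h - 4)), a$los_h - 1)
  time <- a$admit_time + rel * 3600
  time[a$infection] <- a$true_onset[a$infection]
  u <- stats::runif(nrow(a))
  pos <- u < p$culture_positive[cat_s]
  contam <- !pos & u < p$culture_positive[cat_s] + p$contamination_rate
  tibble::tibble(
    admission_id = a$admission_id, time = time,
    result = ifelse(pos, "positive", ifelse(contam, "contaminated",
                                            "negative"))
  )
}

build_antibiotics <- function(adm) {
  a <- adm[adm$infection, ]
  n_dose <- sample.int(5, nrow(a), replace = TRUE)
  idx <- rep(seq_len(nrow(a)), n_dose)
  dose_no <- unlist(lapply(n_dose, seq_len)) - 1L
  tibble::tibble(
    admission_id = a$admission_id[idx],
    time = a$true_onset[idx] + dose_no * stats::runif(length(idx), 6, 12) * 3600,
    route = ifelse(stats::runif(length(idx)) < 0.7, "IV", "oral")
  )
}

# common codes drawn for each indicator class; prefix-matched downstream
SEPSIS_CODE_POOL <- c("A41.9", "A41.5", "A40.0", "R57.2")
INFECTION_CODE_POOL <- c("J18.9", "J18.1", "J22", "N39.0", "N10", "A09",
                         "L03.9", "K81.0", "B96.2", "J15.9")
NOISE_CODE_POOL <- c("I10", "I25.1", "E11.9", "N17.9", "C34.9", "F03",
                     "M54.5", "K21.9", "E78.0", "J44.9", "I48", "Z50.1")

build_codes <- function(adm, p) {
  cat <- as.character(adm$true_category)
  sep_code <- stats::runif(nrow(adm)) < p$sepsis_code_rate[cat]
  inf_code <- stats::runif(nrow(adm)) < p$infection_code_rate[cat]
  n_noise <- sample.int(4, nrow(adm), replace = TRUE)
  rows <- list(
    tibble::tibble(
      admission_id = adm$admission_id[sep_code],
      code = sample(SEPSIS_CODE_POOL, sum(sep_code), replace = TRUE)),
    tibble::tibble(
      admission_id = adm$admission_id[inf_code],
      code = sample(INFECTION_CODE_POOL, sum(inf_code), replace = TRUE)),
    tibble::tibble(
      admission_id = rep(adm$admission_id, n_noise),
      code = sample(NOISE_CODE_POOL, sum(n_noise), replace = TRUE))
  )
  out <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$admission_id)
  out$position <- stats::ave(rep(1L, nrow(out)), out$admission_id,
                             FUN = seq_along)
  out
}

build_deaths <- function(adm, p) {
  cat <- as.character(adm$true_category)
  dies <- stats::runif(nrow(adm)) < p$mortality_30d[cat] & adm$los_h >= 24
  death_h <- stats::runif(nrow(adm), 25, 719)
  # infected decedents survive at least 16h past onset so the infection
  # episode (culture, antibiotics, acuity window) exists
  onset_rel <- as.numeric(difftime(adm$true_onset, adm$admit_time,
                                   units = "hours"))
  death_h <- pmax(death_h, ifelse(is.na(onset_rel), 0, onset_rel + 16))
  adm$death_time <- adm$admit_time + death_h * 3600
  adm$death_time[!dies] <- NA
  # death in hospital truncates the stay
  in_hosp <- dies & death_h < adm$los_h
  adm$los_h[in_hosp] <- death_h[in_hosp]
  adm$discharge_time <- adm$admit_time + adm$los_h * 3600
  adm
}
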