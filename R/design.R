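# Study-design operations: eligibility filters, 1:1 blood-culture matching,
# and the critical-care-complete / ward-sampled cohort draw.

#' Apply the cohort eligibility filters
#'
#' Removes maternity-unit admissions and admissions discharged or dying
#' within the first 24 hours, logging counts per exclusion reason.
#'
#' @param admissions tibble with `admission_id`, `admit_time`,
#'   `discharge_time`, `maternity`.
#' @return list with `admissions` (retained rows) and `exclusions` (tibble
#'   of `reason`, `n`).
#' @export
apply_eligibility_filters <- function(admissions) {
  los_h <- as.numeric(difftime(admissions$discharge_time,
                               admissions$admit_time, units = "hours"))
  maternity <- !is.na(admissions$maternity) & admissions$maternity
  short <- !maternity & los_h < 24
  exclusions <- tibble::tibble(
    reason = c("maternity", "los_lt_24h"),
    n = c(sum(maternity), sum(short))
  )
  list(admissions = admissions[!maternity & !short, , drop = FALSE],
       exclusions = exclusions)
}

#' Match culture-sampled admissions 1:1 to unsampled controls
#'
#' Greedy chronological matching: each admission with a blood culture is
#' paired to an admission without one that was in the same ward or clinical
#' area within a location-specific window of the culture time (+/-24h for
#' general wards, +/-96h for critical care) and whose length of stay differs
#' by at most the location-specific tolerance (+/-24h for wards, +/-48h for
#' critical care). Each control is used at most once; ties are broken by the
#' smallest length-of-stay difference, then the earliest control admission.
#'
#' @param admissions tibble with `admission_id`, `admit_time`,
#'   `discharge_time`.
#' @param episodes tibble with `admission_id`, `ward`, `unit_type`
#'   (`"ward"`/`"critical_care"`), `start`, `end`.
#' @param cultures tibble with `admission_id`, `time`; the first culture per
#'   admission anchors the match.
#' @param time_window_h,los_tol_h named numeric vectors (`ward`,
#'   `critical_care`) overriding the default windows/tolerances, hours.
#' @return list with `pairs` (tibble: `case_id`, `control_id`, `ward`,
#'   `unit_type`, `culture_time`, `los_diff_h`) and `unmatched` (case ids).
#' @export
match_culture_pairs <- function(admissions, episodes, cultures,
                                time_window_h = c(ward = 24,
                                                  critical_care = 96),
                                los_tol_h = c(ward = 24,
                                              critical_care = 48)) {
  los <- stats::setNames(
    as.numeric(difftime(admissions$discharge_time, admissions$admit_time,
                        units = "hours")),
    admissions$admission_id)

  first_culture <- cultures |>
    dplyr::group_by(.data$admission_id) |>
    dplyr::summarise(culture_time = min(.data$time), .groups = "drop")
  case_ids <- intersect(first_culture$admission_id, admissions$admission_id)
  control_pool <- setdiff(admissions$admission_id, first_culture$admission_id)

  # location of each case at culture time: the episode covering it
  # (preferring critical care when both cover, e.g. at a transfer boundary)
  cases <- first_culture[first_culture$admission_id %in% case_ids, ]
  cases <- cases[order(cases$culture_time), ]
  ep <- episodes
  control_ep <- ep[ep$admission_id %in% control_pool, , drop = FALSE]

  used <- character(0)
  pairs <- vector("list", nrow(cases))
  unmatched <- character(0)
  for (i in seq_len(nrow(cases))) {
    cid <- cases$admission_id[i]
    ct <- cases$culture_time[i]
    loc <- ep[ep$admission_id == cid & ep$start <= ct & ep$end >= ct, ,
              drop = FALSE]
    if (nrow(loc) == 0) {
      unmatched <- c(unmatched, as.character(cid))
      next
    }
    loc <- loc[order(loc$unit_type == "critical_care", decreasing = TRUE), ][1, ]
    w <- unname(time_window_h[loc$unit_type])
    tol <- unname(los_tol_h[loc$unit_type])
    cand <- control_ep[
      control_ep$ward == loc$ward &
        control_ep$start <= ct + hours(w) &
        control_ep$end >= ct - hours(w) &
        !control_ep$admission_id %in% used, , drop = FALSE]
    if (nrow(cand) > 0) {
      diff_los <- abs(los[as.character(cand$admission_id)] -
                        los[as.character(cid)])
      cand <- cand[diff_los <= tol, , drop = FALSE]
      diff_los <- diff_los[diff_los <= tol]
    } else {
      diff_los <- numeric(0)
    }
    if (nrow(cand) == 0) {
      unmatched <- c(unmatched, as.character(cid))
      next
    }
    adm_t <- admissions$admit_time[match(cand$admission_id,
                                         admissions$admission_id)]
    pick <- order(diff_los, adm_t)[1]
    ctrl <- cand$admission_id[pick]
    used <- c(used, as.character(ctrl))
    pairs[[i]] <- tibble::tibble(
      case_id = cid, control_id = ctrl, ward = loc$ward,
      unit_type = loc$unit_type, culture_time = ct,
      los_diff_h = unname(diff_los[pick])
    )
  }
  list(pairs = dplyr::bind_rows(pairs), unmatched = unmatched)
}

#' Draw the study cohort from matched pairs
#'
#' Keeps every critical-care pair and a simple random sample of ward pairs
#' to reach the target size; pairs are kept or dropped whole.
#'
#' @param pairs tibble from [match_culture_pairs()].
#' @param n_target target number of admissions (2 per pair).
#' @param seed integer seed for the ward-pair sample.
#' @return tibble of retained pairs.
#' @export
sample_study_cohort <- function(pairs, n_target, seed = 1L) {
  n_pairs_target <- ceiling(n_target / 2)
  cc <- pairs[pairs$unit_type == "critical_care", , drop = FALSE]
  ward <- pairs[pairs$unit_type == "ward", , drop = FALSE]
  n_ward_needed <- n_pairs_target - nrow(cc)
  if (n_ward_needed < 0) n_ward_needed <- 0
  if (n_ward_needed > nrow(ward)) {
    stop_invalid("insufficient matched pairs: need ", n_ward_needed,
                 " ward pairs, have ", nrow(ward))
  }
  keep <- with_substream(seed, "cohort_sample",
                         sample.int(nrow(ward), n_ward_needed))
  dplyr::bind_rows(cc, ward[sort(keep), , drop = FALSE])
}
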