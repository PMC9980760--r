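# Administrative-data sepsis indicators: ICD-10 code classes, blood-culture
# flags, and their Boolean combinations, evaluated against a reference sepsis
# definition.

#' Normalise an ICD-10 code
#'
#' Uppercases and canonicalises the dotted form: `"a419"` and `"A41.9"` both
#' become `"A41.9"`. Three-character codes are returned as-is and act as
#' prefixes (chapter/category matching).
#'
#' @param code character vector of ICD-10 codes or prefixes.
#' @return character vector of canonical codes.
#' @export
#' @examples
#' normalise_icd10(c("a41.9", "A419", "R572")) # "A41.9" "A41.9" "R57.2"
normalise_icd10 <- function(code) {
  code <- gsub("\\s", "", toupper(as.character(code)))
  if (any(is.na(code) | code == "")) stop_invalid("empty ICD-10 code")
  ok <- grepl("^[A-Z][0-9]{2}(\\.?[0-9A-Z]{1,4})?$", code)
  if (!all(ok)) stop_invalid("malformed ICD-10 code: ", code[!ok][1])
  undotted <- gsub(".", "", code, fixed = TRUE)
  ifelse(nchar(undotted) > 3,
         paste0(substr(undotted, 1, 3), ".", substr(undotted, 4, 99)),
         undotted)
}

#' Does a code fall under any code/prefix in a list?
#'
#' Matching is hierarchical: the list entry `"A41"` matches `"A41"`,
#' `"A41.9"`, etc.; `"R57.2"` matches only itself and deeper subdivisions.
#'
#' @param code character vector of ICD-10 codes (normalised internally).
#' @param list_codes character vector of codes/prefixes.
#' @return logical vector.
#' @export
icd10_in_list <- function(code, list_codes) {
  code <- gsub(".", "", normalise_icd10(code), fixed = TRUE)
  prefixes <- gsub(".", "", normalise_icd10(list_codes), fixed = TRUE)
  vapply(code, function(cd) {
    any(startsWith(cd, prefixes))
  }, logical(1), USE.NAMES = FALSE)
}

#' Sepsis and infection ICD-10 code lists
#'
#' The sepsis list is the explicit-sepsis set {A40 (streptococcal sepsis),
#' A41 (other sepsis), R57.2 (septic shock)}. The infection list is a
#' packaged, documented reconstruction seeded from the three chapters that
#' dominate infection coding in UK hospital data — respiratory (J),
#' infectious and parasitic diseases (A/B) and genitourinary (N) — plus
#' common site-specific infection categories; replace it with
#' `read_code_list()` for a locally validated list. Sepsis codes are removed
#' from the infection list so the two sets are disjoint.
#'
#' @param sepsis_file,infection_file optional paths to plain-text code lists
#'   (one code/prefix per line, `#` comments); defaults to the packaged lists.
#' @return list with character vectors `sepsis_codes` and `infection_codes`.
#' @export
default_code_lists <- function(sepsis_file = NULL, infection_file = NULL) {
  sepsis_file <- sepsis_file %||%
    system.file("extdata", "sepsis_codes.txt", package = "sepsisperf")
  infection_file <- infection_file %||%
    system.file("extdata", "infection_codes.txt", package = "sepsisperf")
  sepsis <- read_code_list(sepsis_file)
  infection <- read_code_list(infection_file)
  undot <- function(x) gsub(".", "", x, fixed = TRUE)
  overlap <- vapply(undot(infection), function(cd) {
    any(startsWith(cd, undot(sepsis))) || any(startsWith(undot(sepsis), cd))
  }, logical(1))
  list(sepsis_codes = sepsis, infection_codes = unname(infection[!overlap]))
}

#' Read a plain-text ICD-10 code list
#'
#' One code or prefix per line; `#` starts a comment; blank lines ignored.
#'
#' @param path file path.
#' @return character vector of normalised codes.
#' @export
read_code_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  normalise_icd10(lines[lines != ""])
}

#' Administrative-data indicators per admission
#'
#' Builds the seven Boolean indicators evaluated for sepsis surveillance:
#' infection code, sepsis code, either code, blood culture sampled, positive
#' blood culture, code-or-culture, code-and-culture. Contaminated cultures
#' count as sampled but never as positive.
#'
#' @param codes tibble with columns `admission_id`, `code` (any diagnosis
#'   position).
#' @param cultures tibble with columns `admission_id`, `result` (one of
#'   `"negative"`, `"positive"`, `"contaminated"`).
#' @param admission_ids vector of all admission ids in the cohort (so
#'   admissions with no codes and no cultures appear with all-FALSE flags).
#' @param lists code lists from [default_code_lists()].
#' @return tibble with one row per admission and the seven logical columns.
#' @export
build_indicators <- function(codes, cultures, admission_ids,
                             lists = default_code_lists()) {
  bad <- setdiff(unique(cultures$result),
                 c("negative", "positive", "contaminated"))
  if (length(bad) > 0) stop_invalid("unknown culture result: ", bad[1])

  code_flags <- if (nrow(codes) > 0) {
    codes |>
      dplyr::mutate(
        is_sepsis = icd10_in_list(.data$code, lists$sepsis_codes),
        is_infection = icd10_in_list(.data$code, lists$infection_codes)
      ) |>
      dplyr::group_by(.data$admission_id) |>
      dplyr::summarise(has_sepsis_code = any(.data$is_sepsis),
                       has_infection_code = any(.data$is_infection),
                       .groups = "drop")
  } else {
    tibble::tibble(admission_id = admission_ids[0],
                   has_sepsis_code = logical(), has_infection_code = logical())
  }
  cult_flags <- cultures |>
    dplyr::group_by(.data$admission_id) |>
    dplyr::summarise(has_blood_culture = dplyr::n() > 0,
                     has_positive_culture = any(.data$result == "positive"),
                     .groups = "drop")

  out <- tibble::tibble(admission_id = admission_ids) |>
    dplyr::left_join(code_flags, by = "admission_id") |>
    dplyr::left_join(cult_flags, by = "admission_id")
  for (cl in c("has_sepsis_code", "has_infection_code", "has_blood_culture",
               "has_positive_culture")) {
    out[[cl]][is.na(out[[cl]])] <- FALSE
  }
  out |>
    dplyr::mutate(
      has_any_code = .data$has_infection_code | .data$has_sepsis_code,
      code_or_culture = .data$has_any_code | .data$has_blood_culture,
      code_and_culture = .data$has_any_code & .data$has_blood_culture
    )
}

# evaluation grid order mirrors the surveillance analysis
INDICATOR_ORDER <- c(
  infection_code = "has_infection_code",
  sepsis_code = "has_sepsis_code",
  infection_or_sepsis_code = "has_any_code",
  blood_culture = "has_blood_culture",
  positive_blood_culture = "has_positive_culture",
  code_or_culture = "code_or_culture",
  code_and_culture = "code_and_culture"
)

#' Evaluate administrative indicators against a reference sepsis definition
#'
#' For each indicator, cross-tabulates against the reference and reports
#' sensitivity, specificity, PPV and NPV with 95% confidence intervals plus
#' the binary AUROC (= (sensitivity + specificity) / 2).
#'
#' @param indicators tibble from [build_indicators()].
#' @param reference logical vector, one element per row of `indicators`
#'   (e.g. Sepsis-3 label == "sepsis", or infection with NEWS >= 7).
#' @param ci_method passed to [accuracy_stats()].
#' @return tibble with one row per indicator: counts (`tp`, `fp`, `fn`,
#'   `tn`), the four statistics with CIs (proportions), and
#'   `auroc`/`auroc_low`/`auroc_high`.
#' @export
evaluate_indicators <- function(indicators, reference,
                                ci_method = "clopper-pearson") {
  if (nrow(indicators) == 0) stop_invalid("empty cohort")
  if (length(reference) != nrow(indicators)) {
    stop_invalid("reference length must match the indicator table")
  }
  rows <- lapply(names(INDICATOR_ORDER), function(nm) {
    t <- two_by_two(indicators[[INDICATOR_ORDER[[nm]]]], reference)
    st <- accuracy_stats(t, ci_method = ci_method)
    au <- binary_auroc(t)
    wide <- stats::setNames(
      as.list(c(rbind(st$estimate, st$conf_low, st$conf_high))),
      paste0(rep(st$statistic, each = 3), c("", "_low", "_high"))
    )
    tibble::tibble(indicator = nm, tp = t$tp, fp = t$fp, fn = t$fn, tn = t$tn,
                   !!!wide, auroc = au$auroc, auroc_low = au$conf_low,
                   auroc_high = au$conf_high)
  })
  dplyr::bind_rows(rows)
}

#' Display-rounded performance grid
#'
#' Formats an evaluation grid (from [evaluate_indicators()] or
#' [score_performance()]) the way clinical diagnostic-accuracy tables are
#' printed: percentages to one decimal (half-up) with 95% CIs, AUROC to two
#' decimals.
#'
#' @param grid tibble with `estimate`/`_low`/`_high` proportion columns.
#' @return tibble of formatted strings.
#' @export
format_performance <- function(grid) {
  pct <- function(p, lo, hi) {
    sprintf("%.1f%% (%.1f-%.1f)", round_half_up(100 * p, 1),
            round_half_up(100 * lo, 1), round_half_up(100 * hi, 1))
  }
  out <- grid[, intersect(c("indicator", "score", "cutoff", "n_positive"),
                          names(grid)), drop = FALSE]
  for (st in c("sensitivity", "specificity", "ppv", "npv")) {
    if (st %in% names(grid)) {
      out[[st]] <- pct(grid[[st]], grid[[paste0(st, "_low")]],
                       grid[[paste0(st, "_high")]])
    }
  }
  if ("auroc" %in% names(grid)) {
    out$auroc <- sprintf("%.2f (%.2f-%.2f)", round_half_up(grid$auroc, 2),
                         round_half_up(grid$auroc_low, 2),
                         round_half_up(grid$auroc_high, 2))
  }
  out
}
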