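# internal helpers shared across modules

#' Round half away from zero
#'
#' Decimal rounding with ties going up (`0.5 -> 1`), the convention used for
#' all displayed percentages and AUROCs. Base `round()` rounds half to even,
#' which does not reproduce clinically reported tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.265 * 100, 1) # 26.5
#' round_half_up(18.75, 1)       # 18.8
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# recycle scalar/NULL arguments to common length n; NULL becomes NA
rep_arg <- function(x, n, default = NA) {
  if (is.null(x)) x <- default
  if (length(x) == 1L) x <- rep(x, n)
  if (length(x) != n) {
    stop("argument lengths differ: expected 1 or ", n, ", got ", length(x),
         call. = FALSE)
  }
  x
}

# largest length among a list of vectors (NULLs count as 1)
common_length <- function(...) {
  max(vapply(list(...), function(x) max(1L, length(x)), integer(1)))
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("sepsisperf_invalid_input", "error")))
}

# physiological range validation; NA passes (missing is allowed everywhere)
check_range <- function(x, name, lo = 0, hi = Inf) {
  bad <- !is.na(x) & (x < lo | x > hi)
  if (any(bad)) {
    stop_invalid("invalid ", name, ": values outside [", lo, ", ", hi, "] (e.g. ",
                 x[which(bad)[1]], ")")
  }
  invisible(x)
}

check_avpu <- function(avpu) {
  avpu <- toupper(as.character(avpu))
  bad <- !is.na(avpu) & !avpu %in% c("A", "V", "P", "U")
  if (any(bad)) stop_invalid("invalid AVPU level: ", avpu[which(bad)[1]])
  avpu
}

hours <- function(h) h * 3600

is_time <- function(x) inherits(x, "POSIXct")
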