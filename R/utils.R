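# Days per year used for all age arithmetic. Ages in whole years are
# floor(days / 365.25) so that integer day offsets reproduce exactly.
DAYS_PER_YEAR <- 365.25

#' Convert an age in whole years to the day offset of that birthday
#'
#' @param years Age in years.
#' @return Integer day offset since birth.
#' @keywords internal
years_to_days <- function(years) as.integer(floor(years * DAYS_PER_YEAR))

#' Convert a day offset since birth to a completed age in years
#'
#' @param days Integer day offset.
#' @return Completed years of age, `floor(days / 365.25)`.
#' @keywords internal
days_to_years <- function(days) as.integer(floor(days / DAYS_PER_YEAR))

# Add whole calendar years to a Date; 29 Feb anniversaries roll to 1 Mar.
add_years <- function(date, n) {
  lt <- as.POSIXlt(date)
  lt$year <- lt$year + n
  out <- as.Date(lt)
  # 29 Feb + n in a non-leap year overflows into March; as.Date(POSIXlt)
  # already normalises 29 Feb -> 1 Mar, which is the convention we want.
  out
}

#' Round half away from zero to a fixed number of decimals
#'
#' Base `round()` rounds half to even; published tables conventionally round
#' half up, and every derived percentage in the linkage table reproduces the
#' printed value under this rule.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.25, 1) # 0.3, where round(0.25, 1) gives 0.2
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Internal argument check helper
stop_if_not_df <- function(x, arg) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame, not %s.", arg, class(x)[1]))
  }
  invisible(x)
}
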