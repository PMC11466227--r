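#' Count incident chronic-condition cases per cohort and year of age
#'
#' Tallies first-instance events by completed year of age within birth
#' cohorts defined by financial year of birth (1 April to 31 March),
#' regardless of place of birth — immigrants' events count. Events at age 16
#' or older are excluded with a message.
#'
#' @param events Tibble of first events per child with `child_id` and
#'   `age_days`, e.g. [first_chc_events()] output or a subtype slice of
#'   [extract_chc_events()].
#' @param children Tibble with `child_id` and `birth_date` for every child
#'   appearing in `events` (immigrants included).
#' @param cohort_range Optional `c(from, to)` first calendar years; events of
#'   children born outside it are dropped.
#' @return Tibble with `cohort`, `age` (0-15, complete) and `cases`.
#' @export
count_incident_by_age <- function(events, children, cohort_range = NULL) {
  stop_if_not_df(events, "events")
  stop_if_not_df(children, "children")
  ev <- events |>
    inner_join(children |> select("child_id", "birth_date"), by = "child_id") |>
    mutate(
      cohort = assign_cohort(.data$birth_date, type = "financial", range = cohort_range),
      age = days_to_years(.data$age_days)
    ) |>
    filter(!is.na(.data$cohort))
  over <- ev |> filter(.data$age >= 16)
  if (nrow(over) > 0) {
    inform(sprintf("Excluding %d event(s) at age 16 or older.", nrow(over)))
    ev <- ev |> filter(.data$age < 16)
  }
  ev |>
    count(.data$cohort, .data$age, name = "cases") |>
    tidyr::complete(
      cohort = unique(ev$cohort), age = 0:15, fill = list(cases = 0L)
    ) |>
    arrange(.data$cohort, .data$age)
}

#' Open-cohort cumulative incidence from external population denominators
#'
#' For each year of age `a`, the hazard is the incident case count over the
#' external mid-year population estimate discounted by the cumulative number
#' of prior cases: `denom(a) = pop(a) - sum of cases at ages < a`,
#' `h(a) = cases(a) / denom(a)`. The cumulative incidence by the end of age
#' `a` is `1 - exp(-IH(a))` with `IH(a) = sum of h(k) for k <= a`. The
#' default discount excludes cases incident at the current age (a child
#' becoming a case mid-year contributed risk time that year);
#' `discount = "inclusive"` subtracts cases through the current age instead.
#'
#' @param cases Tibble with `age` and `cases` (one cohort), e.g. one cohort
#'   slice of [count_incident_by_age()], or a numeric vector of cases for
#'   ages `0, 1, ...`.
#' @param population Tibble with `age` and `population` (mid-year counts,
#'   treated as exact), or a numeric vector aligned with `cases`.
#' @param max_age Last age band to use (default: all ages supplied).
#' @param discount `"exclusive"` (default) or `"inclusive"`, see above.
#' @return Tibble of class `chc_open_cuminc`: `age` (band), `cases`,
#'   `population`, `denom`, `hazard`, `cum_hazard`, `cum_inc` (by the end of
#'   the age band, i.e. by age `age + 1`).
#' @export
#' @examples
#' open_cuminc(cases = 10, population = 100) # 1 - exp(-0.1)
open_cuminc <- function(cases, population, max_age = NULL,
                        discount = c("exclusive", "inclusive")) {
  discount <- match.arg(discount)
  if (is.data.frame(cases)) {
    cases <- cases |> arrange(.data$age)
    ages <- cases$age
    cases <- cases$cases
  } else {
    ages <- seq_along(cases) - 1L
  }
  if (is.data.frame(population)) {
    population <- population |> arrange(.data$age)
    if (!identical(as.integer(population$age), as.integer(ages))) {
      abort("`cases` and `population` age grids do not align.")
    }
    population <- population$population
  }
  if (length(population) != length(cases)) {
    abort("`cases` and `population` must cover the same ages.")
  }
  if (!is.null(max_age)) {
    keep <- ages <= max_age
    ages <- ages[keep]; cases <- cases[keep]; population <- population[keep]
  }
  if (any(cases < 0) || any(population < 0)) {
    abort("Case and population counts must be non-negative.")
  }
  cum_before <- dplyr::lag(cumsum(cases), default = 0)
  denom <- if (discount == "exclusive") {
    population - cum_before
  } else {
    population - cumsum(cases)
  }
  bad <- which(denom <= 0)
  if (length(bad)) {
    abort(sprintf(
      "Discounted denominator is <= 0 at age %d: incompatible case/population inputs.",
      ages[bad[1]]
    ))
  }
  if (any(cases > denom)) {
    abort(sprintf(
      "More cases than discounted denominator at age %d.",
      ages[which(cases > denom)[1]]
    ))
  }
  hazard <- cases / denom
  out <- tibble(
    age = as.integer(ages), cases = cases, population = population,
    denom = denom, hazard = hazard, cum_hazard = cumsum(hazard),
    cum_inc = 1 - exp(-cumsum(hazard))
  )
  class(out) <- c("chc_open_cuminc", class(out))
  out
}

#' Follow-up horizon of an open cohort
#'
#' Cohorts born later have shorter follow-up: a cohort born in financial
#' year `Y/Y+1` with data to the end of financial year `end_year/end_year+1`
#' attains at most `end_year - Y` complete years of age for all its members,
#' capped at 16 (the analogue of "maximum per-cohort age 8 to 16 years" for
#' the academic-year cohorts).
#'
#' @param cohort Cohort label (e.g. `"2003/4"`).
#' @param end_year First calendar year of the last financial year of data
#'   (default 2019, i.e. data to 2019/20).
#' @return Integer maximum age in years.
#' @export
open_cohort_max_age <- function(cohort, end_year = 2019) {
  y <- as.integer(sub("/.*$", "", cohort))
  as.integer(pmin(16L, pmax(0L, end_year - y)))
}

#' Compare an open-cohort curve with a closed-cohort curve
#'
#' @param open A `chc_open_cuminc` tibble.
#' @param closed A `chc_cuminc` object (closed-cohort estimator).
#' @param tolerance Maximum acceptable absolute difference.
#' @return List with `by_age` (tibble: age, open, closed, abs_diff — both
#'   curves evaluated "by age a + 1", the end of each band), `max_abs_diff`,
#'   and `pass`.
#' @export
reconcile_curves <- function(open, closed, tolerance = 0.015) {
  if (!inherits(open, "chc_open_cuminc")) abort("`open` must be a chc_open_cuminc.")
  if (!inherits(closed, "chc_cuminc")) abort("`closed` must be a chc_cuminc.")
  closed_by <- ci_at(closed, open$age + 1)$estimate
  open_by <- open$cum_inc
  by_age <- tibble(
    age_by = open$age + 1L, open = open_by, closed = closed_by,
    abs_diff = abs(open_by - closed_by)
  )
  list(
    by_age = by_age,
    max_abs_diff = max(by_age$abs_diff),
    pass = max(by_age$abs_diff) <= tolerance
  )
}
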