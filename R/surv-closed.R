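new_chc_cuminc <- function(table, type, n, meta = list()) {
  structure(
    list(
      table = table, type = type, n = n,
      n_events = sum(table$n_event), meta = meta
    ),
    class = "chc_cuminc"
  )
}

validate_followups <- function(followups) {
  stop_if_not_df(followups, "followups")
  if (nrow(followups) == 0) abort("At least one follow-up record is required.")
  if (!all(c("time", "event") %in% names(followups))) {
    abort("`followups` needs columns `time` and `event`.")
  }
  if (any(is.na(followups$time)) || any(followups$time < 0)) {
    abort("Follow-up times must be non-negative and non-missing.")
  }
  invisible(followups)
}

#' One-minus-product-limit cumulative incidence
#'
#' Product-limit (Kaplan-Meier) estimator of the probability of a first
#' chronic-condition record by each age, with right censoring: at each
#' distinct event time `t`, `S <- S * (1 - d_t / n_t)` where the risk set
#' `n_t` counts everyone with follow-up `>= t` (events at `t` are evaluated
#' before same-time censorings are removed). The curve is `1 - S`, with
#' Greenwood standard errors and normal-approximation confidence limits.
#'
#' @param followups Data frame with `time` (days, `>= 0`) and `event`
#'   (logical) columns, e.g. from [build_followup()].
#' @param conf_level Confidence level for the Greenwood interval.
#' @return An object of class `chc_cuminc` whose `$table` has one row per
#'   distinct event time: `time`, `n_risk`, `n_event`, `n_censor` (censorings
#'   in `(previous time, time]`), `estimate` (= cumulative incidence),
#'   `std_err`, `conf_low`, `conf_high`. Use [ci_at()] to evaluate the step
#'   function at chosen ages, [tidy()] for the table, [glance()] for a
#'   one-row summary.
#' @export
#' @examples
#' km_cuminc(data.frame(time = c(1, 2, 3), event = c(FALSE, TRUE, FALSE)))
km_cuminc <- function(followups, conf_level = 0.95) {
  validate_followups(followups)
  time <- followups$time
  event <- as.logical(followups$event)
  ts <- sort(unique(time[event]))
  if (length(ts) == 0) {
    tab <- tibble(
      time = numeric(0), n_risk = integer(0), n_event = integer(0),
      n_censor = integer(0), estimate = numeric(0), std_err = numeric(0),
      conf_low = numeric(0), conf_high = numeric(0)
    )
    return(new_chc_cuminc(tab, "km", length(time)))
  }
  n_risk <- vapply(ts, function(t) sum(time >= t), integer(1))
  n_event <- vapply(ts, function(t) sum(time == t & event), integer(1))
  bounds <- c(-Inf, ts)
  n_censor <- vapply(seq_along(ts), function(i) {
    sum(!event & time > bounds[i] & time <= ts[i])
  }, integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  gw <- surv^2 * cumsum(n_event / (n_risk * pmax(n_risk - n_event, 1)))
  gw[n_risk == n_event] <- 0 # S = 0: variance degenerate
  se <- sqrt(gw)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- 1 - surv
  tab <- tibble(
    time = ts, n_risk = n_risk, n_event = n_event, n_censor = n_censor,
    estimate = est, std_err = se,
    conf_low = pmax(0, est - z * se), conf_high = pmin(1, est + z * se)
  )
  new_chc_cuminc(tab, "km", length(time))
}

followup_status <- function(followups) {
  if ("reason" %in% names(followups)) {
    ifelse(followups$event, 1L,
      ifelse(!is.na(followups$reason) & followups$reason == "death", 2L, 0L)
    )
  } else if ("status" %in% names(followups)) {
    as.integer(followups$status)
  } else {
    # no reason/status column: no censoring is a death
    ifelse(as.logical(followups$event), 1L, 0L)
  }
}

#' Aalen-Johansen cumulative incidence with death as a competing risk
#'
#' Cause-specific cumulative incidence function for a first
#' chronic-condition record, treating death as a competing event rather than
#' a censoring: at each event time, the increment is `S(t-) * d1_t / n_t`
#' where `S` is the all-cause (event-or-death) Kaplan-Meier survival. With no
#' deaths in the input the estimate coincides exactly with [km_cuminc()].
#'
#' @param followups Data frame with `time`, `event` and either a `reason`
#'   column (value `"death"` marks competing deaths, as produced by
#'   [build_followup()]) or an integer `status` column (0 censored, 1 event,
#'   2 death). With neither column, all censorings are treated as non-death
#'   and the estimate coincides with [km_cuminc()].
#' @param cause `"chc"` (default) or `"death"`: which cause-specific curve to
#'   return.
#' @return A `chc_cuminc` object (type `"aj"`).
#' @export
aj_cuminc <- function(followups, cause = c("chc", "death")) {
  validate_followups(followups)
  cause <- match.arg(cause)
  time <- followups$time
  status <- followup_status(followups)
  status[as.logical(followups$event)] <- 1L
  ts <- sort(unique(time[status > 0]))
  want <- if (cause == "chc") 1L else 2L
  if (length(ts) == 0) {
    tab <- tibble(
      time = numeric(0), n_risk = integer(0), n_event = integer(0),
      n_censor = integer(0), estimate = numeric(0), std_err = numeric(0),
      conf_low = numeric(0), conf_high = numeric(0)
    )
    return(new_chc_cuminc(tab, "aj", length(time), list(cause = cause)))
  }
  n_risk <- vapply(ts, function(t) sum(time >= t), integer(1))
  d1 <- vapply(ts, function(t) sum(time == t & status == 1L), integer(1))
  d2 <- vapply(ts, function(t) sum(time == t & status == 2L), integer(1))
  bounds <- c(-Inf, ts)
  n_censor <- vapply(seq_along(ts), function(i) {
    sum(status == 0L & time > bounds[i] & time <= ts[i])
  }, integer(1))
  s_all <- cumprod(1 - (d1 + d2) / n_risk)
  s_minus <- c(1, s_all[-length(s_all)])
  d_want <- if (want == 1L) d1 else d2
  cif <- cumsum(s_minus * d_want / n_risk)
  tab <- tibble(
    time = ts, n_risk = n_risk, n_event = d_want, n_censor = n_censor,
    estimate = cif, std_err = NA_real_,
    conf_low = NA_real_, conf_high = NA_real_
  )
  new_chc_cuminc(tab, "aj", length(time), list(cause = cause))
}

#' Evaluate a cumulative-incidence curve at chosen ages
#'
#' The estimate is a right-continuous step function of time; the value "by
#' age `a`" is the step value at day `floor(a * 365.25)`.
#'
#' @param curve A `chc_cuminc` object.
#' @param ages Ages in years (may be fractional).
#' @return Tibble with `age`, `day`, `estimate` and `n_risk` (risk-set size
#'   just after that day).
#' @export
ci_at <- function(curve, ages) {
  if (!inherits(curve, "chc_cuminc")) abort("`curve` must be a chc_cuminc.")
  days <- floor(ages * DAYS_PER_YEAR)
  tab <- curve$table
  if (nrow(tab) == 0) {
    return(tibble(age = ages, day = days, estimate = 0, n_risk = curve$n))
  }
  idx <- findInterval(days, tab$time)
  est <- c(0, tab$estimate)[idx + 1]
  tibble(age = ages, day = days, estimate = est, n_risk = NA_integer_)
}

#' Report a curve on a whole-year age grid with interval counts
#'
#' @param curve A `chc_cuminc` object.
#' @param max_age Oldest age (years) to report.
#' @return Tibble with one row per age 0..`max_age`: `age`, `cum_inc`
#'   (estimate by that age), `n_events` (events during the preceding year of
#'   age; at age 0, events on day 0).
#' @export
incidence_table <- function(curve, max_age = 16) {
  if (!inherits(curve, "chc_cuminc")) abort("`curve` must be a chc_cuminc.")
  ages <- 0:max_age
  est <- ci_at(curve, ages)$estimate
  tab <- curve$table
  cuts <- years_to_days(ages)
  n_events <- vapply(seq_along(ages), function(i) {
    lo <- if (i == 1) -1 else cuts[i - 1]
    sum(tab$n_event[tab$time > lo & tab$time <= cuts[i]])
  }, numeric(1))
  tibble(age = ages, cum_inc = est, n_events = as.integer(n_events))
}

#' Paper-style pairing of adjacent birth cohorts
#'
#' @return Tibble with `pair`, `cohort` (member) and `horizon_years`, the
#'   shared follow-up horizon of the pair (16, 14, 12, 10, 8 years for the
#'   2002/3+2003/4 through 2010/11+2011/12 pairs).
#' @export
cohort_pairs <- function() {
  tibble(
    pair = rep(c(
      "2002/3-2003/4", "2004/5-2005/6", "2006/7-2007/8",
      "2008/9-2009/10", "2010/11-2011/12"
    ), each = 2),
    cohort = academic_year_labels(2002, 2011),
    horizon_years = rep(c(16, 14, 12, 10, 8), each = 2)
  )
}

#' Estimate cumulative incidence on pooled cohort pairs
#'
#' Pools the member cohorts' follow-up records and re-runs the estimator
#' (the curves are not averaged); each pair's reporting horizon is the
#' shorter of its members' horizons.
#'
#' @param followups A `chc_followup` tibble with a `cohort` column covering
#'   one analysis variant and subtype.
#' @param pairs Pair definition as from [cohort_pairs()].
#' @param estimator [km_cuminc()] (default) or [aj_cuminc()].
#' @return Named list of `chc_cuminc` objects, one per pair present in the
#'   data, each carrying `meta$pair` and `meta$horizon_years`.
#' @export
pair_cohorts <- function(followups, pairs = cohort_pairs(), estimator = km_cuminc) {
  validate_followups(followups)
  if (!"cohort" %in% names(followups)) abort("`followups` needs a `cohort` column.")
  for (col in c("variant", "subtype")) {
    if (col %in% names(followups) && length(unique(followups[[col]])) > 1) {
      abort(sprintf(
        "Follow-ups mix several values of `%s`; pair within one analysis.", col
      ))
    }
  }
  fu <- followups |> inner_join(pairs, by = "cohort")
  split(fu, fu$pair) |>
    lapply(function(d) {
      cur <- estimator(d)
      cur$meta$pair <- d$pair[1]
      cur$meta$horizon_years <- min(d$horizon_years)
      cur
    })
}

#' Mask small cells in a reported incidence table
#'
#' Disclosure control for published tables: ages whose interval event count
#' is below the threshold are masked (`cum_inc` and `n_events`
#' set to `NA`, `suppressed = TRUE`); if the table's total event count is
#' below the threshold the whole subtype is flagged as not reportable. The
#' underlying estimation is unaffected.
#'
#' @param table Tibble from [incidence_table()] (columns `age`, `cum_inc`,
#'   `n_events`).
#' @param threshold Minimum publishable event count (default 10).
#' @return The table with a `suppressed` column and masked cells; attribute
#'   `reportable` is `FALSE` when the whole series is below threshold.
#' @export
suppress_small <- function(table, threshold = 10) {
  stop_if_not_df(table, "table")
  if (threshold < 0) abort("`threshold` must be >= 0.")
  out <- table |>
    mutate(
      suppressed = .data$n_events < threshold,
      cum_inc = ifelse(.data$suppressed, NA_real_, .data$cum_inc),
      n_events = ifelse(.data$suppressed, NA_integer_, .data$n_events)
    )
  attr(out, "reportable") <- sum(table$n_events, na.rm = TRUE) >= threshold
  out
}
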