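#' Configuration for the synthetic linked-records generator
#'
#' Builds and validates the parameter set for [sim_chc_data()]. The generator
#' emulates the statistical structure of linked hospital/education records for
#' English birth cohorts: per-cohort birth counts, piecewise-constant
#' age-specific hazards of a first chronic-health-condition (CHC) record per
#' body-system subtype, child mortality, emigration (with cessation of all
#' records and an optional final non-England-domicile episode), immigration
#' (children with no birth record, at risk only from arrival), linkage failure
#' between the birth record and all later records, school-enrolment coverage,
#' and a background (non-CHC) admission process that can be correlated with
#' CHC status to emulate activity-related selection.
#'
#' All hazards are events per person-year on yearly age bands 0-15. Competing
#' events are drawn as independent exponential clocks per process, so the
#' ground-truth cumulative incidence is analytic: `1 - exp(-cumulative
#' hazard)` (see [truth_curve()]).
#'
#' @param seed Integer seed; [sim_chc_data()] uses it for all randomness.
#' @param cohorts Data frame with columns `cohort` (academic-year label,
#'   e.g. `"2002/3"`) and `n_births` (non-negative integer).
#' @param subtype_hazards Numeric matrix, 9 rows named by [chc_subtypes()],
#'   16 columns (ages 0-15), events per person-year.
#' @param mortality_hazard,emigration_hazard Numeric length-16 vectors.
#' @param immigration `NULL` for the default (a fraction `immigration_rate`
#'   of the cohort's births arriving at each age 1-15), or a data frame with
#'   columns `cohort`, `age`, `n`.
#' @param immigration_rate In-migrants per age year as a fraction of the
#'   cohort's birth count (used only when `immigration` is `NULL`).
#' @param linkage_failure_p Probability that a born child's later records all
#'   fail to link (birth record retained, everything after dropped).
#' @param enrol_p Probability a child present at school ages has school
#'   enrolment records.
#' @param background_rate Non-CHC admissions per person-year.
#' @param op_rate,ae_rate Outpatient / emergency contacts per person-year.
#' @param chc_activity_multiplier Multiplier on all activity rates for
#'   children with a CHC record (1 = no activity-CHC correlation).
#' @param domicile_record_p Probability an emigrant has one final episode with
#'   non-England domicile before disappearing from the data.
#' @param data_end Last calendar date on which any record can be generated.
#' @param staggered_availability If `TRUE`, outpatient activity exists only
#'   from 1 April 2004 and emergency activity only from 1 April 2007,
#'   mirroring the staggered start of those data sets.
#' @param subtype_codes Named character vector mapping each subtype to the
#'   ICD-10 code the generator records for it.
#' @param birth_code,background_code ICD-10 codes used for the birth episode
#'   and for background (non-CHC) admissions; neither should be on the code
#'   list.
#' @return A validated list of class `chc_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, cohorts = data.frame(
#'   cohort = "2002/3", n_births = 100
#' ))
sim_config <- function(seed = 1L,
                       cohorts = tibble(
                         cohort = academic_year_labels(2002, 2011),
                         n_births = 5000L
                       ),
                       subtype_hazards = default_subtype_hazards(),
                       mortality_hazard = c(0.004, rep(0.0002, 15)),
                       emigration_hazard = rep(0.005, 16),
                       immigration = NULL,
                       immigration_rate = 0.004,
                       linkage_failure_p = 0.05,
                       enrol_p = 0.97,
                       background_rate = 0.10,
                       op_rate = 0.15,
                       ae_rate = 0.10,
                       chc_activity_multiplier = 1,
                       domicile_record_p = 0.5,
                       data_end = as.Date("2019-08-31"),
                       staggered_availability = FALSE,
                       subtype_codes = default_subtype_codes(),
                       birth_code = "Z380",
                       background_code = "R104") {
  stop_if_not_df(cohorts, "cohorts")
  if (nrow(cohorts) == 0) abort("`cohorts` must contain at least one cohort.")
  if (!all(c("cohort", "n_births") %in% names(cohorts))) {
    abort("`cohorts` needs columns `cohort` and `n_births`.")
  }
  if (any(cohorts$n_births < 0) || any(cohorts$n_births != floor(cohorts$n_births))) {
    abort("`n_births` must be non-negative integers.")
  }
  subtype_hazards <- as.matrix(subtype_hazards)
  if (!identical(sort(rownames(subtype_hazards)), sort(chc_subtypes())) ||
    ncol(subtype_hazards) != 16) {
    abort("`subtype_hazards` must be a 9 x 16 matrix with rownames chc_subtypes().")
  }
  subtype_hazards <- subtype_hazards[chc_subtypes(), , drop = FALSE]
  for (nm in c("mortality_hazard", "emigration_hazard")) {
    v <- get(nm)
    if (length(v) != 16 || any(v < 0)) {
      abort(sprintf("`%s` must be a non-negative length-16 vector.", nm))
    }
  }
  if (any(subtype_hazards < 0)) abort("Hazards must be non-negative.")
  probs <- c(
    linkage_failure_p = linkage_failure_p, enrol_p = enrol_p,
    domicile_record_p = domicile_record_p
  )
  if (any(probs < 0 | probs > 1)) {
    abort("Probabilities must lie in [0, 1].")
  }
  if (any(c(background_rate, op_rate, ae_rate, immigration_rate) < 0) ||
    chc_activity_multiplier < 0) {
    abort("Rates and multipliers must be non-negative.")
  }
  if (is.null(immigration)) {
    immigration <- tidyr::crossing(
      cohorts[, c("cohort", "n_births")],
      age = 1:15
    ) |>
      mutate(n = as.integer(round(.data$n_births * immigration_rate))) |>
      select("cohort", "age", "n")
  } else {
    stop_if_not_df(immigration, "immigration")
    if (!all(c("cohort", "age", "n") %in% names(immigration))) {
      abort("`immigration` needs columns `cohort`, `age`, `n`.")
    }
    if (any(immigration$n < 0)) abort("Immigration counts must be >= 0.")
  }
  structure(
    list(
      seed = as.integer(seed),
      cohorts = as_tibble(cohorts[, c("cohort", "n_births")]),
      subtype_hazards = subtype_hazards,
      mortality_hazard = mortality_hazard,
      emigration_hazard = emigration_hazard,
      immigration = as_tibble(immigration),
      linkage_failure_p = linkage_failure_p,
      enrol_p = enrol_p,
      background_rate = background_rate,
      op_rate = op_rate,
      ae_rate = ae_rate,
      chc_activity_multiplier = chc_activity_multiplier,
      domicile_record_p = domicile_record_p,
      data_end = as.Date(data_end),
      staggered_availability = staggered_availability,
      subtype_codes = subtype_codes,
      birth_code = birth_code,
      background_code = background_code
    ),
    class = "chc_sim_config"
  )
}

#' Academic-year cohort labels
#'
#' @param from,to First calendar years of the first and last academic years.
#' @return Character vector such as `"2002/3" ... "2011/12"`.
#' @export
academic_year_labels <- function(from, to) {
  vapply(from:to, function(y) sprintf("%d/%d", y, (y + 1) %% 100), character(1))
}

# First calendar day (1 September) of an academic-year cohort label.
academic_year_start <- function(label) {
  y <- as.integer(sub("/.*$", "", label))
  if (anyNA(y)) abort(sprintf("Unparseable cohort label: %s", label[is.na(y)][1]))
  as.Date(sprintf("%d-09-01", y))
}

#' Default age profile of subtype hazards
#'
#' A 9 x 16 matrix of first-record hazards (events per person-year, ages
#' 0-15). Congenital-dominated groups (cardiovascular, neurological,
#' metabolic, respiratory) are infancy-heavy; mental-health/behavioural
#' hazard is concentrated at school ages; chronic infections are rare. The
#' implied any-CHC cumulative hazard to age 16 is about 0.32 (cumulative
#' incidence about 27%).
#'
#' @return Numeric matrix with rownames [chc_subtypes()].
#' @export
default_subtype_hazards <- function() {
  h <- rbind(
    "cancer/blood"              = c(0.003, rep(0.0012, 15)),
    "cardiovascular"            = c(0.008, rep(0.0008, 15)),
    "respiratory"               = c(0.010, rep(0.006, 4), rep(0.002, 11)),
    "neurological"              = c(0.010, rep(0.004, 4), rep(0.0022, 11)),
    "mental health/behavioural" = c(rep(0.0005, 5), rep(0.004, 11)),
    "metabolic and other"       = c(0.020, rep(0.008, 4), rep(0.003, 11)),
    "musculoskeletal/skin"      = rep(0.0011, 16),
    "chronic infections"        = rep(0.00012, 16),
    "non-specific"              = c(0.005, rep(0.0011, 15))
  )
  colnames(h) <- as.character(0:15)
  h
}

#' Default ICD-10 record code per subtype
#'
#' One representative code per body-system group, each resolvable against the
#' synthetic code list shipped in `inst/extdata`.
#'
#' @return Named character vector.
#' @export
default_subtype_codes <- function() {
  c(
    "cancer/blood" = "C910",
    "cardiovascular" = "Q211",
    "respiratory" = "J450",
    "neurological" = "G403",
    "mental health/behavioural" = "F840",
    "metabolic and other" = "K529",
    "musculoskeletal/skin" = "M080",
    "chronic infections" = "B181",
    "non-specific" = "R629"
  )
}

# Inverse-cumulative-hazard draw from a piecewise-constant hazard on yearly
# bands 0-15. Returns event day (floor(age_years * 365.25)); Inf if the event
# falls beyond age 16. `start_years` left-truncates the clock (immigrants).
draw_piecewise_exp <- function(n, rates, start_years = 0) {
  cum <- c(0, cumsum(rates))
  start_cum <- stats::approx(
    x = 0:16, y = cum, xout = pmin(start_years, 16), method = "linear",
    rule = 2
  )$y
  e <- start_cum + rexp(n)
  out <- rep(Inf, n)
  hit <- e < cum[17]
  if (any(hit)) {
    band <- findInterval(e[hit], cum, left.open = FALSE)
    band <- pmin(band, 16L)
    within <- (e[hit] - cum[band]) / rates[band]
    out[hit] <- floor(((band - 1) + within) * DAYS_PER_YEAR)
  }
  out
}

#' Generate synthetic linked child records with known ground truth
#'
#' Simulates every child's competing clocks (per-subtype CHC first records,
#' death, emigration) as independent exponentials on yearly age bands, then
#' materialises the record files the analysis pipeline consumes. Reproducible:
#' identical config and seed give identical output.
#'
#' Structural guarantees: every born child has a birth episode at day 0;
#' emigrants have no records after their emigration day except, with
#' probability `domicile_record_p`, one final episode with non-England
#' domicile; immigrants have no birth record and accrue risk only from
#' arrival; children failing linkage keep only their birth record; no record
#' is dated after `data_end` or after the child's death.
#'
#' @param config A `chc_sim_config` from [sim_config()].
#' @param seed Overrides `config$seed` if supplied.
#' @return List of class `chc_sim_data` with tibbles `births` (child_id,
#'   birth_date, cohort), `children` (all simulated children, including
#'   immigrants, with `immigrant` flag and `arrival_day`), `episodes`
#'   (child_id, day, date, domicile, diag_01...), `activity` (child_id, day,
#'   date, source APC/OP/AE), `enrolments`, `deaths`, the analytic `truth`
#'   curves, the `config`, and a `manifest` (seed, config hash, row counts).
#' @export
sim_chc_data <- function(config, seed = config$seed) {
  if (!inherits(config, "chc_sim_config")) {
    abort("`config` must be built with sim_config().")
  }
  withr::with_seed(as.integer(seed), sim_chc_data_impl(config, as.integer(seed)))
}

sim_chc_data_impl <- function(config, seed) {
  subtypes <- chc_subtypes()
  d16 <- years_to_days(16)

  born <- config$cohorts |>
    filter(.data$n_births > 0) |>
    mutate(start = academic_year_start(.data$cohort))
  born <- born[rep(seq_len(nrow(born)), born$n_births), c("cohort", "start")]
  n_born <- nrow(born)
  if (n_born == 0) abort("Configuration yields zero births.")
  born <- born |>
    mutate(
      child_id = sprintf("b%07d", seq_len(n_born)),
      birth_date = .data$start + floor(runif(n_born) * 365),
      immigrant = FALSE,
      arrival_day = 0L
    )

  imm <- config$immigration |> filter(.data$n > 0)
  if (nrow(imm) > 0) {
    imm <- imm[rep(seq_len(nrow(imm)), imm$n), c("cohort", "age")]
    n_imm <- nrow(imm)
    imm <- imm |>
      mutate(
        start = academic_year_start(.data$cohort),
        child_id = sprintf("m%07d", seq_len(n_imm)),
        birth_date = .data$start + floor(runif(n_imm) * 365),
        immigrant = TRUE,
        arrival_day = as.integer(floor((.data$age + runif(n_imm)) * DAYS_PER_YEAR))
      ) |>
      select(-"age")
  } else {
    imm <- born[0, c("cohort", "start")] |>
      mutate(
        child_id = character(0), birth_date = as.Date(character(0)),
        immigrant = logical(0), arrival_day = integer(0)
      )
  }

  ch <- bind_rows(
    born[, c("child_id", "cohort", "birth_date", "immigrant", "arrival_day")],
    imm[, c("child_id", "cohort", "birth_date", "immigrant", "arrival_day")]
  )
  n <- nrow(ch)
  arrival_years <- ch$arrival_day / DAYS_PER_YEAR

  death_day <- draw_piecewise_exp(n, config$mortality_hazard, arrival_years)
  emig_day <- draw_piecewise_exp(n, config$emigration_hazard, arrival_years)
  event_days <- vapply(
    subtypes,
    function(s) draw_piecewise_exp(n, config$subtype_hazards[s, ], arrival_years),
    numeric(n)
  )
  if (is.null(dim(event_days))) {
    event_days <- matrix(event_days, nrow = n, dimnames = list(NULL, subtypes))
  }

  data_end_day <- as.integer(config$data_end - ch$birth_date)
  # Last day (inclusive) a record can carry: alive, resident, inside the data
  # period, under 16.
  cap <- pmin(death_day, emig_day - 1, data_end_day, d16 - 1)

  observed_event <- event_days <= cap
  has_chc <- rowSums(observed_event) > 0
  mult <- ifelse(has_chc, config$chc_activity_multiplier, 1)
  exposure <- pmax(0, cap - ch$arrival_day + 1) / DAYS_PER_YEAR

  draw_contacts <- function(rate) {
    k <- rpois(n, rate * mult * exposure)
    idx <- rep.int(seq_len(n), k)
    if (length(idx) == 0) {
      return(tibble(child_id = character(0), day = integer(0)))
    }
    span <- cap[idx] - ch$arrival_day[idx] + 1
    tibble(
      child_id = ch$child_id[idx],
      day = as.integer(ch$arrival_day[idx] + floor(runif(length(idx)) * span))
    )
  }
  bg <- draw_contacts(config$background_rate)
  op <- draw_contacts(config$op_rate)
  ae <- draw_contacts(config$ae_rate)

  enrolled <- runif(n) < config$enrol_p
  enr <- tidyr::crossing(i = seq_len(n), age = 4:15) |>
    mutate(day = years_to_days(.data$age) + 30L) |>
    filter(
      enrolled[.data$i],
      .data$day >= ch$arrival_day[.data$i],
      .data$day <= cap[.data$i]
    ) |>
    transmute(child_id = ch$child_id[.data$i], day = .data$day)

  emig_recorded <- is.finite(emig_day) &
    emig_day <= pmin(death_day, data_end_day, d16 - 1) &
    emig_day >= ch$arrival_day &
    runif(n) < config$domicile_record_p

  ev_idx <- which(observed_event, arr.ind = TRUE)
  chc_rows <- tibble(
    child_id = ch$child_id[ev_idx[, 1]],
    day = as.integer(event_days[ev_idx]),
    code = unname(config$subtype_codes[subtypes[ev_idx[, 2]]]),
    domicile = "England"
  )

  episode_rows <- bind_rows(
    tibble(
      child_id = ch$child_id[!ch$immigrant], day = 0L,
      code = config$birth_code, domicile = "England"
    ),
    chc_rows,
    bg |> mutate(code = config$background_code, domicile = "England"),
    tibble(
      child_id = ch$child_id[emig_recorded],
      day = as.integer(emig_day[emig_recorded]),
      code = config$background_code, domicile = "non-England"
    )
  )

  link_fail <- !ch$immigrant & runif(n) < config$linkage_failure_p
  failed_ids <- ch$child_id[link_fail]
  drop_failed <- function(df) df |> filter(!(.data$child_id %in% failed_ids))

  episode_rows <- episode_rows |>
    filter(!(.data$child_id %in% failed_ids & .data$day > 0L))

  episodes <- episode_rows |>
    distinct(.data$child_id, .data$day, .data$domicile, .data$code) |>
    group_by(.data$child_id, .data$day, .data$domicile) |>
    arrange(.data$code, .by_group = TRUE) |>
    mutate(pos = sprintf("diag_%02d", row_number())) |>
    filter(row_number() <= 20) |>
    ungroup() |>
    tidyr::pivot_wider(names_from = "pos", values_from = "code", names_sort = TRUE)

  birth_lut <- setNames(ch$birth_date, ch$child_id)
  episodes <- episodes |>
    mutate(date = birth_lut[.data$child_id] + .data$day) |>
    arrange(.data$child_id, .data$day)

  activity <- bind_rows(
    episodes |>
      filter(.data$day > 0L) |>
      transmute(.data$child_id, .data$day, source = "APC"),
    op |> mutate(source = "OP") |> drop_failed(),
    ae |> mutate(source = "AE") |> drop_failed()
  ) |>
    mutate(date = birth_lut[.data$child_id] + .data$day)
  if (config$staggered_availability) {
    activity <- activity |>
      filter(
        .data$source != "OP" | .data$date >= as.Date("2004-04-01"),
        .data$source != "AE" | .data$date >= as.Date("2007-04-01")
      )
  }
  activity <- activity |> arrange(.data$child_id, .data$day, .data$source)

  enrolments <- enr |>
    drop_failed() |>
    mutate(date = birth_lut[.data$child_id] + .data$day) |>
    arrange(.data$child_id, .data$day)

  death_observed <- is.finite(death_day) &
    death_day <= pmin(emig_day - 1, data_end_day, d16 - 1) &
    death_day >= ch$arrival_day & !link_fail
  deaths <- tibble(
    child_id = ch$child_id[death_observed],
    day = as.integer(death_day[death_observed])
  ) |>
    mutate(date = birth_lut[.data$child_id] + .data$day) |>
    arrange(.data$child_id)

  truth <- bind_rows(lapply(c("any", subtypes), function(s) {
    truth_curve(config, s)
  }))

  # children carries the ground-truth clocks (including unrecorded deaths
  # and emigrations) so denominator truth is recoverable in tests.
  ch$true_death_day <- as.integer(ifelse(is.finite(death_day), death_day, NA_real_))
  ch$true_emig_day <- as.integer(ifelse(is.finite(emig_day), emig_day, NA_real_))

  out <- list(
    births = as_tibble(born[, c("child_id", "birth_date", "cohort")]),
    children = as_tibble(ch),
    episodes = episodes,
    activity = activity,
    enrolments = enrolments,
    deaths = deaths,
    truth = truth,
    config = config,
    manifest = list(
      seed = seed,
      config_hash = rlang::hash(unclass(config)),
      n_children = n,
      n_births = n_born,
      n_immigrants = n - n_born,
      n_episodes = nrow(episodes),
      n_activity = nrow(activity),
      n_enrolments = nrow(enrolments),
      n_deaths = nrow(deaths)
    )
  )
  class(out) <- "chc_sim_data"
  out
}

#' Analytic ground-truth cumulative incidence implied by a configuration
#'
#' Under the competing-exponential-clocks construction the probability of a
#' first record of subtype `s` by age `a` (treating death and emigration as
#' censoring) is `1 - exp(-sum of the subtype's hazards over ages < a)`. The
#' "any" curve uses the sum of all subtype hazards, because independent
#' competing clocks superpose.
#'
#' @param config A `chc_sim_config`.
#' @param subtype One of [chc_subtypes()] or `"any"`.
#' @return Tibble with `subtype`, `age` (0-16) and `cum_inc`.
#' @export
#' @examples
#' cfg <- sim_config(cohorts = data.frame(cohort = "2002/3", n_births = 10))
#' truth_curve(cfg, "any")
truth_curve <- function(config, subtype = "any") {
  if (!inherits(config, "chc_sim_config")) {
    abort("`config` must be built with sim_config().")
  }
  if (identical(subtype, "any")) {
    h <- colSums(config$subtype_hazards)
  } else if (subtype %in% chc_subtypes()) {
    h <- config$subtype_hazards[subtype, ]
  } else {
    abort(sprintf(
      "Unknown subtype %s; use 'any' or one of chc_subtypes().", sQuote(subtype)
    ))
  }
  tibble(
    subtype = subtype,
    age = 0:16,
    cum_inc = unname(1 - exp(-c(0, cumsum(h))))
  )
}

#' Write a synthetic data set to delimited files
#'
#' Writes the record tables of a [sim_chc_data()] result as CSV files plus a
#' plain-text manifest recording the seed and config hash.
#'
#' @param data A `chc_sim_data` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sim_data <- function(data, dir) {
  if (!inherits(data, "chc_sim_data")) abort("`data` must come from sim_chc_data().")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("births", "children", "episodes", "activity", "enrolments", "deaths", "truth")
  paths <- file.path(dir, paste0(tables, ".csv"))
  for (i in seq_along(tables)) {
    readr::write_csv(data[[tables[i]]], paths[i])
  }
  manifest <- file.path(dir, "manifest.txt")
  counts <- unlist(data$manifest[-(1:2)])
  writeLines(
    c(
      sprintf("seed: %d", data$manifest$seed),
      sprintf("config_hash: %s", data$manifest$config_hash),
      sprintf("%s: %d", names(counts), counts)
    ),
    manifest
  )
  invisible(c(paths, manifest))
}
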