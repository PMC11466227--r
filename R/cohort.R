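#' Assign birth dates to academic-year or financial-year cohorts
#'
#' Academic years run 1 September to 31 August (closed birth cohorts);
#' financial years run 1 April to 31 March (open cohorts). Labels take the
#' form `"2002/3"`, `"2011/12"`.
#'
#' @param birth_date Date vector.
#' @param type `"academic"` or `"financial"`.
#' @param range Optional integer vector `c(from, to)` of first calendar years
#'   of the allowed cohorts; dates outside it map to `NA` (out of scope).
#' @return Character vector of cohort labels.
#' @export
#' @examples
#' assign_cohort(as.Date(c("2002-09-01", "2003-08-31")))          # both 2002/3
#' assign_cohort(as.Date("2003-03-31"), type = "financial")       # 2002/3
assign_cohort <- function(birth_date, type = c("academic", "financial"),
                          range = NULL) {
  type <- match.arg(type)
  birth_date <- as.Date(birth_date)
  m <- as.integer(format(birth_date, "%m"))
  y <- as.integer(format(birth_date, "%Y"))
  cut <- if (type == "academic") 9L else 4L
  start_year <- ifelse(m >= cut, y, y - 1L)
  lab <- sprintf("%d/%d", start_year, (start_year + 1) %% 100)
  if (!is.null(range)) {
    lab[start_year < range[1] | start_year > range[2]] <- NA_character_
  }
  lab
}

#' Eligibility requirements for the main and sensitivity analyses
#'
#' Returns the requirement set for one of the eight analysis variants. Every
#' variant requires a hospital-recorded live birth. The main analysis
#' additionally requires any hospital activity before age 16 *or* a link to
#' school records; sensitivity variants 1-7 progressively vary the activity
#' and school-link requirements:
#' \itemize{
#'   \item s1: birth record only
#'   \item s2: birth + hospital activity before age 5
#'   \item s3: birth + hospital activity before age 16
#'   \item s4: birth + school (NPD) link
#'   \item s5: birth + hospital activity before 5 + school link
#'   \item s6: birth + hospital activity before 5 + activity age 5 to <16
#'   \item s7: as s6 + school link
#' }
#'
#' @param variant One of `"main"`, `"s1"` ... `"s7"`.
#' @return A list of class `chc_eligibility_spec` with logical fields
#'   `birth`, `hes_lt5`, `hes_5to16`, `hes_lt16`, `npd`, `hes_or_npd`.
#' @export
eligibility_spec <- function(variant = c("main", "s1", "s2", "s3", "s4", "s5", "s6", "s7")) {
  variant <- match.arg(variant)
  req <- switch(variant,
    main = list(hes_lt5 = FALSE, hes_5to16 = FALSE, hes_lt16 = FALSE, npd = FALSE, hes_or_npd = TRUE),
    s1 = list(hes_lt5 = FALSE, hes_5to16 = FALSE, hes_lt16 = FALSE, npd = FALSE, hes_or_npd = FALSE),
    s2 = list(hes_lt5 = TRUE, hes_5to16 = FALSE, hes_lt16 = FALSE, npd = FALSE, hes_or_npd = FALSE),
    s3 = list(hes_lt5 = FALSE, hes_5to16 = FALSE, hes_lt16 = TRUE, npd = FALSE, hes_or_npd = FALSE),
    s4 = list(hes_lt5 = FALSE, hes_5to16 = FALSE, hes_lt16 = FALSE, npd = TRUE, hes_or_npd = FALSE),
    s5 = list(hes_lt5 = TRUE, hes_5to16 = FALSE, hes_lt16 = FALSE, npd = TRUE, hes_or_npd = FALSE),
    s6 = list(hes_lt5 = TRUE, hes_5to16 = TRUE, hes_lt16 = FALSE, npd = FALSE, hes_or_npd = FALSE),
    s7 = list(hes_lt5 = TRUE, hes_5to16 = TRUE, hes_lt16 = FALSE, npd = TRUE, hes_or_npd = FALSE)
  )
  structure(c(list(variant = variant, birth = TRUE), req),
    class = "chc_eligibility_spec"
  )
}

#' Assemble per-child histories from linked record tables
#'
#' Joins births, inpatient episodes, hospital activity, school enrolments and
#' deaths into one row per born child, with the activity flags the
#' eligibility variants test, the death day, and the day of the first episode
#' with non-England domicile. Records dated after a child's death are a data
#' error and are rejected.
#'
#' @param births Tibble: `child_id`, `birth_date`, optional `cohort` (derived
#'   via [assign_cohort()] if absent).
#' @param episodes Tibble: `child_id`, `day`, `domicile` (optional; assumed
#'   England when absent), diagnosis columns.
#' @param activity Tibble of post-birth hospital contacts: `child_id`, `day`,
#'   `source` (`"APC"`, `"OP"`, `"AE"`). Eligibility treats all sources alike.
#' @param enrolments Tibble of school records: `child_id`, `day`.
#' @param deaths Tibble: `child_id`, `day`.
#' @return Tibble, one row per born child: `child_id`, `birth_date`,
#'   `cohort`, `hes_lt5`, `hes_5to16`, `hes_lt16`, `npd`, `death_day`,
#'   `emigration_day` (NA when absent).
#' @export
assemble_histories <- function(births, episodes, activity, enrolments, deaths) {
  stop_if_not_df(births, "births")
  for (nm in c("child_id", "birth_date")) {
    if (!nm %in% names(births)) abort(sprintf("`births` needs column `%s`.", nm))
  }
  d5 <- years_to_days(5)
  d16 <- years_to_days(16)

  deaths_by_child <- deaths |>
    arrange(.data$day) |>
    distinct(.data$child_id, .keep_all = TRUE) |>
    select("child_id", death_day = "day")

  late <- bind_rows(
    episodes |> select("child_id", "day"),
    activity |> select("child_id", "day"),
    enrolments |> select("child_id", "day")
  ) |>
    inner_join(deaths_by_child, by = "child_id") |>
    filter(.data$day > .data$death_day)
  if (nrow(late) > 0) {
    bad <- unique(late$child_id)
    abort(sprintf(
      "%d record(s) dated after death for child(ren): %s.",
      nrow(late), paste(head(bad, 5), collapse = ", ")
    ))
  }

  act_flags <- activity |>
    group_by(.data$child_id) |>
    summarise(
      hes_lt5 = any(.data$day > 0 & .data$day < d5),
      hes_5to16 = any(.data$day >= d5 & .data$day < d16),
      hes_lt16 = any(.data$day > 0 & .data$day < d16),
      .groups = "drop"
    )
  npd_flags <- enrolments |>
    distinct(.data$child_id) |>
    mutate(npd = TRUE)
  emig <- if ("domicile" %in% names(episodes)) {
    episodes |>
      filter(!is.na(.data$domicile), .data$domicile != "England") |>
      arrange(.data$day) |>
      distinct(.data$child_id, .keep_all = TRUE) |>
      select("child_id", emigration_day = "day")
  } else {
    tibble(child_id = character(0), emigration_day = integer(0))
  }

  out <- births |>
    select("child_id", "birth_date", any_of("cohort")) |>
    left_join(act_flags, by = "child_id") |>
    left_join(npd_flags, by = "child_id") |>
    left_join(deaths_by_child, by = "child_id") |>
    left_join(emig, by = "child_id") |>
    mutate(across(
      c("hes_lt5", "hes_5to16", "hes_lt16", "npd"),
      ~ tidyr::replace_na(.x, FALSE)
    ))
  if (!"cohort" %in% names(out)) {
    out$cohort <- assign_cohort(out$birth_date)
  }
  out
}

#' Apply an eligibility variant to assembled histories
#'
#' @param histories Tibble from [assemble_histories()].
#' @param spec A `chc_eligibility_spec` from [eligibility_spec()], or a
#'   variant name.
#' @return `histories` with logical `included` and character
#'   `exclusion_reason` (`NA` when included) columns, plus a `variant` column.
#' @export
apply_eligibility <- function(histories, spec = eligibility_spec("main")) {
  if (is.character(spec)) spec <- eligibility_spec(spec)
  stop_if_not_df(histories, "histories")
  h <- histories
  ok <- rep(TRUE, nrow(h))
  reason <- rep(NA_character_, nrow(h))
  fail <- function(ok, reason, cond, label) {
    newly <- ok & !cond
    reason[newly] <- label
    list(ok = ok & cond, reason = reason)
  }
  if (spec$hes_lt5) {
    r <- fail(ok, reason, h$hes_lt5, "no HES activity before age 5")
    ok <- r$ok; reason <- r$reason
  }
  if (spec$hes_5to16) {
    r <- fail(ok, reason, h$hes_5to16, "no HES activity age 5 to <16")
    ok <- r$ok; reason <- r$reason
  }
  if (spec$hes_lt16) {
    r <- fail(ok, reason, h$hes_lt16, "no HES activity before age 16")
    ok <- r$ok; reason <- r$reason
  }
  if (spec$npd) {
    r <- fail(ok, reason, h$npd, "no NPD link")
    ok <- r$ok; reason <- r$reason
  }
  if (spec$hes_or_npd) {
    r <- fail(ok, reason, h$hes_lt16 | h$npd, "no HES activity before 16 and no NPD link")
    ok <- r$ok; reason <- r$reason
  }
  h |>
    mutate(variant = spec$variant, included = ok, exclusion_reason = reason)
}

#' Build per-child follow-up with event and censoring per analysis rules
#'
#' Follow-up runs from birth to the earliest of: the first chronic-condition
#' record (of the requested subtype), death, the first non-England-domicile
#' episode, the 16th birthday, or the administrative end of the data. An
#' event on the same day as death, emigration or the administrative end
#' counts as an event (birth-episode events at day 0 must be countable); an
#' event on or after the day of the 16th birthday is out of window.
#'
#' @param histories Tibble from [assemble_histories()], optionally filtered by
#'   [apply_eligibility()] (rows with `included == FALSE` are dropped).
#' @param events Tibble from [extract_chc_events()].
#' @param subtype `"any"` or one of [chc_subtypes()].
#' @param admin_end Administrative end of follow-up (date).
#' @return Tibble of class `chc_followup`: `child_id`, `cohort`, `time`
#'   (days), `event` (logical), `reason` (one of `"death"`,
#'   `"non-England domicile"`, `"16th birthday"`, `"administrative end"`,
#'   `NA` for events), `subtype`, and `variant` if present in `histories`.
#' @export
build_followup <- function(histories, events, subtype = "any",
                           admin_end = as.Date("2019-08-31")) {
  stop_if_not_df(histories, "histories")
  if (!identical(subtype, "any") && !subtype %in% chc_subtypes()) {
    abort(sprintf("Unknown subtype %s.", sQuote(subtype)))
  }
  h <- histories
  if ("included" %in% names(h)) h <- h |> filter(.data$included)
  ev <- if (identical(subtype, "any")) {
    first_chc_events(events)
  } else {
    events |> filter(.data$subtype == !!subtype)
  }
  ev <- ev |> select("child_id", event_day = "age_days")

  d16 <- as.integer(add_years(h$birth_date, 16) - h$birth_date)
  admin_day <- as.integer(as.Date(admin_end) - h$birth_date)
  if (any(admin_day < 0)) {
    abort("Some births fall after `admin_end`: negative follow-up.")
  }
  big <- .Machine$integer.max
  death <- ifelse(is.na(h$death_day), big, h$death_day)
  emig <- ifelse(is.na(h$emigration_day), big, h$emigration_day)
  censor_time <- pmin(death, emig, d16, admin_day)
  reason <- dplyr::case_when(
    censor_time == death ~ "death",
    censor_time == emig ~ "non-England domicile",
    censor_time == d16 ~ "16th birthday",
    TRUE ~ "administrative end"
  )

  out <- h |>
    select("child_id", "cohort", any_of("variant")) |>
    mutate(
      censor_time = censor_time, reason = reason, d16 = d16
    ) |>
    left_join(ev, by = "child_id") |>
    mutate(
      event = !is.na(.data$event_day) &
        .data$event_day <= .data$censor_time &
        .data$event_day < .data$d16,
      time = as.integer(ifelse(.data$event, .data$event_day, .data$censor_time)),
      reason = ifelse(.data$event, NA_character_, .data$reason),
      subtype = !!subtype
    ) |>
    select(-"censor_time", -"event_day", -"d16")
  if (any(out$time < 0)) abort("Negative follow-up time: data error.")
  class(out) <- c("chc_followup", class(out))
  out
}
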