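#' Count distinct body-system subtypes recorded before a landmark age
#'
#' "By age X" means strictly before the Xth birthday: a subtype counts if its
#' first record falls at `age_days < X * 365.25`. Repeat records within a
#' subtype never add to the count.
#'
#' @param events Tibble from [extract_chc_events()].
#' @param landmark_age Landmark in years.
#' @param include_unreported Whether subtypes excluded from curve reporting
#'   (chronic infections) still count toward multimorbidity (default `TRUE`:
#'   the reporting exclusion is presentational).
#' @return Tibble with `child_id` and `n_subtypes` (children with zero
#'   subtypes by the landmark do not appear).
#' @export
subtype_count <- function(events, landmark_age, include_unreported = TRUE) {
  stop_if_not_df(events, "events")
  ev <- events
  if (!include_unreported) {
    ev <- ev |> filter(.data$subtype != "chronic infections")
  }
  ev |>
    filter(.data$age_days < years_to_days(landmark_age)) |>
    distinct(.data$child_id, .data$subtype) |>
    count(.data$child_id, name = "n_subtypes")
}

#' Multimorbidity summary at landmark ages
#'
#' Among children with at least one body-system subtype recorded by the
#' landmark age, the proportion with more than one. Children with no subtype
#' are excluded from the denominator. When `children` is supplied, the
#' summary is restricted to (and grouped by the cohorts of) those children —
#' typically the main-analysis eligible population.
#'
#' @param events Tibble from [extract_chc_events()].
#' @param landmarks Landmark ages in years (default 5, 11, 16).
#' @param children Optional tibble with `child_id` and optionally `cohort`;
#'   restricts the population and adds a `cohort` column to the output.
#' @param max_age Follow-up horizon in years available for this population;
#'   landmarks beyond it are an error.
#' @param include_unreported Passed to [subtype_count()].
#' @return Tibble with (optional `cohort`,) `landmark_age`, `n_ge1`, `n_ge2`
#'   and `prop_multimorbid` = `n_ge2 / n_ge1`.
#' @export
multimorbidity_summary <- function(events, landmarks = c(5, 11, 16),
                                   children = NULL, max_age = 16,
                                   include_unreported = TRUE) {
  stop_if_not_df(events, "events")
  if (any(landmarks > max_age)) {
    abort(sprintf(
      "Landmark age %g exceeds the cohort's follow-up horizon (%g years).",
      max(landmarks), max_age
    ))
  }
  ev <- events
  cohorts <- NULL
  if (!is.null(children)) {
    stop_if_not_df(children, "children")
    ev <- ev |> semi_join(children, by = "child_id")
    if ("cohort" %in% names(children)) {
      cohorts <- children |> select("child_id", "cohort")
    }
  }
  one <- function(lm) {
    counts <- subtype_count(ev, lm, include_unreported = include_unreported)
    if (!is.null(cohorts)) {
      counts |>
        inner_join(cohorts, by = "child_id") |>
        group_by(.data$cohort) |>
        summarise(
          landmark_age = lm,
          n_ge1 = sum(.data$n_subtypes >= 1),
          n_ge2 = sum(.data$n_subtypes >= 2),
          .groups = "drop"
        )
    } else {
      tibble(
        landmark_age = lm,
        n_ge1 = sum(counts$n_subtypes >= 1),
        n_ge2 = sum(counts$n_subtypes >= 2)
      )
    }
  }
  purrr::map(landmarks, one) |>
    list_rbind() |>
    mutate(
      prop_multimorbid = ifelse(.data$n_ge1 > 0, .data$n_ge2 / .data$n_ge1, NA_real_)
    )
}
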