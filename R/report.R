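#' Derived linkage-rate percentages per birth cohort
#'
#' From per-cohort counts of national live births, hospital-recorded births
#' and study-included children, computes the three derived percentages of the
#' linkage table: hospital births as a share of live births, included
#' children as a share of live births, and included children as a share of
#' hospital births — each rounded half-up to one decimal place.
#'
#' Included children exceeding hospital births, or hospital births exceeding
#' live births, trigger a warning (inclusion requires a hospital birth
#' record); zero denominators give `NA` percentages.
#'
#' @param counts Data frame with columns `cohort`, `live_births`,
#'   `hes_births`, `included`.
#' @return Tibble adding `pct_hes_of_live`, `pct_included_of_live`,
#'   `pct_included_of_hes`.
#' @export
#' @examples
#' linkage_rates(data.frame(
#'   cohort = "2002/3", live_births = 565709,
#'   hes_births = 533406, included = 423456
#' ))
linkage_rates <- function(counts) {
  stop_if_not_df(counts, "counts")
  need <- c("cohort", "live_births", "hes_births", "included")
  if (!all(need %in% names(counts))) {
    abort(sprintf("`counts` needs columns %s.", paste(need, collapse = ", ")))
  }
  if (any(counts[c("live_births", "hes_births", "included")] < 0)) {
    abort("Counts must be non-negative.")
  }
  if (any(counts$included > counts$hes_births)) {
    warn("Some cohorts have more included children than hospital-recorded births.")
  }
  if (any(counts$hes_births > counts$live_births)) {
    warn("Some cohorts have more hospital-recorded births than live births.")
  }
  pct <- function(num, den) {
    ifelse(den > 0, round_half_up(100 * num / den, 1), NA_real_)
  }
  counts |>
    as_tibble() |>
    mutate(
      pct_hes_of_live = pct(.data$hes_births, .data$live_births),
      pct_included_of_live = pct(.data$included, .data$live_births),
      pct_included_of_hes = pct(.data$included, .data$hes_births)
    )
}

#' Published per-cohort birth and inclusion counts
#'
#' The per-cohort counts of live births in England, hospital-recorded births
#' and main-analysis included children for the 2002/3-2011/12 academic-year
#' cohorts, shipped with the package as plain CSV.
#'
#' @return Tibble with `cohort`, `live_births`, `hes_births`, `included`.
#' @export
linkage_counts <- function() {
  path <- system.file("extdata", "table3_linkage_counts.csv",
    package = "chcincidence"
  )
  readr::read_csv(path, col_types = "ciii")
}

#' Run the full estimation pipeline on one data set
#'
#' Orchestrates phenotype ascertainment, history assembly, eligibility,
#' closed-cohort estimation across the requested variants, the open-cohort
#' estimator, and the multimorbidity summary, on either a synthetic data set
#' (supply a `chc_sim_config`) or pre-loaded record tables.
#'
#' @param config A `chc_sim_config` (the data are generated with
#'   [sim_chc_data()]) or a `chc_sim_data` object.
#' @param code_list A `chc_codelist`; defaults to the synthetic list shipped
#'   with the package.
#' @param variants Analysis variants to run (subset of main, s1-s7).
#' @param subtype Subtype analysed in the survival stages (default `"any"`).
#' @param admin_end Administrative end of follow-up.
#' @param suppression_threshold Cell-suppression threshold for reported
#'   tables.
#' @param out_dir Optional directory: when given, all output tables are
#'   written there as CSV along with a plain-text manifest.
#' @return List with `events`, `histories`, `followups` (per variant),
#'   `closed` (per-variant `chc_cuminc`), `closed_tables` (suppressed
#'   whole-year tables), `open` (per-cohort `chc_open_cuminc`),
#'   `multimorbidity`, `stage_counts` and `manifest`.
#' @export
run_chc_pipeline <- function(config,
                             code_list = read_code_list(system.file("extdata",
                               "chc_codelist_synthetic.csv",
                               package = "chcincidence"
                             )),
                             variants = c("main", paste0("s", 1:7)),
                             subtype = "any",
                             admin_end = as.Date("2019-08-31"),
                             suppression_threshold = 10,
                             out_dir = NULL) {
  data <- if (inherits(config, "chc_sim_config")) sim_chc_data(config) else config
  if (!inherits(data, "chc_sim_data")) {
    abort("`config` must be a chc_sim_config or chc_sim_data.")
  }
  variants <- match.arg(variants, c("main", paste0("s", 1:7)), several.ok = TRUE)

  events <- extract_chc_events(data$episodes, code_list)
  histories <- assemble_histories(
    data$births, data$episodes, data$activity, data$enrolments, data$deaths
  )
  inform(sprintf(
    "Ascertainment: %d episodes -> %d subtype events in %d children.",
    nrow(data$episodes), nrow(events), dplyr::n_distinct(events$child_id)
  ))

  followups <- lapply(setNames(variants, variants), function(v) {
    elig <- apply_eligibility(histories, eligibility_spec(v))
    fu <- build_followup(elig, events, subtype = subtype, admin_end = admin_end)
    inform(sprintf(
      "Variant %s: %d/%d children included, %d events.",
      v, sum(elig$included), nrow(elig), sum(fu$event)
    ))
    fu
  })
  closed <- lapply(followups, km_cuminc)
  closed_tables <- lapply(closed, function(cur) {
    suppress_small(incidence_table(cur), threshold = suppression_threshold)
  })

  # Open estimator: external denominators from the simulated resident truth
  # (children alive and in England at each age), per financial-year cohort.
  first_ev <- first_chc_events(events)
  pop <- resident_population(data)
  open_cases <- count_incident_by_age(first_ev, data$children)
  open <- lapply(
    setNames(unique(open_cases$cohort), unique(open_cases$cohort)),
    function(co) {
      cs <- open_cases |> filter(.data$cohort == co)
      pp <- pop |> filter(.data$cohort == co)
      # ages past the cohort's data horizon have zero population and no cases
      grid <- intersect(pp$age[pp$population > 0], cs$age)
      if (length(grid) == 0) {
        return(NULL)
      }
      open_cuminc(
        cs |> filter(.data$age %in% grid),
        pp |> filter(.data$age %in% grid) |> select("age", "population")
      )
    }
  )
  open <- open[!vapply(open, is.null, logical(1))]

  main_children <- apply_eligibility(histories, eligibility_spec("main")) |>
    filter(.data$included) |>
    select("child_id", "cohort")
  multimorbidity <- multimorbidity_summary(
    events,
    landmarks = c(5, 11, 16), children = main_children
  )

  stage_counts <- tibble(
    stage = c("episodes", "events", "histories", "included_main"),
    n = c(nrow(data$episodes), nrow(events), nrow(histories), nrow(main_children))
  )
  manifest <- list(
    seed = data$manifest$seed,
    config_hash = data$manifest$config_hash,
    variants = variants,
    subtype = subtype,
    admin_end = as.character(admin_end),
    stage_counts = stage_counts
  )
  out <- list(
    events = events, histories = histories, followups = followups,
    closed = closed, closed_tables = closed_tables, open = open,
    multimorbidity = multimorbidity, stage_counts = stage_counts,
    manifest = manifest
  )
  if (!is.null(out_dir)) write_pipeline_output(out, out_dir)
  out
}

#' Mid-year resident population implied by a synthetic data set
#'
#' Counts, per financial-year birth cohort and year of age, the simulated
#' children truly resident in England (arrived, not dead, not emigrated —
#' including *unrecorded* deaths and emigrations, which an external national
#' estimate would capture but the record files do not) at the middle of that
#' age year. This is the synthetic analogue of an external mid-year
#' population estimate series.
#'
#' @param data A `chc_sim_data` object.
#' @return Tibble with `cohort` (financial year), `age`, `population`.
#' @export
resident_population <- function(data) {
  if (!inherits(data, "chc_sim_data")) abort("`data` must come from sim_chc_data().")
  ch <- data$children |>
    mutate(cohort_fy = assign_cohort(.data$birth_date, type = "financial"))
  data_end_day <- as.integer(data$config$data_end - ch$birth_date)
  purrr::map(0:15, function(a) {
    mid <- years_to_days(a + 0.5)
    present <- (is.na(ch$true_death_day) | ch$true_death_day > mid) &
      (is.na(ch$true_emig_day) | ch$true_emig_day > mid) &
      ch$arrival_day <= mid &
      mid <= data_end_day
    tibble(cohort = ch$cohort_fy, present = present) |>
      group_by(.data$cohort) |>
      summarise(age = a, population = sum(.data$present), .groups = "drop")
  }) |>
    list_rbind() |>
    arrange(.data$cohort, .data$age)
}

write_pipeline_output <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(out$multimorbidity, file.path(dir, "multimorbidity.csv"))
  readr::write_csv(out$stage_counts, file.path(dir, "stage_counts.csv"))
  closed <- purrr::imap(out$closed_tables, function(tab, v) {
    tab |> mutate(variant = v, .before = 1)
  }) |> list_rbind()
  readr::write_csv(closed, file.path(dir, "closed_incidence.csv"))
  open <- purrr::imap(out$open, function(tab, co) {
    tab |> mutate(cohort = co, .before = 1)
  }) |> list_rbind()
  readr::write_csv(open, file.path(dir, "open_incidence.csv"))
  writeLines(
    c(
      sprintf("seed: %s", out$manifest$seed),
      sprintf("config_hash: %s", out$manifest$config_hash),
      sprintf("variants: %s", paste(out$manifest$variants, collapse = ",")),
      sprintf("subtype: %s", out$manifest$subtype),
      sprintf("admin_end: %s", out$manifest$admin_end)
    ),
    file.path(dir, "manifest.txt")
  )
  invisible(dir)
}
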