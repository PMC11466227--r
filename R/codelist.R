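#' Normalise a raw ICD-10 code
#'
#' Upper-cases, strips dots, and truncates to at most four characters, so
#' `"k52.9"` and `"K529"` are the same code. Idempotent. Codes that do not
#' match the ICD-10 pattern (a letter, two digits, optionally one further
#' alphanumeric) after normalisation raise an error unless `strict = FALSE`,
#' in which case they become `NA`.
#'
#' @param raw Character vector of raw ICD-10 codes.
#' @param strict If `TRUE` (default) invalid codes raise an error; if `FALSE`
#'   they are returned as `NA`.
#' @return Character vector of normalised codes (3 or 4 characters).
#' @export
#' @examples
#' normalize_icd10(c("k52.9", "J450X", "K529"))
normalize_icd10 <- function(raw, strict = TRUE) {
  if (length(raw) == 0) return(character(0))
  x <- toupper(gsub(".", "", as.character(raw), fixed = TRUE))
  x <- trimws(x)
  x <- substr(x, 1, 4)
  ok <- is_valid_icd10(x)
  if (strict && any(!ok, na.rm = TRUE)) {
    bad <- unique(raw[!ok & !is.na(ok)])
    abort(sprintf(
      "Invalid ICD-10 code(s) after normalisation: %s.",
      paste(sQuote(head(bad, 5)), collapse = ", ")
    ))
  }
  x[!ok] <- NA_character_
  x
}

#' Test whether a string is a normalised ICD-10 code
#'
#' @param x Character vector.
#' @return Logical vector: letter + two digits + optional alphanumeric.
#' @export
is_valid_icd10 <- function(x) {
  grepl("^[A-Z][0-9]{2}[A-Z0-9]?$", x)
}

#' Read a chronic-health-condition code list
#'
#' Reads a code-list CSV with columns `code`, `description`, `group` (one row
#' per ICD-10 code; header required), normalises the codes and canonicalises
#' the body-system group labels. Entries may be 3- or 4-character codes; code
#' *ranges* are not supported — each row is a single code.
#'
#' @param path Path to the CSV file.
#' @return A tibble of class `chc_codelist` with columns `code` (normalised),
#'   `description`, `subtype` (canonical label from [chc_subtypes()]).
#' @export
#' @examples
#' path <- system.file("extdata", "chc_codelist_synthetic.csv",
#'   package = "chcincidence"
#' )
#' read_code_list(path)
read_code_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("Code-list file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("code", "description", "group")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort(sprintf(
      "Code-list file must have columns %s; missing: %s.",
      paste(need, collapse = ", "), paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(raw) == 0) {
    warn("Code list is empty (header only).")
    out <- tibble(
      code = character(0), description = character(0), subtype = character(0)
    )
    class(out) <- c("chc_codelist", class(out))
    return(out)
  }
  norm <- toupper(gsub(".", "", trimws(raw$code), fixed = TRUE))
  norm <- substr(norm, 1, 4)
  bad <- which(!is_valid_icd10(norm))
  if (length(bad)) {
    abort(sprintf(
      "Malformed ICD-10 code at row %d: %s (after normalisation %s).",
      bad[1] + 1L, sQuote(raw$code[bad[1]]), sQuote(norm[bad[1]])
    ))
  }
  dup <- norm[duplicated(norm)]
  if (length(dup)) {
    abort(sprintf(
      "Duplicate normalised code(s) in list: %s.",
      paste(sQuote(unique(dup)), collapse = ", ")
    ))
  }
  out <- tibble(
    code = norm,
    description = raw$description,
    subtype = canonicalize_subtype(raw$group)
  )
  class(out) <- c("chc_codelist", class(out))
  out
}

#' Match normalised diagnosis codes against a code list
#'
#' A record code matches a list entry if it equals the entry exactly, or if
#' the record code's 3-character truncation equals a 3-character list entry
#' (so a more specific record code matches a whole-category list entry). A
#' 3-character record code never matches a 4-character list entry. Where both
#' an exact 4-character entry and a 3-character prefix entry match, the more
#' specific (4-character) entry wins.
#'
#' @param code Character vector of normalised ICD-10 codes.
#' @param code_list A `chc_codelist` from [read_code_list()].
#' @return Character vector of subtype labels, `NA` where no entry matches.
#' @export
match_code <- function(code, code_list) {
  stop_if_not_df(code_list, "code_list")
  exact <- setNames(code_list$subtype, code_list$code)
  three <- code_list$code[nchar(code_list$code) == 3]
  prefix <- setNames(code_list$subtype[nchar(code_list$code) == 3], three)
  out <- unname(exact[code])
  need_prefix <- is.na(out) & !is.na(code) & nchar(code) == 4
  out[need_prefix] <- unname(prefix[substr(code[need_prefix], 1, 3)])
  out
}

# Identify the diag_01 ... diag_20-style columns of an episode table.
diag_columns <- function(episodes) {
  cols <- grep("^diag_[0-9]+$", names(episodes), value = TRUE)
  if (length(cols) == 0) {
    abort("Episode table has no `diag_NN` diagnosis columns.")
  }
  if (length(cols) > 20) {
    abort(sprintf(
      "Episode table has %d diagnosis columns; at most 20 positions are allowed.",
      length(cols)
    ))
  }
  cols
}

#' Extract incident chronic-health-condition events from inpatient episodes
#'
#' Scans every diagnosis position of every episode (primary and secondary
#' positions are treated identically) against the code list and returns, per
#' child and body-system subtype, the first recorded instance — including
#' birth episodes at day 0. Input order is irrelevant; non-matching codes are
#' skipped.
#'
#' @param episodes Data frame with a child identifier column (`child_id`), an
#'   integer day offset since birth (`day`), and diagnosis columns
#'   `diag_01` ... `diag_20` (any subset; blanks/`NA` allowed beyond the first).
#' @param code_list A `chc_codelist` from [read_code_list()].
#' @return A tibble with one row per (child, subtype): `child_id`, `subtype`,
#'   `age_days` (minimum matching episode day), `code` (the matched record
#'   code at that age; ties broken alphabetically).
#' @export
extract_chc_events <- function(episodes, code_list) {
  stop_if_not_df(episodes, "episodes")
  if (!all(c("child_id", "day") %in% names(episodes))) {
    abort("`episodes` must have columns `child_id` and `day`.")
  }
  if (any(episodes$day < 0, na.rm = TRUE)) {
    abort("Episode `day` offsets must be >= 0.")
  }
  cols <- diag_columns(episodes)
  long <- episodes |>
    select(all_of(c("child_id", "day", cols))) |>
    tidyr::pivot_longer(all_of(cols), names_to = "position", values_to = "raw") |>
    filter(!is.na(.data$raw), .data$raw != "")
  if (nrow(long) == 0) {
    return(tibble(
      child_id = character(0), subtype = character(0),
      age_days = integer(0), code = character(0)
    ))
  }
  long$code <- normalize_icd10(long$raw, strict = FALSE)
  long$subtype <- match_code(long$code, code_list)
  long |>
    filter(!is.na(.data$subtype)) |>
    group_by(.data$child_id, .data$subtype) |>
    arrange(.data$day, .data$code, .by_group = TRUE) |>
    summarise(
      age_days = as.integer(.data$day[1]), code = .data$code[1],
      .groups = "drop"
    )
}

#' First chronic-health-condition event of any subtype per child
#'
#' Collapses subtype-level events to the single earliest event per child
#' (the "any CHC" event).
#'
#' @param events Tibble from [extract_chc_events()].
#' @return Tibble with one row per child: `child_id`, `age_days`, `subtype`
#'   and `code` of the earliest event (subtype ties at the same day broken
#'   alphabetically).
#' @export
first_chc_events <- function(events) {
  stop_if_not_df(events, "events")
  if (nrow(events) == 0) {
    return(tibble(
      child_id = character(0), age_days = integer(0),
      subtype = character(0), code = character(0)
    ))
  }
  events |>
    group_by(.data$child_id) |>
    arrange(.data$age_days, .data$subtype, .by_group = TRUE) |>
    summarise(
      age_days = .data$age_days[1], subtype = .data$subtype[1],
      code = .data$code[1], .groups = "drop"
    )
}
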