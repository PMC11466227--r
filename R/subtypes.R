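#' Body-system subtype groups for chronic health conditions
#'
#' The nine body-system groups used to classify chronic-health-condition
#' (CHC) ICD-10 codes. The "metabolic and other" group spans metabolic,
#' endocrine, digestive, renal and genitourinary conditions.
#'
#' @return Character vector of the nine canonical subtype labels.
#' @export
#' @examples
#' chc_subtypes()
chc_subtypes <- function() {
  c(
    "cancer/blood",
    "cardiovascular",
    "respiratory",
    "neurological",
    "mental health/behavioural",
    "metabolic and other",
    "musculoskeletal/skin",
    "chronic infections",
    "non-specific"
  )
}

# Accepted spellings of each subtype label (lower-cased, for canonicalisation).
subtype_aliases <- function() {
  list(
    "cancer/blood" = c("cancer/blood", "cancer and blood", "cancer_blood"),
    "cardiovascular" = "cardiovascular",
    "respiratory" = "respiratory",
    "neurological" = c("neurological", "neurology"),
    "mental health/behavioural" = c(
      "mental health/behavioural", "mental health/behavioral",
      "mental health and behavioural", "mental_health_behavioural"
    ),
    "metabolic and other" = c(
      "metabolic and other", "metabolic-and-other", "metabolic_and_other",
      "metabolic/endocrine/digestive/renal/genitourinary"
    ),
    "musculoskeletal/skin" = c(
      "musculoskeletal/skin", "musculoskeletal and skin", "musculoskeletal_skin"
    ),
    "chronic infections" = c("chronic infections", "chronic_infections"),
    "non-specific" = c("non-specific", "non specific", "nonspecific", "non_specific")
  )
}

#' Canonicalise a body-system subtype label
#'
#' Maps common spellings (case, separators, the long form of the metabolic
#' group) onto the canonical labels of [chc_subtypes()].
#'
#' @param x Character vector of subtype labels.
#' @return Character vector of canonical labels.
#' @export
#' @examples
#' canonicalize_subtype("Metabolic/endocrine/digestive/renal/genitourinary")
canonicalize_subtype <- function(x) {
  aliases <- subtype_aliases()
  lut <- unlist(lapply(names(aliases), function(canon) {
    setNames(rep(canon, length(aliases[[canon]])), aliases[[canon]])
  }))
  key <- trimws(tolower(x))
  out <- unname(lut[key])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    abort(sprintf(
      "Unknown subtype label(s): %s. Allowed labels: %s.",
      paste(sQuote(bad), collapse = ", "),
      paste(sQuote(chc_subtypes()), collapse = ", ")
    ))
  }
  out
}
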