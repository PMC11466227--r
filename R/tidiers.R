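#' Tidy a cumulative-incidence fit
#'
#' @param x A `chc_cuminc` object.
#' @param ... Unused.
#' @return The per-event-time step table as a tibble.
#' @export
tidy.chc_cuminc <- function(x, ...) {
  x$table
}

#' One-row summary of a cumulative-incidence fit
#'
#' @param x A `chc_cuminc` object.
#' @param ... Unused.
#' @return Tibble with estimator type, numbers at entry, events, and the
#'   final (largest observed event time) estimate.
#' @export
glance.chc_cuminc <- function(x, ...) {
  tibble(
    type = x$type,
    n = x$n,
    n_events = x$n_events,
    final_estimate = if (nrow(x$table)) x$table$estimate[nrow(x$table)] else 0
  )
}

#' @export
print.chc_cuminc <- function(x, ...) {
  label <- if (x$type == "km") {
    "One-minus-product-limit cumulative incidence"
  } else {
    sprintf("Aalen-Johansen cumulative incidence (cause: %s)",
      x$meta$cause %||% "chc"
    )
  }
  cat(label, "\n", sep = "")
  cat(sprintf(
    "  n = %d, events = %d, final estimate = %.4f\n",
    x$n, x$n_events,
    if (nrow(x$table)) x$table$estimate[nrow(x$table)] else 0
  ))
  if (!is.null(x$meta$pair)) {
    cat(sprintf(
      "  cohort pair %s, horizon %d years\n",
      x$meta$pair, x$meta$horizon_years
    ))
  }
  invisible(x)
}

#' @export
print.chc_sim_data <- function(x, ...) {
  cat("Synthetic linked child records\n")
  cat(sprintf(
    "  %d children (%d born in data, %d immigrants)\n",
    x$manifest$n_children, x$manifest$n_births, x$manifest$n_immigrants
  ))
  cat(sprintf(
    "  %d episodes, %d activity rows, %d enrolments, %d deaths\n",
    x$manifest$n_episodes, x$manifest$n_activity,
    x$manifest$n_enrolments, x$manifest$n_deaths
  ))
  cat(sprintf("  seed %d, config hash %s\n", x$manifest$seed, x$manifest$config_hash))
  invisible(x)
}
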