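#' Step plot of a closed-cohort cumulative-incidence curve
#'
#' Draws the estimate as a right-continuous step function of age with
#' horizontal guides at 10%, 20% and 25%, echoing the conventional
#' presentation of childhood chronic-condition incidence curves.
#'
#' @param object A `chc_cuminc` object.
#' @param guides Horizontal guide positions (proportions).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chc_cuminc <- function(object, guides = c(0.10, 0.20, 0.25), ...) {
  df <- object$table |>
    mutate(age = .data$time / DAYS_PER_YEAR)
  df <- dplyr::bind_rows(tibble(age = 0, estimate = 0), df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$estimate)) +
    ggplot2::geom_hline(
      yintercept = guides, linetype = "dashed", colour = "grey70"
    ) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(
      x = "Age (years)", y = "Cumulative incidence",
      title = if (object$type == "km") {
        "Cumulative incidence (one minus product-limit)"
      } else {
        "Cumulative incidence (competing-risk)"
      }
    ) +
    ggplot2::theme_minimal()
}

#' Step plot of an open-cohort cumulative-incidence curve
#'
#' @param object A `chc_open_cuminc` tibble.
#' @param guides Horizontal guide positions (proportions).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chc_open_cuminc <- function(object, guides = c(0.10, 0.20, 0.25), ...) {
  df <- tibble(age = c(0, object$age + 1), cum_inc = c(0, object$cum_inc))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$cum_inc)) +
    ggplot2::geom_hline(
      yintercept = guides, linetype = "dashed", colour = "grey70"
    ) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(
      x = "Age (years)", y = "Cumulative incidence",
      title = "Open-cohort cumulative incidence (1 - exp(-integrated hazard))"
    ) +
    ggplot2::theme_minimal()
}

#' Compare cumulative incidence across eligibility variants
#'
#' @param curves Named list of `chc_cuminc` objects (names = variant labels).
#' @param age Age (years) at which to compare.
#' @return A ggplot bar chart of the estimate by variant.
#' @export
plot_variant_comparison <- function(curves, age = 16) {
  df <- purrr::imap(curves, function(cur, v) {
    tibble(variant = v, estimate = ci_at(cur, age)$estimate)
  }) |> list_rbind()
  df$variant <- factor(df$variant, levels = df$variant)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variant, y = .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(
      x = "Eligibility variant", y = sprintf("Cumulative incidence by age %g", age)
    ) +
    ggplot2::theme_minimal()
}
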