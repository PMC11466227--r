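fu <- function(time, event, reason = NULL) {
  out <- tibble::tibble(time = time, event = event)
  if (!is.null(reason)) out$reason <- reason
  out
}

test_that("product-limit estimator reproduces hand-computed examples", {
  # 4 children, events at 100 and 200, two censored late: empirical 0.5
  k <- km_cuminc(fu(c(100, 200, 5844, 5844), c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(k$table$estimate[nrow(k$table)], 0.5, tolerance = 1e-12)

  # all censored: identically zero
  k0 <- km_cuminc(fu(c(10, 20), c(FALSE, FALSE)))
  expect_equal(nrow(k0$table), 0)
  expect_equal(ci_at(k0, c(1, 16))$estimate, c(0, 0))

  # events {2}, censored {1, 3}: risk set at 2 is {2, 3} so CI = 0.5
  k1 <- km_cuminc(fu(c(1, 2, 3), c(FALSE, TRUE, FALSE)))
  expect_equal(k1$table$estimate, 0.5, tolerance = 1e-12)
  expect_equal(k1$table$n_risk, 2L)

  expect_error(km_cuminc(fu(numeric(0), logical(0))), "At least one")
  expect_error(km_cuminc(fu(-1, TRUE)), "non-negative")
})

test_that("product-limit estimator agrees with the risk-set oracle and survival::survfit", {
  skip_if_not_installed("survival")
  withr::with_seed(11, {
    for (rep in 1:25) {
      n <- sample(2:40, 1)
      time <- sample(1:15, n, replace = TRUE)
      event <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (!any(event)) event[1] <- TRUE
      k <- km_cuminc(fu(time, event))
      o <- km_oracle(time, event)
      expect_equal(k$table$time, o$time)
      expect_equal(k$table$estimate, o$estimate, tolerance = 1e-12)
      sf <- survival::survfit(survival::Surv(time, event) ~ 1)
      sf_est <- 1 - sf$surv[sf$n.event > 0]
      expect_equal(k$table$estimate, sf_est, tolerance = 1e-12)
    }
  })
})

test_that("with no censoring before the horizon the curve is the empirical CDF", {
  withr::with_seed(12, {
    for (rep in 1:10) {
      n <- sample(2:8, 1)
      time <- sample(1:6, n, replace = TRUE)
      k <- km_cuminc(fu(time, rep(TRUE, n)))
      ecdf_vals <- vapply(k$table$time, function(t) mean(time <= t), numeric(1))
      expect_equal(k$table$estimate, ecdf_vals, tolerance = 1e-12)
    }
  })
})

test_that("estimator is invariant to input order and dataset duplication", {
  withr::with_seed(13, {
    time <- sample(1:50, 30, replace = TRUE)
    event <- sample(c(TRUE, FALSE), 30, replace = TRUE)
  })
  base <- km_cuminc(fu(time, event))
  shuf <- sample(30)
  expect_equal(km_cuminc(fu(time[shuf], event[shuf]))$table, base$table)
  doubled <- km_cuminc(fu(rep(time, 2), rep(event, 2)))
  expect_equal(doubled$table$estimate, base$table$estimate, tolerance = 1e-12)
})

test_that("competing-risk estimator matches hand calculation and dominates correctly", {
  # child 1: CHC at day 10; child 2: death at day 5
  f <- fu(c(10, 5), c(TRUE, FALSE), reason = c(NA, "death"))
  aj <- aj_cuminc(f)
  expect_equal(aj$table$estimate[nrow(aj$table)], 0.5, tolerance = 1e-12)
  km <- km_cuminc(f) # death treated as plain censoring
  expect_equal(km$table$estimate[nrow(km$table)], 1.0, tolerance = 1e-12)

  # no deaths: the two estimators coincide exactly
  f2 <- fu(c(3, 7, 9, 12), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(aj_cuminc(f2)$table$estimate, km_cuminc(f2)$table$estimate,
    tolerance = 1e-15
  )
})

test_that("competing-risk estimator agrees with survival's multi-state estimator", {
  skip_if_not_installed("survival")
  withr::with_seed(14, {
    for (rep in 1:10) {
      n <- sample(10:60, 1)
      time <- sample(1:20, n, replace = TRUE)
      status <- sample(0:2, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
      f <- tibble::tibble(
        time = time, event = status == 1,
        reason = ifelse(status == 2, "death", NA_character_)
      )
      aj <- aj_cuminc(f)
      st <- factor(status, levels = 0:2, labels = c("censor", "chc", "death"))
      sf <- survival::survfit(survival::Surv(time, st) ~ 1)
      ref_t <- sf$time[rowSums(sf$n.event) > 0]
      ref <- sf$pstate[rowSums(sf$n.event) > 0, which(sf$states == "chc")]
      got <- c(0, aj$table$estimate)[findInterval(ref_t, aj$table$time) + 1]
      expect_equal(got, ref, tolerance = 1e-10)
    }
  })
})

test_that("cause-specific incidences sum below one", {
  withr::with_seed(15, {
    time <- sample(1:30, 200, replace = TRUE)
    status <- sample(0:2, 200, replace = TRUE)
  })
  f <- tibble::tibble(
    time = time, event = status == 1,
    reason = ifelse(status == 2, "death", NA_character_)
  )
  chc <- aj_cuminc(f, cause = "chc")
  death <- aj_cuminc(f, cause = "death")
  grid <- sort(unique(time)) / 365.25
  total <- ci_at(chc, grid)$estimate + ci_at(death, grid)$estimate
  expect_true(all(total <= 1 + 1e-12))
})

test_that("cohort pairing pools follow-ups rather than averaging curves", {
  f1 <- fu(c(10, 20, 30), c(TRUE, TRUE, FALSE)) |>
    dplyr::mutate(child_id = paste0("a", 1:3), cohort = "2002/3")
  f2 <- fu(c(10, 40), c(TRUE, FALSE)) |>
    dplyr::mutate(child_id = paste0("b", 1:2), cohort = "2003/4")
  pooled <- pair_cohorts(dplyr::bind_rows(f1, f2))
  expect_named(pooled, "2002/3-2003/4")
  expect_equal(pooled[[1]]$meta$horizon_years, 16)
  direct <- km_cuminc(dplyr::bind_rows(f1, f2))
  expect_equal(pooled[[1]]$table, direct$table)

  # pooling two identical cohorts leaves the curve unchanged
  f2b <- f1 |> dplyr::mutate(cohort = "2003/4")
  same <- pair_cohorts(dplyr::bind_rows(f1, f2b))[[1]]
  expect_equal(same$table$estimate, km_cuminc(f1)$table$estimate, tolerance = 1e-12)

  late <- fu(c(5, 6), c(TRUE, TRUE)) |>
    dplyr::mutate(child_id = c("c1", "c2"), cohort = "2010/11")
  expect_equal(pair_cohorts(late)[[1]]$meta$horizon_years, 8)

  mixed <- dplyr::bind_rows(
    f1 |> dplyr::mutate(variant = "main"),
    f2 |> dplyr::mutate(variant = "s1")
  )
  expect_error(pair_cohorts(mixed), "mix")
})

test_that("small-cell suppression masks cells without touching estimation", {
  tab <- tibble::tibble(
    age = 0:3, cum_inc = c(0.01, 0.02, 0.03, 0.04), n_events = c(50L, 3L, 0L, 12L)
  )
  none <- suppress_small(tab, threshold = 0)
  expect_false(any(none$suppressed))
  expect_true(attr(none, "reportable"))

  some <- suppress_small(tab, threshold = 10)
  expect_equal(some$suppressed, c(FALSE, TRUE, TRUE, FALSE))
  expect_true(is.na(some$cum_inc[2]))
  expect_equal(some$cum_inc[1], 0.01)
  expect_true(attr(some, "reportable"))

  all_masked <- suppress_small(tab, threshold = 1000)
  expect_true(all(all_masked$suppressed))
  expect_false(attr(all_masked, "reportable"))
})

test_that("tidy, glance, autoplot and the year-grid report behave", {
  k <- km_cuminc(fu(c(100, 400, 800, 5000), c(TRUE, TRUE, FALSE, FALSE)))
  expect_s3_class(tidy(k), "tbl_df")
  g <- glance(k)
  expect_equal(g$n, 4L)
  expect_equal(g$n_events, 2L)
  expect_s3_class(autoplot(k), "ggplot")
  tab <- incidence_table(k, max_age = 3)
  expect_equal(tab$age, 0:3)
  expect_equal(sum(tab$n_events), 2L)
  expect_true(all(diff(tab$cum_inc) >= 0))
  expect_output(print(k), "product-limit")
})
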