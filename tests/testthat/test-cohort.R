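test_that("academic and financial cohort assignment honour the year boundaries", {
  expect_equal(assign_cohort(as.Date("2002-09-01")), "2002/3")
  expect_equal(assign_cohort(as.Date("2003-08-31")), "2002/3")
  expect_equal(assign_cohort(as.Date("2011-09-01")), "2011/12")
  expect_equal(assign_cohort(as.Date("2003-03-31"), type = "financial"), "2002/3")
  expect_equal(assign_cohort(as.Date("2003-04-01"), type = "financial"), "2003/4")
  expect_equal(
    assign_cohort(as.Date("2001-05-01"), range = c(2002, 2011)),
    NA_character_
  )
  expect_equal(academic_year_labels(2009, 2011), c("2009/10", "2010/11", "2011/12"))
})

test_that("the eight eligibility variants match a brute-force truth table", {
  flags <- tidyr::crossing(
    hes_lt5 = c(TRUE, FALSE), hes_5to16 = c(TRUE, FALSE), npd = c(TRUE, FALSE)
  ) |>
    dplyr::mutate(
      child_id = sprintf("c%d", dplyr::row_number()),
      birth_date = as.Date("2003-01-01"),
      cohort = "2002/3",
      hes_lt16 = hes_lt5 | hes_5to16,
      death_day = NA_integer_, emigration_day = NA_integer_
    )
  # independent statement of the inclusion rules, written from the published
  # requirements table
  oracle <- function(v, f) {
    switch(v,
      main = f$hes_lt16 | f$npd,
      s1 = TRUE,
      s2 = f$hes_lt5,
      s3 = f$hes_lt16,
      s4 = f$npd,
      s5 = f$hes_lt5 & f$npd,
      s6 = f$hes_lt5 & f$hes_5to16,
      s7 = f$hes_lt5 & f$hes_5to16 & f$npd
    )
  }
  for (v in c("main", paste0("s", 1:7))) {
    got <- apply_eligibility(flags, eligibility_spec(v))
    want <- vapply(seq_len(nrow(flags)), function(i) oracle(v, flags[i, ]), logical(1))
    expect_equal(got$included, want, info = v)
    expect_true(all(is.na(got$exclusion_reason[got$included])))
    expect_true(all(!is.na(got$exclusion_reason[!got$included])))
  }
})

test_that("published example children fall on the right side of each variant", {
  birth_only <- make_history("a", "2003-01-01", hes_lt5 = FALSE, npd = FALSE) |>
    dplyr::mutate(hes_5to16 = FALSE, hes_lt16 = FALSE)
  expect_false(apply_eligibility(birth_only, "main")$included)
  expect_true(apply_eligibility(birth_only, "s1")$included)

  npd_only <- birth_only |> dplyr::mutate(npd = TRUE)
  expect_true(apply_eligibility(npd_only, "main")$included)
  expect_true(apply_eligibility(npd_only, "s4")$included)
  expect_false(apply_eligibility(npd_only, "s2")$included)

  # one outpatient contact at age 6 and nothing else
  op6 <- birth_only |>
    dplyr::mutate(hes_5to16 = TRUE, hes_lt16 = TRUE)
  expect_true(apply_eligibility(op6, "main")$included)
  expect_true(apply_eligibility(op6, "s3")$included)
  expect_false(apply_eligibility(op6, "s2")$included)
  expect_false(apply_eligibility(op6, "s6")$included)
})

test_that("eligibility variants nest on synthetic data", {
  d <- sim_chc_data(sim_config(
    seed = 31,
    cohorts = data.frame(cohort = c("2002/3", "2007/8"), n_births = 1500L)
  ))
  h <- assemble_histories(d$births, d$episodes, d$activity, d$enrolments, d$deaths)
  inc <- lapply(
    setNames(c("main", paste0("s", 1:7)), c("main", paste0("s", 1:7))),
    function(v) h$child_id[apply_eligibility(h, v)$included]
  )
  expect_true(all(inc$s7 %in% inc$s6))
  expect_true(all(inc$s6 %in% inc$s2))
  expect_true(all(inc$s2 %in% inc$s1))
  expect_true(all(inc$s3 %in% inc$main))
  expect_true(all(inc$s4 %in% inc$main))
  expect_true(all(inc$s5 %in% inc$s2), info = "s5 requires HES<5")
  expect_setequal(inc$s1, h$child_id)
})

test_that("follow-up endpoint is the earliest of event, death, domicile change, 16th birthday, data end", {
  ev <- tibble::tibble(
    child_id = "a", subtype = "respiratory", age_days = 0L, code = "J450"
  )
  # event on the birth episode
  fu <- build_followup(make_history("a", "2003-01-01"), ev)
  expect_true(fu$event)
  expect_equal(fu$time, 0L)
  expect_true(is.na(fu$reason))

  # death at age 3, no event
  fu <- build_followup(make_history("b", "2003-01-01", death_day = 1096L), ev)
  expect_false(fu$event)
  expect_equal(fu$time, 1096L)
  expect_equal(fu$reason, "death")

  # born 1 Sep 2003: reaches the 16th birthday just after the data end
  fu <- build_followup(make_history("c", "2003-09-01"), ev)
  expect_equal(fu$reason, "administrative end")
  expect_equal(fu$time, as.integer(as.Date("2019-08-31") - as.Date("2003-09-01")))

  # born 31 Aug 2003: 16th birthday (31 Aug 2019) coincides with the data end;
  # death priority ordering never applies, the birthday is reached
  fu <- build_followup(make_history("c2", "2003-08-31"), ev)
  expect_equal(fu$reason, "16th birthday")
  expect_equal(fu$time, as.integer(as.Date("2019-08-31") - as.Date("2003-08-31")))

  # born 1 Sep 2011: censored at the data end around age 8
  fu <- build_followup(make_history("d", "2011-09-01"), ev)
  expect_equal(fu$reason, "administrative end")
  expect_equal(fu$time, as.integer(as.Date("2019-08-31") - as.Date("2011-09-01")))
  expect_lt(fu$time / 365.25, 8.01)

  # domicile change censors at the first qualifying episode
  fu <- build_followup(make_history("e", "2003-01-01", emigration_day = 500L), ev)
  expect_equal(fu$reason, "non-England domicile")
  expect_equal(fu$time, 500L)
})

test_that("same-day ties: events beat death/domicile/data end but not the 16th birthday", {
  ev_at <- function(day) {
    tibble::tibble(child_id = "a", subtype = "respiratory", age_days = day, code = "J450")
  }
  h_death <- make_history("a", "2003-01-01", death_day = 400L)
  fu <- build_followup(h_death, ev_at(400L))
  expect_true(fu$event)
  expect_equal(fu$time, 400L)

  h <- make_history("a", "2003-01-01")
  d16 <- as.integer(as.Date("2019-01-01") - as.Date("2003-01-01"))
  fu <- build_followup(h, ev_at(d16))
  expect_false(fu$event)
  expect_equal(fu$reason, "16th birthday")
  fu <- build_followup(h, ev_at(d16 - 1L))
  expect_true(fu$event)
})

test_that("histories assemble flags from activity windows and reject records after death", {
  births <- tibble::tibble(
    child_id = c("a", "b"), birth_date = as.Date(c("2003-01-01", "2003-02-01"))
  )
  episodes <- make_episodes(c("a", "b"), c(0L, 0L), list("Z380", "Z380"))
  episodes$domicile <- "England"
  activity <- tibble::tibble(
    child_id = c("a", "b"), day = c(2200L, 100L), source = c("OP", "APC")
  )
  enrolments <- tibble::tibble(child_id = "a", day = 1830L)
  deaths <- tibble::tibble(child_id = "b", day = 150L)
  h <- assemble_histories(births, episodes, activity, enrolments, deaths)
  a <- h[h$child_id == "a", ]
  expect_false(a$hes_lt5)
  expect_true(a$hes_5to16 && a$hes_lt16 && a$npd)
  b <- h[h$child_id == "b", ]
  expect_true(b$hes_lt5)
  expect_equal(b$death_day, 150L)

  bad_activity <- dplyr::bind_rows(
    activity, tibble::tibble(child_id = "b", day = 200L, source = "APC")
  )
  expect_error(
    assemble_histories(births, episodes, bad_activity, enrolments, deaths),
    "after death"
  )
})

test_that("every included child yields exactly one bounded follow-up and tallies reconcile", {
  d <- sim_chc_data(sim_config(
    seed = 32, cohorts = data.frame(cohort = "2002/3", n_births = 2000L)
  ))
  ev <- extract_chc_events(d$episodes, synthetic_code_list())
  h <- assemble_histories(d$births, d$episodes, d$activity, d$enrolments, d$deaths)
  for (v in c("main", "s1", "s7")) {
    elig <- apply_eligibility(h, v)
    fu <- build_followup(elig, ev)
    expect_equal(nrow(fu), sum(elig$included))
    expect_equal(anyDuplicated(fu$child_id), 0)
    expect_true(all(fu$time >= 0 & fu$time <= 5844))
    expect_equal(sum(fu$event) + sum(table(fu$reason)), sum(elig$included))
  }
})
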