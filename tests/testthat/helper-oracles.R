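# Independent oracles and fixture builders used across tests.

# Exhaustive risk-set product-limit oracle: direct definition, plain loops,
# no shared code with km_cuminc().
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event]))
  s <- 1
  est <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_t <- 0
    d_t <- 0
    for (j in seq_along(time)) {
      if (time[j] >= ts[i]) n_t <- n_t + 1
      if (time[j] == ts[i] && event[j]) d_t <- d_t + 1
    }
    s <- s * (1 - d_t / n_t)
    est[i] <- 1 - s
  }
  data.frame(time = ts, estimate = est)
}

# Cause-1 Aalen-Johansen oracle by direct definition (status 0/1/2).
aj_oracle <- function(time, status) {
  ts <- sort(unique(time[status > 0]))
  s_prev <- 1
  cif <- 0
  est <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_t <- sum(time >= ts[i])
    d1 <- sum(time == ts[i] & status == 1)
    d2 <- sum(time == ts[i] & status == 2)
    cif <- cif + s_prev * d1 / n_t
    s_prev <- s_prev * (1 - (d1 + d2) / n_t)
    est[i] <- cif
  }
  data.frame(time = ts, estimate = est)
}

# Proportion multimorbid among those with >= 1 subtype, from independent
# per-subtype cumulative incidences p (closed form under independence).
multimorbid_closed_form <- function(p) {
  p_none <- prod(1 - p)
  p_exactly_one <- sum(vapply(seq_along(p), function(i) {
    p[i] * prod(1 - p[-i])
  }, numeric(1)))
  (1 - p_none - p_exactly_one) / (1 - p_none)
}

synthetic_code_list <- function() {
  read_code_list(system.file("extdata", "chc_codelist_synthetic.csv",
    package = "chcincidence"
  ))
}

# Minimal single-subtype hazard matrix.
one_subtype_hazards <- function(subtype = "respiratory", rate = 0.02) {
  hz <- matrix(0, 9, 16, dimnames = list(chc_subtypes(), 0:15))
  hz[subtype, ] <- rate
  hz
}

no_immigration <- function() {
  data.frame(cohort = character(0), age = integer(0), n = integer(0))
}

# Write a code-list CSV fixture and return its path.
write_codelist_csv <- function(rows, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "codelist.csv")
  readr::write_csv(rows, path)
  path
}

# Episode-table fixture builder: one row per episode, codes as a list column
# flattened into diag_01, diag_02, ...
make_episodes <- function(child_id, day, codes) {
  k <- max(lengths(codes))
  mat <- t(vapply(codes, function(cs) c(cs, rep(NA_character_, k - length(cs))),
    character(k)
  ))
  out <- data.frame(child_id = child_id, day = day, stringsAsFactors = FALSE)
  for (i in seq_len(k)) out[[sprintf("diag_%02d", i)]] <- mat[, i]
  out
}

# Bare history rows for follow-up tests.
make_history <- function(child_id, birth_date,
                         death_day = NA_integer_, emigration_day = NA_integer_,
                         hes_lt5 = TRUE, hes_5to16 = TRUE, npd = TRUE) {
  tibble::tibble(
    child_id = child_id,
    birth_date = as.Date(birth_date),
    cohort = assign_cohort(as.Date(birth_date)),
    hes_lt5 = hes_lt5, hes_5to16 = hes_5to16,
    hes_lt16 = hes_lt5 | hes_5to16, npd = npd,
    death_day = death_day, emigration_day = emigration_day
  )
}
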