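test_that("waning leaves the relative rate intact until after onset", {
  w <- waning_exponential(onset_week = 260, half_life_weeks = 52)
  expect_equal(waning_relative_rate(0.48, 100, waning_none()), 0.48)
  expect_equal(waning_relative_rate(0.48, 260, w), 0.48)
  expect_equal(waning_relative_rate(0.48, 260 + 52, w), exp(log(0.48) / 2))
  expect_equal(waning_relative_rate(0.48, 260 + 104, w), exp(log(0.48) / 4))
  # immediate loss of effect in the zero-half-life limit
  w0 <- waning_exponential(260, 0)
  expect_equal(waning_relative_rate(0.48, 261, w0), 1)
  # essentially no waning in the long-half-life limit
  winf <- waning_exponential(260, 1e9)
  expect_equal(waning_relative_rate(0.48, 1000, winf), 0.48, tolerance = 1e-6)
  expect_error(waning_relative_rate(0, 1, w), "positive")
  expect_error(waning_relative_rate(-2, 1, w), "positive")
})

test_that("transition matrices are row-stochastic with absorbing death", {
  draw <- point_estimates(published_ps)
  for (strategy in cea_strategies()) {
    for (week in c(0, 57, 259)) {
      m <- build_transition_matrix(draw, strategy, week, settings_5y,
                                   published_ps$life_table)
      expect_equal(unname(rowSums(m)), rep(1, 5), tolerance = 1e-12)
      expect_true(all(m >= 0 & m <= 1))
      expect_equal(unname(m["dead", ]), c(0, 0, 0, 0, 1))
      # exacerbation states last one cycle: no self-loops, no cross-flows
      expect_equal(unname(m["ocs", c("ocs", "ed", "hosp")]), c(0, 0, 0))
    }
  }
})

test_that("sampled-parameter matrices stay valid across many draws", {
  draws <- sample_parameters(published_ps, n = 40, seed = 3)
  for (i in seq_len(nrow(draws))) {
    m <- build_transition_matrix(draws[i, ], "bt", 12, settings_5y,
                                 published_ps$life_table)
    expect_equal(unname(rowSums(m)), rep(1, 5), tolerance = 1e-12)
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("degenerate inputs give degenerate transitions", {
  d <- draw_null()
  m <- build_transition_matrix(d, "standard", 0, settings_5y, lt_no_mortality())
  expect_equal(unname(m["free", ]), c(1, 0, 0, 0, 0))
  expect_equal(unname(m["hosp", "free"]), 1)
})

test_that("hospitalization death risk applies on the single hospitalized cycle", {
  d <- point_estimates(published_ps)
  d$death_risk_hosp <- 0.02
  m <- build_transition_matrix(d, "standard", 0, settings_5y, lt_no_mortality())
  expect_equal(unname(m["hosp", "dead"]), 0.02)
  expect_equal(unname(m["hosp", "free"]), 0.98)
})

test_that("competing-risk allocation matches a numerical cause-specific oracle", {
  # oracle: integrate the cause-specific incidence over the cycle on a fine
  # grid, under constant hazards acting simultaneously
  d <- point_estimates(published_ps)
  h <- c(ocs = 1.35, ed = 0.07, hosp = 0.06) / 52
  h_bg <- -log(1 - 0.002) / 52
  H <- sum(h) + h_bg
  tt <- seq(0, 1, length.out = 20001)
  surv <- exp(-H * tt)
  p_ocs_oracle <- h[["ocs"]] * sum((surv[-1] + surv[-length(surv)]) / 2) * diff(tt)[1]
  m <- build_transition_matrix(d, "standard", 0, settings_5y,
                               published_ps$life_table)
  expect_equal(unname(m["free", "ocs"]), p_ocs_oracle, tolerance = 1e-8)
  expect_equal(unname(m["free", "ocs"]), 0.0256, tolerance = 1e-3)
})

test_that("discounted QALYs follow the geometric series in the null model", {
  d <- draw_null(u_free = 1)
  out <- run_cohort(d, "standard", settings_5y, lt_no_mortality())
  expected <- sum((1 / 52) * 1.03^(-(0:259) / 52))
  expect_equal(out$qalys, expected, tolerance = 1e-12)
  expect_equal(expected, 4.65, tolerance = 1e-2)
  expect_equal(out$total_exacerbations, 0)
  expect_equal(out$prop_dead, 0)
})

test_that("a zero-week horizon produces all-zero outcomes", {
  d <- point_estimates(published_ps)
  out <- run_cohort(d, "bt", model_settings(horizon_weeks = 0),
                    published_ps$life_table)
  expect_equal(out$qalys, 0)
  expect_equal(out$total_exacerbations, 0)
  expect_equal(out$prop_dead, 0)
  expect_equal(out$cost, 14900)  # upfront cost is charged at entry
})

test_that("cohort trace conserves mass and is monotone where required", {
  d <- point_estimates(published_ps)
  out <- run_cohort(d, "bt", settings_short, published_ps$life_table,
                    trace = TRUE)
  tr <- attr(out, "trace")
  occ <- tr$free + tr$ocs + tr$ed + tr$hosp + tr$dead
  expect_equal(occ, rep(1, nrow(tr)), tolerance = 1e-12)
  expect_true(all(diff(tr$dead) >= 0))
  expect_true(all(diff(cumsum(tr$inc_ocs + tr$inc_ed + tr$inc_hosp)) >= 0))
  expect_true(all(diff(tr$cum_cost) >= 0))
  expect_true(all(diff(tr$cum_qalys) >= 0))
})

test_that("outcomes are monotone in the horizon", {
  d <- point_estimates(published_ps)
  horizons <- c(26, 52, 104, 260)
  outs <- purrr::map_dfr(horizons, function(h) {
    run_cohort(d, "standard", model_settings(horizon_weeks = h),
               published_ps$life_table)
  })
  expect_true(all(diff(outs$cost) > 0))
  expect_true(all(diff(outs$qalys) > 0))
  expect_true(all(diff(outs$prop_dead) > 0))
  expect_true(all(diff(outs$total_exacerbations) > 0))
})

test_that("a treatment with null effects reproduces standard-therapy clinical outcomes", {
  d <- point_estimates(published_ps)
  d$rr_bt_ocs <- d$rr_bt_ed <- d$rr_bt_hosp <- 1
  d$utility_delta_bt <- 0
  std <- run_cohort(d, "standard", settings_5y, published_ps$life_table)
  bt <- run_cohort(d, "bt", settings_5y, published_ps$life_table)
  expect_equal(bt$qalys, std$qalys, tolerance = 1e-12)
  expect_equal(bt$total_exacerbations, std$total_exacerbations, tolerance = 1e-12)
  expect_equal(bt$prop_dead, std$prop_dead, tolerance = 1e-12)
  # costs differ exactly by the upfront payment (same drug costs)
  expect_equal(bt$cost - std$cost, 14900, tolerance = 1e-9)
})

test_that("waning configurations bracket the constant-effect results", {
  ps <- published_ps
  s_none <- model_settings(horizon_weeks = 520)
  s_inf <- model_settings(horizon_weeks = 520,
                          waning = waning_exponential(260, 1e9))
  s_zero <- model_settings(horizon_weeks = 520,
                           waning = waning_exponential(260, 0))
  d <- point_estimates(ps)
  bt_none <- run_cohort(d, "bt", s_none, ps$life_table)
  bt_inf <- run_cohort(d, "bt", s_inf, ps$life_table)
  bt_zero <- run_cohort(d, "bt", s_zero, ps$life_table)
  expect_equal(bt_inf$total_exacerbations, bt_none$total_exacerbations,
               tolerance = 1e-4)
  # with the effect lost right after onset, event counts approach the
  # standard-therapy profile over the post-onset years
  std <- run_cohort(d, "standard", s_none, ps$life_table)
  expect_gt(bt_zero$total_exacerbations, bt_none$total_exacerbations)
  expect_lt(bt_zero$total_exacerbations, std$total_exacerbations)
})

test_that("batch and single-draw cohort runs agree", {
  draws <- sample_parameters(published_ps, n = 5, seed = 21)
  batch <- run_cohort(draws, "omalizumab", settings_short, published_ps$life_table)
  for (i in seq_len(5)) {
    single <- run_cohort(draws[i, ], "omalizumab", settings_short,
                         published_ps$life_table)
    expect_equal(batch[i, ], single, tolerance = 1e-12)
  }
})
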