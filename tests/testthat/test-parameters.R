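test_that("bundled parameter set carries the published point estimates", {
  pe <- point_estimates(published_ps)
  expect_equal(pe$rate_ocs, 1.35)
  expect_equal(pe$rate_ed, 0.07)
  expect_equal(pe$rr_bt_ocs, 0.48)
  expect_equal(pe$rr_omalizumab_hosp, 0.49)
  expect_equal(pe$cost_drug_omalizumab, 22700)
  expect_equal(pe$cost_bt_upfront, 14900)
  expect_equal(pe$utility_free, 0.67)
  expect_equal(pe$utility_hosp, 0.33)
  # no sampling: identical on repeated calls
  expect_identical(pe, point_estimates(published_ps))
})

test_that("parameter file round-trips through the JSON interchange format", {
  path <- withr::local_tempfile(fileext = ".json")
  write_parameters(published_ps, path)
  reloaded <- load_parameters(path)
  expect_equal(reloaded$params, published_ps$params)
})

test_that("the installed fixture file matches the in-code parameter set", {
  path <- system.file("extdata", "asthma_parameters.json", package = "btcea")
  skip_if(path == "", "fixture not installed")
  expect_equal(load_parameters(path)$params, published_ps$params)
})

test_that("parameter validation rejects malformed inputs", {
  p <- published_ps$params
  bad <- p
  bad$value[bad$name == "cost_event_ocs"] <- -5
  expect_error(cea_parameters(bad), "cost_event_ocs")

  expect_error(cea_parameters(p[p$name != "rate_ocs", ]), "rate_ocs")

  extra <- dplyr::bind_rows(p, dplyr::mutate(p[1, ], name = "not_a_parameter"))
  expect_error(cea_parameters(extra), "not_a_parameter")

  bad_beta <- p
  bad_beta$param1[bad_beta$name == "utility_free"] <- -1
  expect_error(cea_parameters(bad_beta), "utility_free")

  utility_out <- p
  utility_out$value[utility_out$name == "utility_ed"] <- 1.4
  expect_error(cea_parameters(utility_out), "utility_ed")
})

test_that("JSON loader rejects unknown keys and malformed distributions", {
  path <- withr::local_tempfile(fileext = ".json")
  write_parameters(published_ps, path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)

  doc_extra <- c(doc, list(surprise = 1))
  p2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc_extra, p2, auto_unbox = TRUE)
  expect_error(load_parameters(p2), "surprise")

  doc_badfam <- doc
  doc_badfam$parameters[[1]]$dist <- list(family = "cauchy", location = 0, scale = 1)
  p3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc_badfam, p3, auto_unbox = TRUE)
  expect_error(load_parameters(p3), "cauchy")

  doc_pos <- doc
  doc_pos$parameters[[1]]$dist <- list(family = "lognormal", a = 0.29, b = 0.1)
  p4 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc_pos, p4, auto_unbox = TRUE)
  expect_error(load_parameters(p4), "meanlog")
})

test_that("each distribution's analytic centre sits near its point estimate", {
  p <- published_ps$params
  for (i in seq_len(nrow(p))) {
    centre <- if (p$family[i] == "lognormal") {
      dist_median(p$family[i], p$param1[i], p$param2[i])
    } else if (p$name[i] == "death_risk_hosp") {
      # this beta is strongly right-skewed; its median, not its mean, tracks
      # the published point estimate
      dist_median(p$family[i], p$param1[i], p$param2[i])
    } else {
      dist_mean(p$family[i], p$param1[i], p$param2[i])
    }
    expect_lt(abs(centre - p$value[i]) / p$value[i], 0.10,
              label = sprintf("%s relative deviation", p$name[i]))
  }
})

test_that("sampled distributions have the expected closed-form centres", {
  set.seed(101)
  x <- dist_sample("lognormal", 0.29, 0.10, 2e4)
  expect_equal(stats::median(x), exp(0.29), tolerance = 0.01)
  y <- dist_sample("beta", 5.92, 2.93, 2e4)
  expect_equal(mean(y), 5.92 / (5.92 + 2.93), tolerance = 0.01)
  expect_equal(dist_sample("normal", 0.04, 0, 5), rep(0.04, 5))
  expect_equal(dist_sample("fixed", 14900, NA, 3), rep(14900, 3))
})

test_that("parameter sampling is bit-reproducible given a seed", {
  d1 <- sample_parameters(published_ps, n = 50, seed = 7)
  d2 <- sample_parameters(published_ps, n = 50, seed = 7)
  expect_identical(d1, d2)
  d3 <- sample_parameters(published_ps, n = 50, seed = 8)
  expect_false(identical(d1, d3))
})

test_that("sampled draws respect domain constraints", {
  d <- sample_parameters(published_ps, n = 500, seed = 11)
  expect_true(all(d$rate_ocs >= 0 & d$rate_ed >= 0 & d$rate_hosp >= 0))
  expect_true(all(d$death_risk_hosp >= 0 & d$death_risk_hosp <= 1))
  expect_true(all(d$utility_free >= 0 & d$utility_free <= 1))
  expect_true(all(d$cost_event_hosp >= 0))
  # fixed entries never vary
  expect_true(all(d$cost_bt_upfront == 14900))
})

test_that("annual rates convert to weekly probabilities by 1 - exp(-rate/52)", {
  expect_equal(rate_to_weekly_probability(0), 0)
  expect_equal(rate_to_weekly_probability(1.35), 1 - exp(-1.35 / 52))
  expect_equal(rate_to_weekly_probability(1.35), 0.02563, tolerance = 1e-3)
  rates <- seq(0, 10, by = 0.25)
  expect_true(all(diff(rate_to_weekly_probability(rates)) > 0))
  expect_true(all(rate_to_weekly_probability(rates) >= 0 &
                    rate_to_weekly_probability(rates) < 1))
  expect_error(rate_to_weekly_probability(-1), "nonnegative")
})

test_that("relative rates scale baseline rates multiplicatively", {
  expect_equal(apply_relative_rate(1.35, 0.48), 0.648)
  expect_equal(apply_relative_rate(0.07, 0.40), 0.028)
  expect_equal(apply_relative_rate(2.2, 1), 2.2)
  expect_error(apply_relative_rate(-1, 0.5), "nonnegative")
  expect_error(apply_relative_rate(1, -0.5), "nonnegative")
})

test_that("perturb_parameters scales spreads and degenerates at zero", {
  expect_equal(perturb_parameters(published_ps, 1)$params, published_ps$params)
  ps0 <- perturb_parameters(published_ps, 0)
  expect_true(all(ps0$params$family == "fixed"))
  expect_identical(point_estimates(ps0), point_estimates(published_ps))
  d <- sample_parameters(ps0, n = 3, seed = 1)
  expect_equal(d[1, ], point_estimates(published_ps))
  expect_error(perturb_parameters(published_ps, -1), "nonnegative")

  # doubling spreads at least doubles the lognormal SD and keeps centres
  ps2 <- perturb_parameters(published_ps, 2)
  i <- which(ps2$params$name == "rate_ocs")
  expect_equal(ps2$params$param2[i], 0.20)
  j <- which(ps2$params$name == "utility_free")
  expect_equal(dist_mean("beta", ps2$params$param1[j], ps2$params$param2[j]),
               dist_mean("beta", 5.92, 2.93))
})

test_that("set_parameter_value overrides one value and rejects unknown paths", {
  ps2 <- set_parameter_value(published_ps, "cost_bt_upfront", 30000)
  expect_equal(point_estimates(ps2)$cost_bt_upfront, 30000)
  expect_equal(point_estimates(ps2)$cost_drug_standard, 2610)
  expect_error(set_parameter_value(published_ps, "no_such", 1), "no_such")
})
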