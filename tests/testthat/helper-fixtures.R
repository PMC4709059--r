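# Shared fixtures: the published parameter set and small settings objects.
published_ps <- default_parameters()

settings_5y <- model_settings()

# Short-horizon settings for fast property loops.
settings_short <- model_settings(horizon_weeks = 26)

# A life table with no background mortality (terminal age still absorbing),
# for tests that isolate the disease process.
lt_no_mortality <- function() {
  lt <- default_life_table()
  lt$qx <- c(rep(0, nrow(lt) - 1), 1)
  lt
}

# A draw with no events and no excess death: isolates utility accrual.
draw_null <- function(u_free = 1) {
  d <- point_estimates(published_ps)
  d$rate_ocs <- d$rate_ed <- d$rate_hosp <- 0
  d$death_risk_hosp <- 0
  d$utility_free <- u_free
  d$utility_delta_bt <- d$utility_delta_omalizumab <- 0
  d
}
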