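# shared fixtures: random order-valid parameter draws and model beats

draw_valid_theta <- function(bounds = load_table_bounds()) {
  repeat {
    th <- stats::runif(24, bounds$lower, bounds$upper)
    i <- (0:5) * 4
    tp <- th[i + 3] + exp(th[i + 1] - th[i + 2]^2)
    if (all(diff(tp) > 0)) return(stats::setNames(th, param_names()))
  }
}

draw_valid_params <- function(bounds = load_table_bounds()) {
  sigma_lognormal_params(theta = draw_valid_theta(bounds))
}

model_beat <- function(theta) {
  synthesize(sigma_lognormal_params(theta = theta, check = FALSE))
}

# single-beat epoch fixture on the unit RR grid
as_epoch <- function(x, alpha = 1) beat_epoch(x, 0, alpha, 2 * alpha)

# closed-form peak times from a flat theta (independent re-statement)
.peak_times_test <- function(th) {
  i <- (0:5) * 4
  th[i + 3] + exp(th[i + 1] - th[i + 2]^2)
}

# 10 strong age slopes (~50% of box width over the 1-15 month span),
# signs chosen so drifting parameters move neighboring peaks apart
# rather than together, keeping order-valid draws feasible at the
# extreme ages; the other 14 parameters stay null
strong_slope_design <- function() {
  b <- load_table_bounds()
  width <- b$upper - b$lower
  sgn <- c(P_mu = -1, P_sigma = 1, Q_t0 = -1, Q_D = -1, R_sigma = -1,
           R_D = 1, S_t0 = 1, Tp_t0 = 1, Tm_mu = 1, Tm_D = -1)
  slopes <- stats::setNames(numeric(24), param_names())
  slopes[names(sgn)] <- sgn * 0.5 * width[names(sgn)] / 14
  list(slopes = slopes, strong = names(sgn))
}
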