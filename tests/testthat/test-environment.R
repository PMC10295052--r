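# episodic fitting environment: reset, constrained actions, reward,
# observations, termination

test_that("reset starts at the box midpoint with deterministic observations", {
  cfg <- env_config()
  b <- cfg$bounds
  set.seed(81)
  target <- model_beat(draw_valid_theta())
  s1 <- env_reset(target, cfg)
  expect_equal(s1$estimate, (b$lower + b$upper) / 2)
  expect_identical(s1$step_index, 0L)

  s2 <- env_reset(target, cfg)
  expect_identical(env_observation(s1, cfg), env_observation(s2, cfg))

  # self-target: zero residual, SNR at cap; the error observation is
  # the normalized image of the all-zero residual
  self <- model_beat(b$reference)
  s3 <- env_reset(self, cfg)
  expect_equal(s3$cur_snr_db, cfg$snr_cap)
  lo <- cfg$error_obs_bounds$lower; hi <- cfg$error_obs_bounds$upper
  expect_equal(error_observation(s3, cfg),
               pmin(pmax(-2 * lo / (hi - lo) - 1, -1), 1))

  expect_error(env_reset(c(target[-1], NA), cfg), "finite")
})

test_that("apply_action honors null actions, clipping and ordering", {
  cfg <- env_config()
  set.seed(83)
  target <- model_beat(draw_valid_theta())
  s <- env_reset(target, cfg)

  # null action leaves the estimate unchanged
  s0 <- apply_action(s, numeric(24), cfg)
  expect_equal(s0$estimate, s$estimate)
  expect_identical(s0$step_index, 1L)

  # action pushing one parameter past its bound lands exactly on it
  # (the step is a * reference, so with a negative reference a positive
  # action walks the parameter downward, onto the lower bound)
  a <- numeric(24)
  k <- match("P_mu", param_names())
  big <- s
  for (i in 1:200) {
    a[k] <- 0.01
    big <- apply_action(big, a, cfg)
    if (big$estimate[k] == cfg$bounds$lower[k]) break
  }
  expect_equal(unname(big$estimate[k]), unname(cfg$bounds$lower[k]))

  # out-of-box action components are clipped, not rejected
  huge <- rep(5, 24)
  sh <- apply_action(s, huge, cfg)
  expect_true(validate_in_box(
    sigma_lognormal_params(theta = sh$estimate), cfg$bounds)$ok)
})

test_that("an ordering-violating component update is cancelled, others kept", {
  cfg <- env_config()
  set.seed(85)
  target <- model_beat(draw_valid_theta())
  s <- env_reset(target, cfg)
  # drive R's t0 upward until its peak would pass S's: R updates must
  # cancel while other components keep moving
  a <- numeric(24)
  a[match("R_t0", param_names())] <- 0.01   # t0 ref is negative: move down?
  # use the sign that pushes R's peak later in time
  ref <- cfg$bounds$reference
  a[match("R_t0", param_names())] <- 0.01 * sign(1 / ref["R_t0"])
  a[match("P_mu", param_names())] <- -0.005
  st <- s
  for (i in 1:400) st <- apply_action(st, a, cfg)
  tp <- peak_time(sigma_lognormal_params(theta = st$estimate,
                                         check = FALSE))
  expect_true(all(diff(tp) > 0))
  # P's mu moved even while R was being constrained
  expect_false(st$estimate[["P_mu"]] == s$estimate[["P_mu"]])
})

test_that("rewards telescope to final minus initial SNR over an episode", {
  cfg <- env_config(max_steps = 60, patience = 50)
  set.seed(87)
  for (rep in 1:3) {
    target <- model_beat(draw_valid_theta())
    s <- env_reset(target, cfg)
    first <- s$cur_snr_db
    total <- 0
    repeat {
      a <- runif(24, -0.01, 0.01)
      prev <- s
      st <- env_step(s, a, cfg)
      expect_equal(st$reward, env_reward(prev, st$state, target, cfg),
                   tolerance = 1e-10)
      total <- total + st$reward
      s <- st$state
      if (st$done) break
    }
    expect_equal(total, s$cur_snr_db - first, tolerance = 1e-9)
  }
})

test_that("error observation selects window indices 176..425 and normalizes", {
  cfg <- env_config()
  grid <- normalized_time_grid()
  expect_identical(cfg$window_idx, 176:425)
  expect_true(all(grid[cfg$window_idx] >= -0.3 &
                    grid[cfg$window_idx] < 0.7))
  expect_false(grid[175] >= -0.3)
  expect_false(grid[426] < 0.7)

  # residual exactly at its upper bound maps to +1
  st <- env_reset(model_beat(cfg$bounds$reference), cfg)
  synth_ref <- model_beat(cfg$bounds$reference)
  target <- synth_ref
  target[cfg$window_idx] <- synth_ref[cfg$window_idx] +
    cfg$error_obs_bounds$upper
  st$target <- target
  expect_equal(error_observation(st, cfg), rep(1, 250))
})

test_that("termination triggers on max_steps and patience", {
  cfg <- env_config(max_steps = 30, patience = 10)
  set.seed(89)
  target <- model_beat(draw_valid_theta())
  s <- env_reset(target, cfg)
  # null actions never improve: patience fires after 10 steps
  for (i in 1:9) {
    s <- apply_action(s, numeric(24), cfg)
    expect_false(is_terminal(s, cfg)$done)
  }
  s <- apply_action(s, numeric(24), cfg)
  trm <- is_terminal(s, cfg)
  expect_true(trm$done)
  expect_identical(trm$reason, "patience")

  # step cap fires even with constant improvement bookkeeping reset
  cfg2 <- env_config(max_steps = 5, patience = 4)
  s2 <- env_reset(target, cfg2)
  for (i in 1:5) s2 <- apply_action(s2, runif(24, -0.01, 0.01), cfg2)
  expect_identical(is_terminal(s2, cfg2)$reason,
                   if (s2$steps_since_improvement >= 4) "patience"
                   else "max_steps")
  s3 <- env_reset(target, cfg2)
  for (i in 1:5) s3 <- apply_action(s3, numeric(24), cfg2)
  expect_true(is_terminal(s3, cfg2)$done)
})

test_that("estimate stays in the box and order-valid under random fuzz", {
  cfg <- env_config(max_steps = 1e6, patience = 1e6 - 1)
  set.seed(91)
  target <- model_beat(draw_valid_theta())
  s <- env_reset(target, cfg)
  worst_lo <- 0; worst_hi <- 0; order_ok <- TRUE; obs_ok <- TRUE
  for (i in 1:10000) {
    a <- runif(24, -0.015, 0.015)   # deliberately beyond the box
    s <- apply_action(s, a, cfg)
    th <- s$estimate
    worst_lo <- max(worst_lo, max(cfg$bounds$lower - th))
    worst_hi <- max(worst_hi, max(th - cfg$bounds$upper))
    if (!all(diff(.peak_times_test(th)) > 0)) order_ok <- FALSE
    if (i %% 500 == 0) {
      o <- env_observation(s, cfg)
      if (max(abs(c(o$params, o$errors))) > 1) obs_ok <- FALSE
    }
  }
  expect_lte(worst_lo, 0)
  expect_lte(worst_hi, 0)
  expect_true(order_ok)
  expect_true(obs_ok)
})
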