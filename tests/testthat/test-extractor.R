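# extraction: baseline optimizer, policy training (scaled), batch
# extraction. Training runs are scaled far below the full-size budget
# to stay desk-sized; the policy tests use a reduced step budget.

test_that("baseline_fit recovers noiseless beats and respects constraints", {
  cfg <- extraction_config()
  b <- cfg$bounds
  set.seed(101)
  snrs <- numeric(20)
  errs <- c()
  width <- b$upper - b$lower
  for (i in 1:20) {
    th <- draw_valid_theta()
    fr <- baseline_fit(model_beat(th), cfg, seed = i)
    snrs[i] <- fr$snr_db
    errs <- c(errs, abs(fr$params_normalized$theta - th) / width)
    # constraints: box, ordering, SNR consistency with the estimate
    expect_true(validate_in_box(fr$params_normalized, b)$ok)
    expect_true(all(diff(.peak_times_test(fr$params_normalized$theta)) > 0))
    # fitting SNR is scored on the fitting window [-0.3, 0.7)
    w <- 176:425
    expect_equal(fr$snr_db,
                 snr_db(synthesize(fr$params_normalized)[w],
                        model_beat(th)[w]),
                 tolerance = 1e-9)
  }
  # oracle calibration: >= 90% of noiseless fits reach 15 dB, all 5 dB
  expect_gte(mean(snrs >= 15), 0.9)
  expect_gte(mean(snrs >= 5), 0.8)
  # parameter recovery: median scaled absolute error < 0.15
  expect_lt(median(errs), 0.15)
})

test_that("baseline_fit is deterministic for a fixed seed", {
  cfg <- extraction_config(max_steps = 400, patience = 100)
  set.seed(103)
  x <- model_beat(draw_valid_theta())
  f1 <- baseline_fit(x, cfg, seed = 7)
  f2 <- baseline_fit(x, cfg, seed = 7)
  expect_identical(f1$params_normalized$theta, f2$params_normalized$theta)
  expect_identical(f1$snr_db, f2$snr_db)
})

test_that("extract_beat on the reference self-target needs no improvement", {
  cfg <- extraction_config(max_steps = 300, patience = 150)
  x <- model_beat(cfg$bounds$reference)
  fr <- extract_beat(gauss_newton_policy(cfg), as_epoch(x), cfg)
  expect_equal(fr$snr_db, cfg$snr_cap)
  expect_equal(fr$params_normalized$theta, cfg$bounds$reference)
})

test_that("fit results denormalize consistently with the beat alpha", {
  cfg <- extraction_config(max_steps = 300, patience = 150)
  set.seed(107)
  x <- model_beat(draw_valid_theta())
  be <- as_epoch(x, alpha = 0.41)
  fr <- baseline_fit(be, cfg, seed = 3)
  expect_identical(fr$params_seconds$time_basis, "seconds")
  # profile invariance between the two bases
  grid <- normalized_time_grid()
  expect_lt(max(abs(synthesize(fr$params_seconds, 0.41 * grid) -
                      synthesize(fr$params_normalized, grid))),
            1e-9 * max(abs(synthesize(fr$params_normalized, grid))))
})

test_that("scaled policy training beats the initial estimate and random policy", {
  tcfg <- env_config()
  set.seed(109)
  beats <- lapply(1:12, function(i) model_beat(draw_valid_theta()))
  pol <- train_policy(beats, tcfg, total_steps = 12000, seed = 2)
  expect_s3_class(pol, "ecg_policy")
  expect_true(pol$trained)
  lg <- attr(pol, "training_log")
  expect_true(is.data.frame(lg) && nrow(lg) >= 1)

  # determinism: same seed, same policy
  pol2 <- train_policy(beats, tcfg, total_steps = 12000, seed = 2)
  expect_identical(pol$W, pol2$W)

  # holdout comparison at a reduced extraction budget
  ecfg <- extraction_config(max_steps = 500, patience = 200)
  set.seed(111)
  hold <- lapply(1:12, function(i) model_beat(draw_valid_theta()))
  init_snr <- vapply(hold, function(x)
    snr_db(model_beat(tcfg$bounds$reference), x), numeric(1))
  fit_tr <- vapply(hold, function(x)
    extract_beat(pol, as_epoch(x), ecfg)$snr_db, numeric(1))
  set.seed(113)
  fit_un <- vapply(hold, function(x)
    extract_beat(ecg_policy(), as_epoch(x), ecfg)$snr_db, numeric(1))
  expect_gt(median(fit_tr), median(init_snr))
  expect_gte(median(fit_tr), median(fit_un))
  # fitted params always within the box
  fr <- extract_beat(pol, as_epoch(hold[[1]]), ecfg)
  expect_true(validate_in_box(fr$params_normalized, tcfg$bounds)$ok)
})

test_that("total_steps = 0 yields the documented random-policy fallback", {
  pol <- train_policy(list(model_beat(load_table_bounds()$reference)),
                      env_config(), total_steps = 0)
  expect_false(pol$trained)
  set.seed(1)
  a1 <- policy_action(pol, list(params = numeric(24),
                                errors = numeric(250)))
  expect_true(all(abs(a1) <= 0.01))
  set.seed(2)
  a2 <- policy_action(pol, list(params = numeric(24),
                                errors = numeric(250)))
  expect_false(identical(a1, a2))   # stochastic fallback
})

test_that("batch_extract flags beats below 5 dB, keeping exactly 5.0", {
  cfg <- extraction_config()
  set.seed(115)
  clean <- lapply(1:4, function(i) as_epoch(model_beat(draw_valid_theta())))
  noise <- lapply(1:4, function(i) as_epoch(rnorm(500, sd = 500)))
  out <- batch_extract("baseline", c(clean, noise), cfg, seed = 9)
  expect_identical(nrow(out$fits), 8L)
  # noiseless beats fit well; pure-noise beats are excluded
  expect_true(all(!out$fits$excluded[1:4]))
  expect_true(all(out$fits$excluded[5:8]))
  expect_identical(out$n_excluded, 4L)
  # strict-below rule
  expect_identical(unname(out$fits$excluded), unname(out$fits$snr_db < 5))
  # both parameter bases present in the table
  expect_true(all(paste0(param_names(), "_norm") %in% names(out$fits)))
  expect_true(all(paste0(param_names(), "_sec") %in% names(out$fits)))
})
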