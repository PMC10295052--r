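# resampling, R-peak detection, epoching, SNR, segment filtering

test_that("resample_to_1024 is the identity at 1024 Hz and alias-safe below", {
  set.seed(61)
  x <- rnorm(4096)
  seg <- ecg_segment(x, 1024)
  expect_identical(resample_to_1024(seg)$samples, x)

  # 5 Hz sine at 512 Hz: length doubles, spectral peak stays at 5 Hz
  fs <- 512; n <- fs * 4
  tone <- sin(2 * pi * 5 * (0:(n - 1)) / fs)
  up <- resample_to_1024(ecg_segment(tone, fs))
  expect_identical(up$fs, 1024)
  expect_length(up$samples, 2L * n)
  spec <- Mod(fft(up$samples))[1:(n)]
  f_axis <- (0:(n - 1)) * 1024 / (2 * n)
  expect_equal(f_axis[which.max(spec)], 5)
  # mid-signal values interpolate accurately
  expect_lt(max(abs(up$samples[seq(1, 2 * n, by = 2)] - tone)[100:1900]),
            1e-6)

  expect_length(resample_to_1024(ecg_segment(rnorm(256), 128))$samples,
                256L * 8L)
  expect_error(ecg_segment(rnorm(100), 200), "unsupported")
})

test_that("detect_r_peaks finds synthetic R peaks and rejects poor segments", {
  spec <- synth_spec(target_snr_db = 15, beats_per_segment = 120,
                     mean_rr_s = 0.5, rr_jitter_s = 0.015)
  set.seed(63)
  off <- draw_subject_offsets(spec)
  pars <- lapply(1:120, function(b) sample_beat_params(spec, off[1, ], 6))
  tr <- render_trace(spec, pars)   # ~60 s at 120 bpm
  pk <- detect_r_peaks(tr$segment)
  expect_true(all(diff(pk) > 0))
  expect_true(abs(length(pk) - 120) <= 2)
  d <- vapply(tr$r_times, function(t) min(abs(pk - t)), numeric(1))
  expect_gte(mean(d <= 0.010), 0.99)

  # flat zero signal: rejected (fewer than 20 beats)
  expect_error(detect_r_peaks(ecg_segment(numeric(8192), 1024)),
               class = "segment_rejected")

  # 19 true beats: rejected by the 20-beat rule
  pars19 <- lapply(1:19, function(b) sample_beat_params(spec, off[1, ], 6))
  tr19 <- render_trace(spec, pars19)
  expect_error(detect_r_peaks(tr19$segment), class = "segment_rejected")
})

test_that("epoch_beats yields peaks-minus-2 epochs of 500 samples", {
  fs <- 1024
  seg <- ecg_segment(rep(1, 10 * fs), fs)
  peaks <- seq(0.5, 9.5, by = 0.5)
  eps <- epoch_beats(seg, peaks)
  expect_length(eps, length(peaks) - 2L)
  expect_true(all(vapply(eps, function(e) length(e$x) == 500L, logical(1))))
  # constant signal -> constant epochs; alpha = (t3 - t1)/2
  expect_equal(eps[[1]]$x, rep(1, 500))
  expect_equal(eps[[1]]$alpha, 0.5)
  expect_identical(epoch_beats(seg, c(1, 2)), list())
})

test_that("a rendered beat epochs back onto the synthesized waveform", {
  # isolate one beat: zero-amplitude neighbors, so the epoch contains
  # only the middle beat and the round trip is interpolation error only
  spec <- synth_spec(target_snr_db = Inf, rr_jitter_s = 0.03,
                     param_noise_sd = 0)
  set.seed(67)
  zero <- load_prototype()
  zero$theta[(0:5) * 4 + 4] <- 0
  zero <- sigma_lognormal_params(theta = zero$theta)
  for (mid in list(load_prototype(), draw_valid_params())) {
    tr <- render_trace(spec, list(zero, mid, zero))
    eps <- epoch_beats(tr$segment, tr$anchors)
    expect_length(eps, 3L)
    expect_gte(snr_db(eps[[2]]$x, synthesize(mid)), 40)
  }
  # for the prototype beat the R maximum lands at normalized time ~ 0
  tr <- render_trace(spec, list(zero, load_prototype(), zero))
  eps <- epoch_beats(tr$segment, tr$anchors)
  grid <- normalized_time_grid()
  expect_lte(abs(grid[which.max(eps[[2]]$x)]), 0.0041)
})

test_that("snr_db implements the power-ratio formula with a cap", {
  set.seed(71)
  x_ref <- model_beat(draw_valid_theta())

  # noise power equal to signal power -> 0 dB
  noise <- rnorm(500)
  noise <- noise * sqrt(sum(x_ref^2) / sum(noise^2))
  expect_equal(snr_db(x_ref + noise, x_ref), 0, tolerance = 1e-10)

  # noise power 1e-4 / 1e-2 of signal power -> 40 / 20 dB
  expect_equal(snr_db(x_ref + noise * 1e-2, x_ref), 40, tolerance = 1e-10)
  expect_equal(snr_db(x_ref + noise * 1e-1, x_ref), 20, tolerance = 1e-10)

  # zero residual -> capped
  expect_equal(snr_db(x_ref, x_ref), 120)
  expect_error(snr_db(noise, numeric(500)), "all zero")

  # invariant to common positive rescaling
  expect_equal(snr_db(7.3 * (x_ref + noise), 7.3 * x_ref),
               snr_db(x_ref + noise, x_ref))
})

test_that("segment_quality averages epochs and SNRs per the definition", {
  x <- model_beat(draw_valid_theta())
  same <- lapply(1:5, function(i) as_epoch(x))
  q <- segment_quality(same)
  expect_equal(q$mean_beat, x)
  expect_true(all(q$snr_per_beat == 120))
  expect_equal(q$snr_bar, 120)
  expect_identical(q$n_beats, 5L)

  # epochs at xbar +/- d with sum(d^2) = sum(xbar^2) -> 0 dB each
  d <- rnorm(500)
  d <- d * sqrt(sum(x^2) / sum(d^2))
  q2 <- segment_quality(list(as_epoch(x + d), as_epoch(x - d)))
  expect_equal(q2$mean_beat, x)
  expect_equal(q2$snr_bar, 0, tolerance = 1e-10)
  expect_error(segment_quality(list()), "at least one")
})

test_that("filter_segments keeps snr_bar >= 5 and rejects below", {
  mk <- function(snr) structure(list(mean_beat = numeric(500),
                                     snr_per_beat = snr, snr_bar = snr,
                                     n_beats = 1L, segment_id = "s"),
                                class = "segment_quality")
  out <- filter_segments(list(mk(5.0), mk(4.99), mk(-3), mk(12)))
  expect_identical(out$report$kept, c(TRUE, FALSE, FALSE, TRUE))
  expect_length(out$kept, 2L)
  expect_length(out$rejected, 2L)
})

test_that("generator-targeted segment SNR calibrates within a dB", {
  spec <- synth_spec(target_snr_db = 10, beats_per_segment = 30)
  set.seed(73)
  off <- draw_subject_offsets(spec)
  pars <- lapply(1:30, function(b) sample_beat_params(spec, off[1, ], 4))
  tr <- render_trace(spec, pars)
  eps <- epoch_beats(tr$segment, tr$anchors)
  q <- segment_quality(eps)
  expect_lt(abs(q$snr_bar - 10), 1)

  # mixed batch at known targets {-5, 0, 5, 10}: exactly 2 kept
  quals <- lapply(c(-5, 0, 5, 10), function(tgt) {
    sp <- synth_spec(target_snr_db = tgt, beats_per_segment = 25)
    ps <- lapply(1:25, function(b) sample_beat_params(sp, off[2, ], 4))
    trk <- render_trace(sp, ps)
    segment_quality(epoch_beats(trk$segment, trk$anchors))
  })
  out <- filter_segments(quals)
  expect_length(out$kept, 2L)
})
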