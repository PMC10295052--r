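# Synthetic single-lead infant ECG with known ground truth.
#
# Emulates the statistical structure of an infant longitudinal ECG
# sample: repeated PQRST complexes rendered from the forward model with
# per-beat parameter jitter, between-subject offsets, variable RR
# intervals, additive noise calibrated to a target segment SNR, and an
# age covariate inducing linear drifts in chosen parameters. It does
# not emulate respiratory sinus arrhythmia, electrode artifacts, or
# non-lognormal wave shapes.

#' Synthetic-dataset specification
#'
#' Defaults state the emulated world: eight age levels spanning 1-15
#' months with the recording counts of the emulated design (N = 121),
#' an infant heart rate near 140 bpm (mean RR 0.43 s), moderate RR
#' jitter, between-subject parameter spread at 5% of each box width,
#' between-beat jitter at 2%, and a 10 dB target segment SNR.
#'
#' @param ages_months Age levels (months).
#' @param recordings_per_age Recordings at each age level (same length
#'   as `ages_months`).
#' @param n_subjects Number of distinct participants; recordings are
#'   assigned to subjects round-robin so subjects repeat across ages.
#' @param beats_per_segment Beats rendered per segment.
#' @param mean_rr_s,rr_jitter_s Mean and SD of the RR interval (s).
#' @param param_age_slopes Named 24-vector: linear drift per month in
#'   each parameter's native units (default all zero).
#' @param subject_sd_frac Between-subject offset SD as a fraction of
#'   each parameter's box width.
#' @param param_noise_sd Between-beat jitter SD as a fraction of box
#'   width.
#' @param target_snr_db Target segment mean SNR; `Inf` renders
#'   noiseless traces.
#' @param fs Sampling rate (Hz).
#' @param bounds Constraint box used for clipping and widths.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(ages_months = c(1, 2, 3, 4, 6, 9, 12, 15),
                       recordings_per_age = c(9, 13, 19, 21, 14, 19, 17, 9),
                       n_subjects = 40,
                       beats_per_segment = 30,
                       mean_rr_s = 0.43, rr_jitter_s = 0.02,
                       param_age_slopes = NULL,
                       subject_sd_frac = 0.05,
                       param_noise_sd = 0.02,
                       target_snr_db = 10,
                       fs = 1024,
                       bounds = load_table_bounds()) {
  stopifnot(length(recordings_per_age) == length(ages_months),
            mean_rr_s > 0, rr_jitter_s >= 0, beats_per_segment >= 3)
  if (is.null(param_age_slopes)) {
    param_age_slopes <- stats::setNames(numeric(24), param_names())
  } else {
    stopifnot(length(param_age_slopes) == 24L)
    param_age_slopes <- stats::setNames(as.numeric(param_age_slopes),
                                        param_names())
  }
  structure(list(ages_months = ages_months,
                 recordings_per_age = recordings_per_age,
                 n_subjects = n_subjects,
                 beats_per_segment = beats_per_segment,
                 mean_rr_s = mean_rr_s, rr_jitter_s = rr_jitter_s,
                 param_age_slopes = param_age_slopes,
                 subject_sd_frac = subject_sd_frac,
                 param_noise_sd = param_noise_sd,
                 target_snr_db = target_snr_db, fs = fs,
                 bounds = bounds),
            class = "synth_spec")
}

# clip into box and enforce strict peak ordering; jitter is redrawn
# up to max_tries times before failing
.draw_valid_theta <- function(base, jitter_sd, bounds, max_tries = 100) {
  width <- bounds$upper - bounds$lower
  for (i in seq_len(max_tries)) {
    th <- base + stats::rnorm(24, sd = jitter_sd * width)
    th <- pmin(pmax(th, bounds$lower), bounds$upper)
    if (all(diff(.peak_times(th)) > 0)) return(th)
  }
  stop("could not draw an order-valid parameter set in ", max_tries,
       " attempts")
}

#' Draw ground-truth parameters for one beat
#'
#' Prototype + age x slope + per-subject offset + per-beat jitter,
#' clipped into the box and rejected (up to 100 redraws of the jitter)
#' until the peak order is strictly valid.
#'
#' @param spec A [synth_spec()].
#' @param subject_offset Named 24-vector of the subject's random
#'   offsets (see [draw_subject_offsets()]).
#' @param age_months Age covariate.
#' @return A [sigma_lognormal_params()] in normalized basis.
#' @export
sample_beat_params <- function(spec, subject_offset, age_months) {
  proto <- load_prototype()$theta
  base <- proto + age_months * spec$param_age_slopes + subject_offset
  base <- pmin(pmax(base, spec$bounds$lower), spec$bounds$upper)
  th <- if (spec$param_noise_sd > 0)
    .draw_valid_theta(base, spec$param_noise_sd, spec$bounds)
  else {
    if (any(diff(.peak_times(base)) <= 0))
      stop("could not draw an order-valid parameter set in 100 attempts")
    base
  }
  sigma_lognormal_params(theta = th)
}

#' @rdname sample_beat_params
#' @return For `draw_subject_offsets()`: an `n_subjects` x 24 matrix
#'   of centered Gaussian offsets (SD = `subject_sd_frac` x box width).
#' @export
draw_subject_offsets <- function(spec) {
  width <- spec$bounds$upper - spec$bounds$lower
  m <- matrix(stats::rnorm(spec$n_subjects * 24,
                           sd = rep(spec$subject_sd_frac * width,
                                    each = spec$n_subjects)),
              spec$n_subjects, 24)
  colnames(m) <- param_names()
  m
}

#' Render a continuous trace from per-beat parameters
#'
#' Concatenates beats at the drawn RR intervals: beat k is anchored at
#' R time `T_k` and rendered through the piecewise-linear warp that
#' duration-normalized epoching inverts (normalized time -1..0 spans
#' the previous RR interval, 0..1 the next), so a noiseless render
#' epoched at the true anchors reproduces the synthesized beats up to
#' interpolation error. The symmetric `alpha_k = (T_{k+1} - T_{k-1}) /
#' 2` reported alongside is the time scale the analysis pipeline will
#' use for denormalization. A single noise realization (white Gaussian
#' plus a 0.3 Hz baseline-wander sinusoid, 70/30 power split) is
#' scaled by root finding so the epoched segment's mean SNR hits
#' `spec$target_snr_db` almost exactly; an error is raised when
#' beat-to-beat variability alone already puts the segment below the
#' target.
#'
#' @param spec A [synth_spec()].
#' @param beat_params List of [sigma_lognormal_params()] (normalized
#'   basis), one per beat.
#' @param segment_id Identifier for the returned segment.
#' @return List with `segment` (an [ecg_segment()]), `r_times` (the
#'   ground-truth R-time anchors, one per rendered beat), `anchors`
#'   (all n + 2 anchors including the unrendered neighbors, directly
#'   usable with [epoch_beats()]), `alpha` (per-beat time scales, s),
#'   `noise_sd` and `measured_snr_bar_db`.
#' @export
render_trace <- function(spec, beat_params, segment_id = "synth") {
  n <- length(beat_params)
  stopifnot(n >= 3)
  rr <- pmax(0.25, stats::rnorm(n + 1, spec$mean_rr_s, spec$rr_jitter_s))
  r_all <- cumsum(c(spec$mean_rr_s, rr))      # n + 2 anchors, first at t0
  fs <- spec$fs
  total <- r_all[n + 2] + spec$mean_rr_s
  m <- ceiling(total * fs)
  tgrid <- (0:(m - 1)) / fs
  clean <- numeric(m)
  # interior anchors 2..n+1 carry the n beats; each beat is rendered
  # through the same piecewise-linear warp that epoching inverts:
  # normalized time -1..0 spans the previous RR, 0..1 the next RR
  alphas <- (r_all[3:(n + 2)] - r_all[1:n]) / 2
  for (k in seq_len(n)) {
    Tk <- r_all[k + 1]
    rr_prev <- Tk - r_all[k]
    rr_next <- r_all[k + 2] - Tk
    lo <- max(1, floor((Tk - rr_prev) * fs) + 1)
    hi <- min(m, ceiling((Tk + 1.5 * rr_next) * fs) + 1)
    idx <- lo:hi
    dt <- tgrid[idx] - Tk
    u <- ifelse(dt < 0, dt / rr_prev, dt / rr_next)
    clean[idx] <- clean[idx] +
      .synthesize_theta(beat_params[[k]]$theta, u)
  }
  r_times <- r_all[2:(n + 1)]
  measure <- function(x) {
    seg <- ecg_segment(x, fs, segment_id)
    segment_quality(epoch_beats(seg, r_all), segment_id)$snr_bar
  }
  if (!is.finite(spec$target_snr_db)) {
    return(list(segment = ecg_segment(clean, fs, segment_id),
                r_times = r_times, anchors = r_all, alpha = alphas,
                noise_sd = 0, measured_snr_bar_db = measure(clean)))
  }
  # unit-scale noise realization (white + 0.3 Hz wander, 70/30 power
  # split), drawn once; only its scale s is calibrated, so the
  # measured SNR is a strictly decreasing function of s and the target
  # can be hit by root finding
  unit_noise <- stats::rnorm(m, sd = sqrt(0.7)) +
    sqrt(2 * 0.3) * sin(2 * pi * 0.3 * tgrid + stats::runif(1, 0, 2 * pi))
  q0 <- segment_quality(epoch_beats(ecg_segment(clean, fs, segment_id),
                                    r_all), segment_id)
  if (q0$snr_bar <= spec$target_snr_db)
    stop("beat-to-beat variability alone leaves the segment below the ",
         "target SNR (", round(q0$snr_bar, 1), " dB)")
  p_sig <- sum(q0$mean_beat^2)
  s0 <- sqrt(p_sig / 500 / 10^(spec$target_snr_db / 10))
  g <- function(s) measure(clean + s * unit_noise) - spec$target_snr_db
  hi_s <- s0
  while (g(hi_s) > 0) hi_s <- 2 * hi_s
  s <- stats::uniroot(g, c(0, hi_s), tol = s0 * 1e-4)$root
  s <- s * (1 - 1e-4)   # land a hair above the target, never below
  noisy <- clean + s * unit_noise
  list(segment = ecg_segment(noisy, fs, segment_id),
       r_times = r_times, anchors = r_all, alpha = alphas, noise_sd = s,
       measured_snr_bar_db = measure(noisy))
}

#' Generate a full synthetic dataset
#'
#' Draws subject offsets, assigns recordings to subjects round-robin
#' within each age level, samples per-beat ground-truth parameters and
#' renders one segment per recording.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed; the whole dataset is reproducible.
#' @param render When `FALSE`, skip waveform rendering and return only
#'   the ground-truth parameter table (fast path for analysis-stage
#'   simulations; `alpha_s` is then drawn from the RR model directly).
#' @return List with `truth` (data.frame: `recording_id`, `segment_id`,
#'   `subject`, `age_months`, `beat_id`, `alpha_s`, 24 normalized
#'   ground-truth parameter columns) and `segments` (named list of
#'   [render_trace()] outputs; empty if `render = FALSE`).
#' @export
generate_dataset <- function(spec = synth_spec(), seed = 1,
                             render = TRUE) {
  set.seed(seed)
  offsets <- draw_subject_offsets(spec)
  rows <- list(); segments <- list()
  rec <- 0L
  subj_cycle <- rep_len(seq_len(spec$n_subjects),
                        sum(spec$recordings_per_age))
  pos <- 0L
  for (ai in seq_along(spec$ages_months)) {
    age <- spec$ages_months[ai]
    for (r in seq_len(spec$recordings_per_age[ai])) {
      rec <- rec + 1L; pos <- pos + 1L
      subj <- subj_cycle[pos]
      rid <- sprintf("rec%03d", rec)
      pars <- lapply(seq_len(spec$beats_per_segment), function(b)
        sample_beat_params(spec, offsets[subj, ], age))
      if (render) {
        tr <- render_trace(spec, pars, segment_id = paste0(rid, "_seg1"))
        alphas <- tr$alpha
        segments[[rid]] <- tr
      } else {
        alphas <- pmax(0.25, stats::rnorm(length(pars), spec$mean_rr_s,
                                          spec$rr_jitter_s))
      }
      th <- t(vapply(pars, function(p) p$theta, numeric(24)))
      colnames(th) <- param_names()
      rows[[rec]] <- cbind(
        data.frame(recording_id = rid, segment_id = paste0(rid, "_seg1"),
                   subject = sprintf("subj%02d", subj), age_months = age,
                   beat_id = sprintf("%s_b%03d", rid,
                                     seq_len(spec$beats_per_segment)),
                   alpha_s = alphas),
        as.data.frame(th))
    }
  }
  truth <- do.call(rbind, rows)
  list(truth = truth, segments = segments)
}
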