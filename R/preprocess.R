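# Beat preprocessing: resampling to 1024 Hz, R-peak detection,
# duration-normalized 500-sample epoching, per-beat/segment SNR and the
# quality filters.

#' Single-lead ECG segment
#'
#' @param samples Numeric voltage vector (uV).
#' @param fs Sampling rate in Hz; inputs must be 128, 512 or 1024
#'   (internal processing is always at 1024 after [resample_to_1024()]).
#' @param segment_id Optional identifier carried through reports.
#' @return An object of class `ecg_segment`.
#' @export
ecg_segment <- function(samples, fs, segment_id = NA_character_) {
  stopifnot(is.numeric(samples), length(samples) > 1)
  if (!fs %in% c(128, 512, 1024))
    stop("unsupported sampling rate: ", fs, " (expected 128, 512 or 1024)")
  structure(list(samples = as.numeric(samples), fs = fs,
                 segment_id = segment_id),
            class = "ecg_segment")
}

#' Read a two-column ECG CSV
#'
#' Expects columns `time_s` and `ecg_uv` with a uniform sampling grid.
#'
#' @param path CSV file path.
#' @param segment_id Optional identifier.
#' @return An [ecg_segment()].
#' @export
read_ecg_csv <- function(path, segment_id = basename(path)) {
  tab <- utils::read.csv(path)
  if (!all(c("time_s", "ecg_uv") %in% names(tab)))
    stop("ECG CSV must have columns time_s, ecg_uv: ", path)
  dt <- diff(tab$time_s)
  fs <- round(1 / stats::median(dt))
  if (max(abs(dt - 1 / fs)) > 0.25 / fs)
    stop("non-uniform sampling grid in ", path)
  ecg_segment(tab$ecg_uv, fs, segment_id)
}

#' Write an ECG segment as a two-column CSV
#'
#' @param seg An [ecg_segment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(seg, path) {
  n <- length(seg$samples)
  utils::write.csv(data.frame(time_s = (0:(n - 1)) / seg$fs,
                              ecg_uv = seg$samples),
                   path, row.names = FALSE)
  invisible(path)
}

# FFT-based integer-factor upsampling (ideal lowpass interpolation)
.upsample_fft <- function(x, L) {
  n <- length(x)
  m <- n * L
  X <- stats::fft(x)
  Y <- complex(m)
  half <- floor((n - 1) / 2)
  Y[1] <- X[1]
  if (half > 0) {
    Y[2:(half + 1)] <- X[2:(half + 1)]
    Y[(m - half + 1):m] <- X[(n - half + 1):n]
  }
  if (n %% 2 == 0) {
    # split the Nyquist bin symmetrically
    Y[n / 2 + 1] <- X[n / 2 + 1] / 2
    Y[m - n / 2 + 1] <- X[n / 2 + 1] / 2
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Resample a segment to 1024 Hz
#'
#' Identity when already at 1024 Hz; otherwise Fourier-domain
#' zero-insertion upsampling (equivalent to ideal lowpass
#' interpolation, alias-safe) by the integer factor 1024 / fs.
#'
#' @param seg An [ecg_segment()] at 128, 512 or 1024 Hz.
#' @return An `ecg_segment` at 1024 Hz.
#' @export
resample_to_1024 <- function(seg) {
  stopifnot(inherits(seg, "ecg_segment"))
  if (seg$fs == 1024) return(seg)
  L <- 1024 / seg$fs
  ecg_segment(.upsample_fft(seg$samples, L), 1024, seg$segment_id)
}

# zero-phase FFT bandpass
.fft_bandpass <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)           # two-sided frequency magnitude
  X[f < lo | f > hi] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Detect R peaks
#'
#' Pan-Tompkins-style plumbing: 5-30 Hz zero-phase bandpass, squaring,
#' an adaptive threshold at 0.35 x the median of the 2 s block maxima
#' of the squared signal (robust to isolated artifacts and, unlike a
#' low-percentile threshold, far above the residual T-wave energy),
#' local-maximum picking with a 200 ms refractory period, and peak
#' refinement on the raw signal within +/- 30 ms.
#'
#' Segments in which fewer than `min_beats` beats are found are
#' rejected with a condition of class `segment_rejected` (mirroring the
#' preprocessing rejection rule).
#'
#' @param seg An [ecg_segment()] (any supported rate; resampled
#'   internally).
#' @param min_beats Minimum detected beats; fewer rejects the segment.
#' @return Numeric vector of strictly increasing peak times (s).
#' @export
detect_r_peaks <- function(seg, min_beats = 20) {
  stopifnot(inherits(seg, "ecg_segment"))
  seg <- resample_to_1024(seg)
  x <- seg$samples
  fs <- seg$fs
  n <- length(x)
  reject <- function(msg)
    stop(errorCondition(msg, class = "segment_rejected"))
  if (n < 2 * fs) reject("segment shorter than 2 s")
  e <- .fft_bandpass(x, fs, 5, 30)^2
  # QRS-energy threshold: median of 2 s block maxima, scaled down
  blk <- ceiling(seq_len(n) / (2 * fs))
  bmax <- tapply(e, blk, max)
  thr <- 0.35 * stats::median(as.numeric(bmax))
  cand <- which(e > thr & e >= c(-Inf, e[-n]) & e >= c(e[-1], Inf))
  if (length(cand) == 0) reject("no candidate peaks above threshold")
  # refractory: greedy keep of the largest candidate in each 200 ms span
  refr <- round(0.2 * fs)
  ord <- cand[order(e[cand], decreasing = TRUE)]
  keep <- logical(n)
  blocked <- logical(n)
  for (i in ord) {
    if (!blocked[i]) {
      keep[i] <- TRUE
      lo <- max(1, i - refr); hi <- min(n, i + refr)
      blocked[lo:hi] <- TRUE
    }
  }
  peaks <- which(keep)
  # refine on the raw signal within +/- 30 ms
  w <- as.integer(round(0.03 * fs))
  peaks <- vapply(peaks, function(i) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  if (length(peaks) < min_beats)
    reject(sprintf("detected %d beats (< %d)", length(peaks), min_beats))
  (peaks - 1) / fs
}

#' Duration-normalized 500-sample beat epoch
#'
#' @param x Numeric 500-vector on the normalized-time grid.
#' @param t1,t2,t3 Previous, own and next R-peak times (s).
#' @param beat_id Optional identifier.
#' @return An object of class `beat_epoch` with `alpha = (t3 - t1) / 2`.
#' @export
beat_epoch <- function(x, t1, t2, t3, beat_id = NA_character_) {
  stopifnot(length(x) == 500L, t1 < t2, t2 < t3)
  structure(list(x = as.numeric(x), t1 = t1, t2 = t2, t3 = t3,
                 alpha = (t3 - t1) / 2, beat_id = beat_id),
            class = "beat_epoch")
}

#' Epoch beats into duration-normalized 500-sample windows
#'
#' One epoch per interior peak (the first and last peaks lack a
#' neighbor and are dropped). Each epoch linearly interpolates the ECG
#' over 250 regularly spaced samples from the previous R peak to the
#' own R peak and 250 more to the next R peak, mapping those spans onto
#' normalized time `[-1, 0)` and `[0, 1)`; the halves are half-open so
#' the shared R sample appears once, at normalized time 0.
#'
#' @param seg An [ecg_segment()] (1024 Hz).
#' @param peaks Strictly increasing R-peak times (s).
#' @return List of [beat_epoch()]; empty when fewer than 3 peaks.
#' @export
epoch_beats <- function(seg, peaks) {
  stopifnot(inherits(seg, "ecg_segment"))
  if (length(peaks) < 3) return(list())
  st <- (seq_along(seg$samples) - 1) / seg$fs
  lapply(seq(2, length(peaks) - 1), function(k) {
    t1 <- peaks[k - 1]; t2 <- peaks[k]; t3 <- peaks[k + 1]
    tt <- c(t1 + (0:249) * (t2 - t1) / 250,
            t2 + (0:249) * (t3 - t2) / 250)
    y <- stats::approx(st, seg$samples, xout = tt, rule = 2)$y
    beat_epoch(y, t1, t2, t3, beat_id = sprintf("beat%04d", k))
  })
}

#' Signal-to-noise ratio in dB
#'
#' `10 * log10(sum(x_ref^2) / sum((x - x_ref)^2))`: the power of the
#' reference signal over the power of the residual. 0 dB means noise
#' power as large as the signal; the value is capped at +120 dB once
#' the residual power drops below 1e-12 of the signal power, keeping
#' averages finite for exact fits. Invariant to common rescaling of
#' both inputs.
#'
#' @param x Signal under test.
#' @param x_ref Reference signal (same length, not all zero).
#' @param cap Cap in dB for (near-)zero residuals.
#' @return SNR in dB.
#' @export
snr_db <- function(x, x_ref, cap = 120) {
  stopifnot(length(x) == length(x_ref))
  sp <- sum(x_ref^2)
  if (sp == 0) stop("undefined SNR: reference signal is all zero")
  rp <- sum((x - x_ref)^2)
  if (rp < 1e-12 * sp) return(cap)
  min(cap, 10 * log10(sp / rp))
}

#' Per-segment beat stability summary
#'
#' Computes the pointwise mean beat across epochs, each beat's SNR
#' against that mean, and their arithmetic mean in dB
#' (`snr_bar`) which characterizes segment quality.
#'
#' @param epochs Non-empty list of [beat_epoch()].
#' @param segment_id Optional identifier.
#' @return An object of class `segment_quality` with fields
#'   `mean_beat`, `snr_per_beat`, `snr_bar`, `n_beats`, `segment_id`.
#' @export
segment_quality <- function(epochs, segment_id = NA_character_) {
  if (length(epochs) == 0) stop("segment_quality needs at least one epoch")
  xm <- matrix(unlist(lapply(epochs, `[[`, "x")), nrow = 500)
  mean_beat <- rowMeans(xm)
  snrs <- apply(xm, 2, snr_db, x_ref = mean_beat)
  structure(list(mean_beat = mean_beat, snr_per_beat = snrs,
                 snr_bar = mean(snrs), n_beats = length(epochs),
                 segment_id = segment_id),
            class = "segment_quality")
}

#' Partition segments by mean-SNR quality
#'
#' Keeps a segment iff `snr_bar >= threshold` (strict-below rejection:
#' exactly 5 dB is kept).
#'
#' @param quals List of [segment_quality()] objects.
#' @param threshold Quality threshold in dB (default 5).
#' @return List with `kept` and `rejected` (sub-lists) and `report`, a
#'   data.frame (`segment_id`, `n_beats`, `snr_bar_db`, `kept`).
#' @export
filter_segments <- function(quals, threshold = 5) {
  keep <- vapply(quals, function(q) q$snr_bar >= threshold, logical(1))
  report <- data.frame(
    segment_id = vapply(quals, `[[`, "", "segment_id"),
    n_beats = vapply(quals, `[[`, 0, "n_beats"),
    snr_bar_db = vapply(quals, `[[`, 0, "snr_bar"),
    kept = keep)
  list(kept = quals[keep], rejected = quals[!keep], report = report)
}
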