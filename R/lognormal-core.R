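# Forward model: sums of time-shifted, scaled lognormal components.
#
# A beat is modeled as six components in fixed physiological order
# P, Q, R, S, T+ ("Tp"), T- ("Tm"); each contributes D * Lambda(t; mu,
# sigma, t0) with Lambda the shifted lognormal density. All logs are
# natural logs; the density is defined as exactly 0 for t <= t0.

#' Component labels in physiological order
#'
#' The six waves of the modeled PQRST complex. The T wave is represented
#' by a positive (`Tp`) and a negative (`Tm`) lognormal to capture its
#' negative skew.
#'
#' @return Character vector of the six labels, in peak-time order.
#' @export
component_labels <- function() c("P", "Q", "R", "S", "Tp", "Tm")

# sign of D fixed per label (depolarization vs repolarization direction)
.component_signs <- c(P = 1, Q = -1, R = 1, S = -1, Tp = 1, Tm = -1)

#' Names of the 24 free parameters
#'
#' Flat naming used for vectors, CSV records and bounds tables:
#' `<label>_<mu|sigma|t0|D>` in component order.
#'
#' @return Character vector of length 24.
#' @export
param_names <- function() {
  as.vector(t(outer(component_labels(), c("mu", "sigma", "t0", "D"),
                    paste, sep = "_")))
}

#' The 500-point normalized-time grid
#'
#' Beats are duration-normalized onto `[-1, 1)` with 500 equally spaced
#' samples (step 0.004): the first 250 cover the previous-R to own-R
#' half, the last 250 the own-R to next-R half, so index 251 sits at
#' normalized time 0 (the R peak).
#'
#' @return Numeric vector of length 500.
#' @export
normalized_time_grid <- function() {
  -1 + (0:499) * (2 / 500)
}

# unit-amplitude shifted lognormal density; 0 for t <= t0
.ln_pdf <- function(t, mu, sigma, t0) {
  out <- numeric(length(t))
  x <- t - t0
  pos <- x > 0
  if (any(pos)) {
    xx <- x[pos]
    z <- (log(xx) - mu) / sigma
    out[pos] <- exp(-0.5 * z * z) / (sigma * xx * sqrt(2 * pi))
  }
  out
}

#' Single lognormal component
#'
#' @param label One of `component_labels()`.
#' @param mu Log-time location (natural log of the time axis in use).
#' @param sigma Log-time spread; must be > 0.
#' @param t0 Onset time; the component is identically 0 for `t <= t0`.
#' @param D Signed amplitude-integral (uV times time-unit). The sign is
#'   fixed by the label: positive for P, R, Tp; negative for Q, S, Tm
#'   (zero allowed).
#'
#' @return An object of class `lognormal_component`.
#' @export
lognormal_component <- function(label, mu, sigma, t0, D) {
  label <- match.arg(label, component_labels())
  stopifnot(is.finite(mu), is.finite(t0), is.finite(D))
  if (!is.finite(sigma) || sigma <= 0)
    stop("invalid parameter: sigma must be > 0, got ", sigma)
  sgn <- .component_signs[[label]]
  if (D * sgn < 0)
    stop("invalid parameter: D for component ", label, " must be ",
         if (sgn > 0) "non-negative" else "non-positive", ", got ", D)
  structure(list(label = label, mu = unname(mu), sigma = unname(sigma),
                 t0 = unname(t0), D = unname(D)),
            class = "lognormal_component")
}

#' Evaluate one scaled lognormal component
#'
#' Returns `D * Lambda(t; mu, sigma, t0)` with `Lambda` the shifted
#' lognormal density, exactly 0 wherever `t <= t0`.
#'
#' @param t Numeric time grid (finite).
#' @param comp A [lognormal_component()].
#' @return Numeric vector, same length as `t`.
#' @export
lognormal_density <- function(t, comp) {
  stopifnot(inherits(comp, "lognormal_component"), all(is.finite(t)))
  comp$D * .ln_pdf(t, comp$mu, comp$sigma, comp$t0)
}

#' Peak (mode) time of a lognormal component
#'
#' Closed form `t0 + exp(mu - sigma^2)`; this is the abscissa of the
#' density maximum and defines the ordering of the six waves.
#'
#' @param comp A [lognormal_component()], or a list of them.
#' @return Numeric scalar (or vector for a list input).
#' @export
peak_time <- function(comp) {
  if (inherits(comp, "lognormal_component"))
    return(comp$t0 + exp(comp$mu - comp$sigma^2))
  if (inherits(comp, "sigma_lognormal_params"))
    return(.peak_times(comp$theta))
  stop("peak_time expects a lognormal_component or sigma_lognormal_params")
}

# peak times from a flat 24-vector (hot path)
.peak_times <- function(theta) {
  i <- (0:5) * 4
  theta[i + 3] + exp(theta[i + 1] - theta[i + 2]^2)
}

#' Six-component PQRST parameter set
#'
#' Bundles exactly six components in fixed order P, Q, R, S, Tp, Tm
#' (24 free scalars) together with the time basis the values live in.
#' Construction enforces strictly increasing peak times across
#' consecutive components; ties are rejected as degenerate.
#'
#' @param components List of six [lognormal_component()] in order, or
#'   `NULL` when `theta` is given.
#' @param time_basis `"normalized"` (per-beat axis on `[-1, 1)`) or
#'   `"seconds"`.
#' @param theta Alternative input: named or unnamed numeric vector of
#'   the 24 parameters in `param_names()` order.
#' @param check When `FALSE`, skip validation (internal hot paths).
#' @return An object of class `sigma_lognormal_params` with fields
#'   `theta` (named 24-vector) and `time_basis`.
#' @export
sigma_lognormal_params <- function(components = NULL,
                                   time_basis = c("normalized", "seconds"),
                                   theta = NULL, check = TRUE) {
  time_basis <- match.arg(time_basis)
  if (is.null(theta)) {
    if (length(components) != 6L)
      stop("exactly six components required")
    labs <- vapply(components, `[[`, "", "label")
    if (!identical(labs, component_labels()))
      stop("components must be in order ",
           paste(component_labels(), collapse = ", "))
    theta <- unlist(lapply(components, function(cp)
      c(cp$mu, cp$sigma, cp$t0, cp$D)), use.names = FALSE)
  }
  theta <- as.numeric(theta)
  if (length(theta) != 24L) stop("theta must have 24 entries")
  names(theta) <- param_names()
  obj <- structure(list(theta = theta, time_basis = time_basis),
                   class = "sigma_lognormal_params")
  if (check) .validate_theta(theta)
  obj
}

.validate_theta <- function(theta) {
  i <- (0:5) * 4
  if (!all(is.finite(theta))) stop("non-finite parameter value")
  if (any(theta[i + 2] <= 0))
    stop("invalid parameter: all sigma must be > 0")
  sgn <- .component_signs[component_labels()]
  if (any(theta[i + 4] * sgn < 0))
    stop("invalid parameter: D sign must match component polarity")
  tp <- .peak_times(theta)
  if (any(diff(tp) <= 0))
    stop("peak-order violation: peak times must be strictly increasing ",
         "(P < Q < R < S < Tp < Tm)")
  invisible(TRUE)
}

#' @export
print.sigma_lognormal_params <- function(x, ...) {
  cat("Sigma-lognormal PQRST parameters (", x$time_basis, " basis)\n",
      sep = "")
  m <- matrix(x$theta, nrow = 6, byrow = TRUE,
              dimnames = list(component_labels(),
                              c("mu", "sigma", "t0", "D")))
  print(round(m, 6))
  invisible(x)
}

#' Extract one component from a parameter set
#'
#' @param params A [sigma_lognormal_params()].
#' @param label Component label.
#' @return A [lognormal_component()].
#' @export
get_component <- function(params, label) {
  label <- match.arg(label, component_labels())
  i <- (match(label, component_labels()) - 1L) * 4L
  th <- params$theta
  lognormal_component(label, th[i + 1], th[i + 2], th[i + 3], th[i + 4])
}

# raw synthesis from a flat 24-vector (hot path, no validation)
.synthesize_theta <- function(theta, t) {
  out <- numeric(length(t))
  for (k in 0:5) {
    i <- k * 4
    D <- theta[i + 4]
    if (D != 0)
      out <- out + D * .ln_pdf(t, theta[i + 1], theta[i + 2], theta[i + 3])
  }
  out
}

#' Synthesize the PQRST waveform
#'
#' Pointwise sum of the six scaled component densities.
#'
#' @param params A [sigma_lognormal_params()].
#' @param t Time grid in the same basis as `params`; defaults to the
#'   500-point normalized grid.
#' @return Numeric signal vector (uV).
#' @export
synthesize <- function(params, t = normalized_time_grid()) {
  stopifnot(inherits(params, "sigma_lognormal_params"), all(is.finite(t)))
  .synthesize_theta(params$theta, t)
}

#' Rescale parameters from normalized time to seconds
#'
#' Undoes the per-beat duration normalization. For a time compression
#' `t* = alpha * t` the profile is numerically preserved by the map
#' `{mu, sigma, t0, D} -> {mu + log(alpha), sigma, alpha * t0,
#' alpha * D}` (natural log). Amplitude in uV is unchanged; D changes
#' units from uV·(normalized time) to uV·s.
#'
#' @param params A [sigma_lognormal_params()] in normalized basis.
#' @param alpha Positive time-scale factor in seconds per normalized
#'   unit (half the previous-R to next-R span).
#' @return A `sigma_lognormal_params` in seconds basis.
#' @export
denormalize_params <- function(params, alpha) {
  stopifnot(inherits(params, "sigma_lognormal_params"))
  if (!is.finite(alpha) || alpha <= 0)
    stop("invalid scale: alpha must be > 0, got ", alpha)
  if (params$time_basis != "normalized")
    stop("params already in seconds basis")
  sigma_lognormal_params(theta = .denorm_theta(params$theta, alpha),
                         time_basis = "seconds")
}

.denorm_theta <- function(theta, alpha) {
  i <- (0:5) * 4
  theta[i + 1] <- theta[i + 1] + log(alpha)
  theta[i + 3] <- theta[i + 3] * alpha
  theta[i + 4] <- theta[i + 4] * alpha
  theta
}

#' Flatten / restore parameter sets as one-row records
#'
#' `params_to_record()` returns a one-row data.frame with the 24 named
#' parameter columns plus `time_basis`; `params_from_record()` inverts
#' it. This is the CSV/JSON exchange format used by the extractor and
#' the synthetic generator.
#'
#' @param params A [sigma_lognormal_params()].
#' @return A one-row `data.frame`.
#' @export
params_to_record <- function(params) {
  stopifnot(inherits(params, "sigma_lognormal_params"))
  rec <- as.data.frame(as.list(params$theta))
  rec$time_basis <- params$time_basis
  rec
}

#' @rdname params_to_record
#' @param record A one-row data.frame or named list with the 24
#'   parameter fields and optionally `time_basis`.
#' @export
params_from_record <- function(record) {
  nm <- param_names()
  if (!all(nm %in% names(record)))
    stop("record is missing parameter fields: ",
         paste(setdiff(nm, names(record)), collapse = ", "))
  basis <- if (!is.null(record[["time_basis"]]))
    as.character(record[["time_basis"]]) else "normalized"
  sigma_lognormal_params(theta = as.numeric(record[nm]), time_basis = basis)
}
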