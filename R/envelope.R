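# Closed-form pointwise envelopes of a lognormal component over a
# parameter box, and their signed sums for the six-component model.
#
# The upper envelope is a 10-branch piecewise construction: on each
# time interval the supremum of the unit-amplitude density over the
# box is attained either at a box corner or at an interior stationary
# point (sigma* = mu_lo - log(t - t0_lo) on the rising flank,
# mu* = log(t - t0_hi) around the crest, sigma* = log(t - t0_hi) -
# mu_hi on the falling flank), with a constant plateau at the peak
# value between the two mode abscissae. The lower envelope is the
# minimum over five corner evaluations. Envelopes are for the
# unit-amplitude density; amplitude signs enter only in the model-level
# signed sums.

#' Parameter box for a single component
#'
#' @param mu_lo,mu_hi,sigma_lo,sigma_hi,t0_lo,t0_hi,D_lo,D_hi Scalar
#'   bounds, `lo <= hi`, `sigma_lo > 0`. Amplitude bounds default to
#'   the unit interval and only matter for the signed model sums.
#' @return An object of class `component_box`.
#' @export
component_box <- function(mu_lo, mu_hi, sigma_lo, sigma_hi,
                          t0_lo, t0_hi, D_lo = 0, D_hi = 1) {
  stopifnot(mu_lo <= mu_hi, sigma_lo <= sigma_hi, t0_lo <= t0_hi,
            D_lo <= D_hi, sigma_lo > 0)
  structure(list(mu_lo = mu_lo, mu_hi = mu_hi, sigma_lo = sigma_lo,
                 sigma_hi = sigma_hi, t0_lo = t0_lo, t0_hi = t0_hi,
                 D_lo = D_lo, D_hi = D_hi),
            class = "component_box")
}

# six component boxes from a parameter_bounds object
.component_boxes <- function(bounds) {
  lapply(0:5, function(k) {
    i <- k * 4
    component_box(bounds$lower[i + 1], bounds$upper[i + 1],
                  bounds$lower[i + 2], bounds$upper[i + 2],
                  bounds$lower[i + 3], bounds$upper[i + 3],
                  bounds$lower[i + 4], bounds$upper[i + 4])
  })
}

#' Pointwise lower envelope of a component over its box
#'
#' Minimum over five corner evaluations of the unit-amplitude shifted
#' lognormal density; 0 wherever every candidate has no support.
#'
#' @param t Numeric time grid.
#' @param box A [component_box()].
#' @return Numeric vector, `min` over the candidate densities at each t.
#' @export
component_lower_envelope <- function(t, box) {
  stopifnot(inherits(box, "component_box"))
  pmin(.ln_pdf(t, box$mu_hi, box$sigma_lo, box$t0_hi),
       .ln_pdf(t, box$mu_hi, box$sigma_hi, box$t0_hi),
       .ln_pdf(t, box$mu_hi, box$sigma_hi, box$t0_lo),
       .ln_pdf(t, box$mu_lo, box$sigma_hi, box$t0_lo),
       .ln_pdf(t, box$mu_lo, box$sigma_lo, box$t0_lo))
}

#' Pointwise upper envelope of a component over its box
#'
#' Exact piecewise supremum of the unit-amplitude density over the box
#' (10 branches, continuous across breakpoints). Branch intervals are
#' left-open/right-closed; the construction assumes `sigma_hi < 1` so
#' the mode abscissa ordering `exp(mu - sigma) < exp(mu - sigma^2) <
#' exp(mu)` holds.
#'
#' @inheritParams component_lower_envelope
#' @return Numeric vector.
#' @export
component_upper_envelope <- function(t, box) {
  stopifnot(inherits(box, "component_box"))
  mu_l <- box$mu_lo; mu_h <- box$mu_hi
  sg_l <- box$sigma_lo; sg_h <- box$sigma_hi
  t0_l <- box$t0_lo; t0_h <- box$t0_hi
  bp <- c(t0_l,
          t0_l + exp(mu_l - sg_h),
          t0_l + exp(mu_l - sg_l),
          t0_l + exp(mu_l - sg_l^2),
          t0_h + exp(mu_l - sg_l^2),
          t0_h + exp(mu_l),
          t0_h + exp(mu_h),
          t0_h + exp(mu_h + sg_l),
          t0_h + exp(mu_h + sg_h))
  # branch index: number of breakpoints strictly below t (]a, b] bins)
  idx <- rowSums(outer(t, bp, ">"))
  out <- numeric(length(t))
  peak_val <- exp(sg_l^2 / 2 - mu_l) / (sg_l * sqrt(2 * pi))
  for (b in sort(unique(idx))) {
    sel <- idx == b
    tt <- t[sel]
    out[sel] <- switch(as.character(b),
      "0" = 0,
      "1" = .ln_pdf(tt, mu_l, sg_h, t0_l),
      "2" = .ln_pdf(tt, mu_l, mu_l - log(tt - t0_l), t0_l),
      "3" = .ln_pdf(tt, mu_l, sg_l, t0_l),
      "4" = rep(peak_val, length(tt)),
      "5" = .ln_pdf(tt, mu_l, sg_l, t0_h),
      "6" = 1 / (sg_l * (tt - t0_h) * sqrt(2 * pi)),
      "7" = .ln_pdf(tt, mu_h, sg_l, t0_h),
      "8" = .ln_pdf(tt, mu_h, log(tt - t0_h) - mu_h, t0_h),
      "9" = .ln_pdf(tt, mu_h, sg_h, t0_h))
  }
  out
}

#' Signed model-level envelopes over the full constraint box
#'
#' Combines the six per-component unit-amplitude envelopes with the
#' amplitude bounds: a component whose lower amplitude is positive
#' contributes `D_lo * lower_envelope` to the model lower envelope and
#' `D_hi * upper_envelope` to the upper one; a negative-amplitude
#' component contributes with the envelopes swapped. Every waveform
#' synthesizable from in-box parameters lies between the two curves.
#'
#' @param t Numeric time grid (defaults to the 500-point normalized
#'   grid).
#' @param bounds A [parameter_bounds()].
#' @return A list with numeric vectors `lower` and `upper`.
#' @export
model_envelopes <- function(t = normalized_time_grid(),
                            bounds = load_table_bounds()) {
  boxes <- .component_boxes(bounds)
  lower <- numeric(length(t)); upper <- numeric(length(t))
  for (bx in boxes) {
    lo_env <- component_lower_envelope(t, bx)
    hi_env <- component_upper_envelope(t, bx)
    lower <- lower + if (bx$D_lo > 0) bx$D_lo * lo_env else bx$D_lo * hi_env
    upper <- upper + if (bx$D_hi > 0) bx$D_hi * hi_env else bx$D_hi * lo_env
  }
  list(lower = lower, upper = upper)
}
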