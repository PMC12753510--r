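# DSC-MRI forward model: concentration conversion, gamma transit-time
# family, and the tissue curve with a linear leakage term.

#' Gamma transit-time distribution
#'
#' Parameterizes the capillary transit-time distribution as a gamma family
#' with shape `alpha = mtt^2 / cth^2` and scale `beta = cth^2 / mtt`, so
#' that the mean is MTT and the standard deviation is CTH.
#'
#' @param mtt mean transit time (s), > 0.
#' @param cth capillary transit-time heterogeneity (s), >= 0; `cth = 0`
#'   denotes the degenerate single-transit-time limit.
#' @return a `transit_distribution` (alpha, beta, mtt, cth).
#' @export
transit_distribution <- function(mtt, cth) {
  stopifnot(mtt > 0, cth >= 0)
  if (cth == 0)
    return(structure(list(alpha = Inf, beta = 0, mtt = mtt, cth = cth),
                     class = "transit_distribution"))
  structure(list(alpha = mtt^2 / cth^2, beta = cth^2 / mtt,
                 mtt = mtt, cth = cth),
            class = "transit_distribution")
}

#' Vascular residue function
#'
#' Fraction of tracer still inside the vasculature t seconds after an
#' idealized instantaneous input: `R(t) = 1 - integral_0^t h(tau)`.
#'
#' @param t time (s), >= 0.
#' @param dist a [transit_distribution()].
#' @return values in `[0, 1]`, monotone non-increasing, `R(0) = 1`.
#' @export
residue_function <- function(t, dist) {
  stopifnot(inherits(dist, "transit_distribution"), all(t >= 0))
  if (!is.finite(dist$alpha)) return(as.numeric(t < dist$mtt))
  1 - pgamma(t, shape = dist$alpha, scale = dist$beta)
}

#' Convert DSC signal to concentration
#'
#' Gradient-echo relation `C(t) = -ln(S(t)/S0) / TE` with S0 the mean over
#' the baseline window, so baseline frames map to approximately zero.
#'
#' @param signal signal vector per frame.
#' @param te echo time (s).
#' @param baseline_idx indices of the pre-bolus baseline window.
#' @return concentration (Delta-R2*, 1/s) vector, or `NULL` if any frame is
#'   non-positive (unfittable voxel).
#' @export
signal_to_deltaR2 <- function(signal, te, baseline_idx) {
  stopifnot(te > 0, length(baseline_idx) >= 1,
            max(baseline_idx) <= length(signal))
  if (any(!is.finite(signal)) || any(signal <= 0)) return(NULL)
  s0 <- mean(signal[baseline_idx])
  -log(signal / s0) / te
}

# linear fractional-frame shift of a curve sampled on a uniform grid,
# zero-padded on the left
shift_curve <- function(values, times, delay) {
  if (delay == 0) return(values)
  approx(times + delay, values, xout = times, yleft = 0, rule = c(1, 2))$y
}

# trapezoidal discrete convolution of two curves on a shared uniform grid
conv_trap <- function(a, r, dt) {
  n <- length(a)
  full <- convolve(a, rev(r), type = "open")[seq_len(n)]
  dt * (full - 0.5 * (a[1] * r + a * r[1]))
}

# cumulative trapezoidal integral on a uniform grid
cumtrapz_uniform <- function(y, dt) {
  n <- length(y)
  c(0, cumsum((y[-n] + y[-1]) / 2 * dt))
}

#' Predict a tissue concentration curve
#'
#' `C_t(t) = cbf * (AIF (x) R)(t - delay) + k2 * integral_0^t AIF(u - delay) du`
#' with the convolution evaluated trapezoidally on the frame grid and the
#' delay applied by fractional-frame linear interpolation of the AIF. The
#' additive cumulative-AIF term is the linear leakage component used for
#' extravasation-insensitive fitting.
#'
#' @param aif arterial input concentration per frame.
#' @param times uniform time grid (s).
#' @param cbf flow scale (1/s when the AIF is in Delta-R2* units).
#' @param dist a [transit_distribution()].
#' @param delay bolus delay (s), >= 0.
#' @param k2 leakage coefficient (1/s).
#' @return concentration vector on `times`.
#' @export
predict_tissue_curve <- function(aif, times, cbf, dist, delay = 0, k2 = 0) {
  stopifnot(length(aif) == length(times), delay >= 0)
  dt <- times[2] - times[1]
  if (max(abs(diff(times) - dt)) > 1e-9 * dt)
    stop("times must be a uniform grid")
  if (delay >= max(times))
    stop("delay pushes the bolus outside the time grid")
  a <- shift_curve(aif, times, delay)
  rt <- residue_function(times, dist)
  curve <- cbf * conv_trap(a, rt, dt)
  if (k2 != 0) curve <- curve + k2 * cumtrapz_uniform(a, dt)
  curve
}
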