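# Extended flow-diffusion oxygen transport: Hill-equation capillary
# extraction, gamma-weighted OEF(MTT, CTH, PtO2), and the tissue oxygen
# tension solve under a resting metabolic demand constraint.

#' Oxygen transport model parameters
#'
#' Constants of the extended flow-diffusion model. The capillary transfer is
#' `dB/dt = -k * alpha_o2 * (P(B) - pt)` with B the blood oxygen content
#' (mL O2 / mL blood), P(B) the inverse Hill tension of the saturation
#' B/ca, and the driving gradient expressed as a dissolved-plasma
#' concentration difference via the oxygen solubility `alpha_o2`. All
#' constants are configuration-exposed.
#'
#' @param p50 half-saturation tension (mmHg).
#' @param h Hill cooperativity exponent.
#' @param ca arterial oxygen carrying capacity B0 (mL O2 / mL blood).
#' @param k oxygen transfer rate constant (1/s).
#' @param alpha_o2 plasma oxygen solubility (mL O2 / mL / mmHg).
#' @param p_a arterial plasma oxygen tension (mmHg).
#' @param cmro2_target resting metabolic demand (ml O2 / 100 ml / min).
#' @param n_nodes quadrature node count for the transit-time integral.
#' @param ode_rtol,ode_atol step-control tolerances of the capillary ODE.
#' @return an `oxygen_params` object.
#' @export
oxygen_params <- function(p50 = 26, h = 2.8, ca = 0.19, k = 118,
                          alpha_o2 = 3.1e-5, p_a = 95, cmro2_target = 2.5,
                          n_nodes = 96, ode_rtol = 1e-8, ode_atol = 1e-12) {
  stopifnot(p50 > 0, h > 0, ca > 0, k > 0, alpha_o2 > 0, p_a > 0,
            cmro2_target >= 0, n_nodes >= 4)
  if (p50 >= p_a) stop("p50 must be below the arterial tension p_a")
  structure(list(p50 = p50, h = h, ca = ca, k = k, alpha_o2 = alpha_o2,
                 p_a = p_a, cmro2_target = cmro2_target, n_nodes = n_nodes,
                 ode_rtol = ode_rtol, ode_atol = ode_atol),
            class = "oxygen_params")
}

#' Hill oxygen-hemoglobin saturation and its inverse
#'
#' `S(P) = P^h / (P^h + P50^h)`; the inverse maps a saturation in `[0, 1)`
#' back to a tension.
#'
#' @param p tension (mmHg), >= 0.
#' @param params an [oxygen_params()].
#' @return saturation fraction in `[0, 1)`.
#' @export
hill_saturation <- function(p, params = oxygen_params()) {
  stopifnot(all(p >= 0))
  p^params$h / (p^params$h + params$p50^params$h)
}

#' @rdname hill_saturation
#' @param s saturation fraction in `[0, 1)`.
#' @export
inverse_hill <- function(s, params = oxygen_params()) {
  if (any(s >= 1)) stop("saturation 1 corresponds to unbounded tension")
  stopifnot(all(s >= 0))
  params$p50 * (s / (1 - s))^(1 / params$h)
}

# one dense solve of the capillary oxygen content B(t) on [0, max(taus)]:
# because the transit-time tau only rescales capillary position onto
# physical time, a single trajectory yields the outlet content for every
# tau simultaneously. Back-transfer is clamped (one-way extraction).
capillary_content <- function(taus, pt, params) {
  b0 <- params$ca * hill_saturation(params$p_a, params)
  taus <- as.numeric(taus)
  tgrid <- sort(unique(c(0, taus)))
  if (length(tgrid) == 1) return(rep(b0, length(taus)))
  deriv <- function(t, y, parms) {
    s <- clamp(y[1] / params$ca, 0, 1 - 1e-12)
    p <- inverse_hill(s, params)
    list(-params$k * params$alpha_o2 * max(p - pt, 0))
  }
  sol <- deSolve::ode(y = c(B = b0), times = tgrid, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = params$ode_rtol, atol = params$ode_atol)
  if (nrow(sol) < length(tgrid) || any(!is.finite(sol[, "B"])))
    stop("capillary ODE integration failed at pt = ", pt,
         ", tau up to ", max(taus))
  bt <- approx(sol[, "time"], sol[, "B"], xout = taus)$y
  clamp(bt, 0, b0)
}

#' Single-capillary oxygen extraction
#'
#' Fraction of the inlet oxygen content extracted during one transit of
#' duration `tau` at tissue tension `pt`: the capillary ODE
#' `dB/dx = -k alpha_o2 tau (P(B) - pt)` integrated over the normalized
#' capillary length.
#'
#' @param tau transit time (s), >= 0.
#' @param pt tissue oxygen tension (mmHg) in `[0, p_a]`.
#' @param params an [oxygen_params()].
#' @return extraction fraction Q in `[0, 1]`.
#' @export
single_capillary_extraction <- function(tau, pt, params = oxygen_params()) {
  stopifnot(all(tau >= 0), pt >= 0, pt <= params$p_a)
  b0 <- params$ca * hill_saturation(params$p_a, params)
  bt <- capillary_content(tau, pt, params)
  (b0 - bt) / b0
}

# cached Gauss-Legendre nodes on (0, 1)
.gl_cache <- new.env(parent = emptyenv())
gl_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]]))
    .gl_cache[[key]] <- pracma::gaussLegendre(n, 0, 1)
  .gl_cache[[key]]
}

#' Gamma-weighted oxygen extraction fraction
#'
#' `OEF(mtt, cth, pt) = integral h(tau; alpha, beta) Q(tau, pt) dtau`, the
#' extraction averaged over the gamma transit-time distribution. The
#' integral is evaluated by Gauss-Legendre quadrature in the probability
#' domain (nodes mapped through the gamma quantile function), so the
#' density integrates exactly to one.
#'
#' @param mtt mean transit time (s), > 0.
#' @param cth transit-time heterogeneity (s), >= 0; 0 gives the
#'   single-transit limit `Q(mtt, pt)`.
#' @param pt tissue oxygen tension (mmHg).
#' @param params an [oxygen_params()].
#' @param check_convergence re-evaluate with doubled nodes and error if the
#'   two results differ by more than 1e-5.
#' @return OEF in `[0, 1]`.
#' @export
oef_gamma <- function(mtt, cth, pt, params = oxygen_params(),
                      check_convergence = FALSE) {
  stopifnot(mtt > 0, cth >= 0)
  eval_n <- function(n) {
    if (cth == 0)
      return(single_capillary_extraction(mtt, pt, params))
    dist <- transit_distribution(mtt, cth)
    gl <- gl_nodes(n)
    taus <- qgamma(gl$x, shape = dist$alpha, scale = dist$beta)
    q <- single_capillary_extraction(taus, pt, params)
    sum(gl$w * q)
  }
  oef <- eval_n(params$n_nodes)
  if (check_convergence && cth > 0) {
    oef2 <- eval_n(2 * params$n_nodes)
    if (abs(oef2 - oef) > 1e-5)
      stop("transit-time quadrature did not converge (node doubling ",
           "changed OEF by ", signif(abs(oef2 - oef), 3), ")")
  }
  clamp(oef, 0, 1)
}

#' Forward metabolic rate of oxygen
#'
#' `CMRO2 = CA * CBF * OEF(mtt, cth, pt)` in ml O2/100 ml/min.
#'
#' @inheritParams oef_gamma
#' @param cbf_abs absolute cerebral blood flow (ml/100 ml/min).
#' @return CMRO2 (ml O2/100 ml/min).
#' @export
cmro2_forward <- function(cbf_abs, mtt, cth, pt, params = oxygen_params()) {
  params$ca * cbf_abs * oef_gamma(mtt, cth, pt, params)
}

#' Solve tissue oxygen tension under the resting demand constraint
#'
#' Finds the tension at which net oxygen extraction exactly meets the
#' resting metabolic demand, `CMRO2(pt) = cmro2_target`. CMRO2 is strictly
#' decreasing in pt, so the root is bracketed on `[0, p_a]` and refined by
#' bisection until the forward CMRO2 matches the target to 1e-6 relative.
#' When even `pt = 0` cannot meet the demand the voxel is flagged
#' infeasible with `pto2 = 0`.
#'
#' @param cbf_abs absolute CBF (ml/100 ml/min).
#' @param mtt mean transit time (s).
#' @param cth transit-time heterogeneity (s).
#' @param params an [oxygen_params()].
#' @return an `oxygen_estimate`: `oef`, `pto2` (mmHg), `cmro2`, `feasible`.
#' @export
solve_pto2 <- function(cbf_abs, mtt, cth, params = oxygen_params()) {
  stopifnot(cbf_abs >= 0, mtt > 0, cth >= 0)
  target <- params$cmro2_target
  f <- function(pt) cmro2_forward(cbf_abs, mtt, cth, pt, params) - target
  est <- function(oef, pto2, cmro2, feasible)
    structure(list(oef = oef, pto2 = pto2, cmro2 = cmro2,
                   feasible = feasible), class = "oxygen_estimate")
  c0 <- f(0) + target
  if (c0 < target)
    return(est(oef_gamma(mtt, cth, 0, params), 0, c0, FALSE))
  if (target == 0)
    return(est(0, params$p_a, 0, TRUE))
  lo <- 0; hi <- params$p_a
  flo <- c0 - target; fhi <- f(hi)
  pt <- NA_real_
  for (it in seq_len(200)) {
    pt <- (lo + hi) / 2
    fm <- f(pt)
    if (abs(fm) < 1e-6 * target) break
    if (sign(fm) == sign(flo)) { lo <- pt; flo <- fm } else { hi <- pt }
    if (hi - lo < 1e-14 * params$p_a) break
  }
  est(oef_gamma(mtt, cth, pt, params), pt, f(pt) + target, TRUE)
}

#' @export
tidy.oxygen_estimate <- function(x, ...) {
  tibble::tibble(oef = x$oef, pto2 = x$pto2, cmro2 = x$cmro2,
                 feasible = x$feasible)
}

#' Oxygen estimates for a table of perfusion values
#'
#' Vectorized [solve_pto2()] over rows of a tibble, calibrating relative
#' flow to absolute units via a reference deep-NAWM CBF.
#'
#' @param data tibble with columns `mtt`, `cth` and either `cbf_abs` or
#'   `rcbf`.
#' @param nawm_cbf reference absolute CBF (ml/100 ml/min) multiplying
#'   `rcbf` when `cbf_abs` is absent.
#' @param params an [oxygen_params()].
#' @return `data` with `oef`, `pto2`, `cmro2`, `feasible` columns added.
#' @export
oxygen_estimates <- function(data, nawm_cbf = 22, params = oxygen_params()) {
  cbf <- if ("cbf_abs" %in% names(data)) data$cbf_abs else data$rcbf * nawm_cbf
  res <- purrr::pmap(list(cbf, data$mtt, data$cth), function(cb, m, ct)
    tidy.oxygen_estimate(solve_pto2(cb, m, ct, params)))
  dplyr::bind_cols(data, dplyr::bind_rows(res))
}
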