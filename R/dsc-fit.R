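# Parametric deconvolution of DSC concentration curves: bounded nonlinear
# least squares over (MTT, CTH, delay) with the flow scale and the leakage
# coefficient profiled out linearly at each step.

#' Fit the gamma transit-time model to one concentration curve
#'
#' Minimizes the sum of squared residuals of [predict_tissue_curve()] over
#' (log MTT, log CTH, delay) with L-BFGS-B from a multistart grid
#' (MTT in {2, 4, 8} s crossed with CTH in {0.5, 1} x MTT); for each shape
#' candidate the linear parameters (CBF, and K2 when `fit_k2`) are solved
#' exactly by least squares.
#'
#' @param curve tissue concentration curve (Delta-R2*, 1/s).
#' @param aif arterial input curve on the same uniform time grid.
#' @param times time grid (s).
#' @param fit_k2 co-estimate the linear leakage coefficient (default TRUE);
#'   set FALSE to pin K2 = 0 for non-enhancing analyses.
#' @param mtt_starts,cth_frac_starts multistart grid.
#' @param bounds named list with elements `mtt`, `cth`, `delay` giving
#'   (lower, upper) box constraints.
#' @param rss_tol convergence flag threshold: relative residual
#'   `rss / sum(curve^2)` must fall below it.
#' @return a `perfusion_fit`: cbf, cbv, mtt, cth, alpha, beta, delay, k2,
#'   rss, converged.
#' @export
fit_perfusion_voxel <- function(curve, aif, times, fit_k2 = TRUE,
                                mtt_starts = c(2, 4, 8),
                                cth_frac_starts = c(0.5, 1),
                                bounds = list(mtt = c(0.3, 30),
                                              cth = c(0.02, 30),
                                              delay = c(0, 8)),
                                rss_tol = 0.25) {
  stopifnot(length(curve) == length(times), length(aif) == length(times))
  dt <- times[2] - times[1]
  if (sum(aif) * dt <= 0) stop("AIF must have positive area")
  lin_solve <- function(mtt, cth, delay) {
    a <- shift_curve(aif, times, delay)
    x1 <- conv_trap(a, residue_function(times, transit_distribution(mtt, cth)),
                    dt)
    X <- if (fit_k2) cbind(x1, cumtrapz_uniform(a, dt)) else cbind(x1)
    cf <- tryCatch(qr.coef(qr(X), curve), error = function(e) NULL)
    if (is.null(cf) || any(!is.finite(cf))) return(NULL)
    if (cf[1] < 0) {                     # flow must be non-negative
      cf <- c(0, if (fit_k2) qr.coef(qr(X[, 2, drop = FALSE]), curve) else NULL)
    }
    resid <- curve - X %*% cf
    list(cbf = unname(cf[1]), k2 = if (fit_k2) unname(cf[2]) else 0,
         rss = sum(resid^2))
  }
  obj <- function(par) {
    ls <- lin_solve(exp(par[1]), exp(par[2]), par[3])
    if (is.null(ls)) return(1e12)
    ls$rss
  }
  lower <- c(log(bounds$mtt[1]), log(bounds$cth[1]), bounds$delay[1])
  upper <- c(log(bounds$mtt[2]), log(bounds$cth[2]), bounds$delay[2])
  best <- NULL
  for (m0 in mtt_starts) for (cf0 in cth_frac_starts) {
    par0 <- c(log(m0), log(cf0 * m0), bounds$delay[1])
    o <- tryCatch(
      optim(par0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(factr = 1e4, pgtol = 1e-12, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) {
    return(structure(list(cbf = NA_real_, cbv = NA_real_, mtt = NA_real_,
                          cth = NA_real_, alpha = NA_real_, beta = NA_real_,
                          delay = NA_real_, k2 = NA_real_, rss = NA_real_,
                          converged = FALSE),
                     class = "perfusion_fit"))
  }
  status_ok <- best$convergence == 0
  # derivative-free polish from the best box-constrained solution
  o2 <- optim(best$par, function(p) {
    if (any(p < lower | p > upper)) return(1e12)
    obj(p)
  }, method = "Nelder-Mead",
  control = list(maxit = 400, reltol = 1e-14))
  if (o2$value < best$value) best <- o2
  mtt <- exp(best$par[1]); cth <- exp(best$par[2]); delay <- best$par[3]
  ls <- lin_solve(mtt, cth, delay)
  dist <- transit_distribution(mtt, cth)
  converged <- status_ok && ls$rss <= rss_tol * sum(curve^2)
  structure(list(cbf = ls$cbf, cbv = ls$cbf * mtt, mtt = mtt, cth = cth,
                 alpha = dist$alpha, beta = dist$beta, delay = delay,
                 k2 = ls$k2, rss = ls$rss, converged = converged),
            class = "perfusion_fit")
}

#' @export
tidy.perfusion_fit <- function(x, ...) {
  tibble::tibble(cbf = x$cbf, cbv = x$cbv, mtt = x$mtt, cth = x$cth,
                 delay = x$delay, k2 = x$k2, rss = x$rss,
                 converged = x$converged)
}

#' Voxelwise perfusion maps
#'
#' Converts each in-mask voxel's signal to concentration and fits the
#' transit-time model, producing CBF/CBV/MTT/CTH/delay/K2 maps; unfittable
#' voxels (non-positive signal, failed fits) become `NA` and are counted.
#'
#' @param series 4D signal array (x, y, z, frame).
#' @param aif arterial input curve per frame.
#' @param times frame time grid (s).
#' @param mask logical 3D inclusion array.
#' @param te echo time (s).
#' @param baseline_idx baseline window indices.
#' @param fit_k2 co-estimate leakage (see [fit_perfusion_voxel()]).
#' @param max_unfittable hard-error threshold on the unfittable fraction.
#' @return list of 3D arrays (`cbf`, `cbv`, `mtt`, `cth`, `delay`, `k2`)
#'   plus `n_unfittable` and `n_voxels`.
#' @export
perfusion_maps <- function(series, aif, times, mask, te, baseline_idx,
                           fit_k2 = TRUE, max_unfittable = 0.5) {
  dims <- dim(series)
  stopifnot(length(dims) == 4, all(dim(mask) == dims[1:3]))
  idx <- which(mask)
  maps <- lapply(1:6, function(i) array(NA_real_, dims[1:3]))
  names(maps) <- c("cbf", "cbv", "mtt", "cth", "delay", "k2")
  flat <- matrix(aperm(series, c(4, 1, 2, 3)), nrow = dims[4])
  n_bad <- 0L
  for (v in idx) {
    conc <- signal_to_deltaR2(flat[, v], te, baseline_idx)
    if (is.null(conc)) { n_bad <- n_bad + 1L; next }
    fit <- fit_perfusion_voxel(conc, aif, times, fit_k2 = fit_k2)
    if (!isTRUE(fit$converged)) { n_bad <- n_bad + 1L; next }
    for (m in c("cbf", "cbv", "mtt", "cth", "delay", "k2"))
      maps[[m]][v] <- fit[[m]]
  }
  if (n_bad > max_unfittable * length(idx))
    stop("more than ", round(100 * max_unfittable),
         " % of in-mask voxels are unfittable: data/AIF mismatch")
  c(maps, list(n_unfittable = n_bad, n_voxels = length(idx)))
}

#' Normalize a metric volume to a reference region
#'
#' Divides by the mean over the reference mask, so relative maps (rCBF,
#' rCBV) average 1 in the reference tissue.
#'
#' @param volume numeric 3D array.
#' @param ref_mask logical 3D array, nonempty among finite voxels.
#' @return array of the same shape.
#' @export
normalize_relative <- function(volume, ref_mask) {
  stopifnot(all(dim(volume) == dim(ref_mask)))
  vals <- volume[ref_mask]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("reference mask is empty within valid voxels")
  m <- mean(vals)
  if (m <= 0) stop("reference mean is non-positive")
  volume / m
}
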