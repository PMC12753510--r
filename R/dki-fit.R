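# Constrained weighted-least-squares DKI fitting and the derived metric set.

dki_design <- function(scheme) {
  bb <- scheme$bval / 1000
  cbind(1, -bb * d_design(scheme$bvec), bb^2 / 6 * w_design(scheme$bvec))
}

#' Fit the DKI model to one voxel by weighted least squares
#'
#' Two-stage linear estimation on the log signal: ordinary least squares for
#' the 22 unknowns (log S0, 6 diffusion components, 15 components of the
#' joint block MD^2 W), then one reweighting iteration with weights equal to
#' the squared predicted signal. The kurtosis tensor is recovered by dividing
#' the joint block by the fitted MD^2. Negative diffusion eigenvalues are
#' clipped post hoc and flagged.
#'
#' @param signals positive signal vector, one per scheme volume.
#' @param scheme an [acquisition_scheme()].
#' @param clip_eig floor applied to diffusion eigenvalues (um^2/ms).
#' @return a `dki_fit` object (`s0`, `d6`, `w15`, `rss`, `flags`), or `NULL`
#'   for an unfittable voxel (any non-positive signal).
#' @export
fit_dki_wls <- function(signals, scheme, clip_eig = 1e-6) {
  X <- dki_design(scheme)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design: the scheme does not identify all 22 DKI ",
         "parameters (need >= 2 nonzero shells and 15+ outer directions)")
  fit_dki_wls_(signals, X, clip_eig)
}

# core used by both the single-voxel and volume paths (X prevalidated)
fit_dki_wls_ <- function(signals, X, clip_eig = 1e-6) {
  if (any(!is.finite(signals)) || any(signals <= 0)) return(NULL)
  y <- log(signals)
  beta <- qr.coef(qr(X), y)
  w <- exp(as.vector(X %*% beta))            # predicted signal = sqrt(weight)
  beta <- .lm.fit(X * w, y * w)$coefficients
  s0 <- exp(beta[1])
  d6 <- beta[2:7]
  md <- sum(d6[1:3]) / 3
  if (!is.finite(md) || md <= 0) return(NULL)
  w15 <- beta[8:22] / md^2
  flags <- c(clipped_eig = FALSE, clamped_k = FALSE)
  ev <- eigen(d6_to_matrix(d6), symmetric = TRUE)
  if (any(ev$values < clip_eig)) {
    vals <- pmax(ev$values, clip_eig)
    d6 <- matrix_to_d6(ev$vectors %*% diag(vals) %*% t(ev$vectors))
    flags["clipped_eig"] <- TRUE
  }
  rss <- sum((signals - exp(as.vector(X %*% beta)))^2)
  structure(list(s0 = s0, d6 = d6, w15 = w15, rss = rss, flags = flags),
            class = "dki_fit")
}

# eigen decomposition with the package's deterministic conventions:
# eigenvalues descending; each eigenvector's first component of magnitude
# > 1e-8 made positive; degeneracy of the principal pair flagged
dki_eigen <- function(d6, tie_tol = 1e-6) {
  ev <- eigen(d6_to_matrix(d6), symmetric = TRUE)
  V <- ev$vectors
  for (j in 1:3) {
    nz <- which(abs(V[, j]) > 1e-8)[1]
    if (!is.na(nz) && V[nz, j] < 0) V[, j] <- -V[, j]
  }
  degenerate <- (ev$values[1] - ev$values[2]) <=
    tie_tol * max(abs(ev$values[1]), 1e-12)
  list(values = ev$values, vectors = V, degenerate = degenerate)
}

#' Scalar DKI metrics from fitted tensors
#'
#' Computes MD, AD, RD from the diffusion eigenvalues, and MK, AK, RK, AWF
#' from directional averages of apparent kurtosis. The sphere sample for MK
#' (and the equator sample for RK) is anchored to the diffusion eigenframe,
#' which makes all scalar metrics exactly rotation equivariant and defines
#' the package's mean-kurtosis convention. AWF uses the kurtosis-maximum
#' formula `K_max / (K_max + 3)`.
#'
#' @param fit a `dki_fit`, or any list with `d6` and `w15`.
#' @param sphere_n sphere sample size for MK (default 1000).
#' @param equator_n equatorial directions for RK (default 64).
#' @param k_clamp apparent kurtosis is clamped to this range before
#'   averaging; clamping is flagged.
#' @return one-row tibble: md, ad, rd (um^2/ms); mk, ak, rk, awf (unitless);
#'   flags `degenerate` and `clamped_k`.
#' @export
dki_metrics <- function(fit, sphere_n = 1000, equator_n = 64,
                        k_clamp = c(0, 10)) {
  v <- dki_metrics_core(fit$d6, fit$w15, sphere_n, equator_n, k_clamp)
  tibble::tibble(
    md = v[["md"]], ad = v[["ad"]], rd = v[["rd"]],
    mk = v[["mk"]], ak = v[["ak"]], rk = v[["rk"]], awf = v[["awf"]],
    degenerate = v[["degenerate"]] > 0, clamped_k = v[["clamped_k"]] > 0)
}

# numeric-vector core shared by the tibble API and the volume hot loop
dki_metrics_core <- function(d6, w15, sphere_n = 1000, equator_n = 64,
                             k_clamp = c(0, 10)) {
  eg <- dki_eigen(d6)
  lam <- eg$values
  md <- mean(lam)
  # sphere and equator samples anchored to the diffusion eigenframe
  dirs <- fibonacci_sphere(sphere_n) %*% t(eg$vectors)
  phi <- (seq_len(equator_n) - 1) / equator_n * pi   # half-turn: K is even
  eq_dirs <- outer(cos(phi), eg$vectors[, 2]) + outer(sin(phi), eg$vectors[, 3])
  all_dirs <- rbind(dirs, eq_dirs, eg$vectors[, 1])
  dn <- as.vector(d_design(all_dirs) %*% d6)
  wn <- as.vector(w_design(all_dirs) %*% w15)
  k <- md^2 / pmax(dn, 1e-12)^2 * wn
  clamped <- any(k < k_clamp[1] | k > k_clamp[2])
  k <- clamp(k, k_clamp[1], k_clamp[2])
  i_sph <- seq_len(sphere_n)
  i_eq <- sphere_n + seq_len(equator_n)
  kmax <- max(k)
  c(md = md, ad = lam[1], rd = (lam[2] + lam[3]) / 2,
    mk = mean(k[i_sph]), ak = k[length(k)], rk = mean(k[i_eq]),
    awf = kmax / (kmax + 3),
    degenerate = as.numeric(eg$degenerate), clamped_k = as.numeric(clamped))
}

#' Fit DKI over a volume
#'
#' @param signals 4D array (x, y, z, volume) of diffusion signals.
#' @param scheme an [acquisition_scheme()].
#' @param mask logical 3D array selecting voxels to fit (default: all).
#' @param metrics character vector of metric maps to produce (any of
#'   "md", "ad", "rd", "mk", "ak", "rk", "awf").
#' @param sphere_n sphere sample size passed to [dki_metrics()].
#' @return list with one 3D array per requested metric (`NA` outside the
#'   mask and at unfittable voxels) and `n_unfittable`.
#' @export
fit_dki_volume <- function(signals, scheme, mask = NULL,
                           metrics = c("md", "mk"), sphere_n = 1000) {
  dims <- dim(signals)
  stopifnot(length(dims) == 4, dims[4] == length(scheme$bval))
  if (is.null(mask)) mask <- array(TRUE, dims[1:3])
  X <- dki_design(scheme)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
  idx <- which(mask)
  smat <- matrix(aperm(signals, c(4, 1, 2, 3)), nrow = dims[4])[, idx,
                                                                drop = FALSE]
  eigen_only <- all(metrics %in% c("md", "ad", "rd"))
  out <- lapply(metrics, function(m) array(NA_real_, dims[1:3]))
  names(out) <- metrics
  n_bad <- 0L
  for (v in seq_along(idx)) {
    fit <- fit_dki_wls_(smat[, v], X)
    if (is.null(fit)) { n_bad <- n_bad + 1L; next }
    if (eigen_only) {
      lam <- dki_eigen(fit$d6)$values
      vals <- c(md = mean(lam), ad = lam[1], rd = (lam[2] + lam[3]) / 2)
    } else {
      vals <- dki_metrics_core(fit$d6, fit$w15, sphere_n = sphere_n)
    }
    for (m in metrics) out[[m]][idx[v]] <- vals[[m]]
  }
  out$n_unfittable <- n_bad
  out
}
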