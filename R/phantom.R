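# Digital phantom: tissue compartments with ground-truth microstructure and
# hemodynamics on a 1 mm label grid, plus synthetic DKI / DSC acquisitions.

#' Default tissue compartment table
#'
#' Ground-truth microstructure and hemodynamics for the seven phantom
#' compartments. Diffusion ground truths are axisymmetric (AD, RD, AK, RK
#' plus a mean-kurtosis target realised under the package's directional
#' averaging convention); normal-appearing values are parameterized to the
#' reported tissue means (deep NAWM MD 0.96 um^2/ms, MK 1.04; corpus
#' callosum RK 1.65; NAGM MD 0.99, MK 0.88) and lesion compartments are
#' defined by exact multiplicative contrasts on them: unspecific lesion =
#' NAWM x 1.13 in MD and x 0.933 in kurtosis; MS lesion = unspecific x 1.13
#' in MD, x 0.84 in kurtosis, x 1.32 in MTT and x 1.31 in CTH. Absolute
#' hemodynamics (CBF ml/100 ml/min, MTT s, CTH s) are plausible white-matter
#' stand-ins; only their ratios are asserted downstream.
#'
#' @return tibble with one row per compartment; tensor parameters in
#'   um^2/ms, `axis` and `extent` as list columns (extents are 1-based
#'   inclusive index ranges on the 1 mm grid).
#' @export
default_compartments <- function() {
  md_nawm <- 0.96; mk_scale_unspec <- 0.933; mk_scale_ms <- 0.84
  md_unspec <- md_nawm * 1.13
  md_ms <- md_unspec * 1.13
  ext <- function(x, y, z) list(x = x, y = y, z = z)
  tb <- tibble::tribble(
    ~label, ~name,               ~ad,   ~rd,    ~ak,   ~rk,   ~mk,  ~cbf, ~mtt, ~cth, ~k2,
    1L, "deep_nawm",          1.40,  0.74,   0.75,  1.31,  1.04, 22,  3.5,  3.0,  0,
    2L, "cc_nawm",            1.70,  0.50,   0.70,  1.65,  1.10, 20,  3.6,  3.1,  0,
    3L, "cortical_nagm",      1.08,  0.945,  0.85,  0.90,  0.88, 50,  2.2,  1.6,  0,
    4L, "thalamus_nagm",      1.04,  0.905,  0.86,  0.92,  0.90, 45,  2.4,  1.7,  0,
    5L, "unspecific_lesion",  1.50,  (3 * md_unspec - 1.50) / 2,
                                      0.75 * mk_scale_unspec,
                                             1.31 * mk_scale_unspec,
                                                    1.04 * mk_scale_unspec,
                                                          22,  3.2,  2.6,  0,
    6L, "ms_lesion",          1.45,  (3 * md_ms - 1.45) / 2,
                                      0.75 * mk_scale_unspec * mk_scale_ms,
                                             1.31 * mk_scale_unspec * mk_scale_ms,
                                                    1.04 * mk_scale_unspec * mk_scale_ms,
                                                          22,  3.2 * 1.32, 2.6 * 1.31, 0,
    7L, "enhancing_lesion",   1.30,  1.075,  0.80,  0.95,  0.90, 25,  3.0,  1.5,  0.01)
  tb$axis <- list(c(0, 0, 1), c(1, 0, 0), c(0, 0, 1), c(0, 0, 1),
                  c(0, 0, 1), c(0, 0, 1), c(0, 0, 1))
  tb$extent <- list(
    ext(5:24, 5:54, 3:18),     # deep NAWM
    ext(29:40, 15:44, 9:14),   # corpus callosum NAWM
    ext(45:60, 5:28, 3:18),    # cortical NAGM
    ext(45:60, 33:58, 3:18),   # thalamus NAGM
    ext(19:22, 9:12, 19:20),   # unspecific T2-FLAIR lesion
    ext(9:14, 9:14, 19:22),    # MS T2-FLAIR lesion
    ext(27:30, 9:12, 19:20))   # enhancing T1 lesion
  tb
}

#' Default per-group effect table
#'
#' Multiplicative group effects applied to compartment means when cohorts
#' are generated: MS subjects carry the reported normal-appearing
#' white-matter contrast (MD x 1.024, kurtosis x 0.972 in deep NAWM).
#' Lesion-vs-tissue contrasts live in the compartment table itself.
#'
#' @return nested list `effects[[group]][[compartment]][metric]`.
#' @export
default_effect_table <- function() {
  list(MS = list(deep_nawm = c(md = 1.024, mk = 0.972)))
}

#' Default between-subject coefficients of variation
#'
#' Relative SDs of compartment means across subjects, matching the reported
#' cohort SDs (e.g. NAWM MD 0.05/0.96, MK 0.04/1.04).
#'
#' @return named numeric vector.
#' @export
default_between_subject_cv <- function() {
  c(md = 0.052, mk = 0.038, cbf = 0.15, mtt = 0.10, cth = 0.12)
}

#' Phantom specification
#'
#' @param grid_dim dimensions of the 1 mm label grid.
#' @param vox_fine,vox_dki,vox_dsc voxel sizes (mm) of the label, diffusion
#'   and perfusion grids.
#' @param compartments compartment table, see [default_compartments()].
#' @param effect_table per-group effect multipliers.
#' @param between_subject_cv per-metric between-subject relative SD.
#' @param seed integer recorded in the spec and used by consumers.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(grid_dim = c(64, 64, 24), vox_fine = 1,
                         vox_dki = 2, vox_dsc = 3,
                         compartments = default_compartments(),
                         effect_table = default_effect_table(),
                         between_subject_cv = default_between_subject_cv(),
                         seed = 1L) {
  stopifnot(length(grid_dim) == 3, all(grid_dim > 0),
            vox_fine > 0, vox_dki > 0, vox_dsc > 0)
  bad <- vapply(seq_len(nrow(compartments)), function(i) {
    with(compartments[i, ], ad < rd || rd < 0 || mtt <= 0 || cth < 0 || cbf < 0)
  }, logical(1))
  if (any(bad))
    stop("invalid compartment parameters: ",
         paste(compartments$name[bad], collapse = ", "))
  for (eg in unlist(effect_table, recursive = FALSE))
    if (any(eg <= 0)) stop("effect multipliers must be positive")
  structure(list(grid_dim = grid_dim, vox_fine = vox_fine, vox_dki = vox_dki,
                 vox_dsc = vox_dsc, compartments = compartments,
                 effect_table = effect_table,
                 between_subject_cv = between_subject_cv, seed = seed),
            class = "phantom_spec")
}

# apply per-subject multiplicative effects to compartment means: the md
# multiplier scales AD and RD jointly, the mk multiplier scales AK, RK and
# the MK target jointly
apply_subject_effects <- function(comp, subject_effects) {
  truth <- comp
  if (is.null(subject_effects)) {
    truth$md <- (truth$ad + 2 * truth$rd) / 3
    return(truth)
  }
  for (i in seq_len(nrow(truth))) {
    eff <- subject_effects[[truth$name[i]]]
    if (is.null(eff)) next
    if (any(unlist(eff) <= 0)) stop("effect multipliers must be positive")
    get_m <- function(metric) {
      v <- eff[[metric]]
      if (is.null(v) || is.na(v)) 1 else v
    }
    truth$ad[i] <- truth$ad[i] * get_m("md")
    truth$rd[i] <- truth$rd[i] * get_m("md")
    truth$ak[i] <- truth$ak[i] * get_m("mk")
    truth$rk[i] <- truth$rk[i] * get_m("mk")
    truth$mk[i] <- truth$mk[i] * get_m("mk")
    truth$cbf[i] <- truth$cbf[i] * get_m("cbf")
    truth$mtt[i] <- truth$mtt[i] * get_m("mtt")
    truth$cth[i] <- truth$cth[i] * get_m("cth")
  }
  truth$md <- (truth$ad + 2 * truth$rd) / 3
  truth
}

# minimum-size rule shared with the ROI module: >= `min_run` collinear
# in-plane voxels in each of >= `min_slices` contiguous slices
mask_passes_size_rule <- function(mask, min_run = 3, min_slices = 2) {
  dims <- dim(mask)
  ok_slice <- vapply(seq_len(dims[3]), function(z) {
    sl <- mask[, , z, drop = TRUE]
    if (!any(sl)) return(FALSE)
    max_inplane_run(sl) >= min_run
  }, logical(1))
  runs <- rle(ok_slice)
  any(runs$values & runs$lengths >= min_slices)
}

# longest run of consecutive TRUE voxels along either in-plane axis
max_inplane_run <- function(slice) {
  best <- 0L
  for (m in list(slice, t(slice))) {
    r <- apply(m, 1, function(row) {
      rl <- rle(row)
      mx <- rl$lengths[rl$values]
      if (length(mx)) max(mx) else 0L
    })
    best <- max(best, r)
  }
  best
}

#' Build a labelled phantom volume with its ground-truth table
#'
#' Rasterizes the compartments onto the 1 mm grid, applies per-subject
#' multiplicative effects to compartment means, and derives the full
#' ground-truth metric set (including tensors) per compartment.
#'
#' @param spec a [phantom_spec()].
#' @param subject_effects optional nested list `effects[[compartment]][metric]`
#'   of positive multipliers (metrics: md, mk, cbf, mtt, cth). The `md`
#'   multiplier scales AD and RD jointly; the `mk` multiplier scales AK, RK
#'   and the MK target jointly.
#' @param compartment_names optional subset of compartments to include
#'   (e.g. SC subjects carry no MS lesions).
#' @param sphere_n directional-averaging convention passed through to the
#'   tensor construction.
#' @return list: `labels` (integer 3D array with `voxdim` attribute),
#'   `truth` (tibble, one row per compartment with post-effect values and
#'   tensor list-columns), `spec`.
#' @export
build_phantom <- function(spec = phantom_spec(), subject_effects = NULL,
                          compartment_names = NULL, sphere_n = 1000) {
  stopifnot(inherits(spec, "phantom_spec"))
  comp <- spec$compartments
  if (!is.null(compartment_names))
    comp <- comp[comp$name %in% compartment_names, , drop = FALSE]
  dims <- spec$grid_dim
  labels <- array(0L, dims)
  for (i in seq_len(nrow(comp))) {
    e <- comp$extent[[i]]
    if (max(e$x) > dims[1] || max(e$y) > dims[2] || max(e$z) > dims[3] ||
        min(unlist(e)) < 1)
      stop("compartment ", comp$name[i], " extends outside the grid")
    if (any(labels[e$x, e$y, e$z] != 0L)) {
      prev <- comp$name[match(unique(labels[e$x, e$y, e$z][
        labels[e$x, e$y, e$z] != 0]), comp$label)]
      stop("overlapping compartment extents: ", comp$name[i], " and ",
           paste(prev, collapse = ", "))
    }
    labels[e$x, e$y, e$z] <- comp$label[i]
  }
  # lesion compartments must satisfy the minimum-size rule by construction
  for (i in which(grepl("lesion", comp$name))) {
    m <- labels == comp$label[i]
    if (!mask_passes_size_rule(m))
      stop("lesion compartment ", comp$name[i], " violates the minimum-size ",
           "rule (>= 3 collinear in-plane voxels in >= 2 contiguous slices)")
  }
  truth <- apply_subject_effects(comp, subject_effects)
  tensors <- lapply(seq_len(nrow(truth)), function(i)
    axisymmetric_dki(truth$ad[i], truth$rd[i], truth$ak[i], truth$rk[i],
                     truth$mk[i], axis = truth$axis[[i]], sphere_n = sphere_n))
  truth$d6 <- lapply(tensors, `[[`, "d6")
  truth$w15 <- lapply(tensors, `[[`, "w15")
  truth$md <- (truth$ad + 2 * truth$rd) / 3
  truth$awf <- vapply(seq_len(nrow(truth)), function(i)
    dki_metrics(list(d6 = truth$d6[[i]], w15 = truth$w15[[i]]),
                sphere_n = sphere_n)$awf, numeric(1))
  attr(labels, "voxdim") <- rep(spec$vox_fine, 3)
  list(labels = labels, truth = truth, spec = spec)
}

# modal-label block downsampling (ties resolved toward the smallest label,
# background included); trims trailing voxels when dims are not multiples
downsample_labels <- function(labels, factor) {
  dims <- dim(labels)
  nd <- dims %/% factor
  lab <- labels[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                seq_len(nd[3] * factor), drop = FALSE]
  dim(lab) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  lab <- aperm(lab, c(1, 3, 5, 2, 4, 6))
  m <- matrix(lab, nrow = factor^3)
  vals <- sort(unique(as.integer(m)))
  counts <- vapply(vals, function(v) colSums(m == v), numeric(ncol(m)))
  out <- vals[max.col(counts, ties.method = "first")]
  array(as.integer(out), nd)
}

#' Simulate a multi-shell diffusion acquisition of a phantom
#'
#' Produces the noiseless DKI forward signal of each compartment's tensors
#' on the 2 mm grid (labels downsampled by modal pooling) and adds Rician
#' noise with a single sigma = S0 / SNR referenced to the b = 0 signal.
#'
#' @param phantom output of [build_phantom()].
#' @param scheme an [acquisition_scheme()].
#' @param snr signal-to-noise ratio at b = 0; `Inf` gives the exact forward
#'   model.
#' @param s0 baseline signal (arbitrary units, uniform across tissue).
#' @param seed optional RNG seed for reproducibility.
#' @return 4D signal array with attributes `labels` (coarse grid) and
#'   `voxdim`.
#' @export
simulate_dki_signals <- function(phantom, scheme = default_scheme(),
                                 snr = 30, s0 = 1000, seed = NULL) {
  stopifnot(snr > 0)
  if (!is.null(seed)) set.seed(seed)
  f <- phantom$spec$vox_dki / phantom$spec$vox_fine
  lab <- downsample_labels(phantom$labels, f)
  nd <- dim(lab)
  nvol <- length(scheme$bval)
  sig <- array(0, c(nd, nvol))
  truth <- phantom$truth
  flat <- matrix(0, prod(nd), nvol)
  for (i in seq_len(nrow(truth))) {
    idx <- which(lab == truth$label[i])
    if (!length(idx)) next
    if (is.null(truth$d6[[i]]))
      stop("compartment ", truth$name[i], " has no diffusion ground truth")
    s <- predict_dki_signal(s0, truth$d6[[i]], truth$w15[[i]], scheme)
    flat[idx, ] <- matrix(s, length(idx), nvol, byrow = TRUE)
  }
  if (is.finite(snr)) {
    sigma <- s0 / snr
    nz <- flat > 0
    n <- sum(nz)
    flat[nz] <- sqrt((flat[nz] + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  }
  sig <- array(flat, c(nd, nvol))
  attr(sig, "labels") <- lab
  attr(sig, "voxdim") <- rep(phantom$spec$vox_dki, 3)
  sig
}

#' Gamma-variate arterial input function
#'
#' `peak * ((t - t0) / (r * scale))^r * exp(r - (t - t0) / scale)` for
#' `t > t0`, zero before: a standard bolus shape normalized so its maximum
#' equals `peak`.
#'
#' @param times time grid (s).
#' @param t0 bolus arrival (s).
#' @param r shape exponent.
#' @param scale decay time (s).
#' @param peak maximum concentration (1/s, Delta-R2* units).
#' @return numeric vector of concentrations.
#' @export
gamma_variate_aif <- function(times, t0 = 8, r = 3, scale = 1.5, peak = 15) {
  dt <- pmax(times - t0, 0)
  peak * (dt / (r * scale))^r * exp(r - dt / scale)
}

#' Simulate a DSC bolus-passage acquisition of a phantom
#'
#' Each compartment's concentration curve follows the gamma transit-time
#' model with its ground-truth CBF, MTT, CTH and leakage; the signal is
#' `S(t) = S0 exp(-TE * C(t))` on the 3 mm grid with optional additive
#' Gaussian signal noise.
#'
#' @param phantom output of [build_phantom()].
#' @param tr repetition time (s).
#' @param te echo time (s).
#' @param n_frames number of dynamic frames.
#' @param baseline_frames frames before bolus arrival used as S0 reference.
#' @param aif named list of [gamma_variate_aif()] parameters.
#' @param noise_sd additive Gaussian signal noise SD (signal units).
#' @param s0 baseline signal.
#' @param seed optional RNG seed.
#' @return list: `series` (4D array), `aif` (tibble time_s, concentration),
#'   `labels` (coarse grid), `tr`, `te`, `baseline_frames`.
#' @export
simulate_dsc_series <- function(phantom, tr = 0.8, te = 0.032, n_frames = 80,
                                baseline_frames = 10,
                                aif = list(t0 = 8, r = 3, scale = 1.5, peak = 15),
                                noise_sd = 0, s0 = 1000, seed = NULL) {
  stopifnot(tr > 0, te > 0)
  if (!is.null(seed)) set.seed(seed)
  times <- (seq_len(n_frames) - 1) * tr
  if (max(times) < aif$t0 + aif$r * aif$scale + 2)
    stop("n_frames too short: the bolus passage does not fit on the time grid")
  aif_curve <- do.call(gamma_variate_aif, c(list(times = times), aif))
  f <- phantom$spec$vox_dsc / phantom$spec$vox_fine
  lab <- downsample_labels(phantom$labels, f)
  nd <- dim(lab)
  flat <- matrix(s0, prod(nd), n_frames)
  truth <- phantom$truth
  for (i in seq_len(nrow(truth))) {
    idx <- which(lab == truth$label[i])
    if (!length(idx)) next
    cbf_frac <- truth$cbf[i] / 6000        # ml/100ml/min -> 1/s
    ct <- predict_tissue_curve(aif_curve, times, cbf = cbf_frac,
                               dist = transit_distribution(truth$mtt[i],
                                                           truth$cth[i]),
                               delay = 0, k2 = truth$k2[i])
    s <- s0 * exp(-te * ct)
    flat[idx, ] <- matrix(s, length(idx), n_frames, byrow = TRUE)
  }
  if (noise_sd > 0)
    flat <- flat + matrix(rnorm(length(flat), 0, noise_sd), nrow(flat))
  series <- array(flat, c(nd, n_frames))
  attr(series, "voxdim") <- rep(phantom$spec$vox_dsc, 3)
  list(series = series, aif = tibble::tibble(time_s = times,
                                             concentration = aif_curve),
       labels = lab, tr = tr, te = te, baseline_frames = baseline_frames)
}
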