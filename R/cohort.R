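# Cohort generation: seeded subject demographics plus per-subject
# ground-truth multipliers, and the simulated-acquisition ROI record
# pipeline the statistics layer consumes.

#' Cohort specification
#'
#' @param n_ms,n_sc group sizes (defaults 54 MS, 26 symptomatic controls).
#' @param age_ms,age_sc mean/SD of age per group (years).
#' @param female_prop_ms,female_prop_sc female proportions.
#' @param phenotype_props MS phenotype mix (proportions, normalized).
#' @param phantom a [phantom_spec()].
#' @param seed integer seed; every cohort draw derives from it.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_ms = 54, n_sc = 26,
                        age_ms = c(38, 11), age_sc = c(36, 13),
                        female_prop_ms = 0.61, female_prop_sc = 0.69,
                        phenotype_props = c(CIS = 8, RIS = 7, RRMS = 32,
                                            PPMS = 7) / 54,
                        phantom = phantom_spec(), seed = 1L) {
  stopifnot(n_ms > 0, n_sc > 0,
            female_prop_ms >= 0, female_prop_ms <= 1,
            female_prop_sc >= 0, female_prop_sc <= 1,
            all(phenotype_props >= 0))
  structure(list(n_ms = n_ms, n_sc = n_sc, age_ms = age_ms, age_sc = age_sc,
                 female_prop_ms = female_prop_ms,
                 female_prop_sc = female_prop_sc,
                 phenotype_props = phenotype_props / sum(phenotype_props),
                 phantom = phantom, seed = as.integer(seed)),
            class = "cohort_spec")
}

# largest-remainder apportionment of n subjects across phenotype classes
apportion <- function(props, n) {
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Generate a seeded cohort with ground truth
#'
#' Samples demographics from the stated group distributions and, per
#' subject and compartment, multiplicative deviations of the compartment
#' means (between-subject variation) on top of the per-group effect table.
#' MS-specific lesion compartments (MS T2-FLAIR and enhancing T1 lesions)
#' are present only in MS subjects.
#'
#' @param spec a [cohort_spec()].
#' @return list: `subjects` (tibble id, group, age, sex, phenotype),
#'   `effects` (named list of per-subject compartment multipliers),
#'   `truth` (tibble, one row per subject x compartment with post-effect
#'   metric values), `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  set.seed(spec$seed)
  n <- spec$n_ms + spec$n_sc
  group <- c(rep("MS", spec$n_ms), rep("SC", spec$n_sc))
  age <- numeric(n)
  age[group == "MS"] <- pmax(18, rnorm(spec$n_ms, spec$age_ms[1],
                                       spec$age_ms[2]))
  age[group == "SC"] <- pmax(18, rnorm(spec$n_sc, spec$age_sc[1],
                                       spec$age_sc[2]))
  sex <- ifelse(runif(n) < ifelse(group == "MS", spec$female_prop_ms,
                                  spec$female_prop_sc), "F", "M")
  phen_counts <- apportion(spec$phenotype_props, spec$n_ms)
  phenotype <- c(sample(rep(names(phen_counts), phen_counts)),
                 rep("SC", spec$n_sc))
  subjects <- tibble::tibble(
    id = sprintf("S%03d", seq_len(n)), group = group,
    age = round(age, 1), sex = sex, phenotype = phenotype)
  ph <- spec$phantom
  comp_names <- ph$compartments$name
  cv <- ph$between_subject_cv
  effects <- vector("list", n)
  names(effects) <- subjects$id
  ms_only <- c("ms_lesion", "enhancing_lesion")
  for (i in seq_len(n)) {
    grp_eff <- ph$effect_table[[group[i]]]
    cnames <- if (group[i] == "MS") comp_names else setdiff(comp_names, ms_only)
    eff_i <- lapply(cnames, function(cn) {
      e <- c(md = 1, mk = 1, cbf = 1, mtt = 1, cth = 1)
      ge <- grp_eff[[cn]]
      if (!is.null(ge)) e[names(ge)] <- e[names(ge)] * ge
      draw <- pmax(0.2, 1 + rnorm(length(cv), 0, cv))
      e * setNames(draw, names(cv))[names(e)]
    })
    names(eff_i) <- cnames
    effects[[i]] <- eff_i
  }
  comp_tab <- ph$compartments
  truth <- purrr::map2_dfr(subjects$id, effects, function(id, eff) {
    tt <- apply_subject_effects(
      comp_tab[comp_tab$name %in% names(eff), , drop = FALSE], eff)
    out <- tt[, c("name", "md", "ad", "rd", "mk", "ak", "rk",
                  "cbf", "mtt", "cth", "k2")]
    out$subject <- id
    out
  })
  truth <- dplyr::relocate(truth, "subject")
  list(subjects = subjects, effects = effects, truth = truth, spec = spec)
}

#' Simulate, fit and extract DKI ROI records for a whole cohort
#'
#' The full parameter-recovery loop of the imaging arm: per subject, build
#' the phantom with that subject's effect multipliers, simulate the
#' multi-shell diffusion acquisition at the requested SNR, fit the DKI
#' model voxelwise inside the requested ROI masks, and extract ROI records
#' through the mask logic (fill-fraction resampling of the 1 mm
#' compartment masks to the 2 mm diffusion grid, lesion masks as
#' exclusions for normal-appearing tissue).
#'
#' @param cohort output of [generate_cohort()].
#' @param regions compartment names to extract (default deep NAWM).
#' @param metrics DKI metrics to record (subset of md, ad, rd, mk, ak, rk,
#'   awf; eigenvalue-only requests are much faster).
#' @param scheme an [acquisition_scheme()].
#' @param snr diffusion SNR at b = 0.
#' @param seed base RNG seed; subject i uses `seed + i`.
#' @param progress print a dot per subject.
#' @return ROI record tibble (one row per subject x region x metric).
#' @export
cohort_dki_records <- function(cohort, regions = "deep_nawm",
                               metrics = "md", scheme = default_scheme(),
                               snr = 30, seed = 1L, progress = FALSE) {
  ph <- cohort$spec$phantom
  f <- ph$vox_dki / ph$vox_fine
  base <- build_phantom(ph)
  lesions <- grep("lesion", ph$compartments$name, value = TRUE)
  roi_masks <- lapply(regions, function(rn) {
    lab <- ph$compartments$label[ph$compartments$name == rn]
    resample_mask_fraction(base$labels == lab, factor = f)$mask
  })
  names(roi_masks) <- regions
  excl_masks <- lapply(lesions, function(rn) {
    lab <- ph$compartments$label[ph$compartments$name == rn]
    resample_mask_fraction(base$labels == lab, factor = f)$mask
  })
  names(excl_masks) <- lesions
  fit_mask <- Reduce(`|`, roi_masks)
  records <- vector("list", nrow(cohort$subjects))
  for (i in seq_len(nrow(cohort$subjects))) {
    sub <- cohort$subjects[i, ]
    pht <- build_phantom(ph, subject_effects = cohort$effects[[sub$id]],
                         compartment_names = names(cohort$effects[[sub$id]]))
    sig <- simulate_dki_signals(pht, scheme, snr = snr,
                                seed = seed + i)
    maps <- fit_dki_volume(sig, scheme, mask = fit_mask, metrics = metrics)
    recs <- purrr::map_dfr(regions, function(rn) {
      ex <- excl_masks[names(excl_masks) != rn]
      if (grepl("lesion", rn)) ex <- list()
      purrr::map_dfr(metrics, function(m)
        extract_roi_values(maps[[m]], roi_masks[[rn]], exclude = ex,
                           subject_id = sub$id, group = sub$group,
                           age = sub$age, sex = sub$sex,
                           phenotype = sub$phenotype, region = rn,
                           metric_name = m))
    })
    records[[i]] <- recs
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  dplyr::bind_rows(records)
}
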