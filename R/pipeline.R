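# End-to-end orchestration: one validated config drives
# simulate -> fit-dki -> fit-dsc -> oxygen -> roi-extract -> stats,
# with provenance (seeds, config hash, artifact checksums) in a manifest.

#' Default pipeline configuration
#'
#' Every numeric default of the pipeline lives here (and can be overridden
#' from a YAML file); nothing is hard-coded in the stages.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    cohort = list(n_ms = 4, n_sc = 4, seed = 1L),
    stages = list(simulate = TRUE, fit_dki = TRUE, fit_dsc = TRUE,
                  oxygen = TRUE, roi = TRUE, stats = TRUE),
    dki = list(snr = 30, metrics = "md",
               regions = c("deep_nawm", "cc_nawm", "unspecific_lesion",
                           "ms_lesion")),
    dsc = list(tr = 0.8, te = 0.032, n_frames = 80, baseline_frames = 10,
               noise_sd = 0, fit_k2 = TRUE,
               aif = list(t0 = 8, r = 3, scale = 1.5, peak = 15)),
    oxygen = list(nawm_cbf = 22, p50 = 26, h = 2.8, ca = 0.19, k = 118,
                  alpha_o2 = 3.1e-5, p_a = 95, cmro2_target = 2.5),
    output = list(write_nifti = FALSE))
}

# reject unknown keys anywhere in the tree; missing keys fall back to the
# template defaults
validate_config <- function(config, template = default_config(),
                            path = "config") {
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(template))
  if (length(unknown))
    stop("unknown config key(s) under ", path, ": ",
         paste(unknown, collapse = ", "))
  out <- template
  for (k in names(config)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]]))) {
      out[[k]] <- validate_config(config[[k]], template[[k]],
                                  paste(path, k, sep = "$"))
    } else {
      out[[k]] <- config[[k]]
    }
  }
  st <- out$stages
  if (isTRUE(st$stats) && !isTRUE(st$roi))
    stop("invalid stage combination: stats requires roi")
  if (isTRUE(st$roi) && !isTRUE(st$fit_dki))
    stop("invalid stage combination: roi requires fit_dki")
  if (isTRUE(st$oxygen) && !isTRUE(st$fit_dsc))
    stop("invalid stage combination: oxygen requires fit_dsc")
  if ((isTRUE(st$fit_dki) || isTRUE(st$fit_dsc)) && !isTRUE(st$simulate))
    stop("invalid stage combination: fitting stages require simulate")
  out
}

#' Read and validate a pipeline configuration
#'
#' @param path YAML file, or a list already in memory.
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  validate_config(cfg)
}

# per-subject ROI-mean DSC fit (the statistics consume ROI means)
fit_subject_dsc <- function(phantom, cfg_dsc, seed) {
  dsc <- simulate_dsc_series(
    phantom, tr = cfg_dsc$tr, te = cfg_dsc$te, n_frames = cfg_dsc$n_frames,
    baseline_frames = cfg_dsc$baseline_frames, aif = cfg_dsc$aif,
    noise_sd = cfg_dsc$noise_sd, seed = seed)
  times <- dsc$aif$time_s
  base_idx <- seq_len(dsc$baseline_frames)
  flat <- matrix(aperm(dsc$series, c(4, 1, 2, 3)),
                 nrow = dim(dsc$series)[4])
  purrr::map_dfr(seq_len(nrow(phantom$truth)), function(i) {
    lab <- phantom$truth$label[i]
    idx <- which(dsc$labels == lab)
    if (!length(idx)) return(NULL)
    msig <- rowMeans(flat[, idx, drop = FALSE])
    conc <- signal_to_deltaR2(msig, dsc$te, base_idx)
    if (is.null(conc)) return(NULL)
    fit <- fit_perfusion_voxel(conc, dsc$aif$concentration, times,
                               fit_k2 = cfg_dsc$fit_k2)
    tibble::tibble(region = phantom$truth$name[i], cbf = fit$cbf,
                   cbv = fit$cbv, mtt = fit$mtt, cth = fit$cth,
                   delay = fit$delay, k2 = fit$k2,
                   converged = fit$converged, n_voxels = length(idx))
  })
}

#' Run the full synthetic pipeline
#'
#' Executes the enabled stages in dependency order and writes all artifacts
#' plus a JSON manifest (config, seeds, per-file MD5 checksums) to
#' `out_dir`. Reruns with the same config and seed reproduce every
#' deterministic artifact bit-identically.
#'
#' @param config configuration list or YAML path (see [default_config()]).
#' @param out_dir output directory (created if needed).
#' @param seed optional override of the cohort seed.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = NULL) {
  cfg <- read_config(config)
  if (!is.null(seed)) cfg$cohort$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  add <- function(stage, path) {
    artifacts[[stage]] <<- c(artifacts[[stage]], path)
    path
  }
  st <- cfg$stages
  ph_spec <- phantom_spec(seed = cfg$cohort$seed)
  cohort <- NULL
  if (isTRUE(st$simulate)) {
    cohort <- generate_cohort(cohort_spec(n_ms = cfg$cohort$n_ms,
                                          n_sc = cfg$cohort$n_sc,
                                          phantom = ph_spec,
                                          seed = cfg$cohort$seed))
    write_tsv_plain(cohort$subjects, add("simulate",
                                         file.path(out_dir, "demographics.tsv")))
    write_tsv_plain(cohort$truth, add("simulate",
                                      file.path(out_dir, "ground_truth.tsv")))
    scheme <- default_scheme()
    write_scheme_fsl(scheme,
                     add("simulate", file.path(out_dir, "scheme.bval")),
                     add("simulate", file.path(out_dir, "scheme.bvec")))
    times <- (seq_len(cfg$dsc$n_frames) - 1) * cfg$dsc$tr
    aif <- tibble::tibble(
      time_s = times,
      concentration = do.call(gamma_variate_aif,
                              c(list(times = times), cfg$dsc$aif)))
    write_aif_tsv(aif, add("simulate", file.path(out_dir, "aif.tsv")))
    if (isTRUE(cfg$output$write_nifti)) {
      base <- build_phantom(ph_spec)
      write_volume_nifti(base$labels * 1,
                         add("simulate", file.path(out_dir, "labels.nii.gz")),
                         voxdim = rep(ph_spec$vox_fine, 3))
    }
  }
  dki_records <- NULL
  if (isTRUE(st$fit_dki)) {
    dki_records <- cohort_dki_records(
      cohort, regions = cfg$dki$regions, metrics = cfg$dki$metrics,
      snr = cfg$dki$snr, seed = cfg$cohort$seed + 1000L)
    write_tsv_plain(dki_records,
                    add("fit_dki", file.path(out_dir, "dki_records.tsv")))
  }
  dsc_records <- NULL
  if (isTRUE(st$fit_dsc)) {
    dsc_records <- purrr::map_dfr(seq_len(nrow(cohort$subjects)), function(i) {
      sub <- cohort$subjects[i, ]
      pht <- build_phantom(ph_spec,
                           subject_effects = cohort$effects[[sub$id]],
                           compartment_names = names(cohort$effects[[sub$id]]))
      out <- fit_subject_dsc(pht, cfg$dsc, seed = cfg$cohort$seed + 2000L + i)
      out$subject <- sub$id
      out$group <- sub$group
      out
    })
    # NAWM-relative normalization within subject
    dsc_records <- dsc_records |>
      dplyr::group_by(.data$subject) |>
      dplyr::mutate(rcbf = .data$cbf / .data$cbf[.data$region == "deep_nawm"],
                    rcbv = .data$cbv / .data$cbv[.data$region == "deep_nawm"]) |>
      dplyr::ungroup()
    write_tsv_plain(dsc_records,
                    add("fit_dsc", file.path(out_dir, "dsc_records.tsv")))
  }
  oxy_records <- NULL
  if (isTRUE(st$oxygen)) {
    op <- oxygen_params(p50 = cfg$oxygen$p50, h = cfg$oxygen$h,
                        ca = cfg$oxygen$ca, k = cfg$oxygen$k,
                        alpha_o2 = cfg$oxygen$alpha_o2, p_a = cfg$oxygen$p_a,
                        cmro2_target = cfg$oxygen$cmro2_target)
    oxy_records <- oxygen_estimates(
      dsc_records[, c("subject", "group", "region", "mtt", "cth", "rcbf")],
      nawm_cbf = cfg$oxygen$nawm_cbf, params = op)
    write_tsv_plain(oxy_records,
                    add("oxygen", file.path(out_dir, "oxygen_records.tsv")))
  }
  roi_records <- NULL
  if (isTRUE(st$roi)) {
    roi_records <- dki_records
    if (!is.null(dsc_records)) {
      long_dsc <- dsc_records |>
        tidyr::pivot_longer(cols = c("mtt", "cth", "rcbf", "rcbv"),
                            names_to = "metric", values_to = "mean") |>
        dplyr::left_join(cohort$subjects,
                         by = c(subject = "id", group = "group")) |>
        dplyr::transmute(subject = .data$subject, group = .data$group,
                         age = .data$age, sex = .data$sex,
                         phenotype = .data$phenotype, region = .data$region,
                         metric = .data$metric, mean = .data$mean,
                         sd = NA_real_, n_voxels = .data$n_voxels)
      roi_records <- dplyr::bind_rows(roi_records, long_dsc)
    }
    if (!is.null(oxy_records)) {
      long_oxy <- oxy_records |>
        tidyr::pivot_longer(cols = c("pto2", "oef"),
                            names_to = "metric", values_to = "mean") |>
        dplyr::left_join(cohort$subjects,
                         by = c(subject = "id", group = "group")) |>
        dplyr::transmute(subject = .data$subject, group = .data$group,
                         age = .data$age, sex = .data$sex,
                         phenotype = .data$phenotype, region = .data$region,
                         metric = .data$metric, mean = .data$mean,
                         sd = NA_real_, n_voxels = NA_integer_)
      roi_records <- dplyr::bind_rows(roi_records, long_oxy)
    }
    write_tsv_plain(roi_records,
                    add("roi", file.path(out_dir, "roi_records.tsv")))
    # normalized lesion volumes on the label grid
    base <- build_phantom(ph_spec)
    brain <- base$labels > 0
    lesions <- grep("lesion", ph_spec$compartments$name, value = TRUE)
    vol_tab <- purrr::map_dfr(lesions, function(rn) {
      lab <- ph_spec$compartments$label[ph_spec$compartments$name == rn]
      tibble::tibble(region = rn,
                     normalized_volume = normalized_volume(
                       base$labels == lab, brain))
    })
    write_tsv_plain(vol_tab,
                    add("roi", file.path(out_dir, "lesion_volumes.tsv")))
  }
  if (isTRUE(st$stats)) {
    metrics_avail <- unique(roi_records$metric)
    contrasts <- purrr::map_dfr(
      intersect(cfg$dki$metrics, metrics_avail), function(m) {
        tidy(adjusted_contrast(roi_records, region = "deep_nawm", metric = m))
      })
    write_tsv_plain(contrasts,
                    add("stats", file.path(out_dir, "contrasts.tsv")))
    # lesion pairing within MS subjects carrying both lesion types
    wide <- roi_records |>
      dplyr::filter(.data$metric == cfg$dki$metrics[1],
                    .data$region %in% c("ms_lesion", "unspecific_lesion")) |>
      tidyr::pivot_wider(id_cols = "subject", names_from = "region",
                         values_from = "mean") |>
      dplyr::filter(!is.na(.data$ms_lesion) & !is.na(.data$unspecific_lesion))
    paired <- if (nrow(wide) >= 3)
      paired_region_test(wide$ms_lesion, wide$unspecific_lesion)
    else tibble::tibble(method = NA_character_, statistic = NA_real_,
                        p = NA_real_, n = nrow(wide),
                        note = "too few paired subjects")
    write_tsv_plain(paired,
                    add("stats", file.path(out_dir, "paired_tests.tsv")))
    w <- roi_records |>
      dplyr::filter(.data$region == "deep_nawm") |>
      tidyr::pivot_wider(id_cols = "subject", names_from = "metric",
                         values_from = "mean")
    mm <- intersect(metrics_avail, names(w))
    pairs <- expand.grid(var_x = mm, var_y = mm, stringsAsFactors = FALSE)
    cors <- purrr::pmap_dfr(pairs, function(var_x, var_y) {
      res <- tryCatch(spearman_labeled(w[[var_x]], w[[var_y]]),
                      error = function(e) NULL)   # e.g. constant rCBF ref
      if (is.null(res)) return(NULL)
      tibble::tibble(var_x = var_x, var_y = var_y, rho = res$rho,
                     p = res$p, n = res$n, label = res$label)
    })
    write_tsv_plain(cors,
                    add("stats", file.path(out_dir, "correlations.tsv")))
  }
  manifest <- list(
    package = "kurtflow",
    version = as.character(utils::packageVersion("kurtflow")),
    seed = cfg$cohort$seed,
    config = cfg,
    config_hash = unname(tools::md5sum(
      write_yaml_tmp(cfg, file.path(out_dir, "config_resolved.yaml")))),
    stages = lapply(artifacts, function(paths)
      lapply(paths, function(p)
        list(file = basename(p), md5 = unname(tools::md5sum(p))))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

write_yaml_tmp <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  path
}
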