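# Lesion-mask logic: connected-component size filtering, cross-resolution
# partial-volume resampling, ROI value extraction and volume normalization.

# label 26-connected components of a binary 3D mask; returns an integer
# array (0 = background) and the component count
label_components_26 <- function(mask) {
  dims <- dim(mask)
  idx <- which(mask)
  out <- array(0L, dims)
  if (!length(idx)) return(list(labels = out, n = 0L))
  coords <- arrayInd(idx, dims)
  key <- idx
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  # adjacency: for each of the 26 offsets, locate the neighbour's row
  nb <- vector("list", nrow(off))
  for (o in seq_len(nrow(off))) {
    nc <- coords + matrix(off[o, ], nrow(coords), 3, byrow = TRUE)
    valid <- nc[, 1] >= 1 & nc[, 1] <= dims[1] &
             nc[, 2] >= 1 & nc[, 2] <= dims[2] &
             nc[, 3] >= 1 & nc[, 3] <= dims[3]
    nk <- rep(NA_integer_, nrow(coords))
    nk[valid] <- (nc[valid, 3] - 1L) * dims[1] * dims[2] +
                 (nc[valid, 2] - 1L) * dims[1] + nc[valid, 1]
    nb[[o]] <- match(nk, key)
  }
  # union-find over voxel rows
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (o in seq_along(nb)) {
    pairs <- which(!is.na(nb[[o]]))
    for (i in pairs) {
      ri <- find(i); rj <- find(nb[[o]][i])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  comp <- match(roots, unique(roots))
  out[idx] <- comp
  list(labels = out, n = length(unique(roots)))
}

#' Filter lesion components by the minimum-size rule
#'
#' Retains 26-connected components that span at least `min_run` collinear
#' in-plane voxels (>= 3 mm in-plane extent on a 1 mm grid) in at least
#' `min_slices` contiguous slices; everything else is removed and reported
#' with a reason.
#'
#' @param mask logical (or 0/1) 3D array on the fine grid.
#' @param min_run minimum collinear in-plane voxel run per slice.
#' @param min_slices minimum number of contiguous qualifying slices.
#' @return list: `mask` (filtered logical array) and `report` (tibble with
#'   one row per component: n_voxels, n_slices, max_run, retained, reason).
#' @export
filter_lesion_components <- function(mask, min_run = 3, min_slices = 2) {
  mask <- mask > 0
  lab <- label_components_26(mask)
  report <- tibble::tibble(component = integer(), n_voxels = integer(),
                           n_slices = integer(), max_run = integer(),
                           retained = logical(), reason = character())
  out <- array(FALSE, dim(mask))
  for (cmp in seq_len(lab$n)) {
    m <- lab$labels == cmp
    zs <- which(apply(m, 3, any))
    ok_slice <- vapply(zs, function(z) max_inplane_run(m[, , z]) >= min_run,
                       logical(1))
    # contiguous qualifying slices
    ok <- FALSE
    if (any(ok_slice)) {
      qual <- zs[ok_slice]
      if (min_slices <= 1) {
        ok <- TRUE
      } else if (length(qual) >= min_slices) {
        runs <- rle(diff(qual) == 1)
        ok <- any(runs$values & runs$lengths >= (min_slices - 1))
      }
    }
    reason <- if (ok) NA_character_
      else if (!any(ok_slice))
        sprintf("no slice with an in-plane run of >= %d voxels", min_run)
      else sprintf("< %d contiguous qualifying slices", min_slices)
    report <- dplyr::bind_rows(report, tibble::tibble(
      component = cmp, n_voxels = sum(m), n_slices = length(zs),
      max_run = max(vapply(zs, function(z) max_inplane_run(m[, , z]),
                           integer(1))),
      retained = ok, reason = reason))
    if (ok) out <- out | m
  }
  list(mask = out, report = report)
}

#' Resample a fine mask to a coarser grid by fill fraction
#'
#' Computes, for every coarse voxel, the fraction of its volume covered by
#' the fine mask, and retains the voxel when the fraction reaches the
#' partial-volume threshold (default 50 %). Integer-ratio grids are counted
#' exactly; otherwise the coarse voxels are supersampled.
#'
#' @param mask logical 3D array on the fine grid.
#' @param factor integer downsampling factor (scalar or length 3) for
#'   aligned grids; mutually exclusive with `target_vox`.
#' @param fine_vox,target_vox voxel sizes (mm) for the general
#'   shared-origin path.
#' @param threshold fill-fraction threshold for retention.
#' @param supersample per-axis supersampling density for the general path.
#' @param origin_fine,origin_target world origins; a mismatch beyond 1e-6
#'   is an error (resample upstream instead).
#' @return list: `mask` (coarse logical array), `fraction` (coarse numeric
#'   array), `report` (threshold, n_coarse, retained).
#' @export
resample_mask_fraction <- function(mask, factor = NULL, fine_vox = NULL,
                                   target_vox = NULL, threshold = 0.5,
                                   supersample = 5,
                                   origin_fine = c(0, 0, 0),
                                   origin_target = c(0, 0, 0)) {
  mask <- mask > 0
  if (max(abs(origin_fine - origin_target)) > 1e-6)
    stop("mask grids have misaligned world transforms; resample upstream")
  if (!is.null(factor)) {
    f <- rep(as.integer(factor), length.out = 3)
    dims <- dim(mask)
    nd <- dims %/% f
    m <- mask[seq_len(nd[1] * f[1]), seq_len(nd[2] * f[2]),
              seq_len(nd[3] * f[3]), drop = FALSE] * 1
    dim(m) <- c(f[1], nd[1], f[2], nd[2], f[3], nd[3])
    frac <- apply(m, c(2, 4, 6), mean)
  } else {
    stopifnot(!is.null(fine_vox), !is.null(target_vox))
    fine_vox <- rep(fine_vox, length.out = 3)
    target_vox <- rep(target_vox, length.out = 3)
    dims <- dim(mask)
    nd <- pmax(1L, floor(dims * fine_vox / target_vox))
    s <- supersample
    frac <- array(0, nd)
    offs <- (seq_len(s) - 0.5) / s
    pts <- as.matrix(expand.grid(offs, offs, offs))
    for (k in seq_len(nd[3])) for (j in seq_len(nd[2])) for (i in seq_len(nd[1])) {
      world <- cbind((i - 1 + pts[, 1]) * target_vox[1],
                     (j - 1 + pts[, 2]) * target_vox[2],
                     (k - 1 + pts[, 3]) * target_vox[3])
      fi <- ceiling(sweep(world, 2, fine_vox, "/"))
      fi[fi < 1] <- 1L
      ok <- fi[, 1] <= dims[1] & fi[, 2] <= dims[2] & fi[, 3] <= dims[3]
      inside <- logical(nrow(fi))
      inside[ok] <- mask[fi[ok, , drop = FALSE]]
      frac[i, j, k] <- mean(inside)
    }
  }
  keep <- frac >= threshold
  list(mask = keep, fraction = frac,
       report = tibble::tibble(threshold = threshold,
                               n_coarse = length(keep),
                               retained = sum(keep)))
}

#' Extract ROI summary values from a metric volume
#'
#' Mean, SD and voxel count over the inclusion mask minus the union of
#' exclusion masks, ignoring missing-value voxels. An empty effective mask
#' suppresses the record (zero-row tibble) with a message.
#'
#' @param metric numeric 3D array.
#' @param include logical 3D inclusion mask.
#' @param exclude list of logical 3D exclusion masks.
#' @param subject_id,group,age,sex,phenotype,region,metric_name record
#'   metadata.
#' @return tibble with columns subject, group, age, sex, phenotype, region,
#'   metric, mean, sd, n_voxels (zero rows when suppressed).
#' @export
extract_roi_values <- function(metric, include, exclude = list(),
                               subject_id = NA_character_,
                               group = NA_character_, age = NA_real_,
                               sex = NA_character_,
                               phenotype = NA_character_,
                               region = NA_character_,
                               metric_name = NA_character_) {
  stopifnot(all(dim(metric) == dim(include)))
  eff <- include > 0
  for (ex in exclude) {
    stopifnot(all(dim(ex) == dim(include)))
    eff <- eff & !(ex > 0)
  }
  vals <- metric[eff]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) {
    message("ROI record suppressed (empty effective mask): ",
            subject_id, " / ", region, " / ", metric_name)
    return(tibble::tibble(subject = character(), group = character(),
                          age = numeric(), sex = character(),
                          phenotype = character(), region = character(),
                          metric = character(), mean = numeric(),
                          sd = numeric(), n_voxels = integer()))
  }
  tibble::tibble(subject = subject_id, group = group, age = age, sex = sex,
                 phenotype = phenotype, region = region,
                 metric = metric_name, mean = mean(vals),
                 sd = if (length(vals) > 1) sd(vals) else 0,
                 n_voxels = length(vals))
}

#' Volume of a mask normalized to whole-brain volume
#'
#' @param mask logical 3D array.
#' @param brain_mask logical 3D array on the same grid, nonempty.
#' @return fraction of the brain volume occupied by the mask.
#' @export
normalized_volume <- function(mask, brain_mask) {
  stopifnot(all(dim(mask) == dim(brain_mask)))
  nb <- sum(brain_mask > 0)
  if (nb == 0) stop("brain mask is empty")
  sum(mask > 0) / nb
}
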