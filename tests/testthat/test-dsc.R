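# concentration conversion, gamma transit-time model, deconvolution

times80 <- (0:79) * 0.8

test_that("signal-to-concentration conversion satisfies its identities", {
  s0 <- 900
  expect_equal(signal_to_deltaR2(rep(s0, 40), 0.032, 1:10), rep(0, 40))
  x <- c(rep(0, 10), seq(0, 5, length.out = 30))
  s <- s0 * exp(-0.032 * x)
  expect_equal(signal_to_deltaR2(s, 0.032, 1:10), x, tolerance = 1e-12)
  s[17] <- -1
  expect_null(signal_to_deltaR2(s, 0.032, 1:10))
})

test_that("noiseless simulated series invert to the generating curve", {
  ph <- build_phantom()
  dsc <- simulate_dsc_series(ph, noise_sd = 0)
  lab <- dsc$labels
  tr <- ph$truth[ph$truth$name == "deep_nawm", ]
  vox <- which(lab == tr$label)[1]
  sig <- dsc$series[arrayInd(vox, dim(lab))[1], arrayInd(vox, dim(lab))[2],
                    arrayInd(vox, dim(lab))[3], ]
  conc <- signal_to_deltaR2(sig, dsc$te, 1:10)
  truth_curve <- predict_tissue_curve(dsc$aif$concentration, dsc$aif$time_s,
                                      cbf = tr$cbf / 6000,
                                      dist = transit_distribution(tr$mtt,
                                                                  tr$cth))
  expect_equal(conc, truth_curve, tolerance = 1e-12)
  # baseline frames equal S0 exactly without noise
  expect_equal(sig[1:10], rep(1000, 10) * exp(-dsc$te * truth_curve[1:10]))
})

test_that("gamma transit-time family has the stated moments and normalization", {
  d <- transit_distribution(3.5, 1.75)
  expect_equal(d$alpha, 4)
  expect_equal(d$beta, 0.875)
  expect_equal(d$alpha * d$beta, 3.5)          # mean = MTT
  expect_equal(sqrt(d$alpha) * d$beta, 1.75)   # SD = CTH
  # pdf integrates to one across a wide shape range
  for (alpha in c(0.25, 1, 4, 12, 50)) {
    beta <- 2 / alpha
    # integrable singularity at 0 for alpha < 1: analytic head + quadrature
    eps <- 1e-8
    head_int <- eps^alpha * exp(-eps / (2 * beta)) /
      (alpha * gamma(alpha) * beta^alpha)
    int <- head_int +
      stats::integrate(function(x) dgamma(x, alpha, scale = beta),
                       eps, Inf, rel.tol = 1e-11)$value
    expect_lt(abs(int - 1), 1e-8)
  }
})

test_that("residue function starts at one, decreases, and matches quadrature", {
  d <- transit_distribution(3.5, 3.0)
  t <- seq(0, 40, by = 0.01)
  r <- residue_function(t, d)
  expect_equal(r[1], 1)
  expect_true(all(diff(r) <= 1e-14))
  expect_lt(r[length(r)], 1e-4)
  # brute-force integration of the pdf, point by point
  pts <- seq(0.5, 25, by = 0.5)
  oracle <- 1 - vapply(pts, function(tp)
    stats::integrate(function(x) dgamma(x, d$alpha, scale = d$beta),
                     0, tp, rel.tol = 1e-12,
                     subdivisions = 1e5)$value, numeric(1))
  expect_lt(max(abs(residue_function(pts, d) - oracle)), 1e-8)
})

test_that("tissue curve prediction satisfies the convolution identities", {
  aif <- gamma_variate_aif(times80)
  d <- transit_distribution(4, 2)
  expect_equal(predict_tissue_curve(aif, times80, 0, d, 0, 0),
               rep(0, 80))
  # unit impulse AIF: curve proportional to the residue function
  imp <- c(1 / 0.8, rep(0, 79))
  got <- predict_tissue_curve(imp, times80, cbf = 0.005, d, 0, 0)
  want <- 0.005 * residue_function(times80, d)
  expect_equal(got[-1], want[-1], tolerance = 0.02)  # trapezoid endpoints
  # linearity in cbf
  c1 <- predict_tissue_curve(aif, times80, 0.003, d, 0, 0)
  c2 <- predict_tissue_curve(aif, times80, 0.006, d, 0, 0)
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
  expect_error(predict_tissue_curve(aif, times80, 0.003, d, delay = 100),
               "outside the time grid")
})

test_that("frame-grid convolution matches a 100x-oversampled oracle", {
  d <- transit_distribution(3.2, 2.6)
  cbf <- 22 / 6000; k2 <- 0.004
  coarse <- predict_tissue_curve(gamma_variate_aif(times80), times80,
                                 cbf, d, 0, k2)
  tf <- seq(0, max(times80), by = 0.008)
  aif_f <- gamma_variate_aif(tf)
  rt_f <- residue_function(tf, d)
  conv_f <- stats::convolve(aif_f, rev(rt_f), type = "open")[seq_along(tf)]
  conv_f <- 0.008 * (conv_f - 0.5 * (aif_f[1] * rt_f + aif_f * rt_f[1]))
  leak_f <- k2 * c(0, cumsum((aif_f[-1] + aif_f[-length(aif_f)]) / 2 * 0.008))
  oracle <- approx(tf, cbf * conv_f + leak_f, xout = times80)$y
  expect_equal(coarse, oracle, tolerance = 1e-3)
})

test_that("noiseless curves are recovered within 1 % in all five parameters", {
  aif <- gamma_variate_aif(times80)
  cases <- list(c(cbf = 0.0037, mtt = 3.2, cth = 2.6, delay = 0, k2 = 0),
                c(cbf = 0.0037, mtt = 4.224, cth = 3.406, delay = 0, k2 = 0),
                c(cbf = 0.005, mtt = 2.0, cth = 1.0, delay = 0.7, k2 = 0.006))
  for (p in cases) {
    ct <- predict_tissue_curve(aif, times80, p["cbf"],
                               transit_distribution(p["mtt"], p["cth"]),
                               p["delay"], p["k2"])
    f <- fit_perfusion_voxel(ct, aif, times80)
    expect_true(f$converged)
    expect_equal(f$mtt, unname(p["mtt"]), tolerance = 0.01)
    expect_equal(f$cth, unname(p["cth"]), tolerance = 0.01)
    expect_equal(f$cbf, unname(p["cbf"]), tolerance = 0.01)
    expect_lt(abs(f$delay - p["delay"]), 0.4)       # within half a frame
    expect_lt(abs(f$k2 - p["k2"]), 5e-4)
  }
})

test_that("a two-frame shift is recovered within half a frame, matching a delay scan", {
  aif <- gamma_variate_aif(times80)
  d <- transit_distribution(3.5, 3.0)
  ct <- predict_tissue_curve(aif, times80, 0.0037, d, delay = 1.6, k2 = 0)
  f <- fit_perfusion_voxel(ct, aif, times80)
  expect_lt(abs(f$delay - 1.6), 0.4)
  # brute-force delay grid scan with the shape held at truth
  grid <- seq(0, 4, by = 0.05)
  rss <- vapply(grid, function(dl) {
    pred <- predict_tissue_curve(aif, times80, 0.0037, d, dl, 0)
    sum((ct - pred)^2)
  }, numeric(1))
  expect_lt(abs(grid[which.min(rss)] - 1.6), 0.05)
  expect_lt(abs(f$delay - grid[which.min(rss)]), 0.4)
})

test_that("leakage coefficients up to 0.02/s shift recovered MTT by < 3 %", {
  aif <- gamma_variate_aif(times80)
  d <- transit_distribution(3.5, 3.0)
  base <- fit_perfusion_voxel(
    predict_tissue_curve(aif, times80, 0.0037, d, 0, 0), aif, times80)
  for (k2 in c(0.005, 0.01, 0.02)) {
    f <- fit_perfusion_voxel(
      predict_tissue_curve(aif, times80, 0.0037, d, 0, k2), aif, times80)
    expect_lt(abs(f$mtt - base$mtt) / base$mtt, 0.03)
  }
})

test_that("common rescaling of AIF and curve leaves timing fixed and scales flow", {
  aif <- gamma_variate_aif(times80)
  d <- transit_distribution(3.0, 2.0)
  ct <- predict_tissue_curve(aif, times80, 0.004, d, 0.8, 0.003)
  f1 <- fit_perfusion_voxel(ct, aif, times80)
  f2 <- fit_perfusion_voxel(3 * ct, 3 * aif, times80)
  expect_equal(f2$mtt, f1$mtt, tolerance = 1e-6)
  expect_equal(f2$cth, f1$cth, tolerance = 1e-6)
  expect_equal(f2$delay, f1$delay, tolerance = 1e-4)
  expect_equal(f2$cbf, f1$cbf, tolerance = 1e-6)
  # scaling only the tissue curve scales CBF and CBV accordingly
  f3 <- fit_perfusion_voxel(3 * ct, aif, times80)
  expect_equal(f3$cbf, 3 * f1$cbf, tolerance = 1e-4)
  expect_equal(f3$cbv, 3 * f1$cbv, tolerance = 1e-4)
})

test_that("perfusion maps are homogeneous per compartment and satisfy CBV = CBF * MTT", {
  ph <- build_phantom()
  dsc <- simulate_dsc_series(ph, noise_sd = 0)
  lab <- dsc$labels
  # a small homogeneous patch of the unspecific lesion plus some NAWM
  mask <- array(FALSE, dim(lab))
  les <- which(lab == 5)
  nawm <- which(lab == 1)
  mask[c(les, nawm[1:4])] <- TRUE
  maps <- perfusion_maps(dsc$series, dsc$aif$concentration, dsc$aif$time_s,
                         mask, dsc$te, 1:10)
  got <- maps$mtt[les]
  expect_lt(diff(range(got)), 1e-6 * mean(got))     # homogeneity
  expect_equal(maps$cbv[mask], (maps$cbf * maps$mtt)[mask],
               tolerance = 1e-12)                   # central volume theorem
  tr <- ph$truth[ph$truth$name == "unspecific_lesion", ]
  expect_equal(mean(maps$mtt[les]), tr$mtt, tolerance = 0.01)
  expect_equal(mean(maps$cth[les]), tr$cth, tolerance = 0.01)
})

test_that("relative normalization is exact, scale invariant, and guarded", {
  vol <- array(runif(64, 1, 2), c(4, 4, 4))
  ref <- array(FALSE, c(4, 4, 4)); ref[1:8] <- TRUE
  out <- normalize_relative(vol, ref)
  expect_equal(mean(out[ref]), 1)
  expect_equal(normalize_relative(2 * vol, ref), out)
  expect_equal(normalize_relative(array(5, c(4, 4, 4)), ref),
               array(1, c(4, 4, 4)))
  expect_error(normalize_relative(vol, array(FALSE, c(4, 4, 4))), "empty")
  expect_error(normalize_relative(-vol, ref), "non-positive")
})

test_that("lesion contrast ratios propagate to relative flow maps", {
  ph <- build_phantom()
  tr <- ph$truth
  # ratio oracle on synthetic fitted values: rCBF of a lesion equals the
  # ground-truth CBF ratio
  aif <- gamma_variate_aif(times80)
  fits <- lapply(c("deep_nawm", "ms_lesion"), function(rn) {
    row <- tr[tr$name == rn, ]
    ct <- predict_tissue_curve(aif, times80, row$cbf / 6000,
                               transit_distribution(row$mtt, row$cth),
                               0, row$k2)
    fit_perfusion_voxel(ct, aif, times80)
  })
  rcbf <- fits[[2]]$cbf / fits[[1]]$cbf
  truth_ratio <- tr$cbf[tr$name == "ms_lesion"] /
    tr$cbf[tr$name == "deep_nawm"]
  expect_equal(rcbf, truth_ratio, tolerance = 0.01)
})
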