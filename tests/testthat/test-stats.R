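# adjusted contrasts, logistic biomarker models, Spearman labels, paired
# tests

make_records <- function(y, group, age, sex) {
  tibble::tibble(subject = sprintf("s%03d", seq_along(y)), group = group,
                 age = age, sex = sex, phenotype = "x", region = "r",
                 metric = "m", mean = y, sd = 0, n_voxels = 10L)
}

test_that("a constructed null-covariate case gives exactly 10 %", {
  n <- 40
  grp <- rep(c("SC", "MS"), each = n)
  age <- rep(seq(20, 60, length.out = n), 2)
  sex <- rep(rep(c("F", "M"), n / 2), 2)
  m <- 2
  y <- ifelse(grp == "MS", m * 1.1, m)
  # noise-free by construction: the perfect-fit warning is expected
  ct <- suppressWarnings(adjusted_contrast(make_records(y, grp, age, sex)))
  expect_equal(ct$table$percent_diff, 10, tolerance = 1e-10)
  expect_equal(ct$table$estimate, 0.2, tolerance = 1e-10)
  expect_true(ct$table$ci_lo <= ct$table$estimate &
                ct$table$estimate <= ct$table$ci_hi)
})

test_that("coefficients equal an independent normal-equation solution", {
  set.seed(81)
  n <- 60
  grp <- sample(rep(c("SC", "MS"), each = n / 2))
  age <- runif(n, 20, 60)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  y <- 1 + 0.01 * age + 0.2 * (sex == "M") + 0.5 * (grp == "MS") + rnorm(n)
  ct <- adjusted_contrast(make_records(y, grp, age, sex))
  X <- cbind(1, grp == "MS", age, sex == "M")
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(ct$table$estimate, beta[2], tolerance = 1e-10)
})

test_that("scale equivariance: rescaling the outcome rescales the effect only", {
  set.seed(83)
  n <- 50
  grp <- sample(rep(c("SC", "MS"), each = n / 2))
  age <- runif(n, 20, 60)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  y <- 5 + 0.3 * (grp == "MS") + 0.01 * age + rnorm(n, 0, 0.4)
  c1 <- adjusted_contrast(make_records(y, grp, age, sex))
  c2 <- adjusted_contrast(make_records(100 * y, grp, age, sex))
  expect_equal(c2$table$estimate, 100 * c1$table$estimate, tolerance = 1e-9)
  expect_equal(c2$table$percent_diff, c1$table$percent_diff,
               tolerance = 1e-9)
  expect_equal(c2$table$p, c1$table$p, tolerance = 1e-9)
})

test_that("type-I error of the adjusted contrast is calibrated at 5 %", {
  set.seed(85)
  reps <- 5000
  n <- 40
  grp <- rep(c("SC", "MS"), each = n)
  rejected <- 0L
  for (r in seq_len(reps)) {
    age <- runif(2 * n, 20, 60)
    sexm <- runif(2 * n) < 0.5
    y <- rnorm(2 * n)
    X <- cbind(1, grp == "MS", age, sexm)
    qrx <- qr(X)
    beta <- qr.coef(qrx, y)
    res <- y - X %*% beta
    s2 <- sum(res^2) / (2 * n - 4)
    xtxi <- chol2inv(qr.R(qrx))
    tstat <- beta[2] / sqrt(s2 * xtxi[2, 2])
    p <- 2 * pt(-abs(tstat), df = 2 * n - 4)
    if (p < 0.05) rejected <- rejected + 1L
  }
  rate <- rejected / reps
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
  # the fast closed form above matches adjusted_contrast on one draw
  age <- runif(2 * n, 20, 60)
  sex <- ifelse(runif(2 * n) < 0.5, "M", "F")
  y <- rnorm(2 * n)
  ct <- adjusted_contrast(make_records(y, grp, age, sex))
  X <- cbind(1, grp == "MS", age, sex == "M")
  beta <- qr.coef(qr(X), y)
  expect_equal(ct$table$estimate, unname(beta[2]), tolerance = 1e-10)
})

test_that("design guards: group levels, sample size, collinearity", {
  n <- 10
  grp <- rep(c("SC", "MS"), each = n)
  age <- runif(2 * n, 20, 60)
  sex <- sample(c("F", "M"), 2 * n, replace = TRUE)
  y <- rnorm(2 * n)
  rec <- make_records(y, grp, age, sex)
  expect_error(adjusted_contrast(rec[rec$group == "MS", ]), "two levels")
  expect_error(adjusted_contrast(rec[c(1:2, 11:20), ]), "per group")
  rec2 <- rec
  rec2$age2 <- rec2$age
  expect_error(adjusted_contrast(rec2, covariates = c("age", "age2")),
               "collinear")
})

test_that("logistic biomarker: null case, separation, and stationarity", {
  set.seed(87)
  n <- 400
  grp <- rep(c("SC", "MS"), each = n / 2)
  age <- runif(n, 20, 60)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  # predictor independent of class
  y <- rnorm(n)
  res <- logistic_biomarker(make_records(y, grp, age, sex))
  expect_false(res$separated)
  expect_true(res$ci_lo <= 1 & 1 <= res$ci_hi)
  # perfectly separating predictor
  y2 <- ifelse(grp == "MS", 10, 0) + runif(n, 0, 0.1)
  res2 <- logistic_biomarker(make_records(y2, grp, age, sex))
  expect_true(res2$separated)
  expect_equal(res2$odds_ratio, Inf)
  # likelihood stationarity: fitted coefficients beat random draws and
  # have (near) zero gradient
  y3 <- rnorm(n) + 0.8 * (grp == "MS")
  rec3 <- make_records(y3, grp, age, sex)
  res3 <- logistic_biomarker(rec3)
  z <- as.vector(scale(y3))
  X <- cbind(1, z, age, sex == "M")
  yy <- as.integer(grp == "MS")
  loglik <- function(b) {
    eta <- as.vector(X %*% b)
    sum(yy * eta - log(1 + exp(eta)))
  }
  bhat <- c(log(res3$odds_ratio))
  fit <- suppressWarnings(glm(yy ~ z + age + I(sex == "M"),
                              family = binomial()))
  b <- coef(fit)
  expect_equal(unname(exp(b["z"])), res3$odds_ratio, tolerance = 1e-8)
  ll_hat <- loglik(unname(b))
  mu <- 1 / (1 + exp(-as.vector(X %*% unname(b))))
  grad <- t(X) %*% (yy - mu)
  expect_lt(max(abs(grad)), 1e-4)
  set.seed(88)
  for (i in 1:1000) {
    expect_lte(loglik(unname(b) + rnorm(4, 0, 0.3)), ll_hat)
  }
})

test_that("Spearman labels follow the stated bins with exact edges", {
  r <- spearman_labeled(1:10, 1:10)
  expect_equal(r$rho, 1)
  expect_equal(r$label, "perfect")
  # monotone invariance
  x <- rnorm(30)
  expect_equal(spearman_labeled(x, exp(x))$rho, 1)
  # bin edges on constructed correlations
  lab_of <- function(rho) {
    if (abs(rho) >= 1 - 1e-12) "perfect"
    else if (abs(rho) >= 0.7) "strong"
    else if (abs(rho) >= 0.4) "moderate"
    else if (abs(rho) >= 0.1) "weak"
    else "none"
  }
  set.seed(91)
  for (i in 1:20) {
    x <- rnorm(40); y <- rnorm(40) + runif(1, 0, 2) * x
    expect_equal(spearman_labeled(x, y)$label,
                 lab_of(spearman_labeled(x, y)$rho))
  }
  expect_equal(lab_of(0.1), "weak")       # >= 0.1 enters weak
  expect_equal(lab_of(0.4), "moderate")   # >= 0.4 enters moderate
  expect_equal(lab_of(0.7), "strong")     # >= 0.7 enters strong
  expect_equal(lab_of(0.0999), "none")
  expect_error(spearman_labeled(rep(1, 5), 1:5), "constant")
  expect_error(spearman_labeled(1:2, 1:2), "at least 3")
})

test_that("tied data match a brute-force average-rank computation", {
  x <- c(1, 2, 2, 3, 3, 3, 4)
  y <- c(2, 1, 4, 4, 5, 6, 6)
  avg_rank <- function(v) {
    sapply(v, function(vi) mean(which(sort(v) == vi)))
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_labeled(x, y)$rho, oracle, tolerance = 1e-12)
})

test_that("paired tests: identity, exact Wilcoxon enumeration, power", {
  a <- c(1.2, 3.1, 2.2, 5.0, 4.1)
  r0 <- paired_region_test(a, a)
  expect_true(is.na(r0$p))
  rt <- paired_region_test(a, a - 0.001 * seq_along(a), normality = TRUE)
  expect_equal(rt$method, "paired_t")
  # identity for the t statistic
  tt <- paired_region_test(c(1, 2, 3, 4), c(1, 2, 3, 4) + c(-1, 1, -1, 1),
                           normality = TRUE)
  expect_equal(tt$statistic, 0)
  # exact signed-rank p equals enumeration of all sign assignments
  set.seed(93)
  aa <- c(0.3, -1.2, 2.1, 0.8, -0.4, 1.7, 0.9, -2.3)
  bb <- rep(0, 8)
  rw <- paired_region_test(aa, bb, normality = FALSE)
  d <- aa - bb
  rk <- rank(abs(d))
  wplus <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 8))
  wdist <- as.matrix(signs) %*% rk
  p_oracle <- mean(pmin(1, 2 * pmin(mean(wdist >= wplus),
                                    mean(wdist <= wplus))))
  expect_equal(rw$p, p_oracle, tolerance = 1e-12)
  # shift alternative has higher power than the null rejection rate
  set.seed(95)
  reps <- 2000
  pow <- function(delta) {
    mean(vapply(seq_len(reps), function(i) {
      x <- rnorm(30); y <- rnorm(30) + delta
      abs(mean(y - x) / (sd(y - x) / sqrt(30))) > qt(0.975, 29)
    }, logical(1)))
  }
  p_null <- pow(0); p_alt <- pow(1)
  expect_lt(abs(p_null - 0.05), 0.02)
  expect_gt(p_alt, p_null + 0.5)
})

test_that("BH adjustment is available but off by default", {
  tab <- tibble::tibble(p = c(0.01, 0.02, 0.4))
  out <- adjust_pvalues(tab)
  expect_equal(out$p_adj, p.adjust(tab$p, "BH"))
  ct_cols <- names(tidy(adjusted_contrast(make_records(
    rnorm(20), rep(c("SC", "MS"), each = 10), runif(20, 20, 60),
    sample(c("F", "M"), 20, TRUE)))))
  expect_false("p_adj" %in% ct_cols)
})
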