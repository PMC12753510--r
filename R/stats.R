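# Group statistics: age/sex-adjusted contrasts, logistic biomarker models,
# labelled Spearman correlations, paired regional tests.

#' Age- and sex-adjusted group contrast
#'
#' Ordinary least squares of an ROI outcome on group plus covariates. The
#' group coefficient is also expressed as a percent difference relative to
#' the covariate-adjusted reference-group mean (prediction for the
#' reference group at the sample covariate values); the raw-mean percent
#' difference is reported alongside.
#'
#' @param records ROI record tibble (see [extract_roi_values()]), or any
#'   tibble with the outcome and covariate columns.
#' @param outcome name of the outcome column (default "mean", the ROI mean).
#' @param region,metric optional filters applied to `records`.
#' @param group_var grouping column (two levels).
#' @param covariates covariate column names (default age and sex).
#' @param reference reference level of `group_var`; defaults to "SC" when
#'   present, otherwise the first sorted level.
#' @return a `kf_contrast` object; `tidy()` returns the result row and
#'   `glance()` the model summary.
#' @export
adjusted_contrast <- function(records, outcome = "mean", region = NULL,
                              metric = NULL, group_var = "group",
                              covariates = c("age", "sex"),
                              reference = NULL) {
  df <- records
  if (!is.null(region)) df <- df[df$region %in% region, , drop = FALSE]
  if (!is.null(metric)) df <- df[df$metric %in% metric, , drop = FALSE]
  need <- c(outcome, group_var, covariates)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- df[, need, drop = FALSE]
  if (any(!complete.cases(df))) stop("missing covariate or outcome values")
  lv <- sort(unique(as.character(df[[group_var]])))
  if (length(lv) != 2) stop("group variable must have exactly two levels")
  if (is.null(reference)) reference <- if ("SC" %in% lv) "SC" else lv[1]
  lv <- c(reference, setdiff(lv, reference))
  g <- factor(as.character(df[[group_var]]), levels = lv)
  n_per <- table(g)
  if (any(n_per < length(covariates) + 2))
    stop("need at least ", length(covariates) + 2, " observations per group")
  mf <- data.frame(.y = df[[outcome]], .group = g,
                   df[, covariates, drop = FALSE], check.names = FALSE)
  fit <- lm(.y ~ ., data = mf)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "))
  }
  X <- model.matrix(fit)
  gcol <- grep("^\\.group", colnames(X))
  est <- coef(fit)[gcol]
  ci <- confint(fit)[gcol, ]
  p <- summary(fit)$coefficients[gcol, 4]
  X0 <- X
  X0[, gcol] <- 0
  adj_ref <- mean(X0 %*% coef(fit))
  raw_ref <- mean(mf$.y[g == reference])
  raw_alt <- mean(mf$.y[g != reference])
  tab <- tibble::tibble(
    outcome = outcome,
    region = if (is.null(region)) NA_character_ else paste(region, collapse = "+"),
    metric = if (is.null(metric)) NA_character_ else paste(metric, collapse = "+"),
    contrast = paste(lv[2], "vs", lv[1]),
    estimate = unname(est),
    ci_lo = unname(ci[1]), ci_hi = unname(ci[2]), p = unname(p),
    percent_diff = unname(100 * est / adj_ref),
    percent_diff_raw = 100 * (raw_alt - raw_ref) / raw_ref,
    n_ref = unname(n_per[1]), n_alt = unname(n_per[2]),
    covariates = paste(covariates, collapse = ","))
  structure(list(fit = fit, table = tab, reference = reference),
            class = "kf_contrast")
}

#' @export
tidy.kf_contrast <- function(x, ...) x$table

#' @export
glance.kf_contrast <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
                 sigma = s$sigma, df.residual = x$fit$df.residual,
                 nobs = length(x$fit$residuals))
}

#' @export
print.kf_contrast <- function(x, ...) {
  print(x$table)
  invisible(x)
}

#' Logistic biomarker model
#'
#' Maximum-likelihood logistic regression of group membership on a
#' standardized ROI metric plus covariates; the odds ratio is reported per
#' 1 SD of the predictor with a Wald confidence interval. Perfect
#' separation is detected and flagged with an infinite-OR sentinel rather
#' than a silent estimate.
#'
#' @inheritParams adjusted_contrast
#' @param predictor column holding the candidate biomarker (default
#'   "mean").
#' @param conf_level confidence level for the Wald interval.
#' @return tibble: term, odds_ratio, ci_lo, ci_hi, p, n, separated.
#' @export
logistic_biomarker <- function(records, predictor = "mean", region = NULL,
                               metric = NULL, group_var = "group",
                               covariates = c("age", "sex"),
                               reference = NULL, conf_level = 0.95) {
  df <- records
  if (!is.null(region)) df <- df[df$region %in% region, , drop = FALSE]
  if (!is.null(metric)) df <- df[df$metric %in% metric, , drop = FALSE]
  lv <- sort(unique(as.character(df[[group_var]])))
  if (length(lv) != 2) stop("group variable must have exactly two levels")
  if (is.null(reference)) reference <- if ("SC" %in% lv) "SC" else lv[1]
  y <- as.integer(as.character(df[[group_var]]) != reference)
  x <- df[[predictor]]
  if (!all(is.finite(x))) stop("predictor must be finite")
  z <- as.vector(scale(x))
  mf <- data.frame(.y = y, .z = z, df[, covariates, drop = FALSE])
  fit <- suppressWarnings(glm(.y ~ ., data = mf, family = binomial()))
  b <- coef(fit)[".z"]
  se <- sqrt(diag(vcov(fit)))[".z"]
  mu <- fit$fitted.values
  separated <- !fit$converged || abs(b) > 15 ||
    (all(mu[y == 1] > 1 - 1e-6) && all(mu[y == 0] < 1e-6))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  if (separated) {
    return(tibble::tibble(term = predictor, odds_ratio = Inf,
                          ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                          n = length(y), separated = TRUE))
  }
  tibble::tibble(term = predictor, odds_ratio = unname(exp(b)),
                 ci_lo = unname(exp(b - zq * se)),
                 ci_hi = unname(exp(b + zq * se)),
                 p = unname(2 * pnorm(-abs(b / se))), n = length(y),
                 separated = FALSE)
}

#' Spearman correlation with strength label
#'
#' Rank correlation with average ranks for ties; the absolute coefficient
#' is labelled none (< 0.1), weak (>= 0.1 and < 0.4), moderate (>= 0.4 and
#' < 0.7), strong (>= 0.7 and < 1) or perfect (= 1).
#'
#' @param x,y numeric vectors, length >= 3, non-constant.
#' @return tibble: rho, p, n, label.
#' @export
spearman_labeled <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant input: ranks are undefined")
  rho <- cor(x, y, method = "spearman")
  p <- suppressWarnings(cor.test(x, y, method = "spearman",
                                 exact = FALSE)$p.value)
  a <- abs(rho)
  label <- if (a >= 1 - 1e-12) "perfect"
    else if (a >= 0.7) "strong"
    else if (a >= 0.4) "moderate"
    else if (a >= 0.1) "weak"
    else "none"
  tibble::tibble(rho = rho, p = p, n = length(x), label = label)
}

#' Paired regional test
#'
#' Paired t-test for normally distributed differences, Wilcoxon signed-rank
#' otherwise (exact for n <= 25 without ties or zeros, normal approximation
#' with continuity correction above). With `normality = "auto"` a
#' Shapiro-Wilk test at 0.05 selects the branch.
#'
#' @param values_a,values_b paired measurements (same subjects, same order).
#' @param normality `TRUE`, `FALSE` or `"auto"`.
#' @return tibble: method, statistic, p, n (p is `NA` with a note when all
#'   differences are zero and the signed-rank test is undefined).
#' @export
paired_region_test <- function(values_a, values_b, normality = "auto") {
  stopifnot(length(values_a) == length(values_b))
  d <- values_a - values_b
  if (all(d == 0))
    return(tibble::tibble(method = "wilcoxon", statistic = NA_real_,
                          p = NA_real_, n = length(d),
                          note = "all differences zero: no evidence either way"))
  use_t <- if (identical(normality, "auto")) {
    shapiro.test(d)$p.value >= 0.05
  } else isTRUE(normality)
  if (use_t) {
    tt <- t.test(values_a, values_b, paired = TRUE)
    tibble::tibble(method = "paired_t", statistic = unname(tt$statistic),
                   p = tt$p.value, n = length(d), note = NA_character_)
  } else {
    nz <- d[d != 0]
    exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
    wt <- suppressWarnings(
      wilcox.test(values_a, values_b, paired = TRUE, exact = exact,
                  correct = TRUE))
    tibble::tibble(method = "wilcoxon", statistic = unname(wt$statistic),
                   p = wt$p.value, n = length(d), note = NA_character_)
  }
}

#' Benjamini-Hochberg adjustment helper
#'
#' Multiple-comparison correction is off by default throughout the package
#' (exploratory-analysis convention); this helper adds adjusted p-values to
#' any result table when desired.
#'
#' @param table tibble with a `p` column.
#' @param method method passed to [stats::p.adjust()].
#' @return the table with a `p_adj` column.
#' @export
adjust_pvalues <- function(table, method = "BH") {
  table$p_adj <- p.adjust(table$p, method = method)
  table
}
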