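# ggplot2 displays for the package's result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbar
#'   geom_raster geom_tile geom_hline scale_fill_viridis_c
#'   scale_fill_gradient2 coord_fixed labs theme_minimal
NULL

#' Forest-style display of adjusted contrasts
#'
#' @param object a `kf_contrast` or a tibble of bound `tidy()` rows.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.kf_contrast <- function(object, ...) {
  tab <- if (inherits(object, "kf_contrast")) object$table else object
  tab$label <- paste(tab$region, tab$metric, sep = " / ")
  ggplot(tab, aes(x = .data$estimate, y = .data$label)) +
    geom_errorbar(aes(xmin = .data$ci_lo, xmax = .data$ci_hi), width = 0.15) +
    geom_point(size = 2) +
    geom_hline(xintercept = 0, linetype = 2, colour = "grey50") +
    labs(x = "adjusted group difference (95 % CI)", y = NULL) +
    theme_minimal()
}

#' Axial slice of a phantom label volume or metric map
#'
#' @param volume 3D array (labels or metric values).
#' @param z slice index (default: middle slice).
#' @param discrete treat values as labels.
#' @return a ggplot raster.
#' @export
plot_axial_slice <- function(volume, z = NULL, discrete = is.integer(volume)) {
  if (is.null(z)) z <- ceiling(dim(volume)[3] / 2)
  sl <- volume[, , z]
  df <- expand.grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$value <- as.vector(sl)
  p <- ggplot(df, aes(.data$x, .data$y))
  if (discrete) {
    df$value <- factor(df$value)
    p <- ggplot(df, aes(.data$x, .data$y)) +
      geom_raster(aes(fill = .data$value)) +
      labs(fill = "label")
  } else {
    p <- p + geom_raster(aes(fill = .data$value)) +
      scale_fill_viridis_c(na.value = "grey90")
  }
  p + coord_fixed() + theme_minimal() +
    labs(x = NULL, y = NULL, title = paste0("axial slice z = ", z))
}

#' Correlation-matrix tile plot
#'
#' Displays pairwise Spearman correlations (e.g. DKI vs DSC metrics per
#' phenotype stratum) as a signed tile matrix.
#'
#' @param cor_table tibble with columns `var_x`, `var_y`, `rho` (and
#'   optionally `p`).
#' @return a ggplot.
#' @export
plot_correlation_matrix <- function(cor_table) {
  ggplot(cor_table, aes(.data$var_x, .data$var_y, fill = .data$rho)) +
    geom_tile(colour = "white") +
    scale_fill_gradient2(low = "seagreen", mid = "white", high = "violetred",
                         limits = c(-1, 1)) +
    coord_fixed() + theme_minimal() +
    labs(x = NULL, y = NULL, fill = "Spearman rho")
}
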