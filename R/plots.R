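# ggplot2 displays for the main result types: Manhattan and Q-Q plots for
# scans, decay curves for LD profiles, score plots for genotype PCA, power
# curves for power grids.

#' @export
autoplot.gwas_scan <- function(object, ...) {
  meta <- attr(object, "scan_meta")
  df <- as_tibble(object)
  df <- df[!is.na(df$p), ]
  # cumulative genome coordinate for plotting
  offs <- df |>
    dplyr::group_by(.data$lg) |>
    dplyr::summarise(len = max(.data$bp), .groups = "drop") |>
    dplyr::mutate(offset = cumsum(dplyr::lag(.data$len, default = 0)))
  df <- dplyr::left_join(df, offs[, c("lg", "offset")], by = "lg")
  thr <- meta$threshold %||% 5e-7
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bp + .data$offset,
                                   y = .data$log10p,
                                   colour = factor(.data$lg %% 2))) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = 2,
                        colour = "grey40") +
    ggplot2::labs(x = "genome position", y = expression(-log[10](p)),
                  title = "Single-SNP association scan") +
    ggplot2::theme_minimal()
}

#' Manhattan plot of an association scan
#' @param scan A [emmax_scan()] result.
#' @param ... Passed on to [autoplot.gwas_scan()].
#' @return A ggplot object.
#' @export
plot_manhattan <- function(scan, ...) autoplot.gwas_scan(scan, ...)

#' Q-Q plot of an association scan
#'
#' @param scan A [emmax_scan()] result (or [qq_data()] output).
#' @return A ggplot object, annotated with the genomic inflation factor.
#' @export
plot_qq <- function(scan) {
  qq <- if (!is.null(scan$expected)) scan else qq_data(scan)
  lambda <- attr(qq, "lambda_gc")
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)),
                  subtitle = sprintf("lambda[GC] = %.3f", lambda)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ld_profile <- function(object, ...) {
  df <- as_tibble(object)
  df$mid <- (df$bin_lo + df$bin_hi) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid / 1e6, y = .data$mean_r2,
                                   colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "distance (Mb)", y = expression(mean ~ r^2),
                  title = "LD decay") +
    ggplot2::theme_minimal()
}

#' LD decay plot for one or more profiles
#' @param ... [decay_profile()] results (rows are combined).
#' @return A ggplot object.
#' @export
plot_ld_decay <- function(...) {
  autoplot.ld_profile(dplyr::bind_rows(...))
}

#' @export
autoplot.genotype_pca <- function(object, groups = NULL, ...) {
  df <- object$scores
  if (!is.null(groups)) df$group <- groups[df$id]
  aes <- if (is.null(groups)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$group)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    ggplot2::theme_minimal()
}

#' Power curves over a design grid
#'
#' @param grid A [power_grid()] result.
#' @param x Which column to place on the x axis (default `rel_r`).
#' @return A ggplot object, one line per heritability value.
#' @export
plot_power <- function(grid, x = "rel_r") {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data[[x]], y = .data$power,
                                     colour = factor(.data$h2))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(colour = "h2", y = "power") +
    ggplot2::theme_minimal()
}
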