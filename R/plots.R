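#' Plot GRM principal components
#'
#' Scatter of two components, coloured by breed when available, with the
#' percent variance of each component in the axis labels.
#'
#' @param object a `grm_pca` tibble from [grm_pca()].
#' @param x_pc,y_pc components to plot.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.grm_pca <- function(object, x_pc = 1, y_pc = 2, ...) {
  pct <- attr(object, "percent_var")
  xs <- paste0("PC", x_pc)
  ys <- paste0("PC", y_pc)
  p <- ggplot2::ggplot(object, ggplot2::aes(.data[[xs]], .data[[ys]])) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", xs, pct[x_pc]),
      y = sprintf("%s (%.1f%%)", ys, pct[y_pc])
    ) +
    ggplot2::theme_minimal()
  if ("breed" %in% names(object)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$breed), alpha = 0.7)
  } else {
    p + ggplot2::geom_point(alpha = 0.7)
  }
}

#' Manhattan-style plot of association results
#'
#' Debiased effect magnitude (or -log10 p) of selected variants by genomic
#' position, CNVs distinguished from SNPs.
#'
#' @param result an `assoc_result` tibble from [relaxed_refit()].
#' @param value `"effect"` (|debiased beta|) or `"p"` (-log10 p).
#' @return A ggplot object.
#' @export
plot_assoc <- function(result, value = c("effect", "p")) {
  value <- match.arg(value)
  df <- dplyr::mutate(
    tibble::as_tibble(result),
    yval = if (value == "effect") abs(.data$debiased_beta)
           else -log10(.data$p_value)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$pos_bp / 1e6, .data$yval,
                                   colour = .data$type,
                                   shape = .data$type)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)",
                  y = if (value == "effect") "|debiased effect|"
                      else expression(-log[10](p))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.spacing = ggplot2::unit(0.1, "lines"))
}

#' Plot the cross-validation curve of a penalized fit
#'
#' @param fit a `lasso_fit`.
#' @return A ggplot object with the selected lambda marked.
#' @export
plot_cv <- function(fit) {
  stopifnot(inherits(fit, "lasso_fit"))
  ggplot2::ggplot(fit$cv, ggplot2::aes(log(.data$lambda), .data$cvm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$cvm - .data$cvse,
                                      ymax = .data$cvm + .data$cvse),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(fit$lambda), linetype = 2) +
    ggplot2::labs(x = expression(log(lambda)), y = "CV mean squared error") +
    ggplot2::theme_minimal()
}
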