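#' Heatmap of cell contributions to the JSD
#'
#' Tiles the covariate-level by treatment-group decomposition, colored by
#' each cell's signed contribution in bits: positive cells (red) mark
#' level/group combinations over-represented relative to the common
#' distribution, negative cells (blue) under-represented ones.
#'
#' @param object A [jsd_balance()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.jsd_balance <- function(object, ...) {
  cells <- decompose_jsd(object)
  cells$level <- factor(cells$level, levels = rev(rownames(object$cell)))
  cells$group <- factor(cells$group, levels = colnames(object$cell))
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$group, y = .data$level, fill = .data$bits)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.4f", .data$bits)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B") +
    ggplot2::labs(
      x = "Treatment group", y = "Covariate level", fill = "bits",
      title = sprintf("JSD decomposition (overall = %.4f bits)", object$jsd_bits)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a JSD-versus-standardized-difference curve
#'
#' @param object A `"divergence_curve"` from [sdiff_jsd_curve()].
#' @param ... Unused.
#' @return A ggplot object; the dashed line marks the 1-bit asymptote for
#'   two groups.
#' @export
autoplot.divergence_curve <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$standardized_difference, y = .data$jsd_bits)
  ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", color = "grey50") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = "Standardized difference",
      y = "JSD (bits)",
      title = sprintf(
        "Two Gaussian groups, SDs 1 and %g", attr(object, "sigma2") %||% NA
      )
    ) +
    ggplot2::theme_minimal()
}
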