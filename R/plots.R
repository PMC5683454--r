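# ggplot2 display functions for the result objects.

#' Plot a separation test as a PCA panel
#'
#' Scatter of the genes in the plane of the first two principal
#' components, colored by temporal label, with the maximum-margin
#' separating line overlaid when one was computed. Axis labels carry
#' the explained-variance percentages.
#'
#' @param object A `separation_test` from [separation_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.separation_test <- function(object, ...) {
  if (is.null(object$pca)) {
    abort("this separation_test carries no PCA projection")
  }
  sc <- object$pca$scores
  ve <- object$pca$var_explained * 100
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                        color = .data$label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_color_manual(values = c(early = "#2166ac",
                                           late = "#b2182b")) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", ve[1]),
      y = sprintf("PC2 (%.1f%%)", ve[2]),
      color = NULL,
      title = object$virus_id %||% "separation",
      subtitle = sprintf("DBS = %.3f, p = %.3g (%d permutations)",
                         object$dbs_observed, object$p_value,
                         object$n_permutations)
    ) +
    ggplot2::theme_minimal()
  ml <- object$margin_line
  if (is.null(ml) && "label" %in% names(sc)) {
    ml <- tryCatch(
      suppressWarnings(max_margin_line(sc[c("pc1", "pc2")], sc$label)),
      error = function(e) NULL
    )
  }
  if (!is.null(ml) && is.finite(ml$a %||% NA_real_)) {
    if (abs(ml$b) > 1e-12) {
      p <- p + ggplot2::geom_abline(slope = -ml$a / ml$b,
                                    intercept = -ml$c / ml$b,
                                    linetype = "dashed")
    } else {
      p <- p + ggplot2::geom_vline(xintercept = -ml$c / ml$a,
                                   linetype = "dashed")
    }
  }
  p
}

#' @rdname autoplot.separation_test
#' @param x A `separation_test`.
#' @param y Unused.
#' @export
plot.separation_test <- function(x, y, ...) print(autoplot.separation_test(x, ...))

#' Plot the per-virus separation summary of a study
#'
#' Tile panel of viruses by analysis space, shaded by permutation
#' p-value, starring the significant combinations.
#'
#' @param object A `study_report` from [run_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_report <- function(object, ...) {
  sep <- object$separation
  if (nrow(sep) == 0) abort("study report has no separation results")
  ggplot2::ggplot(sep, ggplot2::aes(x = toupper(.data$space),
                                    y = .data$virus_id,
                                    fill = .data$p_value)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$significant,
                                                   "*", "")),
                       size = 6) +
    ggplot2::scale_fill_gradient(low = "#fddbc7", high = "#f7f7f7",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "p-value") +
    ggplot2::theme_minimal()
}

#' Plot per-feature early/late comparisons of a study
#'
#' Tile panel of viruses by genomic feature. Tiles are colored by the
#' direction of the difference (blue-green: higher mean in early genes;
#' red: higher in late genes) with significant Wilcoxon comparisons
#' starred.
#'
#' @param report A `study_report`.
#' @param alpha Significance level for the stars (default the study's).
#' @return A ggplot object.
#' @export
plot_feature_tests <- function(report, alpha = NULL) {
  alpha <- alpha %||% report$alpha
  ft <- report$feature_tests
  if (nrow(ft) == 0) abort("study report has no feature tests")
  ft$signed <- ft$direction * -log10(pmax(ft$p_value, 1e-16))
  ggplot2::ggplot(ft, ggplot2::aes(x = .data$feature, y = .data$virus_id,
                                   fill = .data$signed)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$p_value < alpha,
                                                   "*", "")), size = 6) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#1b7837", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = "signed -log10 p\n(+: early higher)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
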