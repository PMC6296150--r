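# ggplot2 views of the main result types.

#' Plot normalised methylation along the genome
#'
#' @param object A `normalized_profile` tibble (or several bound together).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot normalized_profile
#' @export
autoplot.normalized_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position,
                                       y = .data$normalized_pct,
                                       colour = .data$sample)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "Position (bp)", y = "Normalized methylation (%)",
                  colour = "Sample") +
    ggplot2::theme_minimal()
}

#' Plot per-site full methylation potential
#'
#' @param object A `full_potential` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot full_potential
#' @export
autoplot.full_potential <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position,
                                       y = .data$potential_points,
                                       colour = .data$valid)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Position (bp)",
                  y = "Full potential (percentage points)",
                  colour = "Valid") +
    ggplot2::theme_minimal()
}

#' Volcano-style view of differential methylation results
#'
#' @param object A `differential_result` tibble from [pairwise_contrasts()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot differential_result
#' @export
autoplot.differential_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_difference,
                                       y = -log10(.data$p_value),
                                       colour = .data$passes)) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::facet_wrap(ggplot2::vars(.data$contrast)) +
    ggplot2::labs(x = "Difference in methylation (percentage points)",
                  y = expression(-log[10](p)), colour = "Passes") +
    ggplot2::theme_minimal()
}

#' Bar plot of delta-delta-Ct fold changes with SEM
#'
#' @param folds The `per_group` tibble of a [ddct_fold_change()] result (or
#'   the result itself).
#' @return A ggplot.
#' @export
plot_fold_changes <- function(folds) {
  if (inherits(folds, "ddct_result")) folds <- folds$per_group
  ggplot2::ggplot(folds, ggplot2::aes(x = .data$gene, y = .data$fold,
                                      fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$fold - .data$sem,
                   ymax = .data$fold + .data$sem),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Fold change vs control", fill = "Group") +
    ggplot2::theme_minimal()
}
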