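# ggplot2 views of the main result types.

#' Plot a bulk-segregant scan
#'
#' Windowed delta SNP-index trend per chromosome with the calling threshold
#' and any called regions shaded.
#'
#' @param object A [bsa_scan()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bsa_scan
#' @export
autoplot.bsa_scan <- function(object, ...) {
  w <- filter(object$windows, !is.na(.data$delta))
  p <- ggplot2::ggplot(w, ggplot2::aes(x = .data$win_mid / 1e6, y = .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$params$threshold,
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(Delta * " SNP-index")) +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_bw()
  if (nrow(object$regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$regions,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = -1, ymax = 1),
      inherit.aes = FALSE, fill = "orange", alpha = 0.2
    )
  }
  p
}

#' Plot a half-diallel matrix heat map
#'
#' Genotype means on a parents-by-parents grid, both axes ordered by GCA;
#' the diagonal is the parents' own performance.
#'
#' @param object A [build_diallel_matrix()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diallel_matrix
#' @export
autoplot.diallel_matrix <- function(object, ...) {
  d <- tidy.diallel_matrix(object) %>%
    mutate(
      parent1 = factor(.data$parent1, levels = rownames(object$matrix)),
      parent2 = factor(.data$parent2, levels = colnames(object$matrix))
    )
  ggplot2::ggplot(d, ggplot2::aes(.data$parent1, .data$parent2,
                                  fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick",
                                  midpoint = mean(d$mean, na.rm = TRUE),
                                  name = object$trait) +
    ggplot2::labs(x = "parent (GCA-ordered)", y = "parent (GCA-ordered)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a single-marker scan
#'
#' Manhattan-style view of per-marker significance with the genome-wide
#' permutation threshold.
#'
#' @param object A [marker_scan()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot marker_scan
#' @export
autoplot.marker_scan <- function(object, ...) {
  d <- filter(as_tibble(object), !is.na(.data$p))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos / 1e6, y = -log10(.data$p))) +
    ggplot2::geom_point(size = 0.8, colour = "grey30") +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "threshold")),
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p))) +
    ggplot2::theme_bw()
}

#' Plot expected versus observed QTL-pair effects
#'
#' Scatter of observed pair effects against the sum of singular effects,
#' with the fitted regression and the additivity diagonal.
#'
#' @param object An [expected_vs_observed()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot additivity_regression
#' @export
autoplot.additivity_regression <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "expected pair effect (sum of singles)",
      y = "observed pair effect",
      subtitle = sprintf("slope = %.2f, R² = %.2f", object$slope,
                         object$r2)
    ) +
    ggplot2::theme_bw()
}

#' Plot per-bin study support of the pan-QTLome
#'
#' @param object A [bin_counts()] result.
#' @param hotspot_min_studies Threshold line (default 6).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bin_matrix
#' @export
autoplot.bin_matrix <- function(object, hotspot_min_studies = 6, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2e6,
                               y = .data$n_studies)) +
    ggplot2::geom_col(width = object$params$bin_size / 1e6 * 0.9,
                      fill = "grey40") +
    ggplot2::geom_hline(yintercept = hotspot_min_studies, linetype = "dashed",
                        colour = "red") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "studies with a QTL in bin") +
    ggplot2::theme_bw()
}
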