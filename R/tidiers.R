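# broom-style tidiers for the package's result objects.

#' Tidy a half-diallel matrix into long form
#'
#' @param x A [build_diallel_matrix()] result.
#' @param ... Unused.
#' @return A tibble with one row per cell: `parent1`, `parent2`, `mean`,
#'   `genotype_class`.
#' @method tidy diallel_matrix
#' @export
tidy.diallel_matrix <- function(x, ...) {
  m <- x$matrix
  tidyr::expand_grid(parent1 = rownames(m), parent2 = colnames(m)) %>%
    mutate(
      mean = m[cbind(.data$parent1, .data$parent2)],
      genotype_class = ifelse(.data$parent1 == .data$parent2, "parent", "F1")
    )
}

#' @rdname tidy.diallel_matrix
#' @method glance diallel_matrix
#' @export
glance.diallel_matrix <- function(x, ...) {
  tibble(
    n_parents = nrow(x$matrix),
    n_cells = sum(!is.na(x$matrix[upper.tri(x$matrix, diag = TRUE)])),
    gca_range = diff(range(x$gca$gca)),
    trait = x$trait
  )
}

#' Tidy a bulk-segregant scan
#'
#' @param x A [bsa_scan()] result.
#' @param level `"windows"` (default), `"sites"` or `"regions"`.
#' @param ... Unused.
#' @return The requested component as a tibble.
#' @method tidy bsa_scan
#' @export
tidy.bsa_scan <- function(x, level = c("windows", "sites", "regions"), ...) {
  level <- match.arg(level)
  as_tibble(x[[level]])
}

#' @rdname tidy.bsa_scan
#' @method glance bsa_scan
#' @export
glance.bsa_scan <- function(x, ...) {
  tibble(
    n_sites = nrow(x$sites),
    n_windows = nrow(x$windows),
    n_regions = nrow(x$regions),
    max_abs_delta = if (all(is.na(x$windows$delta))) NA_real_ else
      max(abs(x$windows$delta), na.rm = TRUE),
    threshold = x$params$threshold
  )
}

#' Tidy a single-marker scan
#'
#' @param x A [marker_scan()] result.
#' @param ... Unused.
#' @return The per-marker tibble (the scan itself, without its class).
#' @method tidy marker_scan
#' @export
tidy.marker_scan <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "marker_scan")
  as_tibble(out)
}

#' @rdname tidy.marker_scan
#' @method glance marker_scan
#' @export
glance.marker_scan <- function(x, ...) {
  tibble(
    n_markers = nrow(x),
    n_pass_perm = sum(x$pass_perm, na.rm = TRUE),
    threshold = attr(x, "threshold"),
    alpha = attr(x, "alpha"),
    n_perm = attr(x, "n_perm")
  )
}

#' Tidy a QTL-pair interaction
#'
#' @param x A [pair_interaction()] result.
#' @param ... Unused.
#' @return The class-means tibble with letters.
#' @method tidy pair_interaction
#' @export
tidy.pair_interaction <- function(x, ...) x$classes

#' @rdname tidy.pair_interaction
#' @method glance pair_interaction
#' @export
glance.pair_interaction <- function(x, ...) {
  bind_cols(x$effects, tibble(complete = x$complete))
}

#' Tidy a stacking analysis
#'
#' @param x A [stack_analysis()] result.
#' @param ... Unused.
#' @return The per-favorable-allele-count tibble.
#' @method tidy stack_result
#' @export
tidy.stack_result <- function(x, ...) x$by_count

#' @rdname tidy.stack_result
#' @method glance stack_result
#' @export
glance.stack_result <- function(x, ...) x$contrast

#' Tidy an additivity regression
#'
#' @param x An [expected_vs_observed()] result.
#' @param ... Unused.
#' @return The per-pair table.
#' @method tidy additivity_regression
#' @export
tidy.additivity_regression <- function(x, ...) x$table

#' @rdname tidy.additivity_regression
#' @method glance additivity_regression
#' @export
glance.additivity_regression <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, se_slope = x$se_slope,
         r2 = x$r2, p_slope_eq_1 = x$p_slope_eq_1, n = x$n)
}

#' Tidy a pan-QTLome bin matrix
#'
#' @param x A [bin_counts()] result.
#' @param ... Unused.
#' @return The per-bin tibble.
#' @method tidy bin_matrix
#' @export
tidy.bin_matrix <- function(x, ...) x$bins

#' @rdname tidy.bin_matrix
#' @method glance bin_matrix
#' @export
glance.bin_matrix <- function(x, ...) {
  tibble(
    n_bins = nrow(x$bins),
    n_studies = ncol(x$matrix),
    n_excluded = nrow(x$excluded),
    max_support = max(x$bins$n_studies),
    bin_size = x$params$bin_size
  )
}
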