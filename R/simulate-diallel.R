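#' Describe the generative truth of a half-diallel trial
#'
#' A half-diallel crosses every unordered pair of a parent set once (no
#' reciprocals), so `p` parents yield `choose(p, 2)` F1 hybrids. Each parent
#' carries a fixed genetic value (degrees Brix for a sweetness trait); an F1's
#' genetic value is its mid-parent plus a pair-specific dominance deviation
#' `d`. Plot noise is i.i.d. Gaussian.
#'
#' @param parent_values Named numeric vector of parental genetic values; the
#'   names are the parent ids. At least two parents.
#' @param dominance Dominance deviations `d` per unordered parent pair: a
#'   single number recycled to every pair (default 0, pure additivity), or a
#'   symmetric numeric matrix with parent names on both dimnames.
#' @param env_sd Plot-noise standard deviation (same units as the trait),
#'   `>= 0`.
#' @param n_years,n_reps Number of years (trials) and replicates per year,
#'   each `>= 1`.
#' @param trait Trait label stored in the phenotype records.
#' @return An object of class `diallel_truth`.
#' @seealso [simulate_diallel()], [diallel_genetic_values()]
#' @export
diallel_truth <- function(parent_values, dominance = 0, env_sd = 1,
                          n_years = 1, n_reps = 1, trait = "TSS") {
  if (length(parent_values) < 2) abort("need at least 2 parents")
  if (is.null(names(parent_values)) || anyDuplicated(names(parent_values))) {
    abort("parent_values must be uniquely named")
  }
  if (!is.numeric(env_sd) || env_sd < 0) abort("env_sd must be >= 0")
  if (n_years < 1 || n_reps < 1) abort("n_years and n_reps must be >= 1")
  parents <- names(parent_values)
  p <- length(parents)
  if (is.matrix(dominance)) {
    if (!identical(sort(rownames(dominance)), sort(parents)) ||
        !identical(sort(colnames(dominance)), sort(parents))) {
      abort("dominance matrix dimnames must match the parent names")
    }
    dmat <- dominance[parents, parents]
    if (max(abs(dmat - t(dmat))) > 1e-8) abort("dominance matrix must be symmetric")
  } else {
    stopifnot(is.numeric(dominance), length(dominance) == 1)
    dmat <- matrix(dominance, p, p, dimnames = list(parents, parents))
  }
  structure(
    list(parent_values = parent_values, dominance = dmat, env_sd = env_sd,
         n_years = as.integer(n_years), n_reps = as.integer(n_reps),
         trait = trait),
    class = "diallel_truth"
  )
}

#' Genetic values of every genotype in a half-diallel
#'
#' @param truth A [diallel_truth()] object.
#' @return A tibble with one row per genotype (parents and all unordered F1s):
#'   `line`, `genotype_class` (`"parent"` or `"F1"`), `parent1`, `parent2`,
#'   and the noise-free genetic value `g`.
#' @export
diallel_genetic_values <- function(truth) {
  stopifnot(inherits(truth, "diallel_truth"))
  parents <- names(truth$parent_values)
  par_tbl <- tibble(
    line = parents, genotype_class = "parent",
    parent1 = parents, parent2 = parents,
    g = unname(truth$parent_values)
  )
  pairs <- utils::combn(parents, 2)
  f1_tbl <- tibble(
    parent1 = pairs[1, ], parent2 = pairs[2, ],
    line = paste(pairs[1, ], pairs[2, ], sep = "x"),
    genotype_class = "F1",
    g = unname(
      (truth$parent_values[pairs[1, ]] + truth$parent_values[pairs[2, ]]) / 2 +
        truth$dominance[cbind(pairs[1, ], pairs[2, ])]
    )
  )
  bind_rows(par_tbl, f1_tbl) %>%
    select("line", "genotype_class", "parent1", "parent2", "g")
}

#' Simulate phenotypes of a half-diallel trial
#'
#' Generates one plot record per genotype x year x replicate. Parents realise
#' their own genetic value, F1s their mid-parent plus dominance deviation,
#' and every plot receives independent Gaussian noise with standard deviation
#' `env_sd`. Identical `truth` and `seed` give byte-identical tables.
#'
#' @param truth A [diallel_truth()] object.
#' @param seed Integer seed; required, no global random state is consumed.
#' @return A phenotype tibble with columns `line`, `genotype_class`,
#'   `parent1`, `parent2`, `year`, `rep`, `trait`, `value`.
#' @export
#' @examples
#' truth <- diallel_truth(c(A = 6, B = 10, C = 14), env_sd = 0.5,
#'                        n_years = 2, n_reps = 3)
#' ph <- simulate_diallel(truth, seed = 1)
#' dplyr::count(ph, genotype_class)
simulate_diallel <- function(truth, seed) {
  stopifnot(inherits(truth, "diallel_truth"))
  gv <- diallel_genetic_values(truth)
  grid <- tidyr::expand_grid(
    gv,
    year = seq_len(truth$n_years),
    rep = seq_len(truth$n_reps)
  )
  with_seed(seed, {
    grid %>%
      mutate(
        trait = truth$trait,
        value = .data$g + rnorm(n(), 0, truth$env_sd)
      ) %>%
      select("line", "genotype_class", "parent1", "parent2",
             "year", "rep", "trait", "value")
  })
}

#' Half-diallel pedigree table implied by a truth object
#'
#' @param truth A [diallel_truth()] object.
#' @return A design tibble (`line`, `parent1`, `parent2`) listing the parents
#'   (selfs) and all unordered F1 combinations, as consumed by
#'   [build_diallel_matrix()] and [hybrid_groups()].
#' @export
diallel_design <- function(truth) {
  diallel_genetic_values(truth) %>% select("line", "parent1", "parent2")
}
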