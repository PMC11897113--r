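#' Broad-sense heritability from one-way ANOVA variance components
#'
#' Estimates H2 = Var(G) / Var(P) per experiment from replicated genotype
#' observations using the classical one-way random-effects decomposition:
#' `var_g = (MS_genotype - MS_error) / r` with `r` the harmonic-mean
#' replicate number (robust to unbalance), and plot-level phenotypic
#' variance `var_p = var_g + MS_error`. Negative genetic-variance estimates
#' are clamped to zero and flagged.
#'
#' @param pheno Phenotype tibble with columns `line`, `trait`, `value` (and
#'   any grouping columns named in `by`).
#' @param trait Trait to analyse.
#' @param by Optional character vector of grouping columns defining separate
#'   experiments (e.g. `"year"`); one estimate per group.
#' @return A tibble with one row per group: `var_g`, `var_e` (error mean
#'   square), `var_p`, `h2`, `n_genotypes`, `n_reps` (harmonic mean),
#'   `clamped`.
#' @export
#' @examples
#' truth <- diallel_truth(c(A = 6, B = 10, C = 14), env_sd = 1, n_reps = 4)
#' estimate_heritability(simulate_diallel(truth, seed = 2), trait = "TSS")
estimate_heritability <- function(pheno, trait, by = NULL) {
  assert_columns(pheno, c("line", "trait", "value", by), "pheno")
  dat <- filter(pheno, .data$trait == !!trait)
  if (nrow(dat) == 0) abort(sprintf("trait '%s' absent from phenotypes", trait))
  one <- function(d) {
    grp <- d %>%
      group_by(.data$line) %>%
      summarise(n = n(), m = mean(.data$value),
                ssw = sum((.data$value - mean(.data$value))^2),
                .groups = "drop")
    k <- nrow(grp)
    if (k < 2) abort("heritability needs >= 2 genotypes")
    n_tot <- sum(grp$n)
    if (n_tot - k < 1) abort("heritability needs >= 2 replicates for at least one genotype")
    grand <- sum(grp$n * grp$m) / n_tot
    ms_g <- sum(grp$n * (grp$m - grand)^2) / (k - 1)
    ms_e <- sum(grp$ssw) / (n_tot - k)
    if (ms_g == 0 && ms_e == 0) abort("no phenotypic variance (var_p = 0)")
    r_bar <- harmonic_mean(grp$n)
    var_g <- (ms_g - ms_e) / r_bar
    clamped <- var_g < 0
    var_g <- max(var_g, 0)
    var_p <- var_g + ms_e
    tibble(var_g = var_g, var_e = ms_e, var_p = var_p,
           h2 = var_g / var_p, n_genotypes = k, n_reps = r_bar,
           clamped = clamped)
  }
  if (is.null(by)) {
    one(dat)
  } else {
    dat %>%
      group_by(across(all_of(by))) %>%
      group_modify(~ one(.x)) %>%
      ungroup()
  }
}

#' Assemble the genotype-mean matrix of a half-diallel
#'
#' Builds the symmetric parents-by-parents matrix whose off-diagonal cells
#' hold F1 genotype means and whose diagonal holds the parents' own means,
#' with both axes sorted ascending by general combining ability (GCA: a
#' parent's mean over all its crosses).
#'
#' @param pheno Phenotype tibble (`line`, `trait`, `value`).
#' @param design Pedigree tibble (`line`, `parent1`, `parent2`); parents are
#'   rows with `parent1 == parent2`.
#' @param trait Trait to summarise.
#' @return An object of class `diallel_matrix`: list with `matrix` (numeric,
#'   GCA-ordered, `NA` for missing cells), `gca` (tibble `parent`, `gca`),
#'   and `trait`.
#' @export
build_diallel_matrix <- function(pheno, design, trait = "TSS") {
  assert_columns(pheno, c("line", "trait", "value"), "pheno")
  assert_columns(design, c("line", "parent1", "parent2"), "design")
  parents <- sort(unique(c(design$parent1, design$parent2)))
  means <- pheno %>%
    filter(.data$trait == !!trait) %>%
    group_by(.data$line) %>%
    summarise(m = mean(.data$value), .groups = "drop")
  missing_lines <- setdiff(design$line, means$line)
  if (length(missing_lines) > 0) {
    abort(sprintf("design lines absent from phenotypes: %s",
                  paste(head(missing_lines, 5), collapse = ", ")))
  }
  cells <- design %>% left_join(means, by = "line")
  mat <- matrix(NA_real_, length(parents), length(parents),
                dimnames = list(parents, parents))
  mat[cbind(cells$parent1, cells$parent2)] <- cells$m
  mat[cbind(cells$parent2, cells$parent1)] <- cells$m
  off <- mat
  diag(off) <- NA
  gca <- tibble(
    parent = parents,
    gca = rowMeans(off, na.rm = TRUE)
  ) %>% arrange(.data$gca)
  structure(
    list(matrix = mat[gca$parent, gca$parent], gca = gca, trait = trait),
    class = "diallel_matrix"
  )
}

#' @export
print.diallel_matrix <- function(x, ...) {
  cat(sprintf("half-diallel matrix: %d parents, trait %s (GCA-ordered)\n",
              nrow(x$matrix), x$trait))
  print(round(x$matrix, 2))
  invisible(x)
}

#' Build hybrid groups (F1 plus its two parents) from a diallel
#'
#' @param pheno Phenotype tibble (`line`, `trait`, `value`).
#' @param design Pedigree tibble (`line`, `parent1`, `parent2`).
#' @param trait Trait to summarise.
#' @return A tibble with one row per F1: `parent1`, `parent2`, `p1_mean`,
#'   `p2_mean`, `f1_mean` (genotype means over all records).
#' @export
hybrid_groups <- function(pheno, design, trait = "TSS") {
  assert_columns(design, c("line", "parent1", "parent2"), "design")
  means <- pheno %>%
    filter(.data$trait == !!trait) %>%
    group_by(.data$line) %>%
    summarise(m = mean(.data$value), .groups = "drop")
  f1 <- filter(design, .data$parent1 != .data$parent2)
  f1 %>%
    left_join(means, by = "line") %>%
    mutate(
      p1_mean = means$m[match(.data$parent1, means$line)],
      p2_mean = means$m[match(.data$parent2, means$line)]
    ) %>%
    select("parent1", "parent2", "p1_mean", "p2_mean", f1_mean = "m")
}

#' Mode-of-inheritance statistics of hybrid groups
#'
#' For each group (an F1 and its two parents) computes the mid-parent value,
#' the additive effect `a` (half the absolute parental difference), the
#' dominance effect `d` (F1 minus mid-parent, signed positive toward the
#' higher parent — which for `f1 = mid + dev` is simply `dev`), and the
#' degree of dominance `d / a` (`NA` when `a = 0`; `|d/a| > 1` indicates
#' over- or under-dominance).
#'
#' @param groups Tibble with columns `p1_mean`, `p2_mean`, `f1_mean` (one row
#'   per hybrid group), e.g. from [hybrid_groups()].
#' @return The input with added columns `mid_parent`, `a`, `d`, `degree`.
#' @export
#' @examples
#' hybrid_group_stats(tibble::tibble(
#'   p1_mean = 15.2, p2_mean = 4.9, f1_mean = 12.0
#' ))
hybrid_group_stats <- function(groups) {
  assert_columns(groups, c("p1_mean", "p2_mean", "f1_mean"), "groups")
  groups %>%
    mutate(
      mid_parent = (.data$p1_mean + .data$p2_mean) / 2,
      a = abs(.data$p1_mean - .data$p2_mean) / 2,
      d = .data$f1_mean - .data$mid_parent,
      degree = ifelse(.data$a > 0, .data$d / .data$a, NA_real_)
    )
}

#' Dominance distribution over differential hybrid groups
#'
#' Restricts hybrid groups to those whose parents differ substantially
#' (`a > a_min`, default 2 trait units) and summarises the dominance effects
#' across that subset, including a two-sided one-sample t-test of mean `d`
#' against zero.
#'
#' @param groups Hybrid-group tibble; [hybrid_group_stats()] columns are
#'   computed if absent.
#' @param a_min Additive-effect threshold (`>= 0`); groups with `a > a_min`
#'   are retained.
#' @return One-row tibble: `n_selected`, `mean_d`, `sd_d`, `mean_abs_degree`,
#'   `t_stat`, `df`, `p_value`.
#' @export
dominance_distribution <- function(groups, a_min = 2) {
  if (a_min < 0) abort("a_min must be >= 0")
  if (!all(c("a", "d", "degree") %in% names(groups))) {
    groups <- hybrid_group_stats(groups)
  }
  sel <- filter(groups, .data$a > a_min)
  if (nrow(sel) == 0) abort("no hybrid groups retained at this a_min")
  tt <- if (nrow(sel) >= 2 && sd(sel$d) > 0) t.test(sel$d) else NULL
  tibble(
    n_selected = nrow(sel),
    mean_d = mean(sel$d),
    sd_d = if (nrow(sel) >= 2) sd(sel$d) else NA_real_,
    mean_abs_degree = mean(abs(sel$degree), na.rm = TRUE),
    t_stat = if (is.null(tt)) NA_real_ else unname(tt$statistic),
    df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
    p_value = if (is.null(tt)) NA_real_ else tt$p.value
  )
}

pearson_result <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) abort("need >= 3 paired finite observations")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in one of the variables")
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value,
         r2 = unname(ct$estimate)^2, n = length(x))
}

#' Mid-parent versus F1 correlation
#'
#' Pearson correlation between mid-parent values and F1 means across hybrid
#' groups: the strength of the additive inheritance component (r close to 1
#' means F1s track their parental means).
#'
#' @param groups Hybrid-group tibble (`p1_mean`, `p2_mean`, `f1_mean`).
#' @return One-row tibble `r`, `p`, `r2`, `n`.
#' @export
midparent_f1_correlation <- function(groups) {
  assert_columns(groups, c("p1_mean", "p2_mean", "f1_mean"), "groups")
  pearson_result((groups$p1_mean + groups$p2_mean) / 2, groups$f1_mean)
}

#' Cross-trait correlation on genotype means
#'
#' Pearson correlation between two traits computed on genotype means within
#' each experiment (genotype means, not plot values, are the unit of
#' analysis).
#'
#' @param pheno Phenotype tibble (`line`, `trait`, `value`, plus grouping
#'   columns).
#' @param trait_x,trait_y The two traits.
#' @param by Optional character vector of grouping columns (e.g. `"year"`).
#' @return A tibble with one row per group: `trait_x`, `trait_y`, `r`, `p`,
#'   `r2`, `n`.
#' @export
trait_correlation <- function(pheno, trait_x, trait_y, by = NULL) {
  assert_columns(pheno, c("line", "trait", "value", by), "pheno")
  one <- function(d) {
    wide <- d %>%
      filter(.data$trait %in% c(trait_x, trait_y)) %>%
      group_by(.data$line, .data$trait) %>%
      summarise(m = mean(.data$value), .groups = "drop") %>%
      tidyr::pivot_wider(names_from = "trait", values_from = "m")
    if (!all(c(trait_x, trait_y) %in% names(wide))) {
      abort("both traits must be observed in every group")
    }
    pearson_result(wide[[trait_x]], wide[[trait_y]]) %>%
      mutate(trait_x = trait_x, trait_y = trait_y, .before = 1)
  }
  if (is.null(by)) {
    one(pheno)
  } else {
    pheno %>%
      group_by(across(all_of(by))) %>%
      group_modify(~ one(.x)) %>%
      ungroup()
  }
}
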