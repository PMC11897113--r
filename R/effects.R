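# Marker-level QTL analytics on inbred-line populations. All operations
# work on line means and, following standard practice for near-inbred
# material, use only the two homozygote classes unless stated otherwise.

line_means <- function(pheno, trait) {
  assert_columns(pheno, c("line", "trait", "value"), "pheno")
  d <- filter(pheno, .data$trait == !!trait)
  if (nrow(d) == 0) abort(sprintf("trait '%s' absent from phenotypes", trait))
  d %>%
    group_by(.data$line) %>%
    summarise(y = mean(.data$value), .groups = "drop")
}

# wide line x marker genotype matrix of codes, rows restricted to `lines`
geno_matrix <- function(genos, lines = NULL) {
  assert_columns(genos, c("line", "marker", "geno"), "genos")
  wide <- genos %>%
    select("line", "marker", "geno") %>%
    tidyr::pivot_wider(names_from = "marker", values_from = "geno")
  if (!is.null(lines)) wide <- filter(wide, .data$line %in% lines)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$line
  m
}

marker_map <- function(genos) {
  genos %>% distinct(.data$marker, .data$chrom, .data$pos)
}

#' Single-marker genome scan with permutation threshold
#'
#' Tests each marker by one-way ANOVA of line means between the two
#' homozygote classes (heterozygous and missing lines excluded). The
#' genome-wide significance threshold at level `alpha` is the
#' `alpha`-quantile of the per-permutation minimum p-value across markers
#' (phenotypes permuted over lines, `n_perm` times). Benjamini-Hochberg
#' q-values are also reported. With `n_perm` permutations the smallest
#' attainable permutation p-value is `1 / (n_perm + 1)`.
#'
#' @param genos Long genotype tibble (`line`, `marker`, `chrom`, `pos`,
#'   `geno` in `A/B/H/N`).
#' @param pheno Phenotype tibble (`line`, `trait`, `value`).
#' @param trait Trait to scan.
#' @param n_perm Number of permutations (`>= 100`; default 1000).
#' @param alpha Genome-wide significance level (default 0.05).
#' @param seed Integer seed for the permutations.
#' @return An object of class `marker_scan`: tibble with per-marker `marker`,
#'   `chrom`, `pos`, `n_a`, `n_b`, `f_stat`, `p`, `q`, `perm_p`,
#'   `pass_perm`, plus attributes `threshold`, `alpha`, `n_perm`.
#' @export
marker_scan <- function(genos, pheno, trait, n_perm = 1000, alpha = 0.05,
                        seed) {
  if (n_perm < 100) abort("n_perm must be >= 100")
  ym <- line_means(pheno, trait)
  M <- geno_matrix(genos, lines = ym$line)
  if (nrow(M) == 0) abort("no genotyped lines with phenotypes")
  y <- ym$y[match(rownames(M), ym$line)]
  indA <- (M == "A") * 1
  indB <- (M == "B") * 1
  indA[is.na(indA)] <- 0
  indB[is.na(indB)] <- 0
  nA <- colSums(indA)
  nB <- colSums(indB)
  valid <- nA >= 2 & nB >= 2
  if (!any(valid)) abort("no marker with both homozygote classes populated (>= 2 lines each)")

  f_and_p <- function(yv) {
    # yv: n x k matrix of (possibly permuted) phenotypes
    sA <- crossprod(indA, yv)            # markers x k
    sB <- crossprod(indB, yv)
    sqT <- crossprod(indA + indB, yv^2)
    n <- nA + nB
    mA <- sA / nA
    mB <- sB / nB
    grand <- (sA + sB) / n
    ssb <- nA * (mA - grand)^2 + nB * (mB - grand)^2
    sst <- sqT - n * grand^2
    ssw <- pmax(sst - ssb, 0)
    fstat <- (ssb / 1) / (ssw / (n - 2))
    p <- pf(fstat, 1, n - 2, lower.tail = FALSE)
    p[!valid, ] <- NA
    list(f = fstat, p = p)
  }

  obs <- f_and_p(matrix(y, ncol = 1))
  res <- with_seed(seed, {
    Y <- vapply(seq_len(n_perm), function(i) sample(y), numeric(length(y)))
    perm <- f_and_p(Y)
    min_p <- apply(perm$p, 2, min, na.rm = TRUE)
    threshold <- unname(quantile(min_p, alpha, type = 1))
    perm_p <- vapply(obs$p[, 1], function(pm) {
      if (is.na(pm)) NA_real_ else (1 + sum(min_p <= pm)) / (n_perm + 1)
    }, numeric(1))
    list(min_p = min_p, threshold = threshold, perm_p = perm_p)
  })

  out <- tibble(
    marker = colnames(M),
    n_a = as.integer(nA), n_b = as.integer(nB),
    f_stat = unname(obs$f[, 1]), p = unname(obs$p[, 1]),
    q = unname(p.adjust(obs$p[, 1], method = "BH")),
    perm_p = unname(res$perm_p),
    pass_perm = unname(!is.na(obs$p[, 1]) & obs$p[, 1] <= res$threshold)
  ) %>%
    left_join(marker_map(genos), by = "marker") %>%
    select("marker", "chrom", "pos", everything()) %>%
    arrange(.data$chrom, .data$pos)
  attr(out, "threshold") <- res$threshold
  attr(out, "alpha") <- alpha
  attr(out, "n_perm") <- n_perm
  class(out) <- c("marker_scan", class(out))
  out
}

hom_classes <- function(genos, pheno, trait, markers) {
  ym <- line_means(pheno, trait)
  g <- genos %>%
    filter(.data$marker %in% markers, .data$line %in% ym$line) %>%
    select("line", "marker", "geno") %>%
    tidyr::pivot_wider(names_from = "marker", values_from = "geno")
  g$y <- ym$y[match(g$line, ym$line)]
  g
}

#' Allelic effect and percent variance explained at a marker
#'
#' Compares the two homozygote class means of line means at one marker:
#' `effect = mean(A) - mean(B)` (sign encodes the donor of the increasing
#' allele), `pve = 100 * SS_between / SS_total`, and a one-way ANOVA
#' p-value.
#'
#' @inheritParams marker_scan
#' @param marker Marker id.
#' @return One-row tibble: `marker`, `mean_a`, `mean_b`, `n_a`, `n_b`,
#'   `effect`, `se`, `pve`, `p`.
#' @export
allelic_effect <- function(genos, pheno, trait, marker) {
  d <- hom_classes(genos, pheno, trait, marker)
  if (!marker %in% names(d)) abort(sprintf("marker '%s' not found", marker))
  d <- d[d[[marker]] %in% c("A", "B"), ]
  ya <- d$y[d[[marker]] == "A"]
  yb <- d$y[d[[marker]] == "B"]
  if (length(ya) < 2 || length(yb) < 2) {
    abort("both homozygote classes need >= 2 lines")
  }
  n <- length(ya) + length(yb)
  grand <- mean(c(ya, yb))
  ssb <- length(ya) * (mean(ya) - grand)^2 + length(yb) * (mean(yb) - grand)^2
  sst <- sum((c(ya, yb) - grand)^2)
  ssw <- sst - ssb
  fstat <- if (ssw > 0) (ssb / 1) / (ssw / (n - 2)) else Inf
  p <- if (is.finite(fstat)) pf(fstat, 1, n - 2, lower.tail = FALSE) else 0
  se <- sqrt(ssw / (n - 2)) * sqrt(1 / length(ya) + 1 / length(yb))
  tibble(
    marker = marker,
    mean_a = mean(ya), mean_b = mean(yb),
    n_a = length(ya), n_b = length(yb),
    effect = mean(ya) - mean(yb), se = se,
    pve = if (sst > 0) 100 * ssb / sst else 0,
    p = p
  )
}

tukey_letters <- function(fit, factor_name) {
  glht <- multcomp::glht(fit, linfct = do.call(
    multcomp::mcp, setNames(list("Tukey"), factor_name)
  ))
  letters <- multcomp::cld(glht, level = 0.05)$mcletters$Letters
  tibble(class = names(letters), letter = unname(letters))
}

#' Two-QTL interaction analysis
#'
#' Restricts lines to the four double-homozygote classes at a pair of
#' markers, fits a two-way ANOVA with interaction on line means, and labels
#' the class means with a Tukey HSD compact letter display at alpha = 0.05
#' (classes not sharing a letter differ significantly). The interaction
#' estimate is the sum-to-zero cell contrast
#' `(m_AA + m_BB - m_AB - m_BA) / 4`.
#'
#' @inheritParams marker_scan
#' @param marker_a,marker_b The two markers.
#' @return An object of class `pair_interaction`: list with `classes`
#'   (tibble `geno_a`, `geno_b`, `mean`, `n`, `letter`), `effects` (one-row
#'   tibble `main_a`, `main_b`, `interaction`, `p_interaction`), and
#'   `complete` (FALSE when a class is empty; statistics are then `NA`
#'   rather than silently dropped).
#' @export
pair_interaction <- function(genos, pheno, trait, marker_a, marker_b) {
  d <- hom_classes(genos, pheno, trait, c(marker_a, marker_b))
  d <- d[d[[marker_a]] %in% c("A", "B") & d[[marker_b]] %in% c("A", "B"), ]
  d <- tibble(ga = d[[marker_a]], gb = d[[marker_b]], y = d$y)
  classes <- tidyr::expand_grid(ga = c("A", "B"), gb = c("A", "B")) %>%
    left_join(
      d %>% group_by(.data$ga, .data$gb) %>%
        summarise(mean = mean(.data$y), n = n(), .groups = "drop"),
      by = c("ga", "gb")
    ) %>%
    mutate(n = tidyr::replace_na(.data$n, 0L))
  if (any(classes$n == 0)) {
    return(structure(list(
      classes = rename(classes, geno_a = "ga", geno_b = "gb") %>%
        mutate(letter = NA_character_),
      effects = tibble(main_a = NA_real_, main_b = NA_real_,
                       interaction = NA_real_, p_interaction = NA_real_),
      complete = FALSE
    ), class = "pair_interaction"))
  }
  d$ga <- factor(d$ga)
  d$gb <- factor(d$gb)
  fit <- lm(y ~ ga * gb, data = d)
  an <- anova(fit)
  cm <- with(classes, setNames(mean, paste0(ga, gb)))
  inter <- (cm["AA"] + cm["BB"] - cm["AB"] - cm["BA"]) / 4
  # one-factor recoding of the 4 classes for the all-pairs letter display
  d$cls <- factor(paste0(d$ga, d$gb))
  letters <- if (nlevels(d$cls) == 4 && all(table(d$cls) >= 2) &&
                 stats::sd(d$y) > 0) {
    tryCatch(tukey_letters(aov(y ~ cls, data = d), "cls"),
             error = function(e) tibble(class = levels(d$cls), letter = NA_character_))
  } else {
    tibble(class = levels(d$cls), letter = NA_character_)
  }
  classes <- classes %>%
    mutate(letter = letters$letter[match(paste0(.data$ga, .data$gb),
                                         letters$class)]) %>%
    rename(geno_a = "ga", geno_b = "gb")
  structure(list(
    classes = classes,
    effects = tibble(
      main_a = unname((cm["AA"] + cm["AB"] - cm["BA"] - cm["BB"]) / 2),
      main_b = unname((cm["AA"] + cm["BA"] - cm["AB"] - cm["BB"]) / 2),
      interaction = unname(inter),
      p_interaction = an["ga:gb", "Pr(>F)"]
    ),
    complete = TRUE
  ), class = "pair_interaction")
}

#' @export
print.pair_interaction <- function(x, ...) {
  cat("QTL-pair interaction (double homozygote classes)\n")
  print(x$classes)
  if (x$complete) {
    cat(sprintf("interaction = %.3f (p = %.4g)\n",
                x$effects$interaction, x$effects$p_interaction))
  } else {
    cat("incomplete: at least one class has no lines\n")
  }
  invisible(x)
}

#' Favorable-allele stacking (QTL pyramiding) analysis
#'
#' Groups lines that are homozygous at every listed marker by how many
#' favorable alleles they stack, and contrasts the full-favorable against
#' the full-unfavorable haplotype class, in absolute trait units and as a
#' percent gain over the unfavorable class.
#'
#' @inheritParams marker_scan
#' @param markers Character vector of `>= 2` marker ids.
#' @param favorable Named character vector mapping each marker to its
#'   favorable allele (`"A"` or `"B"`).
#' @return An object of class `stack_result`: list with `by_count` (tibble
#'   `n_favorable`, `mean`, `n`; empty classes flagged with `n = 0`),
#'   `by_class` (per exact haplotype), and `contrast` (one-row tibble
#'   `favorable_mean`, `unfavorable_mean`, `gain`, `gain_pct`, `n_favorable`,
#'   `n_unfavorable`).
#' @export
stack_analysis <- function(genos, pheno, trait, markers, favorable) {
  if (length(markers) < 2) abort("need >= 2 markers to stack")
  if (!all(markers %in% names(favorable))) {
    abort("favorable allele must be declared for every marker")
  }
  if (!all(favorable[markers] %in% c("A", "B"))) {
    abort("favorable alleles must be 'A' or 'B'")
  }
  d <- hom_classes(genos, pheno, trait, markers)
  keep <- Reduce(`&`, lapply(markers, function(m) d[[m]] %in% c("A", "B")))
  d <- d[keep, ]
  fav <- vapply(markers, function(m) d[[m]] == favorable[[m]],
                logical(nrow(d)))
  if (nrow(d) == 1) fav <- matrix(fav, nrow = 1)
  d$n_favorable <- rowSums(fav)
  d$haplotype <- apply(as.matrix(d[, markers]), 1, paste, collapse = "")
  k <- length(markers)
  by_count <- tibble(n_favorable = 0:k) %>%
    left_join(
      d %>% group_by(.data$n_favorable) %>%
        summarise(mean = mean(.data$y), n = n(), .groups = "drop"),
      by = "n_favorable"
    ) %>%
    mutate(n = tidyr::replace_na(.data$n, 0L))
  by_class <- d %>%
    group_by(.data$haplotype, .data$n_favorable) %>%
    summarise(mean = mean(.data$y), n = n(), .groups = "drop") %>%
    arrange(.data$n_favorable, .data$haplotype)
  full <- filter(by_count, .data$n_favorable == k)
  null <- filter(by_count, .data$n_favorable == 0)
  if (full$n == 0 || null$n == 0) {
    abort("no line in the full-favorable or full-unfavorable class")
  }
  contrast <- tibble(
    favorable_mean = full$mean, unfavorable_mean = null$mean,
    gain = full$mean - null$mean,
    gain_pct = 100 * (full$mean - null$mean) / null$mean,
    n_favorable = full$n, n_unfavorable = null$n
  )
  structure(list(by_count = by_count, by_class = by_class,
                 contrast = contrast, markers = markers,
                 favorable = favorable[markers]),
            class = "stack_result")
}

#' @export
print.stack_result <- function(x, ...) {
  cat(sprintf("stacking of %d QTLs: gain %.2f units (%.0f%%)\n",
              length(x$markers), x$contrast$gain, x$contrast$gain_pct))
  print(x$by_count)
  invisible(x)
}

#' Per-pair expected (additive) and observed QTL-pair effects
#'
#' For each marker pair, the expected non-epistatic effect is the sum of the
#' two singular allelic effects (oriented so each favorable allele
#' increases the trait), and the observed effect is the contrast between
#' the double-favorable and double-unfavorable homozygote class means.
#'
#' @inheritParams stack_analysis
#' @param pairs Tibble with columns `marker_a`, `marker_b`.
#' @return A tibble per pair: `marker_a`, `marker_b`, `expected`,
#'   `observed`, `n_favorable`, `n_unfavorable`.
#' @export
pair_effects <- function(genos, pheno, trait, pairs, favorable) {
  assert_columns(pairs, c("marker_a", "marker_b"), "pairs")
  purrr::pmap_dfr(pairs, function(marker_a, marker_b, ...) {
    orient <- function(m) {
      eff <- allelic_effect(genos, pheno, trait, m)
      if (favorable[[m]] == "A") eff$effect else -eff$effect
    }
    expected <- orient(marker_a) + orient(marker_b)
    d <- hom_classes(genos, pheno, trait, c(marker_a, marker_b))
    d <- d[d[[marker_a]] %in% c("A", "B") & d[[marker_b]] %in% c("A", "B"), ]
    fav_a <- d[[marker_a]] == favorable[[marker_a]]
    fav_b <- d[[marker_b]] == favorable[[marker_b]]
    both <- d$y[fav_a & fav_b]
    none <- d$y[!fav_a & !fav_b]
    tibble(
      marker_a = marker_a, marker_b = marker_b,
      expected = expected,
      observed = if (length(both) > 0 && length(none) > 0) {
        mean(both) - mean(none)
      } else {
        NA_real_
      },
      n_favorable = length(both), n_unfavorable = length(none)
    )
  })
}

#' Expected-versus-observed additivity regression over QTL pairs
#'
#' Regresses observed QTL-pair effects on their expected (sum-of-singles)
#' effects and tests whether the slope departs from 1. A slope below 1
#' indicates general less-than-additive epistasis: pairs deliver less than
#' the sum of their parts.
#'
#' @param pairs Tibble with columns `expected` and `observed` (one row per
#'   QTL pair), e.g. from [pair_effects()]. At least 3 complete pairs.
#' @return An object of class `additivity_regression`: list with `slope`,
#'   `intercept`, `r2`, `se_slope`, `p_slope_eq_1` (two-sided test of
#'   slope = 1), `n`, and the per-pair `table`.
#' @export
expected_vs_observed <- function(pairs) {
  assert_columns(pairs, c("expected", "observed"), "pairs")
  d <- filter(pairs, is.finite(.data$expected), is.finite(.data$observed))
  if (nrow(d) < 3) abort("need >= 3 complete QTL pairs")
  if (sd(d$expected) == 0) abort("zero variance in expected effects")
  fit <- lm(observed ~ expected, data = d)
  sm <- summary(fit)
  b <- coef(sm)["expected", ]
  t1 <- (b["Estimate"] - 1) / b["Std. Error"]
  structure(list(
    slope = unname(b["Estimate"]),
    intercept = unname(coef(fit)[1]),
    se_slope = unname(b["Std. Error"]),
    r2 = sm$r.squared,
    p_slope_eq_1 = unname(2 * pt(abs(t1), df = nrow(d) - 2, lower.tail = FALSE)),
    n = nrow(d),
    table = d
  ), class = "additivity_regression")
}

#' @export
print.additivity_regression <- function(x, ...) {
  cat(sprintf(
    "observed ~ expected over %d QTL pairs: slope %.2f (se %.2f), R2 %.2f, p(slope = 1) = %.3g\n",
    x$n, x$slope, x$se_slope, x$r2, x$p_slope_eq_1
  ))
  invisible(x)
}
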