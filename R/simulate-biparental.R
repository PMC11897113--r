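#' Describe the generative truth of a biparental inbred-line population
#'
#' Models a recombinant inbred-line population derived from a cross between
#' two inbred parents ("A" and "B") and advanced by single-seed descent to a
#' given selfing generation (e.g. `generation = 6` for F6 lines). Residual
#' heterozygosity per locus is `(1/2)^(generation - 1)`. Trait variation is
#' controlled by a set of planted biallelic QTLs with additive effects, plus
#' Gaussian noise scaled so the realized plot-level broad-sense heritability
#' equals `h2`.
#'
#' @param n_lines Number of lines (`>= 2`).
#' @param generation Filial generation (`>= 2`); F2 corresponds to
#'   `generation = 2` (one selfing meiosis from the F1).
#' @param qtls Tibble of planted QTLs with columns `chrom`, `pos`,
#'   `effect` (difference between the two homozygote class means, trait
#'   units) and `donor` (`"A"` or `"B"`: the parent contributing the
#'   trait-increasing allele). May have zero rows.
#' @param h2 Target broad-sense heritability at the plot level, in `[0, 1]`.
#'   Ignored (no genetic variance) when `qtls` is empty.
#' @param chrom_sizes Chromosome-sizes tibble; defaults to
#'   [default_chrom_sizes()].
#' @param n_markers Total number of marker loci, spread over chromosomes
#'   proportionally to their length and placed uniformly at random. Planted
#'   QTL positions are always included as markers.
#' @param noise_sd Residual standard deviation used when there is no genetic
#'   variance (zero QTLs or `h2 = 0`).
#' @param baseline Population baseline trait value (degrees Brix scale).
#' @param n_reps Replicates (plots) phenotyped per line.
#' @param crossovers Crossovers per chromosome per meiosis, placed uniformly
#'   (map-distance proxy; default 1).
#' @param missing_rate Per-genotype-call missing rate (`N` codes).
#' @param trait Trait label.
#' @return An object of class `biparental_truth`.
#' @seealso [simulate_biparental()]
#' @export
biparental_truth <- function(n_lines, generation = 6,
                             qtls = tibble(chrom = character(), pos = integer(),
                                           effect = double(), donor = character()),
                             h2 = 0.5, chrom_sizes = default_chrom_sizes(),
                             n_markers = 1000, noise_sd = 1, baseline = 10,
                             n_reps = 1, crossovers = 1, missing_rate = 0,
                             trait = "TSS") {
  if (n_lines < 2) abort("n_lines must be >= 2")
  if (generation < 2) abort("generation must be >= 2")
  if (!is.numeric(h2) || h2 < 0 || h2 > 1) abort("h2 must be in [0, 1]")
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  assert_columns(qtls, c("chrom", "pos", "effect", "donor"), "qtls")
  if (nrow(qtls) > 0) {
    if (!all(qtls$donor %in% c("A", "B"))) abort("qtl donor must be 'A' or 'B'")
    if (!all(qtls$chrom %in% chrom_sizes$chrom)) abort("qtl chrom not in chrom_sizes")
    len <- chrom_sizes$length[match(qtls$chrom, chrom_sizes$chrom)]
    if (any(qtls$pos < 1 | qtls$pos > len)) abort("qtl pos outside chromosome bounds")
    if (h2 == 0) abort("h2 = 0 with planted QTLs has no finite noise scale")
  }
  structure(
    list(n_lines = as.integer(n_lines), generation = as.integer(generation),
         qtls = as_tibble(qtls), h2 = h2, chrom_sizes = chrom_sizes,
         n_markers = as.integer(n_markers), noise_sd = noise_sd,
         baseline = baseline, n_reps = as.integer(n_reps),
         crossovers = as.integer(crossovers), missing_rate = missing_rate,
         trait = trait),
    class = "biparental_truth"
  )
}

# One meiosis for all lines on one chromosome, vectorized across lines.
# hap1/hap2 are n x m logical matrices (TRUE = parent-A allele); returns one
# gamete per line with `crossovers` uniformly placed breakpoints and a random
# starting chromatid.
meiosis_gamete <- function(hap1, hap2, pos, chrom_len, crossovers) {
  n <- nrow(hap1)
  m <- ncol(hap1)
  start_first <- runif(n) < 0.5
  first <- hap1
  first[!start_first, ] <- hap2[!start_first, , drop = FALSE]
  second <- hap2
  second[!start_first, ] <- hap1[!start_first, , drop = FALSE]
  if (crossovers < 1) return(first)
  # Parity of crossover count to the left of each marker decides the strand.
  parity <- matrix(0L, n, m)
  for (k in seq_len(crossovers)) {
    xo <- runif(n, 0, chrom_len)
    parity <- parity + outer(xo, pos, `<`)
  }
  odd <- parity %% 2L == 1L
  gam <- first
  gam[odd] <- second[odd]
  gam
}

#' Simulate genotypes and phenotypes of an SSD inbred-line population
#'
#' Each line starts as an F1 (heterozygous everywhere) and is selfed
#' `generation - 1` times; every meiosis places `crossovers` breakpoints
#' uniformly on each chromosome, so alleles at linked loci co-segregate.
#' Phenotypes are `baseline + sum of signed QTL contributions + noise`, with
#' the noise variance set from the *realized* genetic variance of the
#' simulated lines so that the plot-level broad-sense heritability equals
#' `h2` in each draw.
#'
#' @param truth A [biparental_truth()] object.
#' @param seed Integer seed.
#' @return A list with elements:
#' \describe{
#'   \item{genotypes}{long tibble `line`, `marker`, `chrom`, `pos`, `geno`
#'     with codes `A` (parent-A homozygote), `B`, `H` (heterozygote),
#'     `N` (missing).}
#'   \item{phenotypes}{tibble `line`, `genotype_class`, `year`, `rep`,
#'     `trait`, `value`.}
#'   \item{truth}{bookkeeping: planted QTLs with their marker ids, realized
#'     genetic values, residual sd, target `h2`.}
#' }
#' @export
#' @examples
#' tr <- biparental_truth(
#'   n_lines = 40, generation = 6, n_markers = 120, h2 = 0.8,
#'   qtls = tibble::tibble(chrom = "chr03", pos = 27e6, effect = 2, donor = "A")
#' )
#' sim <- simulate_biparental(tr, seed = 7)
#' head(sim$phenotypes)
simulate_biparental <- function(truth, seed) {
  stopifnot(inherits(truth, "biparental_truth"))
  cs <- truth$chrom_sizes
  with_seed(seed, {
    # marker placement: proportional to chromosome length, uniform positions
    n_per <- pmax(1L, round(truth$n_markers * as.numeric(cs$length) /
                              sum(as.numeric(cs$length))))
    geno_list <- vector("list", nrow(cs))
    qtl_dose <- matrix(0, truth$n_lines, nrow(truth$qtls))
    qtl_marker <- character(nrow(truth$qtls))
    for (ci in seq_len(nrow(cs))) {
      chrom <- cs$chrom[ci]
      len <- cs$length[ci]
      pos <- sort(unique(c(
        ceiling(runif(n_per[ci], 0, len)),
        truth$qtls$pos[truth$qtls$chrom == chrom]
      )))
      m <- length(pos)
      n <- truth$n_lines
      hap1 <- matrix(TRUE, n, m)   # F1: one A haplotype,
      hap2 <- matrix(FALSE, n, m)  # one B haplotype
      for (g in seq_len(truth$generation - 1L)) {
        g1 <- meiosis_gamete(hap1, hap2, pos, len, truth$crossovers)
        g2 <- meiosis_gamete(hap1, hap2, pos, len, truth$crossovers)
        hap1 <- g1
        hap2 <- g2
      }
      dose <- hap1 + hap2  # 0, 1, 2 copies of the A allele
      qi <- which(truth$qtls$chrom == chrom)
      if (length(qi) > 0) {
        j <- match(truth$qtls$pos[qi], pos)
        qtl_dose[, qi] <- dose[, j, drop = FALSE]
        qtl_marker[qi] <- marker_id(chrom, pos[j])
      }
      code <- matrix(c("B", "H", "A")[dose + 1L], n, m)
      if (truth$missing_rate > 0) {
        code[runif(n * m) < truth$missing_rate] <- "N"
      }
      geno_list[[ci]] <- tibble(
        line = rep(sprintf("L%04d", seq_len(n)), times = m),
        marker = rep(marker_id(chrom, pos), each = n),
        chrom = chrom,
        pos = rep(as.integer(pos), each = n),
        geno = as.vector(code)
      )
    }
    genotypes <- bind_rows(geno_list)

    # genetic values: each QTL contributes (effect/2) * signed dosage
    sign <- ifelse(truth$qtls$donor == "A", 1, -1)
    g_val <- truth$baseline +
      as.vector(qtl_dose %*% (sign * truth$qtls$effect / 2)) -
      sum(sign * truth$qtls$effect / 2)  # center: heterozygote at every QTL = baseline
    var_g <- if (nrow(truth$qtls) > 0) var(g_val) else 0
    sigma_e <- if (var_g > 0 && truth$h2 > 0) {
      if (truth$h2 == 1) 0 else sqrt(var_g * (1 - truth$h2) / truth$h2)
    } else {
      truth$noise_sd
    }
    lines <- sprintf("L%04d", seq_len(truth$n_lines))
    phenotypes <- tidyr::expand_grid(
      line = lines, year = 1L, rep = seq_len(truth$n_reps)
    ) %>%
      mutate(
        genotype_class = "line",
        trait = truth$trait,
        value = g_val[match(.data$line, lines)] + rnorm(n(), 0, sigma_e)
      ) %>%
      select("line", "genotype_class", "year", "rep", "trait", "value")

    list(
      genotypes = genotypes,
      phenotypes = phenotypes,
      truth = list(
        qtls = mutate(truth$qtls, marker = qtl_marker),
        genetic_values = tibble(line = lines, g = g_val),
        sigma_e = sigma_e, h2 = truth$h2, var_g = var_g,
        generation = truth$generation
      )
    )
  })
}

#' Select extreme-phenotype tails of a line population
#'
#' Ranks lines by their trait mean and returns the ids of the top `n_high`
#' and bottom `n_low` lines (ties broken by line id, lexically), the standard
#' design for extreme-tail bulk construction in QTL-seq.
#'
#' @param pheno Phenotype tibble with columns `line`, `trait`, `value`.
#' @param trait Trait to rank on.
#' @param n_high,n_low Tail sizes; their sum must not exceed the number of
#'   distinct lines.
#' @return A list with character vectors `high` and `low` (disjoint).
#' @export
select_tails <- function(pheno, trait, n_high, n_low) {
  assert_columns(pheno, c("line", "trait", "value"), "pheno")
  means <- pheno %>%
    filter(.data$trait == !!trait) %>%
    group_by(.data$line) %>%
    summarise(m = mean(.data$value), .groups = "drop")
  if (nrow(means) == 0) abort(sprintf("trait '%s' absent from phenotypes", trait))
  if (n_high + n_low > nrow(means)) {
    abort("n_high + n_low exceeds the number of distinct lines")
  }
  high <- means %>% arrange(desc(.data$m), .data$line) %>% slice_head(n = n_high)
  low <- means %>% arrange(.data$m, .data$line) %>% slice_head(n = n_low)
  list(high = high$line, low = low$line)
}
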