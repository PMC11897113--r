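#' Simulate pooled-sequencing read counts over two phenotype-tail bulks
#'
#' Emulates whole-genome resequencing of a high-tail and a low-tail DNA bulk
#' at a given mean depth (default scenario ~30x). At each site the bulk
#' "reference"-allele frequency is the mean parent-A allele dosage over the
#' bulk's lines (homozygote A = 1, heterozygote = 0.5, homozygote B = 0;
#' missing calls are excluded from the denominator, and lines are pooled
#' equimolar). Total depth is Poisson(`depth_mean`) per site and bulk, and
#' reference reads are Binomial(depth, frequency).
#'
#' @param genos Long genotype tibble (`line`, `marker`, `chrom`, `pos`,
#'   `geno`), e.g. from [simulate_biparental()].
#' @param high,low Character vectors of line ids forming the two bulks,
#'   e.g. from [select_tails()]. Must be non-empty subsets of the lines.
#' @param depth_mean Mean sequencing depth per site per bulk (`> 0`).
#' @param seed Integer seed.
#' @param n_sites Optional number of sites to keep: a seeded random subsample
#'   of the marker loci. `NULL` (default) uses every marker.
#' @return A site-counts tibble: `chrom`, `pos`, `ref_high`, `total_high`,
#'   `ref_low`, `total_low`, sorted by chromosome and position. The
#'   "reference" allele is the parent-A allele.
#' @seealso [bsa_scan()]
#' @export
simulate_bulk_reads <- function(genos, high, low, depth_mean = 30, seed,
                                n_sites = NULL) {
  assert_columns(genos, c("line", "marker", "chrom", "pos", "geno"), "genos")
  if (length(high) == 0 || length(low) == 0) abort("bulks must be non-empty")
  lines <- unique(genos$line)
  if (!all(c(high, low) %in% lines)) abort("bulk ids must be a subset of the genotyped lines")
  if (!is.numeric(depth_mean) || depth_mean <= 0) abort("depth_mean must be > 0")

  dose <- c(A = 1, H = 0.5, B = 0, N = NA_real_)

  map <- genos %>% distinct(.data$marker, .data$chrom, .data$pos)

  bulk_freq <- function(ids) {
    sub <- genos[genos$line %in% ids, ]
    d <- dose[sub$geno]
    ok <- !is.na(d)
    num <- rowsum(ifelse(ok, d, 0), sub$marker)
    den <- rowsum(ok * 1, sub$marker)
    setNames(as.vector(num / den), rownames(num))
  }

  with_seed(seed, {
    fh <- bulk_freq(high)
    fl <- bulk_freq(low)
    sites <- map %>%
      mutate(freq_high = unname(fh[.data$marker]),
             freq_low = unname(fl[.data$marker])) %>%
      arrange(.data$chrom, .data$pos)
    if (!is.null(n_sites) && n_sites < nrow(sites)) {
      keep <- sort(sample.int(nrow(sites), n_sites))
      sites <- sites[keep, ]
    }
    # sites where every genotype in a bulk is missing have no defined frequency
    sites <- filter(sites, is.finite(.data$freq_high), is.finite(.data$freq_low))
    n <- nrow(sites)
    sites %>%
      mutate(
        total_high = rpois(n, depth_mean),
        ref_high = rbinom(n, .data$total_high, .data$freq_high),
        total_low = rpois(n, depth_mean),
        ref_low = rbinom(n, .data$total_low, .data$freq_low)
      ) %>%
      select("chrom", "pos", "ref_high", "total_high", "ref_low", "total_low")
  })
}
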