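#' Simulate QTL interval tables from many mapping studies
#'
#' Generates the kind of multi-study QTL compilation used for pan-QTLome
#' integration: a set of hotspot genomic bins each emits, per study, a QTL
#' interval with a stated probability (centered at the bin midpoint, with a
#' drawn length), and each study additionally reports background QTLs placed
#' uniformly on the genome.
#'
#' @param n_studies Number of studies.
#' @param chrom_sizes Chromosome-sizes tibble.
#' @param hotspots Tibble with columns `chrom`, `start`, `end`, `prob`
#'   (per-study emission probability in `[0, 1]`). May be empty.
#' @param background_rate Expected number (Poisson mean) of background QTLs
#'   per study.
#' @param len_range Length-2 numeric: QTL interval lengths are drawn
#'   uniformly from this range (bp).
#' @param prop_low_donor Probability that a QTL's favorable allele is
#'   contributed by the low-trait parent (the paper-style "blue" QTLs).
#' @param seed Integer seed.
#' @return A list with `qtls` (tibble: `study`, `trait`, `chrom`, `start`,
#'   `end`, `donor`, `source` = `"hotspot"`/`"background"`) and `truth`
#'   (per-study planted counts and per-hotspot emission bookkeeping).
#' @export
simulate_qtl_studies <- function(n_studies, chrom_sizes = default_chrom_sizes(),
                                 hotspots = tibble(chrom = character(),
                                                   start = double(), end = double(),
                                                   prob = double()),
                                 background_rate = 2, len_range = c(1e6, 8e6),
                                 prop_low_donor = 0.2, seed) {
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  assert_columns(hotspots, c("chrom", "start", "end", "prob"), "hotspots")
  if (any(hotspots$prob < 0 | hotspots$prob > 1)) abort("hotspot prob must be in [0, 1]")
  if (!all(hotspots$chrom %in% chrom_sizes$chrom)) abort("hotspot chrom not in chrom_sizes")
  hl <- chrom_sizes$length[match(hotspots$chrom, chrom_sizes$chrom)]
  if (any(hotspots$start < 1 | hotspots$end > hl | hotspots$start > hotspots$end)) {
    abort("hotspot bins must lie within their chromosome")
  }
  if (any(len_range <= 0) || len_range[1] > len_range[2]) abort("invalid len_range")

  clip <- function(x, len) pmin(pmax(x, 1), len)
  studies <- sprintf("S%02d", seq_len(n_studies))

  with_seed(seed, {
    recs <- list()
    emitted <- list()
    for (s in studies) {
      if (nrow(hotspots) > 0) {
        hit <- runif(nrow(hotspots)) < hotspots$prob
        emitted[[s]] <- hit
        if (any(hit)) {
          hs <- hotspots[hit, ]
          len <- chrom_sizes$length[match(hs$chrom, chrom_sizes$chrom)]
          width <- runif(nrow(hs), len_range[1], len_range[2])
          mid <- (hs$start + hs$end) / 2
          recs[[length(recs) + 1]] <- tibble(
            study = s, trait = "TSS", chrom = hs$chrom,
            start = floor(clip(mid - width / 2, len)),
            end = ceiling(clip(mid + width / 2, len)),
            donor = ifelse(runif(nrow(hs)) < prop_low_donor, "low", "high"),
            source = "hotspot"
          )
        }
      } else {
        emitted[[s]] <- logical(0)
      }
      n_bg <- rpois(1, background_rate)
      if (n_bg > 0) {
        ci <- sample.int(nrow(chrom_sizes), n_bg, replace = TRUE,
                         prob = chrom_sizes$length)
        len <- chrom_sizes$length[ci]
        width <- runif(n_bg, len_range[1], len_range[2])
        center <- runif(n_bg, 0, len)
        recs[[length(recs) + 1]] <- tibble(
          study = s, trait = "TSS", chrom = chrom_sizes$chrom[ci],
          start = floor(clip(center - width / 2, len)),
          end = ceiling(clip(center + width / 2, len)),
          donor = ifelse(runif(n_bg) < prop_low_donor, "low", "high"),
          source = "background"
        )
      }
    }
    qtls <- if (length(recs) > 0) {
      bind_rows(recs) %>%
        mutate(start = as.integer(.data$start), end = as.integer(.data$end)) %>%
        arrange(.data$study, .data$chrom, .data$start)
    } else {
      tibble(study = character(), trait = character(), chrom = character(),
             start = integer(), end = integer(), donor = character(),
             source = character())
    }
    list(
      qtls = qtls,
      truth = list(
        per_study_n = qtls %>% count(.data$study, name = "n_qtls"),
        hotspot_emissions = emitted,
        hotspots = hotspots
      )
    )
  })
}
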