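#' Load and validate a multi-study QTL interval table
#'
#' Reads a BED-like TSV with columns `study`, `trait`, `chrom`, `start`,
#' `end`, `donor` (1-based inclusive coordinates on the common assembly).
#' Rows with unknown chromosomes, non-numeric or inverted coordinates are
#' rejected with a warning listing their row numbers; intervals extending
#' past the chromosome end are clipped with a warning.
#'
#' @param path TSV file path.
#' @param chrom_sizes Chromosome-sizes tibble defining the coordinate
#'   system.
#' @return A validated QTL tibble (`study`, `trait`, `chrom`, `start`,
#'   `end`, `donor`).
#' @export
load_qtl_table <- function(path, chrom_sizes) {
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  assert_columns(x, c("study", "chrom", "start", "end"), "QTL table")
  if (!"trait" %in% names(x)) x$trait <- NA_character_
  if (!"donor" %in% names(x)) x$donor <- "unknown"
  x <- x %>% mutate(
    row = dplyr::row_number(),
    start = suppressWarnings(as.numeric(.data$start)),
    end = suppressWarnings(as.numeric(.data$end))
  )
  bad <- !is.finite(x$start) | !is.finite(x$end) | x$start > x$end |
    x$start < 1 | !(x$chrom %in% chrom_sizes$chrom)
  if (any(bad)) {
    warn(sprintf("rejected %d malformed QTL row(s): %s",
                 sum(bad), paste(x$row[bad], collapse = ", ")))
    x <- x[!bad, ]
  }
  len <- chrom_sizes$length[match(x$chrom, chrom_sizes$chrom)]
  over <- x$end > len
  if (any(over)) {
    warn(sprintf("clipped %d QTL interval(s) to chromosome end (rows %s)",
                 sum(over), paste(x$row[over], collapse = ", ")))
    x$end[over] <- len[over]
  }
  x %>%
    select("study", "trait", "chrom", "start", "end", "donor") %>%
    mutate(start = as.integer(.data$start), end = as.integer(.data$end))
}

genome_bins <- function(chrom_sizes, bin_size) {
  purrr::map_dfr(seq_len(nrow(chrom_sizes)), function(ci) {
    len <- chrom_sizes$length[ci]
    starts <- seq(1, len, by = bin_size)
    tibble(
      chrom = chrom_sizes$chrom[ci],
      bin_start = starts,
      bin_end = pmin(starts + bin_size - 1, len)
    )
  }) %>%
    mutate(bin = sprintf("%s:%g-%g", .data$chrom, .data$bin_start, .data$bin_end))
}

#' Bin the genome and count per-bin study support of QTLs
#'
#' Partitions every chromosome into fixed-size bins (terminal bins truncated
#' at the chromosome end), excludes QTL intervals longer than
#' `max_interval` (length counted as `end - start + 1`), and assigns each
#' remaining QTL either to every bin its interval overlaps (default) or to
#' the single bin containing its midpoint. Per-bin study support counts
#' distinct studies, not QTL records.
#'
#' @param qtls QTL tibble (`study`, `chrom`, `start`, `end`).
#' @param chrom_sizes Chromosome-sizes tibble.
#' @param bin_size Bin width in bp (default 5 Mb).
#' @param max_interval Exclusion threshold on interval length (default
#'   15 Mb: intervals strictly longer are dropped).
#' @param assign `"overlap"` (default) or `"midpoint"`.
#' @return An object of class `bin_matrix`: list with `bins` (tibble
#'   `chrom`, `bin_start`, `bin_end`, `bin`, `n_studies`, `n_records`),
#'   `matrix` (bins x studies record counts), `excluded` (the dropped
#'   long-interval records), and `params`.
#' @export
bin_counts <- function(qtls, chrom_sizes, bin_size = 5e6, max_interval = 15e6,
                       assign = c("overlap", "midpoint")) {
  assign <- match.arg(assign)
  if (bin_size <= 0 || max_interval <= 0) abort("bin_size and max_interval must be > 0")
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  assert_columns(qtls, c("study", "chrom", "start", "end"), "qtls")
  bins <- genome_bins(chrom_sizes, bin_size)
  qtls <- mutate(qtls, len = .data$end - .data$start + 1)
  excluded <- filter(qtls, .data$len > max_interval)
  kept <- filter(qtls, .data$len <= max_interval)
  studies <- sort(unique(qtls$study))
  mat <- matrix(0L, nrow(bins), length(studies),
                dimnames = list(bins$bin, studies))
  if (nrow(kept) > 0) {
    hits <- purrr::map_dfr(seq_len(nrow(kept)), function(i) {
      q <- kept[i, ]
      b <- if (assign == "overlap") {
        filter(bins, .data$chrom == q$chrom,
               .data$bin_start <= q$end, .data$bin_end >= q$start)
      } else {
        mid <- floor((q$start + q$end) / 2)
        filter(bins, .data$chrom == q$chrom,
               .data$bin_start <= mid, .data$bin_end >= mid)
      }
      tibble(bin = b$bin, study = q$study)
    })
    tab <- hits %>% count(.data$bin, .data$study)
    mat[cbind(tab$bin, tab$study)] <- tab$n
  }
  support <- apply(mat > 0, 1, sum)
  bins <- bins %>%
    mutate(n_studies = as.integer(support[.data$bin]),
           n_records = as.integer(rowSums(mat)[.data$bin]))
  structure(list(
    bins = bins, matrix = mat, excluded = excluded,
    params = list(bin_size = bin_size, max_interval = max_interval,
                  assign = assign)
  ), class = "bin_matrix")
}

#' @export
print.bin_matrix <- function(x, ...) {
  cat(sprintf("pan-QTLome bin matrix: %d bins x %d studies (%s assignment, %d record(s) excluded as > %g bp)\n",
              nrow(x$bins), ncol(x$matrix), x$params$assign,
              nrow(x$excluded), x$params$max_interval))
  print(head(arrange(x$bins, desc(.data$n_studies)), 10))
  invisible(x)
}

#' Classify genomic bins by their multi-study QTL support
#'
#' Bins are `"empty"` (no supporting study), `"hotspot"` (support at or
#' above `hotspot_min_studies`, default 6), or `"rare"` otherwise. A genome
#' summary reports, for each support level `k`, how many bins are supported
#' by at least `k` studies.
#'
#' @param bm A [bin_counts()] result.
#' @param hotspot_min_studies Minimum study support for a hotspot (default
#'   6).
#' @return A list with `bins` (the bin tibble plus a `class` column) and
#'   `summary` (tibble `n_bins`, `n_empty`, and per-k `k`,
#'   `n_bins_k_or_more`).
#' @export
classify_bins <- function(bm, hotspot_min_studies = 6) {
  stopifnot(inherits(bm, "bin_matrix"))
  bins <- bm$bins %>%
    mutate(class = dplyr::case_when(
      .data$n_studies == 0 ~ "empty",
      .data$n_studies >= hotspot_min_studies ~ "hotspot",
      TRUE ~ "rare"
    ))
  kmax <- max(1, max(bins$n_studies))
  summary <- list(
    n_bins = nrow(bins),
    n_empty = sum(bins$n_studies == 0),
    support = tibble(
      k = seq_len(kmax),
      n_bins_k_or_more = vapply(seq_len(kmax),
                                function(k) sum(bins$n_studies >= k), integer(1))
    )
  )
  list(bins = bins, summary = summary,
       hotspot_min_studies = hotspot_min_studies)
}

#' Per-study QTL counts
#'
#' @param qtls QTL tibble (`study`, `chrom`, `start`, `end`).
#' @param max_interval Optional: when supplied, the long-interval exclusion
#'   rule is applied before counting.
#' @return A list with `per_study` (tibble `study`, `n_qtls`) and `overall`
#'   (one-row tibble `n_studies`, `n_qtls`, `mean`, `min`, `max`).
#' @export
study_summary <- function(qtls, max_interval = NULL) {
  assert_columns(qtls, c("study", "chrom", "start", "end"), "qtls")
  if (nrow(qtls) == 0) abort("empty QTL table")
  if (!is.null(max_interval)) {
    qtls <- filter(qtls, .data$end - .data$start + 1 <= max_interval)
  }
  per_study <- count(qtls, .data$study, name = "n_qtls")
  list(
    per_study = per_study,
    overall = tibble(
      n_studies = nrow(per_study),
      n_qtls = sum(per_study$n_qtls),
      mean = mean(per_study$n_qtls),
      min = min(per_study$n_qtls),
      max = max(per_study$n_qtls)
    )
  )
}
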