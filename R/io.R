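# Readers and writers for the package's plain-text interchange formats.

#' Read / write a phenotype table
#'
#' Long-format TSV with columns `line`, `genotype_class`, `year`, `rep`,
#' `trait`, `value` (extra columns are preserved).
#'
#' @param path File path.
#' @param pheno Phenotype tibble.
#' @return `read_phenotype()` returns a tibble; writers return `path`
#'   invisibly.
#' @export
read_phenotype <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols())
  assert_columns(x, c("line", "trait", "value"), "phenotype table")
  if (any(!is.finite(x$value))) abort("non-finite phenotype values")
  dup <- x %>%
    count(across(any_of(c("line", "year", "rep", "trait")))) %>%
    filter(n > 1)
  if (nrow(dup) > 0) abort("duplicate (line, year, rep, trait) keys in phenotype table")
  x
}

#' @rdname read_phenotype
#' @export
write_phenotype <- function(pheno, path) {
  assert_columns(pheno, c("line", "trait", "value"), "pheno")
  readr::write_tsv(pheno, path)
  invisible(path)
}

#' Read / write a line-by-marker genotype matrix
#'
#' The genotype file is a wide TSV (`line` column, then one column per
#' marker) with codes `A`/`B`/`H`/`N`; the marker map is a TSV with
#' `marker`, `chrom`, `pos`. `write_genotypes()` writes both files from the
#' long genotype tibble; `read_genotypes()` reassembles it.
#'
#' @param genos Long genotype tibble (`line`, `marker`, `chrom`, `pos`,
#'   `geno`).
#' @param geno_path,marker_path The two file paths.
#' @return `read_genotypes()` returns the long tibble; the writer returns
#'   `geno_path` invisibly.
#' @export
write_genotypes <- function(genos, geno_path, marker_path) {
  assert_columns(genos, c("line", "marker", "chrom", "pos", "geno"), "genos")
  wide <- genos %>%
    select("line", "marker", "geno") %>%
    tidyr::pivot_wider(names_from = "marker", values_from = "geno")
  readr::write_tsv(wide, geno_path)
  readr::write_tsv(marker_map(genos) %>% arrange(.data$chrom, .data$pos),
                   marker_path)
  invisible(geno_path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(geno_path, marker_path) {
  wide <- readr::read_tsv(geno_path, col_types = readr::cols(
    line = readr::col_character(), .default = readr::col_character()
  ))
  map <- readr::read_tsv(marker_path, col_types = readr::cols(
    marker = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_integer()
  ))
  long <- wide %>%
    tidyr::pivot_longer(-"line", names_to = "marker", values_to = "geno")
  bad <- setdiff(unique(long$geno), c("A", "B", "H", "N"))
  if (length(bad) > 0) {
    abort(sprintf("invalid genotype code(s): %s", paste(bad, collapse = ", ")))
  }
  long %>%
    inner_join(map, by = "marker") %>%
    select("line", "marker", "chrom", "pos", "geno") %>%
    arrange(.data$chrom, .data$pos, .data$line)
}

#' Read / write bulk allele-depth tables
#'
#' The TSV form has columns `chrom`, `pos`, `ref_high`, `total_high`,
#' `ref_low`, `total_low`. The VCF form is a minimal two-sample VCF (samples
#' `HIGH` and `LOW`) carrying per-bulk allele depths in the `AD` FORMAT
#' field; `read_bulk_vcf()` accepts any VCF with exactly two samples with
#' `AD`, taking the first sample as the high bulk unless sample names
#' contain "high"/"low".
#'
#' @param counts Site-counts tibble.
#' @param path File path.
#' @return Readers return a site-counts tibble; writers return `path`
#'   invisibly.
#' @export
read_bulk_counts <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), .default = readr::col_double()
  ))
  assert_columns(x, c("chrom", "pos", "ref_high", "total_high",
                      "ref_low", "total_low"), "bulk counts")
  x
}

#' @rdname read_bulk_counts
#' @export
write_bulk_counts <- function(counts, path) {
  assert_columns(counts, c("chrom", "pos", "ref_high", "total_high",
                           "ref_low", "total_low"), "counts")
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname read_bulk_counts
#' @export
write_bulk_vcf <- function(counts, path) {
  assert_columns(counts, c("chrom", "pos", "ref_high", "total_high",
                           "ref_low", "total_low"), "counts")
  counts <- arrange(counts, .data$chrom, .data$pos)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sweetqtl",
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "HIGH", "LOW", sep = "\t")
  )
  body <- sprintf(
    "%s\t%d\t.\tA\tT\t.\tPASS\t.\tAD\t%d,%d\t%d,%d",
    counts$chrom, as.integer(counts$pos),
    as.integer(counts$ref_high), as.integer(counts$total_high - counts$ref_high),
    as.integer(counts$ref_low), as.integer(counts$total_low - counts$ref_low)
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname read_bulk_counts
#' @export
read_bulk_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (ncol(ad) != 2) abort("expected a two-sample (high, low) VCF")
  samples <- tolower(colnames(ad))
  hi <- if (any(grepl("high", samples))) which(grepl("high", samples)) else 1L
  lo <- setdiff(1:2, hi)
  split_ad <- function(col) {
    parts <- strsplit(col, ",", fixed = TRUE)
    ref <- as.integer(vapply(parts, `[`, character(1), 1))
    alt <- as.integer(vapply(parts, function(p) if (length(p) > 1) p[2] else "0",
                             character(1)))
    list(ref = ref, total = ref + alt)
  }
  h <- split_ad(ad[, hi])
  l <- split_ad(ad[, lo])
  tibble(
    chrom = as.character(v@fix[, "CHROM"]),
    pos = as.numeric(v@fix[, "POS"]),
    ref_high = h$ref, total_high = h$total,
    ref_low = l$ref, total_low = l$total
  )
}

#' Read / write a multi-study QTL table
#'
#' TSV with columns `study`, `trait`, `chrom`, `start`, `end`, `donor`.
#' Reading with validation against a coordinate system is done by
#' [load_qtl_table()].
#'
#' @param qtls QTL tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_qtl_table <- function(qtls, path) {
  assert_columns(qtls, c("study", "chrom", "start", "end"), "qtls")
  readr::write_tsv(select(qtls, any_of(c("study", "trait", "chrom", "start",
                                         "end", "donor"))), path)
  invisible(path)
}

#' Write a simulation-truth sidecar as JSON
#'
#' Serialises the ground-truth bookkeeping returned by the simulators
#' (planted QTLs, genetic values, noise scales) so that downstream
#' parameter-recovery checks can run from files alone.
#'
#' @param truth A list (e.g. the `truth` element of a
#'   [simulate_biparental()] result).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
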