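#' Melon-like default chromosome sizes
#'
#' A 12-chromosome genome of roughly 366 Mb, sized like the melon (DHL92)
#' reference assembly. Used as the default coordinate system by the
#' simulators; any analysis on real data should supply the sizes of the
#' assembly its coordinates refer to.
#'
#' @return A tibble with columns `chrom` (character) and `length` (integer
#'   base pairs).
#' @export
#' @examples
#' default_chrom_sizes()
default_chrom_sizes <- function() {
  tibble(
    chrom = sprintf("chr%02d", 1:12),
    length = as.integer(c(
      38.9, 26.3, 30.8, 34.1, 28.6, 36.4,
      26.9, 32.2, 27.3, 25.4, 31.9, 27.1
    ) * 1e6)
  )
}

validate_chrom_sizes <- function(chrom_sizes) {
  assert_columns(chrom_sizes, c("chrom", "length"), "chrom_sizes")
  if (anyDuplicated(chrom_sizes$chrom)) abort("duplicated chromosome names in chrom_sizes")
  if (any(!is.finite(chrom_sizes$length) | chrom_sizes$length <= 0)) {
    abort("chromosome lengths must be positive and finite")
  }
  chrom_sizes
}

#' Read / write a chromosome-sizes table
#'
#' Plain two-column TSV (`chrom`, `length`), the conventional "genome file"
#' format of bedtools and UCSC tools.
#'
#' @param path File path.
#' @param chrom_sizes A tibble with columns `chrom` and `length`.
#' @return `read_chrom_sizes()` returns a tibble; `write_chrom_sizes()`
#'   returns `path` invisibly.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = readr::cols(readr::col_character(), readr::col_double()),
                       comment = "#")
  validate_chrom_sizes(x)
}

#' @rdname read_chrom_sizes
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  validate_chrom_sizes(chrom_sizes)
  readr::write_tsv(chrom_sizes, path, col_names = FALSE)
  invisible(path)
}
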