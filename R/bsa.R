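#' Depth-filter bulk site counts
#'
#' Retains sites whose total read depth exceeds `min_depth` in *both* bulks
#' (the stricter per-bulk reading of a ">20 reads per site" rule, avoiding
#' one-sided noise). Site order is preserved.
#'
#' @param counts Site-counts tibble: `chrom`, `pos`, `ref_high`,
#'   `total_high`, `ref_low`, `total_low`.
#' @param min_depth Depth threshold; sites must have depth strictly greater
#'   than this in each bulk. Default 20.
#' @return The filtered tibble (possibly empty).
#' @export
filter_sites <- function(counts, min_depth = 20) {
  assert_columns(counts, c("chrom", "pos", "ref_high", "total_high",
                           "ref_low", "total_low"), "counts")
  bad <- with(counts, ref_high > total_high | ref_low > total_low |
                ref_high < 0 | ref_low < 0)
  if (any(bad, na.rm = TRUE)) abort("malformed counts: ref exceeds total or is negative")
  filter(counts, .data$total_high > min_depth, .data$total_low > min_depth)
}

#' Per-site SNP-index and delta SNP-index
#'
#' The SNP-index of a site within a bulk is the fraction of reads carrying
#' the reference allele; the delta SNP-index is high-bulk minus low-bulk.
#' Sites with zero depth in either bulk must be removed first (see
#' [filter_sites()]).
#'
#' @param counts Filtered site-counts tibble.
#' @return The input with added columns `idx_high`, `idx_low` (in `[0, 1]`)
#'   and `delta` (in `[-1, 1]`).
#' @export
compute_snp_index <- function(counts) {
  assert_columns(counts, c("chrom", "pos", "ref_high", "total_high",
                           "ref_low", "total_low"), "counts")
  if (any(counts$total_high == 0 | counts$total_low == 0)) {
    abort("zero-depth sites present; apply filter_sites() first")
  }
  counts %>%
    mutate(
      idx_high = .data$ref_high / .data$total_high,
      idx_low = .data$ref_low / .data$total_low,
      delta = .data$idx_high - .data$idx_low
    )
}

#' Sliding-window smoothing of a SNP-index track
#'
#' Tiles each chromosome with windows of `window_size` starting every `step`
#' bases (half-open internally: a window starting at `w` covers positions
#' `[w, w + window_size)`), and averages the site-level SNP-indexes of the
#' member sites. Windows containing no site carry `NA` values.
#'
#' @param track Site-level track from [compute_snp_index()].
#' @param window_size Window width in bp (default 1 Mb).
#' @param step Window start spacing in bp (default 100 kb).
#' @param chrom_sizes Optional chromosome-sizes tibble; when `NULL`, each
#'   chromosome extends to its last observed site.
#' @return A window tibble: `chrom`, `win_start`, `win_end` (1-based
#'   inclusive), `win_mid`, `idx_high`, `idx_low`, `delta`, `n_sites`.
#' @export
sliding_window <- function(track, window_size = 1e6, step = 1e5,
                           chrom_sizes = NULL) {
  assert_columns(track, c("chrom", "pos", "idx_high", "idx_low", "delta"), "track")
  if (window_size <= 0 || step <= 0) abort("window_size and step must be > 0")
  chroms <- if (is.null(chrom_sizes)) {
    track %>% group_by(.data$chrom) %>%
      summarise(length = max(.data$pos), .groups = "drop")
  } else {
    validate_chrom_sizes(chrom_sizes)
  }
  out <- purrr::map(seq_len(nrow(chroms)), function(ci) {
    chrom <- chroms$chrom[ci]
    len <- chroms$length[ci]
    starts <- seq(1, max(1, len), by = step)
    nwin <- length(starts)
    d <- filter(track, .data$chrom == !!chrom)
    sum_h <- sum_l <- sum_d <- nn <- numeric(nwin)
    if (nrow(d) > 0) {
      # a site at pos belongs to windows j with start in (pos - window, pos]
      j_hi <- pmin(nwin, (d$pos - 1) %/% step + 1)
      j_lo <- pmax(1, (d$pos - window_size) %/% step + 2)
      for (i in seq_len(nrow(d))) {
        j <- j_lo[i]:j_hi[i]
        sum_h[j] <- sum_h[j] + d$idx_high[i]
        sum_l[j] <- sum_l[j] + d$idx_low[i]
        sum_d[j] <- sum_d[j] + d$delta[i]
        nn[j] <- nn[j] + 1
      }
    }
    tibble(
      chrom = chrom,
      win_start = as.numeric(starts),
      win_end = pmin(starts + window_size - 1, len),
      win_mid = (starts + pmin(starts + window_size - 1, len)) / 2,
      idx_high = ifelse(nn > 0, sum_h / nn, NA_real_),
      idx_low = ifelse(nn > 0, sum_l / nn, NA_real_),
      delta = ifelse(nn > 0, sum_d / nn, NA_real_),
      n_sites = as.integer(nn)
    )
  })
  bind_rows(out)
}

#' Call QTL regions from a windowed delta SNP-index track
#'
#' Maximal runs of consecutive non-empty windows with `|delta| >= threshold`
#' and a consistent sign become candidate regions; same-sign runs separated
#' by at most `merge_gap` windows are merged. Region bounds are the
#' outermost window bounds, tightened to the span of the member sites when
#' site positions are available. The peak is the window with the largest
#' `|delta|` (leftmost on ties).
#'
#' @param windows Window tibble from [sliding_window()].
#' @param threshold Calling threshold on the windowed `|delta|`
#'   (default 0.4).
#' @param min_windows Minimum run length in windows (default 1).
#' @param merge_gap Maximum number of intervening below-threshold windows
#'   bridged between same-sign runs (default 2).
#' @param sites Optional site-level track used to clip region bounds to
#'   covered sites.
#' @return A region tibble: `chrom`, `start`, `end`, `peak_pos`,
#'   `peak_delta`, `sign` (`"high"` if the high bulk carries the reference
#'   excess, else `"low"`), `n_windows`.
#' @export
call_qtl_regions <- function(windows, threshold = 0.4, min_windows = 1,
                             merge_gap = 2, sites = NULL) {
  assert_columns(windows, c("chrom", "win_start", "win_end", "delta"), "windows")
  regions <- windows %>%
    group_by(.data$chrom) %>%
    arrange(.data$win_start, .by_group = TRUE) %>%
    group_modify(function(d, key) {
      hit <- !is.na(d$delta) & abs(d$delta) >= threshold
      sgn <- sign(d$delta)
      # run ids over hit windows, merging same-sign runs separated by a
      # short gap of non-hit windows
      run_id <- integer(nrow(d))
      cur <- 0L
      last_hit <- -Inf
      last_sign <- 0
      for (i in seq_len(nrow(d))) {
        if (!hit[i]) next
        if (sgn[i] == last_sign && (i - last_hit - 1) <= merge_gap) {
          run_id[i] <- cur
        } else {
          cur <- cur + 1L
          run_id[i] <- cur
        }
        last_hit <- i
        last_sign <- sgn[i]
      }
      if (cur == 0L) return(tibble())
      purrr::map_dfr(seq_len(cur), function(r) {
        idx <- which(run_id == r)
        if (length(idx) < min_windows) return(tibble())
        peak <- idx[which.max(abs(d$delta[idx]))]
        tibble(
          start = min(d$win_start[idx]),
          end = max(d$win_end[idx]),
          peak_pos = (d$win_start[peak] + d$win_end[peak]) / 2,
          peak_delta = d$delta[peak],
          sign = if (d$delta[peak] > 0) "high" else "low",
          n_windows = length(idx)
        )
      })
    }) %>%
    ungroup()
  if (nrow(regions) == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  peak_pos = double(), peak_delta = double(),
                  sign = character(), n_windows = integer()))
  }
  if (!is.null(sites)) {
    regions <- regions %>%
      rowwise() %>%
      mutate(
        start = {
          p <- sites$pos[sites$chrom == .data$chrom &
                           sites$pos >= .data$start & sites$pos <= .data$end]
          if (length(p) > 0) max(.data$start, min(p)) else .data$start
        },
        end = {
          p <- sites$pos[sites$chrom == .data$chrom &
                           sites$pos >= .data$start & sites$pos <= .data$end]
          if (length(p) > 0) min(.data$end, max(p)) else .data$end
        }
      ) %>%
      ungroup()
  }
  arrange(regions, .data$chrom, .data$start)
}

#' Whole-genome bulk-segregant scan
#'
#' Composes the full QTL-seq analysis: depth filtering, per-site SNP-index
#' and delta SNP-index, sliding-window smoothing, and threshold-based region
#' calling. Fully deterministic given its inputs.
#'
#' @inheritParams filter_sites
#' @inheritParams sliding_window
#' @inheritParams call_qtl_regions
#' @return An object of class `bsa_scan`: list with `sites` (filtered
#'   site-level track), `windows`, `regions`, and `params`.
#' @export
#' @examples
#' counts <- tibble::tibble(
#'   chrom = "chr01", pos = seq(1e5, 2e6, by = 1e5),
#'   ref_high = 28, total_high = 30, ref_low = 2, total_low = 30
#' )
#' sc <- bsa_scan(counts, chrom_sizes = NULL)
#' sc$regions
bsa_scan <- function(counts, min_depth = 20, window_size = 1e6, step = 1e5,
                     threshold = 0.4, min_windows = 1, merge_gap = 2,
                     chrom_sizes = NULL) {
  kept <- filter_sites(counts, min_depth)
  if (nrow(kept) == 0) {
    empty_sites <- mutate(kept, idx_high = double(0), idx_low = double(0),
                          delta = double(0))
    res <- list(
      sites = empty_sites,
      windows = tibble(chrom = character(), win_start = double(),
                       win_end = double(), win_mid = double(),
                       idx_high = double(), idx_low = double(),
                       delta = double(), n_sites = integer()),
      regions = call_qtl_regions(
        tibble(chrom = character(), win_start = double(),
               win_end = double(), delta = double()),
        threshold, min_windows, merge_gap
      )
    )
  } else {
    track <- compute_snp_index(kept)
    windows <- sliding_window(track, window_size, step, chrom_sizes)
    regions <- call_qtl_regions(windows, threshold, min_windows, merge_gap,
                                sites = track)
    res <- list(sites = track, windows = windows, regions = regions)
  }
  res$params <- list(min_depth = min_depth, window_size = window_size,
                     step = step, threshold = threshold,
                     min_windows = min_windows, merge_gap = merge_gap,
                     reference_allele = "high-parent (parent A) unless stated")
  structure(res, class = "bsa_scan")
}

#' @export
print.bsa_scan <- function(x, ...) {
  cat(sprintf(
    "bulk-segregant scan: %d sites kept, %d windows, %d region(s) at |delta| >= %.2f\n",
    nrow(x$sites), sum(!is.na(x$windows$delta)), nrow(x$regions),
    x$params$threshold
  ))
  if (nrow(x$regions) > 0) print(x$regions)
  invisible(x)
}
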