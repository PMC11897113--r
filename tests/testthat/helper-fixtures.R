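# Shared fixtures and independent oracles, built in code at test time.

# Small hand-built genotype table: `pattern` is a named list
# marker -> character vector of per-line codes.
make_genos <- function(lines, pattern, chrom = "chr01") {
  purrr::imap_dfr(pattern, function(codes, m) {
    tibble::tibble(
      line = lines,
      marker = m,
      chrom = chrom,
      pos = match(m, names(pattern)) * 1e6,
      geno = codes
    )
  })
}

make_pheno <- function(lines, values, trait = "TSS") {
  tibble::tibble(line = lines, genotype_class = "line", year = 1L, rep = 1L,
                 trait = trait, value = values)
}

# 20 parent values scaled so that exactly 90 of the 190 pairwise additive
# effects a = |vi - vj| / 2 exceed 2 (the differential-group construction).
diallel_parents_90of190 <- function() {
  set.seed(42)
  v <- rnorm(20, 10, 2)
  a <- combn(v, 2, function(x) abs(x[1] - x[2]) / 2)
  a_sorted <- sort(a, decreasing = TRUE)
  scale <- 2 / sqrt(a_sorted[90] * a_sorted[91])
  v <- mean(v) + (v - mean(v)) * scale
  names(v) <- sprintf("P%02d", 1:20)
  a <- combn(v, 2, function(x) abs(x[1] - x[2]) / 2)
  stopifnot(sum(a > 2) == 90)
  v
}

# --- independent oracles -----------------------------------------------------

# one-way variance components through stats::aov, as an independent route
oracle_variance_components <- function(df) {
  fit <- stats::aov(value ~ factor(line), data = df)
  ms <- anova(fit)[["Mean Sq"]]
  k <- length(unique(df$line))
  n_i <- table(df$line)
  r_bar <- k / sum(1 / as.numeric(n_i))
  var_g <- max((ms[1] - ms[2]) / r_bar, 0)
  list(var_g = var_g, var_e = ms[2], h2 = var_g / (var_g + ms[2]))
}

# Benjamini-Hochberg step-up by direct enumeration
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    q[i] <- min(vapply(rank_i:m, function(j) m * p[o[j]] / j, numeric(1)), 1)
  }
  q
}

# brute-force window means: filter sites per window explicitly
oracle_window_means <- function(track, window_size, step, chrom_len) {
  starts <- seq(1, chrom_len, by = step)
  purrr::map_dfr(starts, function(s) {
    member <- track$pos >= s & track$pos < s + window_size
    tibble::tibble(
      win_start = s,
      delta = if (any(member)) mean(track$delta[member]) else NA_real_,
      n_sites = sum(member)
    )
  })
}

# explicit two-way balanced ANOVA sums of squares for a 2x2 design
oracle_two_way_ss <- function(y, ga, gb) {
  grand <- mean(y)
  cell <- tapply(y, list(ga, gb), mean)
  nc <- tapply(y, list(ga, gb), length)
  ma <- tapply(y, ga, mean)
  mb <- tapply(y, gb, mean)
  na <- tapply(y, ga, length)
  nb <- tapply(y, gb, length)
  ss_a <- sum(na * (ma - grand)^2)
  ss_b <- sum(nb * (mb - grand)^2)
  ss_cells <- sum(nc * (cell - grand)^2)
  ss_int <- ss_cells - ss_a - ss_b
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_cells
  df_err <- length(y) - 4
  f_int <- (ss_int / 1) / (ss_err / df_err)
  list(ss_int = ss_int, f_int = f_int,
       p_int = stats::pf(f_int, 1, df_err, lower.tail = FALSE))
}
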