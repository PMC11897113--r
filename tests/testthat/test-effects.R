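sim_scan_fixture <- function(seed = 44, n_lines = 50, effect = 3, h2 = 0.7) {
  tr <- biparental_truth(
    n_lines = n_lines, generation = 6, n_markers = 40, h2 = h2,
    qtls = tibble::tibble(chrom = "chr03", pos = 15e6, effect = effect,
                          donor = "A")
  )
  simulate_biparental(tr, seed = seed)
}

test_that("a marker perfectly partitioning a noiseless phenotype tops the scan", {
  lines <- sprintf("L%02d", 1:20)
  genos <- make_genos(lines, list(
    m1 = rep(c("A", "B"), each = 10),
    m2 = rep(c("A", "B"), 10)
  ))
  ph <- make_pheno(lines, rep(c(14, 10), each = 10))
  sc <- marker_scan(genos, ph, "TSS", n_perm = 200, seed = 1)
  m1 <- dplyr::filter(sc, marker == "m1")
  expect_equal(m1$p, min(sc$p, na.rm = TRUE))
  expect_true(m1$pass_perm)
  expect_lt(m1$p, 1e-20)
})

test_that("scan p-values equal per-marker aov recomputation on small instances", {
  sim <- sim_scan_fixture()
  sc <- marker_scan(sim$genotypes, sim$phenotypes, "TSS", n_perm = 100,
                    seed = 2)
  ym <- sim$phenotypes %>%
    dplyr::group_by(line) %>%
    dplyr::summarise(y = mean(value))
  for (m in sample(sc$marker[!is.na(sc$p)], 8)) {
    g <- dplyr::filter(sim$genotypes, marker == m, geno %in% c("A", "B"))
    d <- dplyr::inner_join(g, ym, by = "line")
    want <- anova(stats::aov(y ~ factor(geno), data = d))[["Pr(>F)"]][1]
    expect_equal(dplyr::filter(sc, marker == m)$p, want, tolerance = 1e-9)
  }
})

test_that("BH q-values match the step-up enumeration oracle", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               oracle_bh(c(0.01, 0.02, 0.03, 0.04)))
  expect_true(all(oracle_bh(c(0.01, 0.02, 0.03, 0.04)) <= 0.05))
  for (s in 1:10) {
    set.seed(s)
    p <- runif(sample(3:20, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  # and the scan reports exactly these q-values
  sim <- sim_scan_fixture(seed = 45, n_lines = 30)
  sc <- marker_scan(sim$genotypes, sim$phenotypes, "TSS", n_perm = 100,
                    seed = 3)
  ok <- !is.na(sc$p)
  expect_equal(sc$q[ok], oracle_bh(sc$p[ok]), tolerance = 1e-12)
})

test_that("permutation threshold is seed-deterministic and monotone in alpha", {
  sim <- sim_scan_fixture(seed = 46, n_lines = 40)
  th <- vapply(c(0.01, 0.05, 0.10, 0.25), function(a) {
    attr(marker_scan(sim$genotypes, sim$phenotypes, "TSS", n_perm = 200,
                     alpha = a, seed = 7), "threshold")
  }, numeric(1))
  expect_true(all(diff(th) >= 0))
  s1 <- marker_scan(sim$genotypes, sim$phenotypes, "TSS", n_perm = 200,
                    seed = 7)
  s2 <- marker_scan(sim$genotypes, sim$phenotypes, "TSS", n_perm = 200,
                    seed = 7)
  expect_identical(attr(s1, "threshold"), attr(s2, "threshold"))
  expect_identical(s1$perm_p, s2$perm_p)
})

test_that("the permutation threshold holds its genome-wide type-I error", {
  sim <- sim_scan_fixture(seed = 47, n_lines = 40, effect = 3, h2 = 0.8)
  qm <- sim$truth$qtls$marker
  hits <- vapply(1:200, function(i) {
    ph <- sim$phenotypes
    set.seed(5000 + i)
    ph$value <- sample(ph$value)  # break the genotype-phenotype link
    sc <- marker_scan(sim$genotypes, ph, "TSS", n_perm = 100, alpha = 0.05,
                      seed = 6000 + i)
    dplyr::filter(sc, marker == qm)$pass_perm
  }, logical(1))
  # the once-linked marker should now pass in about alpha of scans
  expect_lt(mean(hits), 0.12)
})

test_that("allelic effects, PVE and their boundary cases are exact", {
  lines <- sprintf("L%02d", 1:8)
  genos <- make_genos(lines, list(m1 = rep(c("A", "B"), each = 4)))
  eff <- allelic_effect(genos, make_pheno(lines, rep(c(14, 10), each = 4)),
                        "TSS", "m1")
  expect_equal(eff$effect, 4)
  expect_equal(eff$pve, 100)

  flat <- allelic_effect(genos, make_pheno(lines, c(1, 2, 3, 4, 1, 2, 3, 4)),
                         "TSS", "m1")
  expect_equal(flat$effect, 0)
  expect_equal(flat$pve, 0)

  mono <- make_genos(lines, list(m1 = rep("A", 8)))
  expect_error(allelic_effect(mono, make_pheno(lines, 1:8), "TSS", "m1"),
               "homozygote classes")
})

test_that("planted QTL effects are recovered within sampling error", {
  est <- purrr::map_dfr(1:10, function(i) {
    sim <- sim_scan_fixture(seed = 400 + i, n_lines = 100, effect = 2,
                            h2 = 0.6)
    allelic_effect(sim$genotypes, sim$phenotypes, "TSS",
                   sim$truth$qtls$marker)
  })
  se_mean <- mean(est$se) / sqrt(nrow(est))
  expect_lt(abs(mean(est$effect) - 2), 2 * se_mean + 1e-8)
})

test_that("pair interactions separate additive from epistatic constructions", {
  lines <- sprintf("L%02d", 1:40)
  genos <- make_genos(lines, list(
    ma = rep(c("A", "B"), each = 20),
    mb = rep(rep(c("A", "B"), each = 10), 2)
  ))
  set.seed(9)
  cell <- list(AA = 3, AB = 2, BA = 1, BB = 0)
  y_add <- unlist(cell[paste0(rep(c("A", "B"), each = 20),
                              rep(rep(c("A", "B"), each = 10), 2))]) +
    rnorm(40, 0, 0.05)
  pi_add <- pair_interaction(genos, make_pheno(lines, y_add), "TSS",
                             "ma", "mb")
  expect_true(pi_add$complete)
  expect_lt(abs(pi_add$effects$interaction), 0.05)
  expect_gt(pi_add$effects$p_interaction, 0.2)

  cell_epi <- list(AA = 5, AB = 2, BA = 1, BB = 0)
  y_epi <- unlist(cell_epi[paste0(rep(c("A", "B"), each = 20),
                                  rep(rep(c("A", "B"), each = 10), 2))]) +
    rnorm(40, 0, 0.2)
  pi_epi <- pair_interaction(genos, make_pheno(lines, y_epi), "TSS",
                             "ma", "mb")
  expect_lt(pi_epi$effects$p_interaction, 0.05)
  # interaction p agrees with explicit sums-of-squares oracle
  keep <- tibble::tibble(ga = rep(c("A", "B"), each = 20),
                         gb = rep(rep(c("A", "B"), each = 10), 2), y = y_epi)
  want <- oracle_two_way_ss(keep$y, keep$ga, keep$gb)
  expect_equal(pi_epi$effects$p_interaction, want$p_int, tolerance = 1e-9)

  # all classes equal: a single shared Tukey letter
  pi_flat <- pair_interaction(genos, make_pheno(lines, rnorm(40, 5, 0.1)),
                              "TSS", "ma", "mb")
  expect_equal(length(unique(pi_flat$classes$letter)), 1)
})

test_that("an empty double-homozygote class is flagged, not dropped", {
  lines <- sprintf("L%02d", 1:12)
  genos <- make_genos(lines, list(
    ma = rep("A", 12),  # no B homozygote at ma x mb = (B, *)
    mb = rep(c("A", "B"), 6)
  ))
  res <- pair_interaction(genos, make_pheno(lines, rnorm(12)), "TSS",
                          "ma", "mb")
  expect_false(res$complete)
  expect_true(any(res$classes$n == 0))
  expect_true(is.na(res$effects$p_interaction))
})

test_that("stacking three additive QTLs recovers the summed gain exactly at zero noise", {
  tr <- biparental_truth(
    n_lines = 250, generation = 6, n_markers = 40, h2 = 1,
    qtls = tibble::tibble(chrom = c("chr03", "chr08", "chr11"),
                          pos = c(27e6, 10e6, 5e6),
                          effect = 1, donor = "A")
  )
  sim <- simulate_biparental(tr, seed = 52)
  mk <- sim$truth$qtls$marker
  fav <- stats::setNames(rep("A", 3), mk)
  st <- stack_analysis(sim$genotypes, sim$phenotypes, "TSS", mk, fav)
  expect_equal(st$contrast$gain, 3, tolerance = 1e-10)
  # purely additive truth: class means affine in the favorable-allele count
  bc <- dplyr::filter(st$by_count, n > 0)
  fit <- stats::lm(mean ~ n_favorable, data = bc)
  expect_gt(suppressWarnings(summary(fit))$r.squared, 0.99)
})

test_that("swapping the declared favorable alleles negates the stack contrast", {
  tr2 <- biparental_truth(
    n_lines = 120, generation = 6, n_markers = 40, h2 = 1,
    qtls = tibble::tibble(chrom = c("chr03", "chr08"), pos = c(15e6, 10e6),
                          effect = 2, donor = "A")
  )
  sim <- simulate_biparental(tr2, seed = 53)
  mk <- sim$truth$qtls$marker
  a <- stack_analysis(sim$genotypes, sim$phenotypes, "TSS", mk,
                      stats::setNames(c("A", "A"), mk))
  b <- stack_analysis(sim$genotypes, sim$phenotypes, "TSS", mk,
                      stats::setNames(c("B", "B"), mk))
  expect_equal(b$contrast$gain, -a$contrast$gain, tolerance = 1e-10)
  expect_error(stack_analysis(sim$genotypes, sim$phenotypes, "TSS", mk[1],
                              stats::setNames("A", mk[1])), ">= 2 markers")
})

test_that("expected-vs-observed regression recovers additivity and its breakdown", {
  set.seed(61)
  expected <- runif(40, 1, 5)
  add <- tibble::tibble(expected = expected,
                        observed = expected + rnorm(40, 0, 0.1))
  fit_add <- expected_vs_observed(add)
  expect_equal(fit_add$slope, 1, tolerance = 0.05)
  expect_gt(fit_add$p_slope_eq_1, 0.05)

  detected <- vapply(1:50, function(i) {
    set.seed(200 + i)
    e <- runif(40, 1, 5)
    d <- tibble::tibble(expected = e, observed = 0.7 * e + rnorm(40, 0, 0.3))
    f <- expected_vs_observed(d)
    f$slope < 1 && f$p_slope_eq_1 < 0.05
  }, logical(1))
  expect_gte(mean(detected), 0.90)

  expect_error(expected_vs_observed(add[1, ]), "3 complete")
  expect_error(expected_vs_observed(
    tibble::tibble(expected = rep(2, 5), observed = rnorm(5))
  ), "zero variance")
})

test_that("pair_effects composes singular effects into expected pair effects", {
  tr <- biparental_truth(
    n_lines = 200, generation = 6, n_markers = 30, h2 = 1,
    qtls = tibble::tibble(chrom = c("chr03", "chr08"), pos = c(15e6, 10e6),
                          effect = c(2, 1), donor = c("A", "B"))
  )
  sim <- simulate_biparental(tr, seed = 71)
  mk <- sim$truth$qtls$marker
  fav <- stats::setNames(c("A", "B"), mk)
  pe <- pair_effects(sim$genotypes, sim$phenotypes, "TSS",
                     tibble::tibble(marker_a = mk[1], marker_b = mk[2]), fav)
  expect_equal(pe$expected, 3, tolerance = 0.2)
  expect_equal(pe$observed, 3, tolerance = 0.2)
})
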