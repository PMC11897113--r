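test_that("heritability hits its boundary cases", {
  # replicates identical within genotype, genotypes differ -> h2 = 1
  ph <- make_pheno(rep(c("a", "b", "c"), each = 3), rep(c(1, 5, 9), each = 3))
  ph$rep <- rep(1:3, 3)
  est <- estimate_heritability(ph, "TSS")
  expect_equal(est$h2, 1)

  # genotype means identical, noisy replicates -> clamped to 0
  set.seed(1)
  noise <- rnorm(6)
  ph0 <- make_pheno(rep(c("a", "b"), each = 3),
                    c(5 + noise[1:3] - mean(noise[1:3]),
                      5 + noise[4:6] - mean(noise[4:6])))
  est0 <- estimate_heritability(ph0, "TSS")
  expect_equal(est0$h2, 0)
  expect_true(est0$clamped)

  expect_error(estimate_heritability(make_pheno("a", 1), "TSS"), "2 genotypes")
  expect_error(
    estimate_heritability(make_pheno(c("a", "b"), c(1, 2)), "TSS"),
    "replicates"
  )
  expect_error(
    estimate_heritability(make_pheno(rep(c("a", "b"), 2), rep(3, 4)), "TSS"),
    "var_p"
  )
})

test_that("variance components agree with an aov-based oracle on unbalanced data", {
  for (s in 1:8) {
    set.seed(s)
    k <- sample(3:10, 1)
    df <- purrr::map_dfr(seq_len(k), function(i) {
      n_i <- sample(2:5, 1)
      tibble::tibble(line = sprintf("g%02d", i),
                     value = rnorm(n_i, mean = i, sd = 1))
    })
    df$trait <- "TSS"
    got <- estimate_heritability(df, "TSS")
    want <- oracle_variance_components(df)
    expect_equal(got$var_g, want$var_g, tolerance = 1e-12)
    expect_equal(got$var_e, want$var_e, tolerance = 1e-12)
    expect_equal(got$h2, want$h2, tolerance = 1e-12)
  }
})

test_that("per-experiment grouping produces one estimate per year", {
  truth <- diallel_truth(c(A = 5, B = 9, C = 13), env_sd = 1,
                         n_years = 3, n_reps = 3)
  ph <- simulate_diallel(truth, seed = 12)
  est <- estimate_heritability(ph, "TSS", by = "year")
  expect_equal(nrow(est), 3)
  expect_true(all(est$h2 >= 0 & est$h2 <= 1))
})

test_that("the diallel matrix is symmetric, GCA-sorted, and order-invariant", {
  set.seed(2)
  vals <- stats::setNames(c(2, 8, 14), c("P1", "P2", "P3"))
  truth <- diallel_truth(vals, env_sd = 0)
  ph <- simulate_diallel(truth, seed = 1)
  dm <- build_diallel_matrix(ph, diallel_design(truth))
  expect_identical(dm$gca$parent, c("P1", "P2", "P3"))  # monotone construction
  expect_true(isSymmetric(dm$matrix))
  expect_true(all(diff(dm$gca$gca) > 0))

  shuffled <- ph[sample(nrow(ph)), ]
  dm2 <- build_diallel_matrix(shuffled, diallel_design(truth))
  expect_identical(dm$matrix, dm2$matrix)

  bad_design <- tibble::tibble(line = "x", parent1 = "P9", parent2 = "P1")
  expect_error(build_diallel_matrix(ph, bad_design), "absent")
})

test_that("a 20-parent diallel yields 190 F1 cells per triangle", {
  vals <- stats::setNames(rnorm(20, 10, 2), sprintf("P%02d", 1:20))
  truth <- diallel_truth(vals, env_sd = 0)
  ph <- simulate_diallel(truth, seed = 3)
  dm <- build_diallel_matrix(ph, diallel_design(truth))
  off <- dm$matrix[upper.tri(dm$matrix)]
  expect_equal(length(off), 190)
  expect_true(all(is.finite(off)))
  expect_equal(nrow(hybrid_groups(ph, diallel_design(truth))), 190)
})

test_that("mode-of-inheritance arithmetic matches its definitions", {
  # sweet x non-sweet parental pair: 15.2 and 4.9 Brix
  g <- hybrid_group_stats(tibble::tibble(
    p1_mean = 15.2, p2_mean = 4.9, f1_mean = 12.0
  ))
  expect_equal(g$mid_parent, 10.05)
  expect_equal(g$a, 5.15)

  # complete additivity: F1 at mid-parent
  g0 <- hybrid_group_stats(tibble::tibble(p1_mean = 4, p2_mean = 10,
                                          f1_mean = 7))
  expect_equal(g0$d, 0)
  expect_equal(g0$degree, 0)

  # complete dominance: F1 at the high parent
  g1 <- hybrid_group_stats(tibble::tibble(p1_mean = 4, p2_mean = 10,
                                          f1_mean = 10))
  expect_equal(g1$degree, 1)

  # label swap leaves a and the d sign convention untouched
  gs <- hybrid_group_stats(tibble::tibble(p1_mean = 10, p2_mean = 4,
                                          f1_mean = 9))
  gs2 <- hybrid_group_stats(tibble::tibble(p1_mean = 4, p2_mean = 10,
                                           f1_mean = 9))
  expect_equal(gs$a, gs2$a)
  expect_equal(gs$d, gs2$d)

  # equal parents: degree undefined, not an error
  ge <- hybrid_group_stats(tibble::tibble(p1_mean = 5, p2_mean = 5,
                                          f1_mean = 6))
  expect_true(is.na(ge$degree))
})

test_that("dominance distribution selects differential groups and tests d against zero", {
  vals <- diallel_parents_90of190()
  truth <- diallel_truth(vals, env_sd = 0)
  ph <- simulate_diallel(truth, seed = 2)
  groups <- hybrid_group_stats(hybrid_groups(ph, diallel_design(truth)))
  dd <- dominance_distribution(groups, a_min = 2)
  expect_equal(dd$n_selected, 90)
  expect_equal(dd$mean_d, 0)
  expect_equal(dd$mean_abs_degree, 0)
  expect_error(dominance_distribution(groups, a_min = 1e6), "retained")
})

test_that("the t-test on mean d holds its nominal size under a null dominance draw", {
  rejections <- vapply(1:200, function(i) {
    set.seed(i)
    d <- rnorm(1000)
    groups <- tibble::tibble(p1_mean = 0, p2_mean = 10, f1_mean = 5 + d)
    dominance_distribution(groups, a_min = 2)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(!rejections), 0.90)
})

test_that("mid-parent/F1 correlation behaves at its limits", {
  vals <- stats::setNames(c(2, 6, 10, 14), LETTERS[1:4])
  truth <- diallel_truth(vals, env_sd = 0)
  ph <- simulate_diallel(truth, seed = 1)
  groups <- hybrid_groups(ph, diallel_design(truth))
  expect_equal(midparent_f1_correlation(groups)$r, 1)

  flat <- dplyr::mutate(groups, f1_mean = 7)
  expect_error(midparent_f1_correlation(flat), "zero variance")
})

test_that("mid-parent/F1 correlation decays monotonically with plot noise", {
  vals <- stats::setNames(rnorm(20, 10, 2), sprintf("P%02d", 1:20))
  r_at <- vapply(c(0, 0.5, 2, 8), function(sdv) {
    truth <- diallel_truth(vals, env_sd = sdv, n_reps = 2)
    ph <- simulate_diallel(truth, seed = 40)
    midparent_f1_correlation(hybrid_groups(ph, diallel_design(truth)))$r
  }, numeric(1))
  expect_equal(r_at[1], 1)
  expect_true(all(diff(r_at) < 0))
})

test_that("trait correlations are computed on genotype means with the right sign", {
  lines <- sprintf("L%02d", 1:50)
  set.seed(5)
  x <- rnorm(50, 10, 2)
  ph <- dplyr::bind_rows(
    make_pheno(lines, x, trait = "TSS"),
    make_pheno(lines, x, trait = "AFW")
  )
  same <- trait_correlation(ph, "TSS", "AFW")
  expect_equal(same$r, 1)
  expect_equal(same$r2, 1)

  ph_neg <- dplyr::bind_rows(
    make_pheno(lines, x, trait = "TSS"),
    make_pheno(lines, -x + rnorm(50, 0, 0.5), trait = "AFW")
  )
  expect_lt(trait_correlation(ph_neg, "TSS", "AFW")$r, 0)

  null_small <- vapply(1:40, function(i) {
    set.seed(1000 + i)
    ph0 <- dplyr::bind_rows(
      make_pheno(sprintf("L%03d", 1:200), rnorm(200), trait = "TSS"),
      make_pheno(sprintf("L%03d", 1:200), rnorm(200), trait = "AFW")
    )
    abs(trait_correlation(ph0, "TSS", "AFW")$r) < 0.2
  }, logical(1))
  expect_gte(mean(null_small), 0.95)

  expect_error(
    trait_correlation(dplyr::filter(ph, line %in% c("L01", "L02")),
                      "TSS", "AFW"),
    "3 paired"
  )
})
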