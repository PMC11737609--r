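test_that("design enumerates the half diallel correctly", {
  d <- make_design(21, n_env = 2, n_rep = 2)
  expect_equal(nrow(d$crosses), 210)
  expect_equal(length(unique(d$crosses$entry)), 210)
  # no selfs, no reciprocals: parent1 strictly before parent2
  expect_true(all(match(d$crosses$parent1, d$parents) <
                    match(d$crosses$parent2, d$parents)))
  expect_equal(nrow(make_design(4)$crosses), 6)
  d5 <- make_design(5, n_env = 1, n_rep = 2)
  expect_equal(nrow(d5$crosses), 10)
  g5 <- simulate_genetics(d5, 1, 1, seed = 1)
  expect_equal(nrow(simulate_trial(d5, g5, seed = 1)), 20)
  expect_error(make_design(3), "at least 4")
  expect_error(make_design(5, n_env = 0), "n_env")
  expect_error(make_design(5, n_rep = 1), "n_rep")
})

test_that("a 21-parent 2-env 2-rep trial has 840 experimental plots", {
  d <- make_design(21, n_env = 2, n_rep = 2,
                   checks = c("CHK1", "CHK2"))
  g <- simulate_genetics(d, 0.22, 0.27, seed = 1)
  pl <- simulate_trial(d, g, seed = 1)
  expect_equal(sum(!pl$is_check), 840)
  expect_equal(sum(pl$is_check), 2 * 2 * 2)
  # every cross appears exactly once per replicate per environment
  counts <- table(pl$entry[!pl$is_check], pl$env[!pl$is_check],
                  pl$rep[!pl$is_check])
  expect_true(all(counts == 1))
})

test_that("simulated effects satisfy the method-4 constraints exactly", {
  for (seed in 1:5) {
    d <- make_design(4 + seed, n_env = 2, n_rep = 2)
    g <- simulate_genetics(d, var_gca = 0.8, var_sca = 1.3, var_env = 0.5,
                           var_gca_env = 0.3, var_sca_env = 0.4, seed = seed)
    expect_lt(abs(sum(g$gca)), 1e-10)
    expect_lt(abs(sum(g$sca)), 1e-10)
    cr <- d$crosses
    for (pp in d$parents) {
      in_p <- cr$entry[cr$parent1 == pp | cr$parent2 == pp]
      expect_lt(abs(sum(g$sca[in_p])), 1e-10)
    }
    for (k in seq_along(d$environments)) {
      expect_lt(abs(sum(g$gca_env[, k])), 1e-10)
      expect_lt(abs(sum(g$sca_env[, k])), 1e-10)
    }
  }
})

test_that("degenerate variances give exactly zero effects and flat trials", {
  d <- make_design(6)
  g <- simulate_genetics(d, var_gca = 0, var_sca = 0, var_error = 0,
                         mu = 5, seed = 3)
  expect_true(all(g$gca == 0))
  expect_true(all(g$sca == 0))
  pl <- simulate_trial(d, g, seed = 3, var_block = 0, var_rep = 0)
  expect_true(all(pl$trait[!pl$is_check] == 5))
})

test_that("ordinal traits are recorded as integers clamped to 1-9", {
  d <- make_design(6)
  g <- simulate_genetics(d, 0.5, 0.5, var_error = 4, mu = 5,
                         type = "ordinal", seed = 2)
  pl <- simulate_trial(d, list(FD1 = g), seed = 2)
  expect_true(all(pl$FD1 == round(pl$FD1)))
  expect_true(all(pl$FD1 >= 1 & pl$FD1 <= 9))
  # latent value far above the scale is clamped to 9
  g9 <- simulate_genetics(d, 0, 0, var_error = 0, mu = 12.3,
                          type = "ordinal", seed = 2)
  pl9 <- simulate_trial(d, g9, seed = 2, var_block = 0, var_rep = 0)
  expect_true(all(pl9$trait == 9))
})

test_that("single-environment genetics carry no interaction terms", {
  d <- make_design(6, n_env = 1, n_rep = 2)
  g <- simulate_genetics(d, 1, 1, var_gca_env = 0.5, var_sca_env = 0.5,
                         seed = 4)
  expect_true(all(g$gca_env == 0))
  expect_true(all(g$sca_env == 0))
})

test_that("identical seeds reproduce identical genetics and trials", {
  d <- make_design(7, checks = "CHK")
  g1 <- simulate_genetics(d, 1, 0.5, var_env = 1, var_gca_env = 0.2,
                          var_sca_env = 0.2, seed = 42)
  g2 <- simulate_genetics(d, 1, 0.5, var_env = 1, var_gca_env = 0.2,
                          var_sca_env = 0.2, seed = 42)
  expect_identical(g1, g2)
  expect_identical(simulate_trial(d, g1, seed = 9),
                   simulate_trial(d, g2, seed = 9))
  g3 <- simulate_genetics(d, 1, 0.5, seed = 43)
  expect_false(identical(g1$gca, g3$gca))
})

test_that("negative variances are rejected", {
  d <- make_design(5)
  expect_error(simulate_genetics(d, -0.1, 0.5, seed = 1), ">= 0")
})

test_that("sample variance of drawn GCA effects tracks the nominal value", {
  d <- make_design(21, n_env = 2, n_rep = 2)
  v <- vapply(1:500, function(s)
    var(simulate_genetics(d, var_gca = 0.22, var_sca = 0.27,
                          seed = s)$gca),
    numeric(1))
  expect_lt(abs(mean(v) - 0.22), 0.1 * 0.22)
})

test_that("marker generator honours its own constraints", {
  mk <- simulate_markers(10, n_snps = 200, missing_rate = 0, seed = 1)
  expect_false(anyNA(mk$geno))
  expect_true(all(mk$geno %in% c(0, 2)))

  mk0 <- simulate_markers(10, n_snps = 100, n_causal = 0, seed = 1)
  expect_true(all(mk0$parent_values == 0))

  # generator-filter consistency at the QC thresholds
  mk21 <- simulate_markers(21, n_snps = 2000, maf_range = c(0.05, 0.5),
                           missing_rate = 0.02, seed = 7)
  kept <- filter_markers(mk21, maf_min = 0.05, max_missing = 0.10)
  expect_equal(ncol(kept$geno), 2000)
  expect_equal(attr(kept, "n_dropped"), 0)

  mk10 <- simulate_markers(21, n_snps = 500, maf_range = c(0.10, 0.5),
                           missing_rate = 0.02, seed = 8)
  expect_equal(ncol(filter_markers(mk10)$geno), 500)
})
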