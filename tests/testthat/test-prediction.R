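manual_marker_matrix <- function(geno) {
  structure(list(
    geno = geno,
    map = data.frame(snp = colnames(geno), chrom = "1",
                     pos = seq_len(ncol(geno)), alleles = "A/B",
                     stringsAsFactors = FALSE),
    causal = data.frame(snp = character(0), effect = numeric(0)),
    parent_values = setNames(rep(0, nrow(geno)), rownames(geno))),
    class = "marker_matrix")
}

test_that("marker QC applies strict thresholds and mean imputation", {
  g <- matrix(2, nrow = 20, ncol = 4,
              dimnames = list(sprintf("P%02d", 1:20), paste0("S", 1:4)))
  g[1, 1] <- 0            # MAF exactly 0.05 -> removed (strict >)
  # S2 monomorphic -> removed
  g[1:6, 3] <- 0          # MAF 0.30, kept
  g[1:2, 4] <- NA; g[3:8, 4] <- 0  # missing 0.10 exactly -> removed
  mk <- manual_marker_matrix(g)
  kept <- filter_markers(mk, maf_min = 0.05, max_missing = 0.10)
  expect_equal(colnames(kept$geno), "S3")
  expect_equal(attr(kept, "n_dropped"), 3)

  g[1, 4] <- 0  # now missing 0.05 < 0.10, MAF 7/18 -> kept and imputed
  kept2 <- filter_markers(manual_marker_matrix(g))
  expect_true("S4" %in% colnames(kept2$geno))
  expect_false(anyNA(kept2$geno))
  obs_mean <- mean(g[!is.na(g[, 4]), 4])
  expect_equal(unname(kept2$geno["P02", "S4"]), obs_mean)
  expect_error(filter_markers(manual_marker_matrix(
    matrix(2, 4, 2, dimnames = list(paste0("P", 1:4), c("a", "b"))))),
    "no SNPs survive")
})

test_that("hybrid genotypes are parental means", {
  d <- make_design(4)
  g <- matrix(c(0, 2, 0, 2,
                2, 2, 0, 0,
                0, 0, 2, 2), nrow = 4,
              dimnames = list(d$parents, paste0("S", 1:3)))
  H <- hybrid_genotypes(manual_marker_matrix(g), d)
  expect_equal(nrow(H), 6)
  expect_equal(unname(H["P01/P02", ]), c(1, 2, 0))
  expect_equal(unname(H["P01/P04", ]), c(1, 1, 1))
})

test_that("GCA-LOO prediction is exact in the purely additive limit", {
  d <- make_design(8)
  g <- simulate_genetics(d, var_gca = 1, var_sca = 0, seed = 4)
  y <- model_entry_means(d, g)
  rep <- loo_gca_predict(y, d)
  expect_equal(rep$r, 1.0, tolerance = 1e-9)
  expect_equal(rep$n, nrow(d$crosses))
  # shift invariance
  rep2 <- loo_gca_predict(y + 100, d)
  expect_equal(rep2$r, rep$r, tolerance = 1e-9)
})

test_that("GCA-LOO equals a brute-force refit per deletion", {
  d <- make_design(6)
  g <- simulate_genetics(d, 1, 0.6, seed = 7)
  y <- model_entry_means(d, g, error_sd = 0.4, seed = 8)
  rep <- loo_gca_predict(y, d)
  for (i in c(1, 5, 12)) {
    ent <- d$crosses$entry[i]
    ca <- griffing_effects(y[setdiff(names(y), ent)], d)
    manual <- ca$mu + ca$gca[[d$crosses$parent1[i]]] +
      ca$gca[[d$crosses$parent2[i]]]
    expect_equal(rep$table$predicted[i], manual, tolerance = 1e-9)
  }
})

test_that("GCA-LOO flags predictions left without parental information", {
  d <- make_design(5)
  g <- simulate_genetics(d, 1, 0, seed = 9)
  y <- model_entry_means(d, g)
  # keep P05 in only two crosses; deleting one leaves a single cross
  y_sub <- y[!(names(y) %in% c("P01/P05", "P02/P05"))]
  rep <- loo_gca_predict(y_sub, d)
  left <- rep$table$predicted[rep$table$entry %in% c("P03/P05", "P04/P05")]
  expect_true(all(is.na(left)))
  expect_equal(rep$n, sum(!is.na(rep$table$predicted)))
})

test_that("the VanRaden GRM has the expected structure", {
  d <- make_design(4)
  mk <- simulate_markers(4, n_snps = 300, seed = 3)
  K <- grm(filter_markers(mk)$geno)
  expect_equal(unclass(K), t(unclass(K)), tolerance = 1e-12)
  # identical rows -> off-diagonal equals the diagonal (duplicating a row
  # fixes some SNPs, hence the zero-variance exclusions)
  g2 <- mk$geno
  g2[2, ] <- g2[1, ]
  K2 <- suppressWarnings(grm(g2))
  expect_equal(K2[1, 2], K2[1, 1], tolerance = 1e-12)
  # single SNP, opposite homozygotes -> negative relationship
  g3 <- matrix(c(0, 2), 2, 1, dimnames = list(c("A", "B"), "S1"))
  expect_lt(grm(g3)["A", "B"], 0)
  # zero-variance SNPs excluded with a warning
  g4 <- cbind(g2, S999 = rep(2, 4))
  expect_warning(grm(g4), "zero-variance")
})

test_that("GBLUP folds partition the hybrids exactly once", {
  d <- make_design(9)
  mk <- simulate_markers(9, n_snps = 400, n_causal = 40, seed = 5)
  H <- hybrid_genotypes(filter_markers(mk), d)
  K <- grm(H)
  y <- setNames(rnorm(nrow(H)), rownames(H))
  rep <- gblup_cv(y, K, k_folds = 5, seed = 3)
  expect_equal(sort(rep$table$entry), sort(rownames(H)))
  expect_equal(sum(table(rep$table$entry) == 1), nrow(H))
  expect_equal(sort(unique(rep$table$fold)), 1:5)
  # determinism
  rep2 <- gblup_cv(y, K, k_folds = 5, seed = 3)
  expect_identical(rep$table, rep2$table)
  expect_identical(rep$r, rep2$r)
  rep3 <- gblup_cv(y, K, k_folds = 5, seed = 4)
  expect_false(identical(rep$table$fold, rep3$table$fold))
})

test_that("GBLUP is accurate at heritability one and linear in y", {
  d <- make_design(15)
  mk <- simulate_markers(15, n_snps = 600, n_causal = 80, seed = 6)
  flt <- filter_markers(mk)
  H <- hybrid_genotypes(flt, d)
  K <- grm(H)
  # all signal in the markers, no noise
  eff <- setNames(flt$causal$effect, flt$causal$snp)
  y <- drop(H[, names(eff)] %*% eff)
  y <- setNames(y - mean(y) + 5, rownames(H))
  rep <- gblup_cv(y, K, k_folds = 5, seed = 1)
  expect_gt(rep$r, 0.95)

  rep_2y <- gblup_cv(2 * y, K, k_folds = 5, seed = 1)
  expect_equal(rep_2y$table$predicted - mean(rep_2y$table$predicted),
               2 * (rep$table$predicted - mean(rep$table$predicted)),
               tolerance = 1e-4)
})

test_that("GBLUP accuracy is near zero on pure-noise phenotypes", {
  d <- make_design(10)
  mk <- simulate_markers(10, n_snps = 400, n_causal = 0, seed = 8)
  K <- grm(hybrid_genotypes(filter_markers(mk), d))
  set.seed(21)
  rs <- vapply(1:30, function(s) {
    y <- setNames(rnorm(nrow(d$crosses)), d$crosses$entry)
    gblup_cv(y, K, k_folds = 5, seed = s)$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)) + 0.05)
})
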