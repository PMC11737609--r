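test_that("equal cross means give zero effects", {
  d <- make_design(4)
  ca <- griffing_effects(setNames(rep(10, 6), d$crosses$entry), d)
  expect_equal(ca$mu, 10)
  expect_true(all(ca$gca == 0))
  expect_true(all(ca$sca == 0))
})

test_that("closed forms agree with an independent constrained LS oracle", {
  for (p in 4:8) {
    d <- make_design(p)
    set.seed(p)
    g <- simulate_genetics(d, 1, 0.6, seed = p)
    y <- model_entry_means(d, g, error_sd = 0.5, seed = p + 100)
    ca <- griffing_effects(y, d)
    oracle <- lm_griffing_oracle(y, d)
    expect_equal(ca$mu, oracle$mu, tolerance = 1e-8)
    expect_equal(ca$gca, oracle$gca, tolerance = 1e-8)
    # zero-sum and reconstruction identities
    expect_lt(abs(sum(ca$gca)), 1e-10)
    expect_lt(max(abs(sca_parent_sums(ca))), 1e-10)
    recon <- ca$mu + ca$gca[d$crosses$parent1] + ca$gca[d$crosses$parent2] +
      ca$sca[d$crosses$entry]
    expect_equal(unname(recon), unname(y[d$crosses$entry]),
                 tolerance = 1e-10)
  }
})

test_that("the unbalanced path agrees with the oracle on missing crosses", {
  d <- make_design(7)
  g <- simulate_genetics(d, 1, 0.5, seed = 2)
  y <- model_entry_means(d, g, error_sd = 0.3, seed = 5)
  y_sub <- y[-c(3, 8, 14)]
  ca <- griffing_effects(y_sub, d)
  expect_false(ca$balanced)
  cr <- d$crosses[match(names(y_sub), d$crosses$entry), ]
  oracle <- lm_griffing_oracle(y_sub, d)
  expect_equal(ca$mu, oracle$mu, tolerance = 1e-8)
  expect_equal(ca$gca, oracle$gca, tolerance = 1e-8)
})

test_that("a parent seen in fewer than 2 crosses is flagged inestimable", {
  d <- make_design(5)
  g <- simulate_genetics(d, 1, 0.5, seed = 3)
  y <- model_entry_means(d, g)
  keep <- !grepl("P05", names(y))
  y_sub <- c(y[keep], y["P04/P05"])  # P05 appears once
  expect_warning(ca <- griffing_effects(y_sub, d), "inestimable")
  expect_true("P05" %in% ca$inestimable)
  expect_true(is.na(ca$gca[["P05"]]))
  expect_false(anyNA(ca$gca[setdiff(d$parents, "P05")]))
})

test_that("ANOVA df follow the method-4 identities for p = 21, e = 2", {
  d <- make_design(21, n_env = 2, n_rep = 2)
  g <- simulate_genetics(d, 0.22, 0.27, var_env = 0.6, var_gca_env = 0.17,
                         var_sca_env = 0.39, var_error = 1.29, seed = 1)
  pl <- simulate_trial(d, list(GY = g), seed = 1)
  M <- entry_mean_matrix(pl, "GY", d, method = "raw")
  pe <- pooled_error(pl, "GY")
  an <- diallel_anova(M, d, 2, ms_error = pe$ms, df_error = pe$df)
  df <- setNames(an$df, an$source)
  expect_equal(df[["Hybrids"]], 209)
  expect_equal(df[["GCA"]], 20)
  expect_equal(df[["SCA"]], 189)
  expect_equal(df[["HxE"]], 209)
  expect_equal(df[["GCAxE"]], 20)
  expect_equal(df[["SCAxE"]], 189)
  expect_equal(an$denominator[an$source == "GCA"], "GCAxE")
  expect_equal(an$denominator[an$source == "SCA"], "SCAxE")
  expect_equal(an$denominator[an$source == "Hybrids"], "HxE")
})

test_that("sums of squares partition: Hybrids = GCA + SCA, HxE = GCAxE + SCAxE", {
  d <- make_design(8, n_env = 2, n_rep = 2)
  g <- simulate_genetics(d, 1, 0.8, var_env = 0.5, var_gca_env = 0.2,
                         var_sca_env = 0.3, seed = 6)
  pl <- simulate_trial(d, list(GY = g), seed = 6)
  M <- entry_mean_matrix(pl, "GY", d, method = "raw")
  an <- diallel_anova(M, d, 2, ms_error = 1, df_error = 10)
  ss <- setNames(an$ss, an$source)
  expect_equal(ss[["Hybrids"]], ss[["GCA"]] + ss[["SCA"]], tolerance = 1e-8)
  expect_equal(ss[["HxE"]], ss[["GCAxE"]] + ss[["SCAxE"]], tolerance = 1e-8)
})

test_that("variance components reproduce the reference reconstruction", {
  an_ph <- reference_anova("PH")
  vc_ph <- variance_components(an_ph, sigma2_e = 109.31)
  expect_equal(round(vc_ph$sigma2_gca, 2), 95.77)
  expect_equal(round(vc_ph$sigma2_sca, 2), 80.88)
  expect_equal(round(vc_ph$sigma2_gca_env, 2), 5.80)
  expect_equal(round(vc_ph$sigma2_p, 2), 381.72)

  an_ad <- reference_anova("AD")
  vc_ad <- variance_components(an_ad)
  expect_equal(round(vc_ad$sigma2_gca, 2), 1.29)
  expect_equal(round(vc_ad$sigma2_a, 2), 2.58)

  # negative SCA solution is clamped (MS_SCA < MS_SCAxE)
  vc_fd1 <- variance_components(reference_anova("FD1"))
  expect_equal(vc_fd1$sigma2_sca, 0)
  expect_true("sigma2_sca" %in% vc_fd1$clamped)
})

test_that("equal mean squares give all-zero components", {
  tab <- reference_anova("GY")
  tab$ms[] <- 2
  vc <- variance_components(tab)
  expect_equal(vc$sigma2_gca, 0)
  expect_equal(vc$sigma2_sca, 0)
  expect_equal(vc$sigma2_gca_env, 0)
  expect_equal(vc$sigma2_sca_env, 0)
})

test_that("Baker ratio and GCA-SCA ratio follow the component definitions", {
  rt_ad <- genetic_ratios(variance_components(reference_anova("AD")),
                          reference_anova("AD"))
  expect_equal(round(rt_ad$baker_ratio, 2), 0.87)
  rt_gy <- genetic_ratios(variance_components(reference_anova("GY")),
                          reference_anova("GY"))
  expect_equal(round(rt_gy$baker_ratio, 2), 0.62)
  # sigma2_sca = 0: Baker ratio 1, GCA-SCA ratio undefined
  rt_fd1 <- genetic_ratios(variance_components(reference_anova("FD1")),
                           reference_anova("FD1"))
  expect_equal(rt_fd1$baker_ratio, 1)
  expect_true(is.na(rt_fd1$gca_sca_ratio))
})

test_that("entry-mean heritability lies in [0,1] and matches the formula", {
  an <- reference_anova("AD")
  rt <- genetic_ratios(variance_components(an), an)
  ms <- setNames(an$ms, an$source)
  s2g <- (ms[["Hybrids"]] - ms[["HxE"]]) / 4
  s2ge <- (ms[["HxE"]] - ms[["Error"]]) / 2
  h2 <- s2g / (s2g + s2ge / 2 + ms[["Error"]] / 4)
  expect_equal(rt$heritability, unname(h2))
  for (tr in c("FD1", "GY", "PH")) {
    a <- reference_anova(tr)
    h <- genetic_ratios(variance_components(a), a)$heritability
    expect_gte(h, 0); expect_lte(h, 1)
  }
})

test_that("effect t-tests behave under scaling and at zero", {
  d <- make_design(6, n_env = 1, n_rep = 2)
  y <- setNames(rep(4, nrow(d$crosses)), d$crosses$entry)
  ca <- griffing_effects(y, d)
  an <- diallel_anova(cbind(E1 = y), d, 2, ms_error = 1.6, df_error = 30)
  tt <- effect_tests(ca, an)
  expect_true(all(tt$gca_tests$t == 0))
  expect_true(all(tt$gca_tests$p == 1))

  # doubling the error MS scales every SE by sqrt(2)
  an2 <- diallel_anova(cbind(E1 = y), d, 2, ms_error = 3.2, df_error = 30)
  tt2 <- effect_tests(ca, an2)
  expect_equal(tt2$gca_tests$se, sqrt(2) * tt$gca_tests$se)
  expect_equal(tt2$sca_tests$se, sqrt(2) * tt$sca_tests$se)
})

test_that("effect t-tests are calibrated on null data", {
  # no genetic signal: rejection rate of GCA effects at 5% stays nominal
  d <- make_design(8, n_env = 2, n_rep = 2)
  set.seed(99)
  rej <- 0; n_eff <- 0
  for (s in 1:80) {
    g <- simulate_genetics(d, 0, 0, var_error = 1, seed = s)
    pl <- simulate_trial(d, list(GY = g), seed = s + 2000,
                         var_block = 0, var_rep = 0)
    M <- entry_mean_matrix(pl, "GY", d, method = "raw")
    pe <- pooled_error(pl, "GY")
    an <- diallel_anova(M, d, 2, ms_error = pe$ms, df_error = pe$df)
    tt <- effect_tests(griffing_effects(rowMeans(M), d), an)
    rej <- rej + sum(tt$gca_tests$p < 0.05)
    n_eff <- n_eff + nrow(tt$gca_tests)
  }
  rate <- rej / n_eff
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_eff) + 0.02)
})

test_that("null simulations keep GCA and SCA tests at nominal size", {
  d <- make_design(8, n_env = 2, n_rep = 2)
  res <- t(sapply(1:60, function(s) {
    g <- simulate_genetics(d, 0, 0, var_error = 1, seed = s)
    pl <- simulate_trial(d, list(GY = g), seed = s + 4000,
                         var_block = 0, var_rep = 0)
    M <- entry_mean_matrix(pl, "GY", d, method = "raw")
    pe <- pooled_error(pl, "GY")
    an <- diallel_anova(M, d, 2, ms_error = pe$ms, df_error = pe$df)
    c(f_gca = an$f[an$source == "GCA"], f_sca = an$f[an$source == "SCA"],
      p_gca = an$p[an$source == "GCA"], p_sca = an$p[an$source == "SCA"])
  }))
  # a null F(df1, df2) ratio has mean df2/(df2 - 2)
  df_gcaxe <- 7; df_scaxe <- 20
  expect_lt(abs(mean(res[, "f_gca"]) - df_gcaxe / (df_gcaxe - 2)),
            3 * sd(res[, "f_gca"]) / sqrt(60))
  expect_lt(abs(mean(res[, "f_sca"]) - df_scaxe / (df_scaxe - 2)),
            3 * sd(res[, "f_sca"]) / sqrt(60))
  # type-I error at nominal 5% within a binomial band
  for (col in c("p_gca", "p_sca"))
    expect_lt(abs(mean(res[, col] < 0.05) - 0.05),
              3 * sqrt(0.05 * 0.95 / 60) + 0.01)
})

test_that("single-environment ANOVA uses the method-4 convention", {
  d <- make_design(6, n_env = 1, n_rep = 2)
  g <- simulate_genetics(d, 1, 0.5, seed = 5)
  pl <- simulate_trial(d, g, seed = 5)
  M <- entry_mean_matrix(pl, "trait", d, method = "raw")
  pe <- pooled_error(pl, "trait")
  an <- diallel_anova(M, d, 2, ms_error = pe$ms, df_error = pe$df)
  expect_false(any(c("HxE", "GCAxE", "SCAxE") %in% an$source))
  expect_equal(an$denominator[an$source == "GCA"], "SCA")
  expect_error(variance_components(an), "single-environment")
})
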