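#' Default pipeline configuration
#'
#' Mirrors the 21-parent study design: 210 crosses plus 4 checks, 2
#' environments x 2 replications in incomplete blocks, the trait panel of
#' [default_trait_params()], a 2,000-SNP parental panel with 200 causal
#' loci, QC at MAF > 0.05 and missingness < 10%, fivefold GBLUP
#' cross-validation.
#'
#' @param seed Master seed (mandatory for every stochastic step).
#' @param out_dir Output directory for the written tables.
#' @param traits Traits to analyse (default: grain yield plus the damage
#'   scores and the main agronomic traits).
#' @return A named list understood by [run_pipeline()].
#' @export
default_config <- function(seed = 1, out_dir = tempfile("fawdiallel_run_"),
                           traits = c("GY", "FD1", "FD2", "FD3", "ED",
                                      "AD", "SD", "PH", "EH")) {
  list(
    p = 21, n_env = 2, n_rep = 2, block_size = 15,
    checks = c("DH04", "DK8031", "Duma43", "WE1101"),
    trait_params = default_trait_params(),
    traits = traits,
    n_snps = 2000, maf_range = c(0.05, 0.5), missing_rate = 0.02,
    n_causal = 200,
    maf_min = 0.05, max_missing = 0.10,
    k_folds = 5, top_n = 15, outlier_sd = 3.5,
    seed = seed, out_dir = out_dir
  )
}

#' Run the full synthetic diallel analysis pipeline
#'
#' simulate -> entry means -> diallel combining-ability analysis ->
#' GCA-LOO and GBLUP prediction -> summaries. All tables are written as
#' CSV under `config$out_dir` together with a manifest and a log recording
#' seeds, clamped variance components and dropped markers. Deterministic:
#' rerunning with the same config reproduces every output byte for byte.
#'
#' @param config List from [default_config()] (possibly modified).
#' @return Invisible list with the in-memory results: `design`, `plots`,
#'   `genetics`, `anova` (per trait), `vc`, `ratios`, `effects`,
#'   `predictions`, `ranking`, `correlations`, `manifest`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.null(config$seed)) stop("config$seed is mandatory")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(paste("seed:", config$seed),
                 paste("R:", R.version.string))
  manifest <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$out_dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    manifest <<- c(manifest, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- simulate ------------------------------------------------------------
  design <- stage("design", make_design(config$p, config$n_env,
                                        config$n_rep, config$block_size,
                                        checks = config$checks))
  params <- config$trait_params
  params <- params[params$trait %in% config$traits, , drop = FALSE]
  sim <- stage("simulate", simulate_study(design, params,
                                          seed = config$seed))
  plots <- sim$plots
  emit(plots, "plots")
  write_truth(sim$genetics, file.path(config$out_dir, "truth.csv"))

  markers <- stage("markers", simulate_markers(
    design$parents, n_snps = config$n_snps, maf_range = config$maf_range,
    missing_rate = config$missing_rate, n_causal = config$n_causal,
    seed = config$seed + 7919L))
  filtered <- stage("marker_qc", filter_markers(markers, config$maf_min,
                                                config$max_missing))
  log_lines <- c(log_lines,
                 paste("markers dropped by QC:", attr(filtered, "n_dropped"),
                       "(maf<=", config$maf_min,
                       "or missing>=", config$max_missing, ")"))

  # -- means, diallel, prediction, per trait -------------------------------
  err <- list(); anovas <- list(); vcs <- list(); ratios <- list()
  effects <- list(); preds <- list()
  K <- grm(hybrid_genotypes(filtered, design))
  blup_cols <- list()
  for (trait in params$trait) {
    flag <- stage("outliers", screen_outliers(plots, trait,
                                              config$outlier_sd))
    clean <- plots
    clean[[trait]][flag] <- NA
    log_lines <- c(log_lines, paste0(trait, ": ", sum(flag),
                                     " plot(s) flagged as outliers"))

    M <- stage("means", entry_mean_matrix(clean, trait, design,
                                          method = "blue"))
    pe <- pooled_error(clean, trait)
    an <- stage("diallel", diallel_anova(M, design, config$n_rep,
                                         ms_error = pe$ms, df_error = pe$df,
                                         ms_rep = pe$ms_rep,
                                         df_rep = pe$df_rep))
    vc <- variance_components(an)
    if (length(vc$clamped))
      log_lines <- c(log_lines, paste0(trait, ": clamped to 0: ",
                                       paste(vc$clamped, collapse = ", ")))
    rt <- genetic_ratios(vc, an)
    ca <- effect_tests(griffing_effects(rowMeans(M), design, trait = trait),
                       an)
    across <- rowMeans(M)
    loo <- stage("predict_gca", loo_gca_predict(across, design,
                                                trait = trait))
    gb <- stage("predict_gblup", gblup_cv(across, K,
                                          k_folds = config$k_folds,
                                          seed = config$seed + 104729L,
                                          trait = trait))

    blups <- entry_means(clean, trait, scope = "across",
                         estimator = "BLUP", include_checks = FALSE)
    blup_cols[[trait]] <- stats::setNames(blups$value, blups$entry)

    anovas[[trait]] <- an; vcs[[trait]] <- vc; ratios[[trait]] <- rt
    effects[[trait]] <- ca
    preds[[trait]] <- list(gca_loo = loo, gblup = gb)
    err[[trait]] <- pe
  }

  # -- write per-trait tables ---------------------------------------------
  anova_tab <- do.call(rbind, lapply(names(anovas), function(tr) {
    a <- as.data.frame(anovas[[tr]]); a$trait <- tr; a }))
  emit(anova_tab, "anova")
  vc_tab <- do.call(rbind, lapply(names(vcs), function(tr) {
    v <- vcs[[tr]]; r <- ratios[[tr]]
    data.frame(trait = tr, sigma2_gca = v$sigma2_gca,
               sigma2_sca = v$sigma2_sca,
               sigma2_gca_env = v$sigma2_gca_env,
               sigma2_sca_env = v$sigma2_sca_env, sigma2_e = v$sigma2_e,
               sigma2_a = v$sigma2_a, sigma2_d = v$sigma2_d,
               sigma2_p = v$sigma2_p, baker_ratio = r$baker_ratio,
               gca_sca_ratio = r$gca_sca_ratio,
               heritability = r$heritability)
  }))
  emit(vc_tab, "variance_components")
  gca_tab <- do.call(rbind, lapply(names(effects), function(tr) {
    g <- effects[[tr]]$gca_tests; g$trait <- tr; g }))
  emit(gca_tab, "gca_effects")
  pred_tab <- do.call(rbind, lapply(names(preds), function(tr) {
    data.frame(trait = tr,
               method = c("GCA-LOO", "GBLUP-kfold"),
               r = c(preds[[tr]]$gca_loo$r, preds[[tr]]$gblup$r),
               n = c(preds[[tr]]$gca_loo$n, preds[[tr]]$gblup$n),
               seed = c(NA, preds[[tr]]$gblup$seed))
  }))
  emit(pred_tab, "prediction_summary")

  # -- summaries -----------------------------------------------------------
  blup_mat <- do.call(cbind, blup_cols)
  corr <- correlate_traits(blup_mat)
  corr_long <- data.frame(
    trait1 = rownames(corr$r)[row(corr$r)[upper.tri(corr$r)]],
    trait2 = colnames(corr$r)[col(corr$r)[upper.tri(corr$r)]],
    r = corr$r[upper.tri(corr$r)], p = corr$p[upper.tri(corr$p)])
  emit(corr_long, "trait_correlations")

  rank_trait <- if ("GY" %in% params$trait) "GY" else params$trait[1]
  blue_across <- entry_means(plots, rank_trait, scope = "across",
                             estimator = "BLUE")
  rank_df <- data.frame(entry = blue_across$entry,
                        value = blue_across$value)
  names(rank_df)[2] <- rank_trait
  ranking <- rank_and_summarize(rank_df, rank_trait, top_n = config$top_n,
                                check_ids = config$checks)
  emit(ranking$top, "top_hybrids")
  emit(cbind(group = rownames(ranking$group_means), ranking$group_means),
       "group_means")

  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  writeLines(basename(manifest), file.path(config$out_dir, "MANIFEST"))

  invisible(list(design = design, plots = plots, genetics = sim$genetics,
                 markers = filtered, kinship = K, anova = anovas, vc = vcs,
                 ratios = ratios, effects = effects, predictions = preds,
                 ranking = ranking, correlations = corr,
                 manifest = manifest, out_dir = config$out_dir))
}
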