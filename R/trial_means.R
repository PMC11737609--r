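#' Flag outlying plots by standardized residuals
#'
#' Fits, separately in each environment, a fixed-effects two-way model
#' (entry + replicate) and flags plots whose standardized residual exceeds
#' the threshold. The input is not modified; downstream calls can drop the
#' flagged rows.
#'
#' @param plots Plot data frame (see [simulate_trial()] / [read_plot_csv()]).
#' @param trait Trait column to screen.
#' @param threshold_sd Positive standardized-residual threshold (default
#'   3.5).
#' @return Logical vector along the rows of `plots`; `TRUE` marks a
#'   flagged plot (missing trait values are never flagged). Screening
#'   never empties an entry within an environment: if every replicate of
#'   an entry would be flagged, the least extreme of them is released, so
#'   the entry keeps at least one observation.
#' @export
screen_outliers <- function(plots, trait, threshold_sd = 3.5) {
  if (threshold_sd <= 0) stop("threshold_sd must be > 0")
  if (!trait %in% names(plots)) stop("no trait column '", trait, "'")
  flag <- rep(FALSE, nrow(plots))
  for (env in unique(plots$env)) {
    rows <- which(plots$env == env & !is.na(plots[[trait]]))
    d <- plots[rows, ]
    if (length(unique(d$rep)) < 2)
      stop("environment ", env,
           " has fewer than 2 replicates; residuals are unidentifiable")
    fit <- stats::lm(d[[trait]] ~ factor(d$entry) + factor(d$rep))
    rs <- stats::rstandard(fit)
    rs[!is.finite(rs)] <- 0
    f <- abs(rs) > threshold_sd
    for (ent in unique(d$entry[f])) {
      in_ent <- which(d$entry == ent)
      if (all(f[in_ent]))
        f[in_ent[which.min(abs(rs[in_ent]))]] <- FALSE
    }
    flag[rows][f] <- TRUE
  }
  flag
}

.block_factor <- function(d) interaction(d$rep, d$block, drop = TRUE)

# Quietly fit an lmer model, tolerating singular fits (zero variance
# components are legitimate here).
.quiet_lmer <- function(formula, data) {
  withCallingHandlers(
    suppressMessages(lme4::lmer(formula, data = data, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE))),
    warning = function(w) invokeRestart("muffleWarning"))
}

#' Entry means (BLUEs) and shrunken entry means (BLUPs)
#'
#' Two-stage mixed-model estimation of per-entry trait means from
#' plot-level alpha-lattice data. Within one environment the model is
#' value ~ entry + (1|rep) + (1|rep:block); across environments it adds
#' (1|env), nests rep and block in env, and includes a random entry-by-
#' environment interaction. For BLUEs the entry enters fixed; for BLUPs it
#' enters random and the reported mean is the grand mean plus the entry's
#' conditional mode (shrunken toward the grand mean). Variance components
#' are estimated by REML; plots with missing trait values are simply
#' absent from the model (no imputation).
#'
#' @param plots Plot data frame.
#' @param trait Trait column name.
#' @param scope `"env"` (one table per environment) or `"across"`.
#' @param estimator `"BLUE"` or `"BLUP"`.
#' @param include_checks Keep check entries (default TRUE; the diallel
#'   analysis itself uses cross entries only).
#' @return A data frame with columns `entry`, `trait`, `scope`, `env`
#'   (NA for across-environment rows), `estimator`, `value`, `se`. Entries
#'   absent from all plots are dropped with a warning.
#' @export
entry_means <- function(plots, trait, scope = c("across", "env"),
                        estimator = c("BLUE", "BLUP"),
                        include_checks = TRUE) {
  scope <- match.arg(scope)
  estimator <- match.arg(estimator)
  if (!trait %in% names(plots)) stop("no trait column '", trait, "'")
  eligible <- if (include_checks) plots else plots[!plots$is_check, ]
  d <- eligible[!is.na(eligible[[trait]]), ]
  if (nrow(d) == 0) stop("no observations for trait ", trait)
  missing_entries <- setdiff(unique(eligible$entry), unique(d$entry))
  if (length(missing_entries))
    warning("entries absent from all plots dropped: ",
            paste(missing_entries, collapse = ", "))
  d$y <- d[[trait]]
  d$entry <- factor(d$entry)
  d$env_f <- factor(d$env)
  d$rep_f <- factor(paste(d$env, d$rep))
  d$blk_f <- factor(paste(d$env, d$rep, d$block))

  fit_one <- function(dd, across) {
    dd$entry <- droplevels(dd$entry)
    if (estimator == "BLUE") {
      f <- if (across)
        y ~ 0 + entry + (1 | env_f) + (1 | rep_f) + (1 | blk_f) +
          (1 | entry:env_f)
      else
        y ~ 0 + entry + (1 | rep_f) + (1 | blk_f)
      m <- .quiet_lmer(f, dd)
      b <- lme4::fixef(m)
      se <- sqrt(diag(as.matrix(stats::vcov(m))))
      ent <- sub("^entry", "", names(b))
      data.frame(entry = ent, value = unname(b), se = unname(se),
                 stringsAsFactors = FALSE)
    } else {
      f <- if (across)
        y ~ 1 + (1 | entry) + (1 | env_f) + (1 | rep_f) + (1 | blk_f) +
          (1 | entry:env_f)
      else
        y ~ 1 + (1 | entry) + (1 | rep_f) + (1 | blk_f)
      m <- .quiet_lmer(f, dd)
      re <- lme4::ranef(m, condVar = TRUE)$entry
      pv <- attr(re, "postVar")
      data.frame(entry = rownames(re),
                 value = lme4::fixef(m)[["(Intercept)"]] + re[, 1],
                 se = sqrt(pv[1, 1, ]), stringsAsFactors = FALSE)
    }
  }

  if (scope == "across") {
    out <- fit_one(d, across = length(unique(d$env)) > 1)
    out$env <- NA_character_
  } else {
    parts <- lapply(split(d, d$env), fit_one, across = FALSE)
    for (env in names(parts)) parts[[env]]$env <- env
    out <- do.call(rbind, parts)
  }
  out$trait <- trait
  out$scope <- scope
  out$estimator <- estimator
  rownames(out) <- NULL
  out[, c("entry", "trait", "scope", "env", "estimator", "value", "se")]
}

#' Per-environment cross-mean matrix for the diallel ANOVA
#'
#' Convenience wrapper: computes per-environment BLUEs for the experimental
#' crosses and arranges them as the crosses x environments matrix that
#' [diallel_anova()] consumes.
#'
#' @param plots Plot data frame.
#' @param trait Trait column name.
#' @param design A [make_design()] object.
#' @param method `"blue"` for mixed-model BLUEs, `"raw"` for arithmetic
#'   plot means (exact on balanced data with no block adjustment wanted;
#'   much faster for simulation studies).
#' @return Numeric matrix, rownames = cross entries, colnames =
#'   environments.
#' @export
entry_mean_matrix <- function(plots, trait, design, method = c("blue", "raw")) {
  method <- match.arg(method)
  d <- plots[!plots$is_check & !is.na(plots[[trait]]), ]
  envs <- design$environments
  M <- matrix(NA_real_, nrow(design$crosses), length(envs),
              dimnames = list(design$crosses$entry, envs))
  if (method == "raw") {
    agg <- stats::aggregate(d[[trait]], by = list(entry = d$entry,
                                                  env = d$env), FUN = mean)
    M[cbind(agg$entry, agg$env)] <- agg$x
  } else {
    em <- entry_means(d, trait, scope = "env", estimator = "BLUE")
    M[cbind(em$entry, em$env)] <- em$value
  }
  M
}

#' Pooled plot-error mean square
#'
#' Residual mean square pooled over environments from per-environment
#' fixed-effects fits (entry + replicate + block within replicate) on the
#' experimental crosses. This is the `Error` row of the diallel ANOVA and
#' the denominator of its interaction strata.
#'
#' @param plots Plot data frame.
#' @param trait Trait column name.
#' @return List with `ms`, `df`, and the replicate stratum `ms_rep`,
#'   `df_rep` (replicates within environments).
#' @export
pooled_error <- function(plots, trait) {
  d <- plots[!plots$is_check & !is.na(plots[[trait]]), ]
  sse <- 0; dfe <- 0; ss_rep <- 0; df_rep <- 0
  for (env in unique(d$env)) {
    dd <- d[d$env == env, ]
    dd$blk <- .block_factor(dd)
    fit <- stats::lm(dd[[trait]] ~ factor(dd$entry) + factor(dd$rep) + dd$blk)
    sse <- sse + sum(stats::residuals(fit)^2)
    dfe <- dfe + fit$df.residual
    a <- stats::anova(stats::lm(dd[[trait]] ~ factor(dd$rep)))
    ss_rep <- ss_rep + a$`Sum Sq`[1]
    df_rep <- df_rep + a$Df[1]
  }
  list(ms = sse / dfe, df = dfe, ms_rep = ss_rep / df_rep, df_rep = df_rep)
}
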