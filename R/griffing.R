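#' @name griffing
#' @title Griffing model-1 method-4 combining-ability analysis
#'
#' @description
#' Method 4 analyses the p(p-1)/2 F1 crosses of a half diallel without
#' parents or reciprocals, with genotype (combining-ability) effects fixed
#' (model 1). On a complete set of cross means the estimators have closed
#' forms:
#' \deqn{\mu = 2 x_{..}/(p(p-1))}
#' \deqn{g_i = [p\,x_{i.} - 2 x_{..}]/[p(p-2)]}
#' \deqn{s_{ij} = x_{ij} - \mu - g_i - g_j}
#' where \eqn{x_{i.}} is the sum of the means of all crosses containing
#' parent i and \eqn{x_{..}} the sum over all crosses. With missing
#' crosses the package solves the equivalent least-squares problem under
#' the sum-to-zero constraint on the GCA effects, and SCA effects are the
#' residuals of observed crosses.
NULL

# Balanced closed-form estimates from a complete vector of cross means
# (named by entry). Returns mu, gca (named by parent).
.griffing_closed_form <- function(means, crosses, parents) {
  p <- length(parents)
  x_tot <- sum(means)
  x_i <- vapply(parents, function(pp) {
    sum(means[crosses$entry[crosses$parent1 == pp | crosses$parent2 == pp]])
  }, numeric(1))
  mu <- 2 * x_tot / (p * (p - 1))
  gca <- (p * x_i - 2 * x_tot) / (p * (p - 2))
  list(mu = mu, gca = gca)
}

# Constrained least squares for mu + g_i + g_j on a possibly incomplete
# set of cross means, with sum(g) = 0 imposed via a Lagrange multiplier.
.griffing_ls <- function(means, crosses, parents) {
  p <- length(parents)
  n <- length(means)
  X <- matrix(0, n, p + 1)
  X[, 1] <- 1
  i1 <- match(crosses$parent1, parents)
  i2 <- match(crosses$parent2, parents)
  X[cbind(seq_len(n), i1 + 1)] <- 1
  X[cbind(seq_len(n), i2 + 1)] <- 1
  A <- crossprod(X)
  b <- crossprod(X, means)
  cvec <- c(0, rep(1, p))
  M <- rbind(cbind(A, cvec), c(cvec, 0))
  sol <- solve(M, c(b, 0), tol = 1e-12)
  list(mu = sol[1], gca = stats::setNames(sol[2:(p + 1)], parents))
}

#' Estimate GCA and SCA effects from diallel entry means
#'
#' @param entry_means Named numeric vector of per-cross entry means (names
#'   are `parent1/parent2` entries of the design), or a data frame with
#'   columns `entry` and `value`. May omit crosses (unbalanced path).
#' @param design A [make_design()] object.
#' @param trait Optional trait label carried through to outputs.
#'
#' @return An object of class `combining_ability`: list with `trait`, `mu`,
#'   `gca` (named by parent, NA where inestimable), `sca` (named by
#'   observed cross), `sca_matrix` (symmetric parent x parent),
#'   `inestimable` (parents present in fewer than 2 observed crosses),
#'   `balanced` (logical), `design`.
#' @examples
#' d <- make_design(4)
#' m <- setNames(c(10, 12, 14, 11, 13, 12), d$crosses$entry)
#' ca <- griffing_effects(m, d)
#' sum(ca$gca)  # 0
#' @export
griffing_effects <- function(entry_means, design, trait = NULL) {
  stopifnot(inherits(design, "diallel_design"))
  if (is.data.frame(entry_means))
    entry_means <- stats::setNames(entry_means$value, entry_means$entry)
  crosses <- design$crosses
  parents <- design$parents
  p <- length(parents)

  keep <- intersect(crosses$entry, names(entry_means)[!is.na(entry_means)])
  if (length(keep) == 0) stop("no cross means supplied for this design")
  obs <- crosses[match(keep, crosses$entry), , drop = FALSE]
  y <- entry_means[keep]

  counts <- table(factor(c(obs$parent1, obs$parent2), levels = parents))
  inestimable <- names(counts)[counts < 2]
  balanced <- length(keep) == nrow(crosses)

  if (balanced) {
    fit <- .griffing_closed_form(y, obs, parents)
  } else {
    if (length(inestimable))
      warning("effects inestimable for parent(s): ",
              paste(inestimable, collapse = ", "))
    est_parents <- setdiff(parents, inestimable)
    obs_est <- obs[obs$parent1 %in% est_parents &
                     obs$parent2 %in% est_parents, , drop = FALSE]
    fit <- .griffing_ls(y[obs_est$entry], obs_est, est_parents)
    gca_full <- stats::setNames(rep(NA_real_, p), parents)
    gca_full[est_parents] <- fit$gca
    fit$gca <- gca_full
  }

  sca <- y - fit$mu - fit$gca[obs$parent1] - fit$gca[obs$parent2]
  names(sca) <- keep
  sca_matrix <- matrix(NA_real_, p, p, dimnames = list(parents, parents))
  sca_matrix[cbind(obs$parent1, obs$parent2)] <- sca
  sca_matrix[cbind(obs$parent2, obs$parent1)] <- sca

  structure(
    list(trait = trait, mu = unname(fit$mu), gca = fit$gca, sca = sca,
         sca_matrix = sca_matrix, inestimable = inestimable,
         balanced = balanced, design = design),
    class = "combining_ability"
  )
}

#' @export
print.combining_ability <- function(x, ...) {
  cat("Combining-ability estimates",
      if (!is.null(x$trait)) paste0("(", x$trait, ")"), "\n")
  cat("  grand mean:", format(x$mu, digits = 4), "\n")
  cat("  GCA range: [", format(min(x$gca, na.rm = TRUE), digits = 3), ",",
      format(max(x$gca, na.rm = TRUE), digits = 3), "]\n")
  if (length(x$inestimable))
    cat("  inestimable parents:", paste(x$inestimable, collapse = ", "), "\n")
  invisible(x)
}

#' Across-environment diallel ANOVA on entry means
#'
#' Computes the combining-ability analysis of variance from per-environment
#' entry means. Sums of squares are computed on the entry means and scaled
#' by the replicate count so that mean squares are on the plot basis; the
#' pooled plot-error mean square then serves directly as the denominator of
#' the interaction rows, and the variance-component recipe of
#' [variance_components()] applies unchanged. F strata: Environment and
#' Hybrids against Hybrids-by-environment; GCA against GCA x E; SCA against
#' SCA x E; every interaction row against the pooled error.
#'
#' @param entry_means_by_env Matrix or data frame of per-environment entry
#'   means: rows = crosses (rownames are entries), columns = environments.
#'   Checks must already be excluded.
#' @param design A [make_design()] object.
#' @param n_rep Replicates per environment (scales means to plot basis).
#' @param ms_error Pooled plot-error mean square (see [pooled_error()]).
#' @param df_error Degrees of freedom of the pooled error.
#' @param ms_rep,df_rep Optional replicate-within-environment stratum from
#'   the plot-level fit, reported as a `Rep(Env)` row when supplied.
#'
#' @return An object of class `diallel_anova` (data frame): columns
#'   `source`, `df`, `ss`, `ms`, `f`, `p`, `denominator`.
#' @export
diallel_anova <- function(entry_means_by_env, design, n_rep,
                          ms_error = NULL, df_error = NULL,
                          ms_rep = NULL, df_rep = NULL) {
  stopifnot(inherits(design, "diallel_design"))
  Y <- as.matrix(entry_means_by_env)
  crosses <- design$crosses
  parents <- design$parents
  p <- length(parents)
  n_c <- nrow(crosses)
  if (nrow(Y) != n_c)
    Y <- Y[match(crosses$entry, rownames(Y)), , drop = FALSE]
  if (anyNA(Y))
    stop("entry means must cover all ", n_c, " crosses in every environment")
  e <- ncol(Y)
  r <- n_rep

  grand <- mean(Y)
  cross_mean <- rowMeans(Y)
  env_mean <- colMeans(Y)

  fit_all <- griffing_effects(stats::setNames(cross_mean, crosses$entry),
                              design)
  g_all <- fit_all$gca
  s_all <- fit_all$sca[crosses$entry]

  rows <- list()
  add_row <- function(source, df, ss) {
    rows[[length(rows) + 1L]] <<- data.frame(
      source = source, df = df, ss = ss, ms = ss / df,
      stringsAsFactors = FALSE)
  }

  if (e > 1) {
    add_row("Environment", e - 1, r * n_c * sum((env_mean - grand)^2))
    if (!is.null(ms_rep) && !is.null(df_rep))
      add_row("Rep(Env)", df_rep, ms_rep * df_rep)
    add_row("Hybrids", n_c - 1, r * e * sum((cross_mean - grand)^2))
    add_row("GCA", p - 1, r * e * (p - 2) * sum(g_all^2))
    add_row("SCA", p * (p - 3) / 2, r * e * sum(s_all^2))

    ss_hxe <- r * sum(sweep(sweep(Y, 1, cross_mean), 2, env_mean - grand)^2)
    ss_gxe <- 0
    ss_sxe <- 0
    for (k in seq_len(e)) {
      fit_k <- griffing_effects(stats::setNames(Y[, k], crosses$entry), design)
      ss_gxe <- ss_gxe + (p - 2) * sum((fit_k$gca - g_all)^2)
      ss_sxe <- ss_sxe + sum((fit_k$sca[crosses$entry] - s_all)^2)
    }
    add_row("HxE", (e - 1) * (n_c - 1), ss_hxe)
    add_row("GCAxE", (e - 1) * (p - 1), r * ss_gxe)
    add_row("SCAxE", (e - 1) * p * (p - 3) / 2, r * ss_sxe)
  } else {
    add_row("Hybrids", n_c - 1, r * sum((cross_mean - grand)^2))
    add_row("GCA", p - 1, r * (p - 2) * sum(g_all^2))
    add_row("SCA", p * (p - 3) / 2, r * sum(s_all^2))
  }
  if (!is.null(ms_error) && !is.null(df_error))
    add_row("Error", df_error, ms_error * df_error)

  tab <- do.call(rbind, rows)

  # F strata; interaction rows are on the plot basis already, so the
  # pooled plot-error MS is their denominator (equivalently: entry-mean MS
  # against pooled error / r -- the F is identical).
  denom_of <- if (e > 1) c(
    Environment = "HxE", "Rep(Env)" = "Error", Hybrids = "HxE",
    GCA = "GCAxE", SCA = "SCAxE",
    HxE = "Error", GCAxE = "Error", SCAxE = "Error"
  ) else c(Hybrids = "Error", GCA = "SCA", SCA = "Error")

  tab$f <- NA_real_
  tab$p <- NA_real_
  tab$denominator <- NA_character_
  for (i in seq_len(nrow(tab))) {
    src <- tab$source[i]
    if (src == "Error" || !src %in% names(denom_of)) next
    den <- denom_of[[src]]
    j <- match(den, tab$source)
    if (is.na(j)) next
    tab$f[i] <- tab$ms[i] / tab$ms[j]
    tab$p[i] <- stats::pf(tab$f[i], tab$df[i], tab$df[j], lower.tail = FALSE)
    tab$denominator[i] <- den
  }
  attr(tab, "p") <- p
  attr(tab, "e") <- e
  attr(tab, "r") <- r
  class(tab) <- c("diallel_anova", "data.frame")
  tab
}

.ms <- function(anova, source) {
  i <- match(source, anova$source)
  if (is.na(i)) NA_real_ else anova$ms[i]
}

.df_of <- function(anova, source) {
  i <- match(source, anova$source)
  if (is.na(i)) NA_real_ else anova$df[i]
}

#' Method-4 expected-mean-squares variance components
#'
#' Solves the across-environment method-4 expected mean squares on the
#' plot basis for the combining-ability variance components:
#' \deqn{\sigma^2_{SCA} = (MS_{SCA} - MS_{SCAxE})/(re)}
#' \deqn{\sigma^2_{GCA} = [(MS_{GCA} - MS_{GCAxE}) - (MS_{SCA} -
#'   MS_{SCAxE})]/[re(p-2)]}
#' \deqn{\sigma^2_{GCAxE} = (MS_{GCAxE} - MS_{SCAxE})/[r(p-2)]}
#' \deqn{\sigma^2_{SCAxE} = (MS_{SCAxE} - MS_{error})/r}
#' Negative solutions are clamped to zero. Derived quantities:
#' additive variance sigma2_A = 2 sigma2_GCA, dominance variance
#' sigma2_D = sigma2_SCA, and phenotypic variance sigma2_P = sigma2_A +
#' sigma2_D + sigma2_e.
#'
#' @param anova A [diallel_anova()] table with the interaction rows.
#' @param p,e,r Parent, environment and replicate counts; defaults are
#'   taken from the table's attributes.
#' @param sigma2_e Error variance used for sigma2_P. Defaults to the pooled
#'   error mean square of the table; supply a separately estimated residual
#'   variance (e.g. from a REML fit) to reproduce workflows that report
#'   one.
#'
#' @return An object of class `variance_components`: named list with
#'   `sigma2_gca`, `sigma2_sca`, `sigma2_gca_env`, `sigma2_sca_env`,
#'   `sigma2_e`, `sigma2_a`, `sigma2_d`, `sigma2_p`, `clamped` (character
#'   vector of components floored at zero), and the test p-values of the
#'   GCA/SCA/interaction rows as `p_values`.
#' @export
variance_components <- function(anova, p = attr(anova, "p", exact = TRUE),
                                e = attr(anova, "e", exact = TRUE), r = attr(anova, "r", exact = TRUE),
                                sigma2_e = NULL) {
  needed <- c("GCA", "SCA", "GCAxE", "SCAxE")
  if (!all(needed %in% anova$source))
    stop("across-environment ANOVA with GCAxE/SCAxE rows required; ",
         "single-environment tables do not identify these components")
  ms_g <- .ms(anova, "GCA"); ms_s <- .ms(anova, "SCA")
  ms_ge <- .ms(anova, "GCAxE"); ms_se <- .ms(anova, "SCAxE")
  ms_err <- .ms(anova, "Error")
  if (is.null(sigma2_e)) sigma2_e <- ms_err

  raw <- c(
    sigma2_sca = (ms_s - ms_se) / (r * e),
    sigma2_gca = ((ms_g - ms_ge) - (ms_s - ms_se)) / (r * e * (p - 2)),
    sigma2_gca_env = (ms_ge - ms_se) / (r * (p - 2)),
    sigma2_sca_env = if (is.na(ms_err)) NA_real_ else (ms_se - ms_err) / r
  )
  clamped <- names(raw)[!is.na(raw) & raw < 0]
  comp <- pmax(raw, 0)

  out <- list(
    sigma2_gca = unname(comp["sigma2_gca"]),
    sigma2_sca = unname(comp["sigma2_sca"]),
    sigma2_gca_env = unname(comp["sigma2_gca_env"]),
    sigma2_sca_env = unname(comp["sigma2_sca_env"]),
    sigma2_e = sigma2_e,
    clamped = clamped,
    p_values = c(
      gca = anova$p[match("GCA", anova$source)],
      sca = anova$p[match("SCA", anova$source)],
      gca_env = anova$p[match("GCAxE", anova$source)],
      sca_env = anova$p[match("SCAxE", anova$source)]
    )
  )
  out$sigma2_a <- 2 * out$sigma2_gca
  out$sigma2_d <- out$sigma2_sca
  out$sigma2_p <- out$sigma2_a + out$sigma2_d + out$sigma2_e
  class(out) <- "variance_components"
  out
}

#' @export
print.variance_components <- function(x, digits = 3, ...) {
  v <- unlist(x[c("sigma2_gca", "sigma2_sca", "sigma2_gca_env",
                  "sigma2_sca_env", "sigma2_e", "sigma2_a", "sigma2_d",
                  "sigma2_p")])
  print(round(v, digits))
  if (length(x$clamped))
    cat("clamped at 0:", paste(x$clamped, collapse = ", "), "\n")
  invisible(x)
}

#' Genetic predictability ratios and entry-mean heritability
#'
#' The Baker ratio 2 sigma2_GCA / (2 sigma2_GCA + sigma2_SCA) measures how
#' predictable hybrid performance is from parental GCA alone (1 = fully
#' additive). The GCA-SCA ratio sigma2_GCA / sigma2_SCA is undefined
#' (reported NA) when sigma2_SCA is zero. Broad-sense heritability on the
#' entry-mean basis uses the genotypic ANOVA rows:
#' sigma2_G = (MS_H - MS_HxE)/(re), sigma2_GxE = (MS_HxE - MS_err)/r,
#' H2 = sigma2_G / (sigma2_G + sigma2_GxE/e + sigma2_e/(re)), clamped to
#' [0, 1].
#'
#' @param vc A [variance_components()] object.
#' @param anova The [diallel_anova()] table (for the Hybrids strata).
#' @param e,r Environment and replicate counts.
#' @return Named list `baker_ratio`, `gca_sca_ratio`, `heritability`.
#' @export
genetic_ratios <- function(vc, anova = NULL, e = attr(anova, "e", exact = TRUE),
                           r = attr(anova, "r", exact = TRUE)) {
  denom <- 2 * vc$sigma2_gca + vc$sigma2_sca
  baker <- if (denom > 0) 2 * vc$sigma2_gca / denom else NA_real_
  gca_sca <- if (vc$sigma2_sca > 0) vc$sigma2_gca / vc$sigma2_sca
             else NA_real_

  h2 <- NA_real_
  if (!is.null(anova) && all(c("Hybrids", "HxE", "Error") %in% anova$source)) {
    ms_h <- .ms(anova, "Hybrids")
    ms_hxe <- .ms(anova, "HxE")
    ms_err <- .ms(anova, "Error")
    sigma2_g <- max((ms_h - ms_hxe) / (r * e), 0)
    sigma2_gxe <- max((ms_hxe - ms_err) / r, 0)
    ph <- sigma2_g + sigma2_gxe / e + ms_err / (r * e)
    h2 <- if (ph > 0) min(max(sigma2_g / ph, 0), 1) else NA_real_
  }
  list(baker_ratio = baker, gca_sca_ratio = gca_sca, heritability = h2)
}

#' t-tests for GCA and SCA effects
#'
#' Standard errors follow the method-4 balanced formulas on the
#' across-environment entry-mean basis,
#' Var(g_i) = (p-1)/(p(p-2)) * s2 and Var(s_ij) = (p-3)/(p-1) * s2,
#' where s2 is the relevant error stratum converted to the mean basis:
#' MS_GCAxE/(re) for GCA and MS_SCAxE/(re) for SCA in the
#' across-environment analysis (pooled error/r in a single environment).
#' Two-sided t-tests use the stratum's degrees of freedom; stars mark 0.05
#' and 0.01.
#'
#' @param result A [griffing_effects()] object.
#' @param anova The matching [diallel_anova()] table.
#' @param r,e,p Design counts; defaults from the table.
#' @return The `combining_ability` object with data frames `gca_tests`
#'   (parent, estimate, se, t, p, stars) and `sca_tests` (entry, estimate,
#'   se, t, p, stars) attached.
#' @export
effect_tests <- function(result, anova, r = attr(anova, "r", exact = TRUE),
                         e = attr(anova, "e", exact = TRUE), p = attr(anova, "p", exact = TRUE)) {
  stopifnot(inherits(result, "combining_ability"))
  if ("GCAxE" %in% anova$source) {
    s2_g <- .ms(anova, "GCAxE") / (r * e); df_g <- .df_of(anova, "GCAxE")
    s2_s <- .ms(anova, "SCAxE") / (r * e); df_s <- .df_of(anova, "SCAxE")
  } else {
    s2_g <- .ms(anova, "Error") / r; df_g <- .df_of(anova, "Error")
    s2_s <- s2_g; df_s <- df_g
  }
  se_g <- sqrt((p - 1) / (p * (p - 2)) * s2_g)
  se_s <- sqrt((p - 3) / (p - 1) * s2_s)

  star <- function(pv) ifelse(is.na(pv), "",
                       ifelse(pv < 0.01, "**", ifelse(pv < 0.05, "*", "")))
  t_g <- result$gca / se_g
  p_g <- 2 * stats::pt(-abs(t_g), df_g)
  result$gca_tests <- data.frame(
    parent = names(result$gca), estimate = unname(result$gca),
    se = se_g, t = unname(t_g), p = unname(p_g),
    stars = star(unname(p_g)), stringsAsFactors = FALSE)

  t_s <- result$sca / se_s
  p_s <- 2 * stats::pt(-abs(t_s), df_s)
  result$sca_tests <- data.frame(
    entry = names(result$sca), estimate = unname(result$sca),
    se = se_s, t = unname(t_s), p = unname(p_s),
    stars = star(unname(p_s)), stringsAsFactors = FALSE)
  result
}
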