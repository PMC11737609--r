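#' Simulate true genetic effects for one trait of a diallel trial
#'
#' Draws the effects of the across-environment diallel model
#' y = mu + E_k + g_i + g_j + s_ij + (EG)_ik + (EG)_jk + (ES)_ijk + e
#' independently normal with the requested variances, then centres them so
#' the method-4 identification constraints hold exactly: GCA effects sum to
#' zero over parents; SCA effects sum to zero over all crosses and, for each
#' parent, over the crosses containing it. Centring is an orthogonal
#' decomposition that conserves the total genetic value of each cross: the
#' component of the raw SCA draw that lies in the mean/GCA space (an i.i.d.
#' SCA draw is not exactly per-parent centred in any finite diallel) is
#' re-attributed to the GCA effects rather than discarded, and likewise for
#' the SCA-by-environment draws. The data-generating process is therefore
#' exactly the i.i.d. random-effects model whose expected mean squares
#' [variance_components()] inverts — the variance parameters are recovered
#' without the finite-population bias that plain projection would introduce
#' (of order var_sca/(p-2) on the GCA component). One consequence,
#' documented here rather than corrected away: the expected sample variance
#' of the realized GCA effects is var_gca + var_sca/(p-2), slightly above
#' the nominal var_gca.
#'
#' @param design A [make_design()] object.
#' @param var_gca,var_sca Variances of GCA and SCA effects.
#' @param var_env Variance of environment main effects.
#' @param var_gca_env,var_sca_env Variances of the GCA-by-environment and
#'   SCA-by-environment interaction effects. With a single environment both
#'   interaction terms are identically zero.
#' @param var_error Plot-level residual variance.
#' @param mu Grand mean of the trait.
#' @param type `"continuous"` or `"ordinal"`. Ordinal traits are recorded
#'   by [simulate_trial()] as the latent value rounded to the nearest
#'   integer and clamped to `bounds` (the 1-9 visual damage scale).
#' @param bounds Length-2 numeric, recording bounds for ordinal traits.
#' @param check_effects Optional named numeric: deviation of each check
#'   entry from the grand mean. Defaults to draws from
#'   N(0, 2*var_gca + var_sca) for every check in the design.
#' @param seed Integer seed; the draw is reproducible given the seed.
#'
#' @return An object of class `true_genetics`: list with `mu`, `gca`
#'   (named by parent), `sca` (named by cross entry), `env_effects`,
#'   `gca_env` (parent x env matrix), `sca_env` (cross x env matrix),
#'   `var_error`, `check_effects`, `type`, `bounds`.
#' @export
simulate_genetics <- function(design, var_gca, var_sca, var_env = 0,
                              var_gca_env = 0, var_sca_env = 0,
                              var_error = 1, mu = 0,
                              type = c("continuous", "ordinal"),
                              bounds = c(1, 9),
                              check_effects = NULL, seed = 1) {
  stopifnot(inherits(design, "diallel_design"))
  type <- match.arg(type)
  vars <- c(var_gca, var_sca, var_env, var_gca_env, var_sca_env, var_error)
  if (any(vars < 0)) stop("variance parameters must be >= 0")

  parents <- design$parents
  p <- length(parents)
  crosses <- design$crosses
  n_c <- nrow(crosses)
  n_env <- length(design$environments)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  gca <- stats::rnorm(p, 0, sqrt(var_gca))
  gca <- gca - mean(gca)
  names(gca) <- parents
  s_raw <- stats::rnorm(n_c, 0, sqrt(var_sca))
  s_split <- .split_sca(s_raw, crosses, parents)
  gca <- gca + s_split$gca
  sca <- stats::setNames(s_split$sca, crosses$entry)

  env_effects <- stats::rnorm(n_env, 0, sqrt(var_env))
  env_effects <- env_effects - mean(env_effects)
  names(env_effects) <- design$environments

  if (n_env > 1) {
    gca_env <- matrix(stats::rnorm(p * n_env, 0, sqrt(var_gca_env)), p, n_env,
                      dimnames = list(parents, design$environments))
    gca_env <- sweep(gca_env, 2, colMeans(gca_env))
    sca_env <- matrix(stats::rnorm(n_c * n_env, 0, sqrt(var_sca_env)),
                      n_c, n_env,
                      dimnames = list(crosses$entry, design$environments))
    for (k in seq_len(n_env)) {
      sp <- .split_sca(sca_env[, k], crosses, parents)
      sca_env[, k] <- sp$sca
      gca_env[, k] <- gca_env[, k] + sp$gca
    }
  } else {
    gca_env <- matrix(0, p, 1, dimnames = list(parents, design$environments))
    sca_env <- matrix(0, n_c, 1,
                      dimnames = list(crosses$entry, design$environments))
  }

  if (is.null(check_effects)) {
    check_effects <- stats::rnorm(length(design$checks), 0,
                                  sqrt(2 * var_gca + var_sca))
    names(check_effects) <- design$checks
  } else {
    if (!all(design$checks %in% names(check_effects)))
      stop("check_effects must name every check in the design")
    check_effects <- check_effects[design$checks]
  }

  structure(
    list(mu = mu, gca = gca, sca = sca, env_effects = env_effects,
         gca_env = gca_env, sca_env = sca_env, var_error = var_error,
         check_effects = check_effects, type = type, bounds = bounds,
         parents = parents),
    class = "true_genetics"
  )
}

# Orthogonal split of cross-indexed values into a GCA-space part and the
# method-4 SCA constraint space (per-parent sums zero). The grand-mean
# part is dropped (absorbed by mu / the environment means).
.split_sca <- function(s, crosses, parents) {
  fit <- .griffing_closed_form(stats::setNames(s, crosses$entry),
                               crosses, parents)
  list(gca = fit$gca,
       sca = unname(s - fit$mu - fit$gca[crosses$parent1] -
                      fit$gca[crosses$parent2]))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}

#' Simulate plot-level data for a diallel trial
#'
#' Generates one plot record per entry per replicate per environment. The
#' continuous (latent) plot value is
#' mu + E_k + g_i + g_j + s_ij + (EG)_ik + (EG)_jk + (ES)_ijk + rep effect +
#' block effect + plot error; ordinal traits are recorded as the latent
#' value rounded to the nearest integer and clamped to the trait's bounds.
#' Entries are randomized to incomplete blocks within each replicate
#' (alpha-lattice-style resolvable layout) under the given seed; the layout
#' is shared by all traits, plot errors are trait-independent.
#'
#' @param design A [make_design()] object.
#' @param genetics A `true_genetics` object, or a named list of them (one
#'   per trait) sharing the same design.
#' @param seed Integer seed controlling layout randomization and errors.
#' @param var_block,var_rep Variances of i.i.d. normal incomplete-block and
#'   replicate effects (shared by all traits, drawn on each trait's own
#'   scale when `scale_nuisance` is TRUE).
#' @param scale_nuisance If TRUE (default) the block and replicate effect
#'   variances are interpreted as multiples of each trait's plot-error
#'   variance, so one number works across traits with very different
#'   scales.
#'
#' @return A data frame of plot records: `env`, `rep`, `block`, `plot`,
#'   `entry`, `parent1`, `parent2`, `is_check`, then one column per trait.
#' @export
simulate_trial <- function(design, genetics, seed = 1,
                           var_block = 0.25, var_rep = 0.1,
                           scale_nuisance = TRUE) {
  stopifnot(inherits(design, "diallel_design"))
  if (inherits(genetics, "true_genetics")) genetics <- list(trait = genetics)
  if (is.null(names(genetics)) || any(!nzchar(names(genetics))))
    stop("multi-trait genetics must be a named list")
  for (g in genetics) {
    if (!inherits(g, "true_genetics")) stop("genetics must be true_genetics")
    if (!identical(g$parents, design$parents))
      stop("design and genetics refer to different parents")
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  entries <- design$entries
  n_entry <- length(entries)
  n_blocks <- ceiling(n_entry / design$block_size)
  cross_lookup <- design$crosses
  rownames(cross_lookup) <- cross_lookup$entry

  layout <- list()
  for (env in design$environments) {
    for (r in seq_len(design$n_rep)) {
      perm <- sample(entries)
      blk <- rep(seq_len(n_blocks), each = design$block_size)[seq_len(n_entry)]
      layout[[length(layout) + 1L]] <- data.frame(
        env = env, rep = sprintf("R%d", r),
        block = sprintf("B%02d", blk),
        plot = seq_len(n_entry),
        entry = perm, stringsAsFactors = FALSE
      )
    }
  }
  plots <- do.call(rbind, layout)
  is_cross <- plots$entry %in% cross_lookup$entry
  plots$parent1 <- ifelse(is_cross, cross_lookup[plots$entry, "parent1"], NA)
  plots$parent2 <- ifelse(is_cross, cross_lookup[plots$entry, "parent2"], NA)
  plots$is_check <- !is_cross

  env_rep <- unique(plots[, c("env", "rep")])
  env_rep_blk <- unique(plots[, c("env", "rep", "block")])

  for (trait in names(genetics)) {
    g <- genetics[[trait]]
    sd_scale <- if (scale_nuisance) sqrt(g$var_error) else 1
    rep_eff <- stats::setNames(
      stats::rnorm(nrow(env_rep), 0, sqrt(var_rep) * sd_scale),
      paste(env_rep$env, env_rep$rep))
    blk_eff <- stats::setNames(
      stats::rnorm(nrow(env_rep_blk), 0, sqrt(var_block) * sd_scale),
      paste(env_rep_blk$env, env_rep_blk$rep, env_rep_blk$block))

    genetic_value <- numeric(nrow(plots))
    cross_rows <- which(!plots$is_check)
    p1 <- plots$parent1[cross_rows]
    p2 <- plots$parent2[cross_rows]
    ent <- plots$entry[cross_rows]
    env <- plots$env[cross_rows]
    genetic_value[cross_rows] <-
      g$gca[p1] + g$gca[p2] + g$sca[ent] +
      g$gca_env[cbind(p1, env)] + g$gca_env[cbind(p2, env)] +
      g$sca_env[cbind(ent, env)]
    check_rows <- which(plots$is_check)
    if (length(check_rows))
      genetic_value[check_rows] <- g$check_effects[plots$entry[check_rows]]

    latent <- g$mu + g$env_effects[plots$env] + genetic_value +
      rep_eff[paste(plots$env, plots$rep)] +
      blk_eff[paste(plots$env, plots$rep, plots$block)] +
      stats::rnorm(nrow(plots), 0, sqrt(g$var_error))

    if (g$type == "ordinal") {
      latent <- pmin(pmax(round(latent), g$bounds[1]), g$bounds[2])
    }
    plots[[trait]] <- unname(latent)
  }
  rownames(plots) <- NULL
  plots
}

#' Default per-trait simulation parameters for the 21-parent study design
#'
#' One row per trait with the grand mean and the variance components used
#' by the generator. Genetic and interaction variances for the nine core
#' traits (FD1-FD3, ED, GY, AD, SD, PH, EH) are set to the entry-mean-scale
#' combining-ability components and error variances estimated in the
#' multi-environment maize FAW diallel this package emulates; means are the
#' all-hybrid trial means. The remaining traits (ER, EXHL, TLGTH, ASI, EPP)
#' have plausible values on their field scales, chosen once and documented
#' in the methods vignette. Environment-effect variances are sized so that
#' environment mean squares dominate the genotypic ones, as in multi-site
#' trials with strongly contrasting infestation pressure.
#'
#' @return A data frame with columns `trait`, `type`, `mu`, `var_gca`,
#'   `var_sca`, `var_env`, `var_gca_env`, `var_sca_env`, `var_error`.
#' @export
default_trait_params <- function() {
  tab <- read.csv(text = "
trait,type,mu,var_gca,var_sca,var_env,var_gca_env,var_sca_env,var_error
FD1,ordinal,4.17,0.04,0.00,0.70,0.01,0.15,0.31
FD2,ordinal,5.00,0.03,0.04,1.46,0.04,0.07,0.33
FD3,ordinal,4.78,0.07,0.04,0.22,0.06,0.15,0.37
ED,ordinal,2.31,0.06,0.04,1.08,0.04,0.04,0.23
GY,continuous,5.32,0.22,0.27,0.62,0.17,0.39,1.29
AD,continuous,56.04,1.29,0.37,1.63,0.03,0.17,1.30
SD,continuous,57.50,1.32,0.45,1.96,0.07,0.56,1.50
PH,continuous,260.06,95.77,80.88,535.0,5.80,107.72,109.31
EH,continuous,130.00,58.34,36.65,78.9,0.21,52.87,46.66
ER,continuous,12.37,8.0,6.0,20.0,2.0,4.0,40.0
EXHL,continuous,1.5,0.15,0.10,0.5,0.05,0.05,0.8
TLGTH,continuous,8.0,4.0,3.0,8.0,1.0,1.0,12.0
ASI,continuous,1.5,0.08,0.05,0.3,0.01,0.05,0.5
EPP,continuous,1.0,0.004,0.003,0.01,0.001,0.002,0.02
", stringsAsFactors = FALSE, strip.white = TRUE)
  tab
}

#' Simulate a complete multi-trait diallel study
#'
#' Convenience wrapper: draws `true_genetics` per trait from a parameter
#' table (see [default_trait_params()]) and generates the plot data in one
#' call. Per-trait seeds are derived deterministically from `seed`.
#'
#' @param design A [make_design()] object.
#' @param params Data frame in the [default_trait_params()] layout; may be
#'   a subset of traits.
#' @param seed Integer master seed.
#' @param ... Passed to [simulate_trial()] (block/rep variances).
#' @return List with `plots` (data frame) and `genetics` (named list of
#'   `true_genetics`).
#' @export
simulate_study <- function(design, params = default_trait_params(),
                           seed = 1, ...) {
  genetics <- list()
  for (i in seq_len(nrow(params))) {
    pr <- params[i, ]
    genetics[[pr$trait]] <- simulate_genetics(
      design,
      var_gca = pr$var_gca, var_sca = pr$var_sca, var_env = pr$var_env,
      var_gca_env = pr$var_gca_env, var_sca_env = pr$var_sca_env,
      var_error = pr$var_error, mu = pr$mu, type = pr$type,
      seed = seed + i * 1009L
    )
  }
  plots <- simulate_trial(design, genetics, seed = seed, ...)
  list(plots = plots, genetics = genetics)
}
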