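#' Simulate a parental SNP panel with known causal effects
#'
#' Parents are fully inbred, so genotypes are coded 0/2 (homozygote dosage
#' of the counted allele) with optional missing calls. Per SNP the allele
#' frequency is drawn uniformly within `maf_range`; a SNP is redrawn until
#' its realized minor-allele frequency on the observed (non-missing) calls
#' lies strictly above the lower bound of `maf_range`, and missing calls
#' per SNP are capped at `ceiling(missing_rate * p)`. The generated panel
#' therefore satisfies the quality-control envelope it was asked for,
#' which makes generator-filter consistency deterministic. `n_causal`
#' SNPs receive additive allele-substitution effects; the implied parental
#' genetic value is the sum of effect times centred genotype, so
#' marker-based prediction has a recoverable signal.
#'
#' @param p Parent count or character vector of parent names.
#' @param n_snps Number of SNPs.
#' @param maf_range Length-2 numeric in (0, 0.5]: sampling range of allele
#'   frequencies.
#' @param missing_rate Per-call missing probability in [0, 1).
#' @param n_causal Number of causal SNPs (0 for a pure-noise panel).
#' @param effect_sd Standard deviation of causal effects.
#' @param seed Integer seed.
#' @return An object of class `marker_matrix`: list with `geno` (parents x
#'   SNPs, values 0/2/NA), `map` (data frame: snp, chrom, pos, alleles),
#'   `causal` (data frame: snp, effect), `parent_values` (named vector of
#'   true marker-derived additive values, centred over parents).
# Floating-point-safe strict MAF comparison, shared by the generator and
# the QC filter so that generator-filter consistency is exact.
.maf_above <- function(maf, maf_min) maf > maf_min + 1e-9

#' @export
simulate_markers <- function(p, n_snps = 2000, maf_range = c(0.05, 0.5),
                             missing_rate = 0, n_causal = 0,
                             effect_sd = 1, seed = 1) {
  if (is.character(p)) { parents <- p; p <- length(parents) }
  else parents <- sprintf("P%02d", seq_len(p))
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] >= maf_range[2])
    stop("maf_range must be within (0, 0.5] with min < max")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (n_causal > n_snps) stop("n_causal must be <= n_snps")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  max_missing <- if (missing_rate > 0) ceiling(missing_rate * p) else 0
  geno <- matrix(NA_real_, p, n_snps,
                 dimnames = list(parents, sprintf("S%05d", seq_len(n_snps))))
  for (m in seq_len(n_snps)) {
    repeat {
      q <- stats::runif(1, maf_range[1], maf_range[2])
      x <- 2 * stats::rbinom(p, 1, q)
      n_miss <- if (max_missing > 0)
        stats::rbinom(1, p, missing_rate) else 0L
      n_miss <- min(n_miss, max_missing)
      if (n_miss > 0) x[sample.int(p, n_miss)] <- NA
      obs <- x[!is.na(x)]
      f <- mean(obs) / 2
      maf <- min(f, 1 - f)
      if (.maf_above(maf, maf_range[1])) break
    }
    geno[, m] <- x
  }

  map <- data.frame(
    snp = colnames(geno),
    chrom = as.character(1 + (seq_len(n_snps) - 1) %% 10),
    pos = 1e5 * (1 + (seq_len(n_snps) - 1) %/% 10),
    alleles = "A/B",
    stringsAsFactors = FALSE
  )

  causal <- data.frame(snp = character(0), effect = numeric(0))
  parent_values <- stats::setNames(rep(0, p), parents)
  if (n_causal > 0) {
    idx <- sort(sample.int(n_snps, n_causal))
    eff <- stats::rnorm(n_causal, 0, effect_sd)
    causal <- data.frame(snp = colnames(geno)[idx], effect = eff,
                         stringsAsFactors = FALSE)
    G <- geno[, idx, drop = FALSE]
    G <- apply(G, 2, function(col) {
      col[is.na(col)] <- mean(col, na.rm = TRUE); col })
    Gc <- sweep(G, 2, colMeans(G))
    parent_values <- stats::setNames(drop(Gc %*% eff), parents)
    parent_values <- parent_values - mean(parent_values)
  }

  structure(list(geno = geno, map = map, causal = causal,
                 parent_values = parent_values),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("Marker panel:", nrow(x$geno), "parents x", ncol(x$geno), "SNPs;",
      sum(is.na(x$geno)), "missing calls;",
      nrow(x$causal), "causal SNPs\n")
  invisible(x)
}

#' Quality-control filter for SNP panels
#'
#' Retains SNPs whose minor allele frequency (on observed calls) is
#' strictly greater than `maf_min` and whose missing fraction is strictly
#' less than `max_missing`; remaining missing calls are imputed to the SNP
#' mean. Column order is preserved.
#'
#' @param markers A `marker_matrix`.
#' @param maf_min MAF threshold (strict >; default 0.05).
#' @param max_missing Missing-fraction threshold (strict <; default 0.10).
#' @return A `marker_matrix` with filtered, mean-imputed `geno` (no NAs)
#'   and the retained rows of `map`/`causal`; attribute `n_dropped` counts
#'   removed SNPs.
#' @export
filter_markers <- function(markers, maf_min = 0.05, max_missing = 0.10) {
  stopifnot(inherits(markers, "marker_matrix"))
  g <- markers$geno
  miss_frac <- colMeans(is.na(g))
  f <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  keep <- .maf_above(maf, maf_min) & miss_frac < max_missing - 1e-9
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("no SNPs survive QC (maf > ", maf_min,
                       ", missing < ", max_missing, ")")
  g <- g[, keep, drop = FALSE]
  for (j in seq_len(ncol(g))) {
    na <- is.na(g[, j])
    if (any(na)) g[na, j] <- mean(g[!na, j])
  }
  out <- markers
  out$geno <- g
  out$map <- markers$map[keep, , drop = FALSE]
  out$causal <- markers$causal[markers$causal$snp %in% colnames(g), ,
                               drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Hybrid genotypes as parental means
#'
#' The F1 of two inbred parents is heterozygous wherever they differ, so
#' its dosage at SNP m is (x_im + x_jm)/2. Only parents are genotyped;
#' hybrid rows are derived.
#'
#' @param markers A filtered `marker_matrix` (no missing calls).
#' @param design A [make_design()] object whose parents match the panel.
#' @return Numeric matrix: crosses (rownames = entries) x SNPs.
#' @export
hybrid_genotypes <- function(markers, design) {
  stopifnot(inherits(markers, "marker_matrix"))
  g <- markers$geno
  if (anyNA(g)) stop("impute or filter the panel first (missing calls)")
  missing_parents <- setdiff(design$parents, rownames(g))
  if (length(missing_parents))
    stop("parents missing from the marker panel: ",
         paste(missing_parents, collapse = ", "))
  cr <- design$crosses
  H <- (g[cr$parent1, , drop = FALSE] + g[cr$parent2, , drop = FALSE]) / 2
  rownames(H) <- cr$entry
  H
}

#' VanRaden genomic relationship matrix
#'
#' Centred cross-product relationship matrix scaled by the sum of
#' 2 p_m (1 - p_m) over SNPs: G = Z Z' / sum(2 p (1 - p)), with Z the
#' allele-frequency-centred dosage matrix. Zero-variance SNPs are excluded
#' from both the cross-product and the scaling, with a warning.
#'
#' @param geno Individuals x SNPs dosage matrix (0..2 scale; hybrid rows
#'   from [hybrid_genotypes()] may contain 0.5 steps).
#' @return Symmetric relationship matrix with class `kinship_matrix`.
#' @export
grm <- function(geno) {
  if (nrow(geno) < 2 || ncol(geno) < 1)
    stop("need >= 2 individuals and >= 1 SNP")
  freq <- colMeans(geno) / 2
  v <- 2 * freq * (1 - freq)
  zero <- v <= .Machine$double.eps
  if (any(zero)) {
    warning(sum(zero), " zero-variance SNP(s) excluded from the GRM")
    geno <- geno[, !zero, drop = FALSE]
    freq <- freq[!zero]
    v <- v[!zero]
  }
  Z <- sweep(geno, 2, 2 * freq)
  K <- tcrossprod(Z) / sum(v)
  K <- (K + t(K)) / 2
  class(K) <- c("kinship_matrix", class(K))
  K
}
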