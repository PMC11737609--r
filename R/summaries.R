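#' Pairwise trait correlations with significance thresholds
#'
#' Pairwise-complete Pearson correlations between trait columns (typically
#' across-environment BLUPs of the experimental hybrids), with two-sided
#' t-based p-values and the critical |r| at the requested alpha levels
#' computed from the t distribution with n - 2 degrees of freedom. A
#' constant trait yields NA correlations.
#'
#' @param blups Data frame or matrix, rows = entries, columns = traits.
#' @param alpha Numeric vector of significance levels for the critical-r
#'   report.
#' @return List with `r` (correlation matrix), `p` (p-value matrix), `n`
#'   (pairwise complete counts) and `critical_r` (named by alpha, at the
#'   median pairwise n).
#' @export
correlate_traits <- function(blups, alpha = c(0.05, 0.01)) {
  X <- as.matrix(blups)
  k <- ncol(X)
  r <- matrix(NA_real_, k, k, dimnames = list(colnames(X), colnames(X)))
  p <- r
  nmat <- r
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- stats::complete.cases(X[, c(i, j)])
    n <- sum(ok)
    nmat[i, j] <- n
    if (n < 3) next
    if (stats::sd(X[ok, i]) == 0 || stats::sd(X[ok, j]) == 0) next
    rr <- stats::cor(X[ok, i], X[ok, j])
    r[i, j] <- rr
    if (i == j) { p[i, j] <- 0; next }
    tt <- rr * sqrt((n - 2) / max(1 - rr^2, .Machine$double.eps))
    p[i, j] <- 2 * stats::pt(-abs(tt), n - 2)
  }
  n_med <- stats::median(nmat[upper.tri(nmat)])
  tcrit <- stats::qt(1 - alpha / 2, n_med - 2)
  critical_r <- tcrit / sqrt(n_med - 2 + tcrit^2)
  names(critical_r) <- format(alpha)
  list(r = r, p = p, n = nmat, critical_r = critical_r)
}

#' Rank hybrids and summarize groups against checks
#'
#' Sorts the experimental entries by one trait (descending for yield-type
#' traits, ascending when `ascending = TRUE` for damage scores, with entry
#' id as the deterministic tie-break) and reports, for every trait column,
#' the arithmetic group means of the top-n experimental hybrids, of all
#' experimental hybrids, and of the checks.
#'
#' @param entry_means Data frame, rows = entries; must contain the column
#'   named in `trait`; rownames (or an `entry` column) identify entries.
#' @param trait Trait to rank by.
#' @param top_n Size of the elite group (<= number of experimental
#'   entries).
#' @param check_ids Character vector of check entry ids (may be empty).
#' @param ascending Rank ascending instead of descending.
#' @return An object of class `ranking_table`: list with `ranked` (the
#'   experimental rows in rank order), `top` (first `top_n` rows), and
#'   `group_means` (data frame: group x trait columns, groups
#'   `checks`, `top_hybrids`, `all_hybrids`).
#' @export
rank_and_summarize <- function(entry_means, trait, top_n = 15,
                               check_ids = character(0),
                               ascending = FALSE) {
  df <- as.data.frame(entry_means)
  if (!"entry" %in% names(df)) df$entry <- rownames(df)
  if (!trait %in% names(df)) stop("no trait column '", trait, "'")
  unknown <- setdiff(check_ids, df$entry)
  if (length(unknown))
    stop("unknown check id(s): ", paste(unknown, collapse = ", "))
  checks <- df[df$entry %in% check_ids, , drop = FALSE]
  exper <- df[!df$entry %in% check_ids, , drop = FALSE]
  if (top_n > nrow(exper))
    stop("top_n exceeds the number of experimental entries")

  ord <- order(exper[[trait]], exper$entry,
               decreasing = c(!ascending, FALSE), method = "radix")
  ranked <- exper[ord, , drop = FALSE]
  top <- ranked[seq_len(top_n), , drop = FALSE]

  num_cols <- names(df)[vapply(df, is.numeric, logical(1))]
  gm <- rbind(
    checks = colMeans(checks[, num_cols, drop = FALSE]),
    top_hybrids = colMeans(top[, num_cols, drop = FALSE]),
    all_hybrids = colMeans(exper[, num_cols, drop = FALSE])
  )
  structure(list(ranked = ranked, top = top,
                 group_means = as.data.frame(gm)),
            class = "ranking_table")
}

#' @export
print.ranking_table <- function(x, digits = 2, ...) {
  cat("Top", nrow(x$top), "of", nrow(x$ranked), "experimental hybrids\n")
  print(round(x$group_means, digits))
  invisible(x)
}

#' Count entries below a threshold
#'
#' Number of experimental entries whose trait value is strictly below the
#' cutoff (e.g. hybrids with foliar damage score < 4 on the 1-9 scale).
#'
#' @param entry_means Data frame with the trait column (and optionally an
#'   `entry` column).
#' @param trait Trait column name.
#' @param cutoff Finite numeric threshold.
#' @return Integer count.
#' @export
count_below <- function(entry_means, trait, cutoff) {
  if (!is.finite(cutoff) && !is.infinite(cutoff))
    stop("cutoff must be numeric")
  df <- as.data.frame(entry_means)
  if (!trait %in% names(df)) stop("no trait column '", trait, "'")
  sum(df[[trait]] < cutoff, na.rm = TRUE)
}
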