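#' Construct a half-diallel trial design
#'
#' Enumerates the p(p-1)/2 unordered crosses of a set of inbred parents
#' (Griffing method 4: F1 crosses only, no selfs, no reciprocals) and lays
#' them out over environments, replicates and incomplete blocks in the style
#' of a resolvable alpha-lattice. Cross enumeration is deterministic
#' (lexicographic in parent order); block membership is randomized later, by
#' [simulate_trial()], under an explicit seed.
#'
#' @param p Number of parents (>= 4), or a character vector of parent names.
#' @param n_env Number of test environments (>= 1).
#' @param n_rep Number of replicates per environment (>= 2).
#' @param block_size Plots per incomplete block (>= 2). If it does not
#'   divide the number of entries, the last block of each replicate is
#'   short.
#' @param checks Character vector of check (commercial hybrid) entry names,
#'   appended to the entry list but excluded from diallel analysis.
#'
#' @return An object of class `diallel_design`: a list with `parents`,
#'   `crosses` (data frame with `parent1`, `parent2`, `entry`),
#'   `environments`, `n_rep`, `block_size`, `checks` and `entries`.
#' @examples
#' d <- make_design(21, n_env = 2, n_rep = 2)
#' nrow(d$crosses)  # 210
#' @export
make_design <- function(p, n_env = 2, n_rep = 2, block_size = 15,
                        checks = character(0)) {
  if (is.character(p)) {
    parents <- p
    p <- length(parents)
  } else {
    p <- as.integer(p)
    parents <- sprintf("P%02d", seq_len(p))
  }
  if (p < 4)
    stop("method-4 diallel analysis needs at least 4 parents (got ", p, ")")
  if (anyDuplicated(parents))
    stop("parent identifiers must be unique")
  n_env <- as.integer(n_env)
  n_rep <- as.integer(n_rep)
  block_size <- as.integer(block_size)
  if (n_env < 1) stop("n_env must be >= 1")
  if (n_rep < 2) stop("n_rep must be >= 2")
  if (block_size < 2) stop("block_size must be >= 2")

  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  crosses <- data.frame(
    parent1 = parents[idx[, "row"]],
    parent2 = parents[idx[, "col"]],
    stringsAsFactors = FALSE
  )
  crosses$entry <- paste(crosses$parent1, crosses$parent2, sep = "/")

  structure(
    list(
      parents = parents,
      crosses = crosses,
      environments = sprintf("E%d", seq_len(n_env)),
      n_rep = n_rep,
      block_size = block_size,
      checks = checks,
      entries = c(crosses$entry, checks)
    ),
    class = "diallel_design"
  )
}

#' @export
print.diallel_design <- function(x, ...) {
  cat("Half-diallel design (method 4):\n")
  cat("  parents:     ", length(x$parents), "\n")
  cat("  crosses:     ", nrow(x$crosses), "\n")
  cat("  checks:      ", length(x$checks), "\n")
  cat("  environments:", length(x$environments),
      " x ", x$n_rep, "reps, block size", x$block_size, "\n")
  invisible(x)
}

# plots per environment (all entries once per replicate)
n_plots_per_env <- function(design) length(design$entries) * design$n_rep
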