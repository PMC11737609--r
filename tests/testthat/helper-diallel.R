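# Shared helpers: small designs, direct model-based entry means, and an
# independent least-squares oracle for the Griffing decomposition.

# entry means generated straight from the genetic model (no field layout):
# mu + g_i + g_j + s_ij + N(0, error_sd^2)
model_entry_means <- function(design, genetics, error_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cr <- design$crosses
  y <- genetics$mu + genetics$gca[cr$parent1] + genetics$gca[cr$parent2] +
    genetics$sca[cr$entry]
  if (error_sd > 0) y <- y + rnorm(nrow(cr), 0, error_sd)
  stats::setNames(unname(y), cr$entry)
}

# Independent constrained least-squares oracle for mu + g_i + g_j with
# sum(g) = 0, via lm() on a reduced parameterization (g_p = -sum of the
# others). Returns mu and the full named gca vector.
lm_griffing_oracle <- function(means, design) {
  cr <- design$crosses[match(names(means), design$crosses$entry), ]
  parents <- design$parents
  p <- length(parents)
  X <- sapply(parents[-p], function(pp) {
    (cr$parent1 == pp | cr$parent2 == pp) -
      (cr$parent1 == parents[p] | cr$parent2 == parents[p])
  })
  fit <- lm(means ~ X)
  g <- coef(fit)[-1]
  g <- c(g, -sum(g))
  names(g) <- parents
  list(mu = unname(coef(fit)[1]), gca = g)
}

# per-parent SCA sums (should be ~0 on balanced data)
sca_parent_sums <- function(ca) {
  cr <- ca$design$crosses
  vapply(ca$design$parents, function(pp) {
    sum(ca$sca[cr$entry[cr$parent1 == pp | cr$parent2 == pp]])
  }, numeric(1))
}
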