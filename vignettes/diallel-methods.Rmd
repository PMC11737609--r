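---
title: "Combining ability and hybrid prediction in a FAW-resistance diallel: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining ability and hybrid prediction in a FAW-resistance diallel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fawdiallel)
```

## The problem

Fall armyworm (*Spodoptera frugiperda*) foliar and ear feeding is a major
yield constraint in sub-Saharan maize. Resistance breeding screens inbred
lines by crossing them in a half diallel, evaluating the F1 hybrids under
infestation, and asking two questions: *which parents transmit resistance
and yield* (combining ability), and *can untested hybrids be predicted
without field evaluation* (GCA-based and marker-based prediction). This
package implements that full analysis chain and a synthetic trial
generator that makes every stage testable.

## The model

For cross $i \times i'$ in environment $k$ the observation model is

$$
y_{ii'k} = \mu + E_k + g_i + g_{i'} + s_{ii'}
  + (Eg)_{ik} + (Eg)_{i'k} + (Es)_{ii'k} + e_{ii'k},
$$

with $g$ the general combining abilities (GCA), $s$ the specific
combining abilities (SCA), the $E\cdot$ terms their environment
interactions, and identification by the method-4 constraints
$\sum_i g_i = 0$ and $\sum_{i' \ne i} s_{ii'} = 0$ for every $i$
(F1 crosses only; no parents, no reciprocals: $p(p-1)/2$ hybrids from $p$
parents, 210 from 21). Genotype effects are treated as fixed (model 1);
replicates, incomplete blocks and environments are random.

On a complete set of cross means the estimators have closed forms
($x_{i.}$ = sum of means of crosses containing parent $i$, $x_{..}$ =
sum over all crosses):

$$
\hat\mu = \frac{2 x_{..}}{p(p-1)}, \qquad
\hat g_i = \frac{p\,x_{i.} - 2 x_{..}}{p(p-2)}, \qquad
\hat s_{ii'} = x_{ii'} - \hat\mu - \hat g_i - \hat g_{i'} .
$$

With missing crosses, `griffing_effects()` solves the same least-squares
problem under the zero-sum constraint (dense augmented normal equations,
pivot tolerance 1e-12); a parent observed in fewer than two crosses is
flagged inestimable. The tests verify that the closed forms and an
independent constrained `lm()` oracle agree to 1e-8 on random diallels of
4 to 8 parents.

## ANOVA, variance components and ratios

`diallel_anova()` computes the combining-ability ANOVA on per-environment
entry means, with sums of squares scaled by the replicate count so the
mean squares are on the plot basis. The F strata follow the standard
multi-environment convention: hybrids and environments are tested against
the hybrid-by-environment interaction, GCA against GCA×E, SCA against
SCA×E, and the interaction rows against the pooled plot-error mean square
(equivalently, on the entry-mean basis, against pooled error divided by
the replicate count — the F ratio is identical; the plot basis is used
because published tables print plot-basis mean squares).

`variance_components()` inverts the method-4 expected mean squares
($r$ replicates, $e$ environments):

$$
\hat\sigma^2_{SCA} = \frac{MS_{SCA} - MS_{SCA\times E}}{re}, \qquad
\hat\sigma^2_{GCA} = \frac{(MS_{GCA} - MS_{GCA\times E})
 - (MS_{SCA} - MS_{SCA\times E})}{re(p-2)},
$$
$$
\hat\sigma^2_{GCA\times E} = \frac{MS_{GCA\times E} - MS_{SCA\times E}}{r(p-2)},
\qquad
\hat\sigma^2_{SCA\times E} = \frac{MS_{SCA\times E} - MS_{error}}{r},
$$

with negative solutions clamped to zero, $\sigma^2_A = 2\sigma^2_{GCA}$,
$\sigma^2_D = \sigma^2_{SCA}$ and
$\sigma^2_P = \sigma^2_A + \sigma^2_D + \sigma^2_e$. The subtraction of
the SCA contrast inside the GCA line is not cosmetic: in the
random-effects derivation an i.i.d. SCA draw leaks into the GCA quadratic
form with expectation exactly $re\,\sigma^2_{SCA}$. Applied to the
shipped reference mean squares of a published 21-parent FAW diallel
(`reference_anova()`), this recipe reproduces every published
$\sigma^2_{GCA}$, $\sigma^2_{SCA}$ and $\sigma^2_{GCA\times E}$ cell to
two decimals — that reconstruction is the package's arithmetic anchor and
is asserted in the test suite.

Two reconstruction caveats, kept visible rather than smoothed over: the
published $\sigma^2_{SCA\times E}$ row matches only within rounding for
some traits (the printed mean squares are themselves rounded), and the
published error variance differs slightly from the printed error mean
square (a separate REML fit in the original workflow). For the latter
reason `variance_components()` accepts a user-supplied `sigma2_e`; the
phenotypic variance uses whichever error variance you pass, defaulting to
the ANOVA error mean square.

Derived ratios (`genetic_ratios()`): the Baker ratio
$2\sigma^2_{GCA}/(2\sigma^2_{GCA}+\sigma^2_{SCA})$ (predictability of
hybrids from parental GCA; undefined when both components vanish), the
GCA–SCA ratio (reported missing when $\sigma^2_{SCA}=0$), and broad-sense
heritability on the entry-mean basis,
$H^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{G\times E}/e +
\sigma^2_e/(re))$ with $\sigma^2_G = (MS_H - MS_{H\times E})/(re)$,
clamped to $[0,1]$. Published heritabilities are not exactly recoverable
from printed mean squares (e.g. 0.86 computed vs 0.84 printed for days to
anthesis); we report the formula value.

Effect tests use the method-4 balanced standard errors
$\mathrm{Var}(\hat g_i) = \tfrac{p-1}{p(p-2)}\,s^2$ and
$\mathrm{Var}(\hat s_{ii'}) = \tfrac{p-3}{p-1}\,s^2$, where $s^2$ is the
relevant error stratum on the across-environment entry-mean basis —
GCA×E for GCA effects and SCA×E for SCA effects, since effects averaged
over environments are judged against their instability across
environments. Two-sided t-tests, no multiplicity correction (matching
common practice in diallel reports).

## Entry means

`entry_means()` fits the two-stage mixed models with **lme4**: per
environment `value ~ entry + (1|rep) + (1|rep:block)` with entry fixed
(BLUE) or random (BLUP, shrunken toward the grand mean); across
environments the model adds environment, nests replicates and blocks in
it, and includes a random entry-by-environment term. REML throughout;
missing plots are simply absent (no imputation); singular fits (zero
variance components) are legitimate and tolerated. The tests pin the
implementation to a dense generalized-least-squares solve of the same
model on a toy 2-environment, 6-hybrid data set.

Outlier screening (`screen_outliers()`) flags plots whose standardized
residual from a per-environment entry+replicate fixed-effects fit exceeds
3.5 (no threshold is standard in the literature; 3.5 keeps the
false-flag rate per 840-plot trial well below one). Screening never
empties an entry within an environment — if every replicate of an entry
would be flagged (a discordant pair rather than a recording error), the
least extreme flag is released.

The diallel ANOVA downstream uses per-environment BLUEs (model 1 treats
genotypes as fixed); across-environment BLUPs feed the trait-correlation
summary.

## Prediction

**GCA route.** `loo_gca_predict()` deletes one cross at a time,
re-estimates $\mu$ and $g$ from the remaining crosses by constrained
least squares, and predicts $\hat\mu + \hat g_i + \hat g_j$. The reported
$r$(GCA, F1P) is the Pearson correlation between predictions and observed
means over all crosses. In the noise-free purely additive limit this
correlation is 1 by construction (asserted to 1e-9). Under a pure-noise
null the concatenated leave-one-out correlation is *not* exactly centred
at zero: re-estimating the grand mean without the held-out cross induces
a small negative leakage, about $-0.03$ at $p = 21$ against a null
standard deviation of about $0.10$. We document this rather than hide it;
the acceptance test asserts that the null mean stays below half the null
standard deviation, i.e. that the bias is noise-dominated in any single
study.

**Marker route.** Parents are genotyped; hybrids are not. Inbred parent
calls are coded 0/2, QC keeps SNPs with minor allele frequency strictly
above 0.05 and missingness strictly below 10% (boundary comparisons use a
1e-9 epsilon so a MAF of exactly 0.05 is removed regardless of floating
point), residual missing calls are imputed to the SNP mean, and hybrid
dosages are parental means. `grm()` builds the VanRaden relationship
matrix $ZZ'/\sum_m 2p_m(1-p_m)$. `gblup_cv()` fits
$y = 1\mu + u + e$, $u \sim N(0, \sigma^2_u K)$ by REML in the spectral
parameterization (eigendecomposition of $K$, profiled restricted
likelihood optimized over $\log \lambda$, $\lambda = \sigma^2_u/\sigma^2_e$),
and predicts held-out hybrids through their kinship with the training
set. The original workflow fitted a Bayesian ridge (BGLR); GBLUP is its
deterministic posterior-mean equivalent under matched hyperparameters,
which keeps the artifact dependency-free and exactly reproducible.

Cross-validation accuracy is the **mean of per-fold correlations**, the
genomic-selection convention. A correlation over the concatenated
held-out predictions carries a structural negative null bias (fold
predictions are close to their training means, which anticorrelate with
the held-out fold; we measured $-0.22$ at 45 hybrids), so it cannot
satisfy a mean-zero null calibration at any simulation size; the
concatenated value is still exposed as `r_concatenated`. Folds are a
seeded permutation at the hybrid level (both parents of a test hybrid may
appear in training crosses — the T2 scenario; predicting hybrids of
unseen parents is a harder problem out of scope here).

A note on what the synthetic study shows: the generator draws genetic
effects independently of the marker panel, yet GBLUP reaches accuracies
close to the GCA route on simulated traits. That is expected — with many
unlinked markers the genomic relationship of parental-mean hybrids
approximates the pedigree relationship of the diallel, so GBLUP recovers
the additive signal through kinship even when causal loci are not typed.
Marker-specific signal is exercised separately via `n_causal`: the
generator assigns additive effects to causal SNPs and reports the implied
parental values, giving a heritability-one benchmark where the
acceptance tests require $r > 0.95$.

## The synthetic generator

The generator's defaults are the study conditions: 21 parents, 210
crosses, 4 commercial checks (simulated as extra entries with their own
means, excluded from the diallel analysis), 2 environments × 2
replicates, incomplete blocks of 15 plots, and per-trait variance
components and grand means set to the published estimates for the nine
core traits (three foliar-damage scores FD1–FD3 and ear damage ED on the
1–9 ordinal scale, grain yield, anthesis and silking dates, plant and ear
height). Where the published tables give no value (ear-rot percentage,
exit holes, tunnelling length, anthesis–silking interval, ears per
plant), field-plausible values were chosen once and recorded in
`default_trait_params()`. Environment-effect variances are sized so
environment mean squares dominate genotypic ones, as in trials
contrasting artificial and natural infestation. Block and replicate
effects are i.i.d. normal with variances expressed as multiples of each
trait's plot-error variance (defaults 0.25 and 0.1), so one number is
meaningful across traits with very different scales.

Design choices worth stating:

* **Effect distributions** are independent normals — the standard
  quantitative-genetics assumption; published reports give only
  variances.
* **Exact constraints without recovery bias.** Raw i.i.d. draws do not
  satisfy the method-4 constraints in a finite diallel. Instead of
  discarding the off-constraint component, `simulate_genetics()`
  re-attributes the GCA-space part of the SCA draw to the GCA effects
  (an orthogonal decomposition conserving each cross's genetic value).
  The realized effects satisfy the constraints to machine precision
  *and* the data-generating process is exactly the i.i.d. model whose
  expected mean squares the estimator inverts, so the 200-simulation
  recovery test is unbiased. Consequence: the expected sample variance of
  the realized GCA effects is $\sigma^2_{GCA} + \sigma^2_{SCA}/(p-2)$,
  slightly above nominal.
* **Ordinal scores** are a latent Gaussian rounded to the nearest integer
  and clamped to 1–9 — the analysis then treats them untransformed,
  exactly as damage scores are handled in practice when residual
  diagnostics look symmetric.
* **Ear rot** is treated as a continuous adjusted percentage and *not*
  clamped at zero (published entry means include small negative values).
* **Marker QC envelope.** Each simulated SNP is redrawn until its
  realized observed-call minor allele frequency clears the lower bound of
  `maf_range` under the same strict comparison the filter uses, and
  missing calls per SNP are capped at `ceiling(missing_rate * p)`. The
  generated panel therefore passes its own QC deterministically —
  generator–filter consistency is a test, not a hope.
* **Per-trait seeds** are derived from the master seed, so adding a trait
  does not perturb the draws of the others.

What the generator does **not** emulate: spatial field trend beyond
i.i.d. blocks, correlated genetics across traits (each trait is drawn
independently, so simulated trait correlations are near zero — the
trait-correlation module is instead validated against an explicit
latent-factor construction in the tests), per-trait environment masks
(traits measured in only one environment), insect population dynamics,
and multi-year effects. Passing tests on synthetic data therefore
demonstrate correctness of the estimators under the stated model, not
robustness to field pathologies outside it.

## Numerical choices and problem sizes

Tolerances: exact identities (zero sums, reconstruction, SS partition)
are asserted at 1e-8 to 1e-10; oracle equivalences at 1e-8; REML ratio
optimization over $\log\lambda \in [-12, 12]$; kinship eigenvalues
clamped at zero, with a 1e-8 ridge only if the matrix is fully
degenerate (logged). Monte-Carlo contracts use 3 standard errors. The
test suite simulates at the full 21-parent scale where the claim is about
that scale (recovery over 200 trials, null prediction over 60–100 seeds)
and at 4–10 parents where the claim is structural; the complete suite
runs in under a minute, and the end-to-end pipeline (9 traits, 2,000
SNPs, fivefold CV, run twice for byte-identity) in well under five
minutes on one CPU.

## Known limitations

* The unbalanced Griffing path estimates SCA as residuals of observed
  crosses; with many missing crosses the SCA zero-sum identities hold
  only in the least-squares sense.
* Heterogeneous error variances per environment and spatial (row-column)
  adjustment are not modelled.
* Only the default T2-style hybrid-level CV is provided; T0/T1 taxonomies
  (unseen parents) are out of scope.
* Griffing methods 1–3 (selfs and reciprocals) are not implemented.
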