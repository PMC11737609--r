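#' Reference summary tables from a published 21-parent FAW diallel trial
#'
#' The package ships, as plain-text fixtures, the printed summary surfaces
#' of a 21-parent, 210-hybrid maize diallel evaluated under fall-armyworm
#' infestation in two Kenyan environments (2 replicates each): the
#' across-environment combining-ability ANOVA mean squares, the published
#' variance components, the per-parent GCA effects, and the trial means of
#' the top 15 hybrids and 4 commercial checks. They serve as worked-input
#' examples and as cross-checks of the expected-mean-squares arithmetic;
#' the underlying plot data are not public.
#'
#' @param table One of `"anova_ms"`, `"variance_components"`,
#'   `"gca_effects"`, `"trial_means"`.
#' @return A data frame.
#' @export
reference_table <- function(table = c("anova_ms", "variance_components",
                                      "gca_effects", "trial_means")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0("reference_", table, ".csv"),
                      package = "fawdiallel", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Assemble a reference ANOVA table for one trait
#'
#' Builds a [diallel_anova()]-compatible object from the shipped reference
#' mean squares, so that [variance_components()] and [genetic_ratios()]
#' can be applied to the published analysis (p = 21 parents, e = 2
#' environments, r = 2 replicates).
#'
#' @param trait Trait column of the reference table (e.g. `"GY"`, `"AD"`,
#'   `"PH"`).
#' @return A `diallel_anova` object.
#' @export
reference_anova <- function(trait) {
  ref <- reference_table("anova_ms")
  if (!trait %in% names(ref))
    stop("no reference mean squares for trait '", trait, "'")
  tab <- data.frame(source = ref$source, df = ref$df, ms = ref[[trait]],
                    stringsAsFactors = FALSE)
  tab$ss <- tab$ms * tab$df
  tab$f <- NA_real_
  tab$p <- NA_real_
  tab$denominator <- NA_character_
  denom_of <- c(Environment = "HxE", "Rep(Env)" = "Error", Hybrids = "HxE",
                GCA = "GCAxE", SCA = "SCAxE",
                HxE = "Error", GCAxE = "Error", SCAxE = "Error")
  for (i in seq_len(nrow(tab))) {
    den <- denom_of[tab$source[i]]
    if (is.na(den)) next
    j <- match(den, tab$source)
    tab$f[i] <- tab$ms[i] / tab$ms[j]
    tab$p[i] <- stats::pf(tab$f[i], tab$df[i], tab$df[j], lower.tail = FALSE)
    tab$denominator[i] <- unname(den)
  }
  tab <- tab[, c("source", "df", "ss", "ms", "f", "p", "denominator")]
  attr(tab, "p") <- 21L
  attr(tab, "e") <- 2L
  attr(tab, "r") <- 2L
  class(tab) <- c("diallel_anova", "data.frame")
  tab
}
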