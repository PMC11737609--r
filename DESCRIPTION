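Package: fawdiallel
Title: Diallel Combining Ability and Hybrid Prediction for Fall Armyworm
    Resistance Breeding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Griffing model-1 method-4 combining-ability analysis for
    half-diallel maize trials evaluated under fall-armyworm infestation:
    general and specific combining ability (GCA/SCA) effects with t-tests,
    the across-environment ANOVA on entry means, expected-mean-squares
    variance components, Baker ratio and entry-mean heritability. Hybrid
    performance is predicted two ways, from parental GCA with
    leave-one-hybrid-out cross-validation and from parental SNP panels with
    GBLUP under k-fold cross-validation. A synthetic diallel-trial generator
    (alpha-lattice layout, ordinal 1-9 damage scores, parental marker
    panels with known causal effects) makes every stage testable end to end
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
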