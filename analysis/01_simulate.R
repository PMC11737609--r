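#!/usr/bin/env Rscript
# Stage 1: generate the synthetic diallel study.
#
# 21 inbred parents crossed in a half diallel (210 F1 hybrids, no parents,
# no reciprocals), plus 4 commercial checks, evaluated in 2 environments x
# 2 replicates in incomplete blocks; 9 traits at the variance components
# and trial means of the multi-environment FAW diallel the package
# emulates; a 2,000-SNP parental panel with 200 causal loci.

library(fawdiallel)

seed <- 20260928L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- make_design(21, n_env = 2, n_rep = 2, block_size = 15,
                      checks = c("DH04", "DK8031", "Duma43", "WE1101"))
print(design)

params <- default_trait_params()
params <- params[params$trait %in% c("GY", "FD1", "FD2", "FD3", "ED",
                                     "AD", "SD", "PH", "EH"), ]
sim <- simulate_study(design, params, seed = seed)
write_plot_csv(sim$plots, file.path(out, "plots.csv"))
write_truth(sim$genetics, file.path(out, "truth.csv"))
cat("plots:", nrow(sim$plots), "rows x", nrow(params), "traits ->",
    file.path(out, "plots.csv"), "\n")

markers <- simulate_markers(design$parents, n_snps = 2000,
                            maf_range = c(0.05, 0.5), missing_rate = 0.02,
                            n_causal = 200, seed = seed + 7919L)
print(markers)
write_markers(markers, file.path(out, "markers.hmp.txt"), format = "hapmap")
write_markers(markers, file.path(out, "markers.vcf"), format = "vcf")
cat("marker panel written as HapMap-style table and minimal VCF\n")
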