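#!/usr/bin/env Rscript
# Stage 5: summary surfaces -- trait correlations on across-environment
# BLUPs, hybrid ranking against the commercial checks, and counts of
# hybrids under foliar-damage thresholds.

library(fawdiallel)

design <- make_design(21, n_env = 2, n_rep = 2, block_size = 15,
                      checks = c("DH04", "DK8031", "Duma43", "WE1101"))
plots <- read_plot_csv("results/data/plots.csv")
means <- read.csv("results/entry_means/entry_means.csv",
                  stringsAsFactors = FALSE)
out <- "results/summaries"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

traits <- c("GY", "FD1", "FD2", "FD3", "ED", "AD", "SD", "PH", "EH")
blup <- means[means$estimator == "BLUP", ]
blup_mat <- sapply(traits, function(tr) {
  b <- blup[blup$trait == tr, ]
  setNames(b$value, b$entry)[design$crosses$entry]
})
ct <- correlate_traits(blup_mat)
cat("critical |r| at alpha 0.05 / 0.01:",
    round(ct$critical_r[1], 3), "/", round(ct$critical_r[2], 3), "\n")
cat(sprintf("r(GY, ED) = %5.2f   r(AD, SD) = %5.2f   r(PH, EH) = %5.2f\n",
            ct$r["GY", "ED"], ct$r["AD", "SD"], ct$r["PH", "EH"]))
wide <- as.data.frame(ct$r)
wide <- cbind(trait = rownames(wide), wide)
write.csv(wide, file.path(out, "correlations_wide.csv"), row.names = FALSE)
long <- data.frame(
  trait1 = rownames(ct$r)[row(ct$r)[upper.tri(ct$r)]],
  trait2 = colnames(ct$r)[col(ct$r)[upper.tri(ct$r)]],
  r = ct$r[upper.tri(ct$r)], p = ct$p[upper.tri(ct$p)])
write.csv(long, file.path(out, "correlations_long.csv"), row.names = FALSE)

# ranking for grain yield with checks, from across-env BLUEs
tab <- NULL
for (tr in traits) {
  b <- entry_means(plots, tr, scope = "across", estimator = "BLUE")
  col <- setNames(b$value, b$entry)
  tab <- if (is.null(tab)) data.frame(entry = names(col), v = col)
         else cbind(tab, v = col[tab$entry])
  names(tab)[ncol(tab)] <- tr
}
rk <- rank_and_summarize(tab, "GY", top_n = 15, check_ids = design$checks)
print(rk)
write.csv(rk$top, file.path(out, "top_hybrids.csv"), row.names = FALSE)
write.csv(cbind(group = rownames(rk$group_means), rk$group_means),
          file.path(out, "group_means.csv"), row.names = FALSE)

hyb <- tab[!tab$entry %in% design$checks, ]
for (tr in c("FD1", "FD2", "FD3"))
  cat(tr, ": ", count_below(hyb, tr, 4), "of", nrow(hyb),
      "hybrids score below 4\n")
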