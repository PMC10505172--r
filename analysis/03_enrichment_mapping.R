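#!/usr/bin/env Rscript
# Step 3 — map enrichment onto the parent proteins.
#
# Computes total log2E and the promiscuity set, then builds the per-residue
# rlog2E profile of each parent (rolling-median smoothed, k = 7), calls
# regions of interest above the upper 95% CI bound of the median rlog2E, and
# compares the top ROI with the planted binding interval.

library(phagescan)

sim <- readRDS("scratch/campaign.rds")

tot <- total_log2E(sim$enrichment)
tot <- tot[order(-tot$total_log2E), ]
write.table(tot, "results/total_log2E.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
prom <- promiscuous_peptides(sim$enrichment, min_chemokines = 3, threshold = 5)
cat(sprintf("promiscuous peptides (log2E > 5 in >= 3 chemokines): %d\n",
            length(prom)))
cat(sprintf("top peptide by total log2E: %s (%.1f)\n",
            tot$peptide_id[1], tot$total_log2E[1]))

for (i in seq_len(nrow(sim$parents))) {
  parent <- sim$parents[i, ]
  pr <- residue_profile(sim$enrichment, sim$library, parent)
  write_profile_tsv(pr, sprintf("results/profile_%s.tsv", parent$id),
                    sprintf("results/roi_%s.tsv", parent$id))
  tr <- sim$truth[sim$truth$parent_id == parent$id, ]
  top <- top_roi(pr)
  jac <- if (is.null(top)) 0 else interval_jaccard(top, c(tr$start, tr$end))
  cat(sprintf("%s: %d ROI; top ROI %s vs planted [%d,%d]; Jaccard %.2f\n",
              parent$id, nrow(pr$roi),
              if (is.null(top)) "none" else sprintf("[%d,%d]", top[1], top[2]),
              tr$start, tr$end, jac))
}

# enrichment tracks the planted affinities
la <- log2(sim$affinities)
idx <- cbind(match(sim$enrichment$peptide_id, rownames(la)),
             match(sim$enrichment$chemokine_id, colnames(la)))
rho <- cor(sim$enrichment$log2E, la[idx], method = "spearman")
cat(sprintf("Spearman(log2E, planted log2 affinity): %.3f\n", rho))
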