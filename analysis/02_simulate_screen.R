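#!/usr/bin/env Rscript
# Step 2 — simulate the phage-display screen and count reads.
#
# Runs three rounds of affinity-weighted panning of the step-1 library
# against a four-chemokine panel, emits paired amplicon FASTQ for the input
# pool and each selected population, and converts the reads back into
# peptide count tables through the full filter cascade.

library(phagescan)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)
seed <- 20240901  # master seed shared by steps 1-4

sim <- simulate_campaign(seed = seed, n_parents = 3,
                         chemokines = paste0("CK", 1:4), depth = 1e5,
                         via_fastq = TRUE, error_rate = 0.001,
                         dir = "scratch", embed_hd2 = TRUE)

write_count_tsv(sim$input, "results/counts_input.tsv")
for (chem in names(sim$outputs)) {
  write_count_tsv(sim$outputs[[chem]], sprintf("results/counts_%s.tsv", chem))
}
write_enrichment_tsv(sim$enrichment, "results/enrichment.tsv")
saveRDS(sim, "scratch/campaign.rds")  # carried to steps 3-4

eff <- cloning_efficiency(sim$input, sim$library)
cat(sprintf("simulated %d peptides x %d chemokines at depth 1e5\n",
            length(sim$library$distinct_peptides), length(sim$outputs)))
cat(sprintf("cloning efficiency of the simulated input pool: %.1f%%\n",
            100 * eff))
cat(sprintf("enrichment entries (recovered peptide x chemokine): %d\n",
            nrow(sim$enrichment)))
cat(sprintf("log2E range: [%.2f, %.2f]\n", min(sim$enrichment$log2E),
            max(sim$enrichment$log2E)))
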