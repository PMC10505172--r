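#!/usr/bin/env Rscript
# Step 1 — design the tiled display library.
#
# Builds a synthetic panel of Cys-rich parent proteins (parent 1 carries the
# HD2 hexadecapeptide verbatim inside its planted binding interval), tiles
# them into hexadecapeptides overlapping by a single residue, adds the joint
# Cys->Ala and Cys->Ser variants, designs the scrambled HD2 control, and
# writes the member table plus the 81-mer oligonucleotide pool.

library(phagescan)

dir.create("results", showWarnings = FALSE)
seed <- 20240901  # master seed shared by steps 1-4

# same parents substream as simulate_campaign(seed) uses in step 2
gen <- make_parents(n = 3, seed = substream_seed(seed, "parents"), embed_hd2 = TRUE)
lib <- design_library(gen$parents)
write_parents_fasta(gen$parents, "results/parents.fasta")
write_library_tsv(lib, "results/library_members.tsv", "results/oligo_pool.fasta")

hd2_tile <- lib$members[lib$members$sequence == HD2, ][1, ]
scr <- design_scrambled(hd2_tile, n_shuffles = 50, seed = seed)

cat(sprintf("parents: %d (lengths %s)\n", nrow(gen$parents),
            paste(nchar(gen$parents$sequence), collapse = ", ")))
print(lib)
cat(sprintf("distinct peptides: %d; oligos: %d x %d nt\n",
            length(lib$distinct_peptides), nrow(lib$oligos),
            unique(nchar(lib$oligos$oligo_nt))))
cat(sprintf("HD2 tile found at %s:%d; scrambled control %s (osa distance %s)\n",
            hd2_tile$parent_id, hd2_tile$start, scr$sequence,
            sub("osa=", "", scr$mutation_label)))
cat(sprintf("planted binding intervals:\n"))
print(gen$truth, row.names = FALSE)
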