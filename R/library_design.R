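## Tiled hexadecapeptide library design: wild-type tiles, Cys->Ala/Ser
## variants, NNK saturation mutants, scrambled controls, and the arm-flanked
## 81-mer oligonucleotides that encode them.

new_variant_table <- function(peptide_id = character(), parent_id = character(),
                              start = integer(), sequence = character(),
                              variant_class = character(),
                              mutation_label = character()) {
  data.frame(peptide_id = peptide_id, parent_id = parent_id,
             start = as.integer(start), sequence = sequence,
             variant_class = variant_class, mutation_label = mutation_label,
             stringsAsFactors = FALSE)
}

#' Tile a parent protein into overlapping hexadecapeptides
#'
#' Slides a `window`-residue window along the mature protein sequence with a
#' step of one residue, so a protein of length L yields exactly
#' `L - window + 1` wild-type tiles. Start coordinates are 1-based on the
#' mature protein.
#'
#' @param protein List or data.frame row with fields `id` and `sequence`
#'   (mature protein, standard amino acids).
#' @param window Tile length in residues (default 16).
#' @return Data frame of peptide variants with columns `peptide_id`,
#'   `parent_id`, `start`, `sequence`, `variant_class` (`"WT"`),
#'   `mutation_label` (`""`).
#' @export
tile_peptides <- function(protein, window = 16L) {
  seq <- toupper(protein$sequence)
  stopifnot_aa(seq, sprintf("protein '%s'", protein$id))
  L <- nchar(seq)
  if (L < window) {
    stop(sprintf("protein '%s' (length %d) is shorter than the tiling window (%d)",
                 protein$id, L, window), call. = FALSE)
  }
  starts <- seq_len(L - window + 1L)
  tiles <- substring(seq, starts, starts + window - 1L)
  new_variant_table(
    peptide_id = sprintf("%s_t%03d_WT", protein$id, starts),
    parent_id = protein$id, start = starts, sequence = tiles,
    variant_class = "WT", mutation_label = "")
}

#' Cys-to-Ala and Cys-to-Ser variants of a wild-type tile
#'
#' Every Cys in the tile is mutated simultaneously: one variant replaces all
#' Cys with Ala and a second replaces all Cys with Ser. Tiles without Cys
#' yield no variants.
#'
#' @param peptide One-row data frame (or list) as produced by
#'   [tile_peptides()], `variant_class == "WT"`.
#' @return Data frame with 0 or 2 variant rows (`CYS_TO_ALA`, `CYS_TO_SER`);
#'   `mutation_label` lists the per-Cys substitutions, e.g. `"C13A"` or
#'   `"C3A+C7A"` relative to the tile.
#' @export
make_cys_variants <- function(peptide) {
  if (!identical(peptide$variant_class, "WT")) {
    stop("make_cys_variants() expects a wild-type tile", call. = FALSE)
  }
  seq <- peptide$sequence
  cys_pos <- which(strsplit(seq, "")[[1]] == "C")
  if (length(cys_pos) == 0L) return(new_variant_table())
  label <- function(to) paste(sprintf("C%d%s", cys_pos, to), collapse = "+")
  new_variant_table(
    peptide_id = paste0(sub("_WT$", "", peptide$peptide_id), c("_CA", "_CS")),
    parent_id = peptide$parent_id, start = rep(peptide$start, 2L),
    sequence = c(gsub("C", "A", seq, fixed = TRUE),
                 gsub("C", "S", seq, fixed = TRUE)),
    variant_class = c("CYS_TO_ALA", "CYS_TO_SER"),
    mutation_label = c(label("A"), label("S")))
}

#' Reverse-translate a hexadecapeptide into a 48-nt insert
#'
#' Uses a deterministic one-codon-per-residue table; the result always
#' translates back to the peptide in frame 0 under the standard genetic code.
#'
#' @param peptide_seq 16-residue amino-acid string (any length is accepted;
#'   the insert is 3x the peptide length).
#' @param codon_map Named codon vector covering every residue used
#'   (default [ecoli_codon_table()]); must be stop-free.
#' @return DNA string of length `3 * nchar(peptide_seq)`.
#' @export
encode_insert <- function(peptide_seq, codon_map = ecoli_codon_table()) {
  res <- strsplit(toupper(peptide_seq), "")[[1]]
  missing <- setdiff(unique(res), names(codon_map))
  if (length(missing) > 0L) {
    stop(sprintf("codon map lacks residues: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (any(translate_nt(unname(codon_map)) == "*")) {
    stop("codon map contains a stop codon", call. = FALSE)
  }
  paste(codon_map[res], collapse = "")
}

#' Assemble the 81-mer library oligonucleotide
#'
#' Flanks a 48-nt insert with the two cloning arms ([ARM5], [ARM3]) used for
#' amplification and cloning, giving an 81-mer.
#'
#' @param insert 48-nt DNA string.
#' @return 81-nt DNA string `ARM5 + insert + ARM3`.
#' @export
build_oligo <- function(insert) {
  if (nchar(insert) != 48L) {
    stop(sprintf("insert must be 48 nt, got %d", nchar(insert)), call. = FALSE)
  }
  if (grepl("[^ACGT]", insert)) stop("insert must be unambiguous DNA", call. = FALSE)
  paste0(ARM5, insert, ARM3)
}

## Amino acids encodable by an NNK codon (N = A/C/G/T, K = G/T): all 20;
## the only stop reachable is TAG, which is dropped.
nnk_amino_acids <- function() {
  codons <- as.vector(outer(
    as.vector(outer(c("A","C","G","T"), c("A","C","G","T"), paste0)),
    c("G","T"), paste0))
  aa <- translate_nt(codons)
  sort(unique(aa[aa != "*"]))
}

#' NNK saturation-mutagenesis library of a hexadecapeptide
#'
#' For each of the 16 positions, emits every protein-level variant encodable
#' by an NNK degenerate codon (all 20 amino acids; the TAG stop is excluded).
#' The parental identity at each position is encodable and is represented by
#' the single parental record; point mutants are deduplicated by sequence.
#'
#' @param peptide One-row data frame/list with at least `peptide_id`,
#'   `parent_id`, `start`, `sequence` (16 residues).
#' @return Data frame: one `WT` row (the parent peptide) plus one
#'   `POINT_MUTANT` row per distinct single-residue substitution
#'   (16 positions x 19 non-parental residues), with `mutation_label` such as
#'   `"T6E"` (position within the peptide).
#' @export
nnk_mutant_library <- function(peptide) {
  seq <- toupper(peptide$sequence)
  if (nchar(seq) != 16L) stop("NNK scan expects a 16-residue peptide", call. = FALSE)
  res <- strsplit(seq, "")[[1]]
  aa <- nnk_amino_acids()
  out <- list(new_variant_table(
    peptide_id = peptide$peptide_id, parent_id = peptide$parent_id,
    start = peptide$start, sequence = seq,
    variant_class = "WT", mutation_label = ""))
  for (pos in seq_len(16L)) {
    muts <- setdiff(aa, res[pos])
    seqs <- vapply(muts, function(m) {
      s <- res; s[pos] <- m; paste(s, collapse = "")
    }, character(1))
    out[[pos + 1L]] <- new_variant_table(
      peptide_id = sprintf("%s_%s%d%s", peptide$peptide_id, res[pos], pos, muts),
      parent_id = peptide$parent_id, start = peptide$start, sequence = seqs,
      variant_class = "POINT_MUTANT",
      mutation_label = sprintf("%s%d%s", res[pos], pos, muts))
  }
  lib <- do.call(rbind, out)
  lib[!duplicated(lib$sequence), , drop = FALSE]
}

#' Design a scrambled (shuffled) control peptide
#'
#' Generates `n_shuffles` seeded random permutations of the peptide and keeps
#' the one with the largest optimal-string-alignment distance to the
#' wild-type ([osa_distance()]); ties broken by generation order.
#'
#' @param peptide One-row data frame/list with `sequence` (and optionally
#'   ids carried through).
#' @param n_shuffles Number of random shuffles to draw (default 50).
#' @param seed Integer seed making the design deterministic.
#' @return Data frame with one `SCRAMBLED` row; `mutation_label` records the
#'   achieved OSA distance as `"osa=<d>"`.
#' @export
design_scrambled <- function(peptide, n_shuffles = 50L, seed = 1L) {
  stopifnot(n_shuffles >= 1L)
  seq <- peptide$sequence
  res <- strsplit(seq, "")[[1]]
  set.seed(seed)
  cand <- vapply(seq_len(n_shuffles), function(i) {
    paste(sample(res), collapse = "")
  }, character(1))
  d <- vapply(cand, osa_distance, numeric(1), b = seq)
  best <- which.max(d)  # first maximal candidate in generation order
  new_variant_table(
    peptide_id = paste0(peptide$peptide_id %||% "peptide", "_SCR"),
    parent_id = peptide$parent_id %||% "", start = peptide$start %||% NA_integer_,
    sequence = cand[best], variant_class = "SCRAMBLED",
    mutation_label = sprintf("osa=%d", as.integer(d[best])))
}

#' Design the full tiled display library for a set of parent proteins
#'
#' Tiles each parent into overlapping hexadecapeptides, adds the joint
#' Cys-to-Ala and Cys-to-Ser variant of every Cys-containing tile, and
#' reverse-translates each distinct peptide into its arm-flanked 81-mer
#' oligonucleotide.
#'
#' @param parents Data frame with columns `id`, `sequence` (mature proteins).
#' @param window Tile length (default 16).
#' @param codon_map Codon table for [encode_insert()].
#' @return List of class `designed_library`: `members` (variant table),
#'   `oligos` (data frame `peptide_id`, `insert_nt`, `oligo_nt`), and
#'   `distinct_peptides` (unique peptide sequences).
#' @export
design_library <- function(parents, window = 16L, codon_map = ecoli_codon_table()) {
  members <- list()
  for (i in seq_len(nrow(parents))) {
    tiles <- tile_peptides(parents[i, ], window = window)
    members[[length(members) + 1L]] <- tiles
    for (j in seq_len(nrow(tiles))) {
      cv <- make_cys_variants(tiles[j, ])
      if (nrow(cv) > 0L) members[[length(members) + 1L]] <- cv
    }
  }
  members <- do.call(rbind, members)
  rownames(members) <- NULL
  inserts <- vapply(members$sequence, encode_insert, character(1),
                    codon_map = codon_map, USE.NAMES = FALSE)
  oligos <- data.frame(peptide_id = members$peptide_id, insert_nt = inserts,
                       oligo_nt = vapply(inserts, build_oligo, character(1),
                                         USE.NAMES = FALSE),
                       stringsAsFactors = FALSE)
  structure(list(members = members, oligos = oligos,
                 distinct_peptides = unique(members$sequence)),
            class = "designed_library")
}

#' @export
print.designed_library <- function(x, ...) {
  cat(sprintf("designed_library: %d members (%d distinct peptides) from %d parents\n",
              nrow(x$members), length(x$distinct_peptides),
              length(unique(x$members$parent_id))))
  print(table(x$members$variant_class))
  invisible(x)
}
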