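## Plain-text interchange: FASTA for proteins and oligos, TSV for library,
## count, enrichment and profile tables.

#' Read mature parent proteins from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Data frame `id`, `sequence`.
#' @export
read_parents_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  data.frame(id = sub("[ \t].*$", "", names(x)), sequence = as.character(x),
             stringsAsFactors = FALSE)
}

#' Write parent proteins to FASTA
#' @param parents Data frame `id`, `sequence`.
#' @param path Output path.
#' @export
write_parents_fasta <- function(parents, path) {
  x <- Biostrings::AAStringSet(stats::setNames(parents$sequence, parents$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write the designed library as TSV (members) and FASTA (81-mer oligos)
#'
#' @param library A `designed_library`.
#' @param tsv_path Members TSV path.
#' @param fasta_path Optional oligo FASTA path (header = peptide id).
#' @export
write_library_tsv <- function(library, tsv_path, fasta_path = NULL) {
  utils::write.table(library$members, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(fasta_path)) {
    x <- Biostrings::DNAStringSet(stats::setNames(library$oligos$oligo_nt,
                                                  library$oligos$peptide_id))
    Biostrings::writeXStringSet(x, fasta_path)
  }
  invisible(tsv_path)
}

#' Read a designed library back from its members TSV
#'
#' Rebuilds the oligo table deterministically from the member sequences.
#' @param tsv_path Members TSV path.
#' @param codon_map Codon table (default [ecoli_codon_table()]).
#' @return A `designed_library`.
#' @export
read_library_tsv <- function(tsv_path, codon_map = ecoli_codon_table()) {
  members <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  members$mutation_label[is.na(members$mutation_label)] <- ""
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

#' Write a per-sample count table as TSV
#' @param table A [count_table()].
#' @param path Output path.
#' @export
write_count_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an enrichment table (long format) as TSV
#' @param table An `enrichment_table`.
#' @param path Output path.
#' @export
write_enrichment_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a residue profile (and its ROI intervals) as TSV
#'
#' @param profile A `residue_profile`.
#' @param path Profile TSV path.
#' @param roi_path Optional BED-like ROI TSV (`parent_id`, `start`, `end`;
#'   1-based inclusive).
#' @export
write_profile_tsv <- function(profile, path, roi_path = NULL) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(roi_path)) {
    roi <- profile$roi
    roi <- cbind(parent_id = rep(profile$parent_id, nrow(roi)), roi)
    utils::write.table(roi, roi_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
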