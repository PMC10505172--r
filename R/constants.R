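## Amplicon landmark sequences used throughout the pipeline.

#' Cloning-arm and amplicon landmark sequences
#'
#' Fixed nucleotide landmarks of the display construct: the two cloning arms
#' flanking every 48-nt insert inside the 81-mer library oligonucleotide, the
#' forward/reverse demultiplexing motifs of the sequencing amplicon, and the
#' two constant regions used to delimit the insert within a read.
#'
#' @format Named length-one character strings.
#' @name landmarks
NULL

#' @rdname landmarks
#' @export
ARM5 <- "GCAGCCTCTTCATCTGGC"

#' @rdname landmarks
#' @export
ARM3 <- "GGTGGAGGATCCGGA"

#' @rdname landmarks
#' @export
DEMUX_FWD <- "CTAGCGCT"

#' @rdname landmarks
#' @export
DEMUX_REV <- "CGCAGACG"

## 5' constant region of the sequencing amplicon; its 3' end fixes the
## translation frame of the insert. Note the last 18 nt equal ARM5.
#' @rdname landmarks
#' @export
CONST5 <- "ATGCCTATGCAGCCTCTTCATCTGGC"

## Full 3' constant region (vector backbone downstream of the insert).
#' @rdname landmarks
#' @export
CONST3 <- paste0(
  "GGTGGAGGATCCGGAGGAGGCGCCGAGGGTGACGATCCCGCAAAAGCGGCCTTTAACTCC",
  "CTGCAAGCCTCAGCGACCGAATATATCGGTTATGCGTGGGCGATGGTTGTTGTCAT"
)

## Printed hexadecapeptide HD2 and its designed scrambled control, plus the
## NMR-derived EVA4 octadecapeptide; used in examples and fixtures.
#' Reference peptides
#'
#' The promiscuous chemokine-binding hexadecapeptide HD2, its scrambled
#' control HD2SCR (an anagram maximising optimal-string-alignment distance),
#' and the EVA4-derived octadecapeptide that differs from HD2 at three
#' positions.
#' @name reference_peptides
NULL

#' @rdname reference_peptides
#' @export
HD2 <- "EEDDYTAYAPLTCYFT"

#' @rdname reference_peptides
#' @export
HD2SCR <- "TLETDTFYECPDAYAY"

#' @rdname reference_peptides
#' @export
EV4_PEPTIDE <- "EEEDDYTAYAPLTAYFTN"

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Default single-codon table (most-used E. coli codon per amino acid)
#'
#' Deterministic amino-acid to codon map used to reverse-translate designed
#' peptides into 48-nt inserts. Any stop-free total map may be supplied in
#' its place; all downstream matching is at the protein level, so the codon
#' choice never changes analysis results.
#'
#' @return Named character vector: 20 codons named by one-letter residue.
#' @export
ecoli_codon_table <- function() {
  c(A = "GCG", R = "CGT", N = "AAC", D = "GAT", C = "TGC",
    Q = "CAG", E = "GAA", G = "GGC", H = "CAT", I = "ATT",
    L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCG",
    S = "AGC", T = "ACC", W = "TGG", Y = "TAT", V = "GTG")
}

## Translate a vector of in-frame DNA strings to peptides (standard code).
translate_nt <- function(nt) {
  if (length(nt) == 0L) return(character(0))
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                     no.init.codon = TRUE))
}

revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(nt)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_aa <- function(seq, what = "sequence") {
  bad <- grepl(sprintf("[^%s]", paste(AA20, collapse = "")), seq)
  if (any(bad)) {
    stop(sprintf("%s contains non-standard residues: %s", what,
                 paste(utils::head(seq[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(seq)
}
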