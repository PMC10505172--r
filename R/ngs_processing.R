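## Paired-end amplicon processing: join mates by read id, extract the 48-nt
## insert between the constant regions, apply the fixed filter cascade, and
## count library peptides.

INSERT_STATUSES <- c("MISSING_DEMUX", "MISSING_CONSTANT", "MATE_MISMATCH",
                     "AMBIGUOUS_BASE", "WRONG_SIZE", "NOT_IN_LIBRARY", "OK")

#' Construct a per-sample peptide count table
#'
#' @param sample_id Sample label.
#' @param counts Named non-negative integer vector (names = `peptide_id`,
#'   one entry per distinct library peptide; zeros allowed).
#' @return Data frame of class `count_table` with columns `peptide_id`,
#'   `count`, `frequency` (count over total counted) and attribute
#'   `sample_id`.
#' @export
count_table <- function(sample_id, counts) {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop(sprintf("sample '%s' has zero counted reads", sample_id),
                       call. = FALSE)
  out <- data.frame(peptide_id = names(counts), count = as.numeric(counts),
                    frequency = as.numeric(counts) / total,
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- sample_id
  class(out) <- c("count_table", class(out))
  out
}

strip_mate_suffix <- function(ids) {
  sub("/[12]$", "", sub("[ \t].*$", "", ids))
}

read_fastq_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = strip_mate_suffix(names(x)),
             seq = as.character(x), stringsAsFactors = FALSE)
}

#' Join paired FASTQ files by read id
#'
#' Mates are matched on the read id after stripping any `/1`/`/2` suffix and
#' comment; unpaired reads on either side are dropped and their number
#' reported.
#'
#' @param fastq1,fastq2 Paths to the two FASTQ files (optionally gzipped).
#' @return Data frame with columns `read_id`, `read1`, `read2`; attribute
#'   `n_unpaired` gives the number of dropped single-end reads.
#' @export
join_pairs <- function(fastq1, fastq2) {
  r1 <- read_fastq_seqs(fastq1)
  r2 <- read_fastq_seqs(fastq2)
  common <- intersect(r1$read_id, r2$read_id)
  out <- data.frame(read_id = common,
                    read1 = r1$seq[match(common, r1$read_id)],
                    read2 = r2$seq[match(common, r2$read_id)],
                    stringsAsFactors = FALSE)
  n_unpaired <- (nrow(r1) - length(common)) + (nrow(r2) - length(common))
  if (n_unpaired > 0) {
    message(sprintf("join_pairs: dropped %d unpaired reads", n_unpaired))
  }
  attr(out, "n_unpaired") <- n_unpaired
  out
}

#' Extract and filter candidate inserts from joined read pairs
#'
#' Mate 2 is reverse-complemented, then both mates are screened for the
#' forward/reverse demultiplexing motifs and both constant regions (exact
#' substring match). The candidate insert is the sequence between the end of
#' the 5' constant and the start of the 3' constant in each mate. Each pair
#' receives exactly one status, assigned in the fixed order
#' `MISSING_DEMUX` -> `MISSING_CONSTANT` -> `MATE_MISMATCH` ->
#' `AMBIGUOUS_BASE` -> `WRONG_SIZE` -> `NOT_IN_LIBRARY` -> `OK`.
#'
#' @param pairs Data frame from [join_pairs()].
#' @param library A `designed_library` (peptide matching is at the
#'   translated-protein level).
#' @return Data frame: `read_id`, `insert_nt` (NA until both constants are
#'   found), `peptide` (NA unless translatable), `status`.
#' @export
extract_inserts <- function(pairs, library) {
  r1 <- pairs$read1
  rc2 <- revcomp(pairs$read2)
  n <- length(r1)
  status <- rep(NA_character_, n)
  insert <- rep(NA_character_, n)
  peptide <- rep(NA_character_, n)

  const3_probe <- substr(CONST3, 1L, 15L)
  has_demux <- grepl(DEMUX_FWD, r1, fixed = TRUE) &
    grepl(DEMUX_REV, rc2, fixed = TRUE)
  status[!has_demux] <- "MISSING_DEMUX"

  p5_1 <- regexpr(CONST5, r1, fixed = TRUE)
  p3_1 <- regexpr(const3_probe, r1, fixed = TRUE)
  p5_2 <- regexpr(CONST5, rc2, fixed = TRUE)
  p3_2 <- regexpr(const3_probe, rc2, fixed = TRUE)
  w5 <- nchar(CONST5)
  ok_const <- p5_1 > 0 & p3_1 > p5_1 + w5 - 1L & p5_2 > 0 & p3_2 > p5_2 + w5 - 1L
  live <- is.na(status)
  status[live & !ok_const] <- "MISSING_CONSTANT"
  live <- is.na(status)

  ins1 <- substr(r1, p5_1 + w5, p3_1 - 1L)
  ins2 <- substr(rc2, p5_2 + w5, p3_2 - 1L)
  insert[live] <- ins1[live]
  mism <- live & ins1 != ins2
  status[mism] <- "MATE_MISMATCH"
  live <- is.na(status)

  ambig <- live & grepl("[^ACGT]", ins1)
  status[ambig] <- "AMBIGUOUS_BASE"
  live <- is.na(status)

  wrong <- live & nchar(ins1) != 48L
  status[wrong] <- "WRONG_SIZE"
  live <- is.na(status)

  ## translate distinct surviving inserts once, then match at protein level
  if (any(live)) {
    uin <- unique(ins1[live])
    upep <- translate_nt(uin)
    peptide[live] <- upep[match(ins1[live], uin)]
    in_lib <- peptide %in% library$distinct_peptides
    status[live & !in_lib] <- "NOT_IN_LIBRARY"
    status[live & in_lib] <- "OK"
  }

  data.frame(read_id = pairs$read_id, insert_nt = insert,
             peptide = peptide, status = status, stringsAsFactors = FALSE)
}

#' Single-pair insert extraction
#'
#' Convenience wrapper around [extract_inserts()] for one read pair.
#' @param pair One-row data frame/list with `read_id`, `read1`, `read2`.
#' @inheritParams extract_inserts
#' @return One-row observation data frame.
#' @export
extract_insert <- function(pair, library) {
  extract_inserts(data.frame(read_id = pair$read_id, read1 = pair$read1,
                             read2 = pair$read2, stringsAsFactors = FALSE),
                  library)
}

## Map peptide sequences to a representative peptide_id (first library member
## carrying that sequence).
representative_ids <- function(library) {
  members <- library$members
  first <- members[!duplicated(members$sequence), ]
  stats::setNames(first$peptide_id, first$sequence)
}

#' Count library peptides in a sample
#'
#' Counts only observations with status `OK`; matching is at the translated
#' protein level, so synonymous codon variants of one peptide are pooled.
#' Every distinct library peptide appears in the table (zero counts kept) and
#' frequencies are normalised over the counted total.
#'
#' @param observations Data frame from [extract_inserts()].
#' @param library A `designed_library`.
#' @param sample_id Sample label for the resulting table.
#' @return A [count_table()].
#' @export
count_sample <- function(observations, library, sample_id = "sample") {
  ok <- observations[observations$status == "OK", , drop = FALSE]
  if (nrow(ok) == 0L) stop(sprintf("sample '%s': no reads passed filtering",
                                   sample_id), call. = FALSE)
  rep_ids <- representative_ids(library)
  counts <- stats::setNames(rep(0, length(rep_ids)), unname(rep_ids))
  tab <- table(rep_ids[ok$peptide])
  counts[names(tab)] <- as.numeric(tab)
  count_table(sample_id, counts)
}

#' Summarise filter attrition
#'
#' @param observations Data frame from [extract_inserts()].
#' @return Data frame `status`, `n` over all defined statuses (fixed order).
#' @export
status_summary <- function(observations) {
  n <- vapply(INSERT_STATUSES, function(s) sum(observations$status == s),
              numeric(1))
  data.frame(status = INSERT_STATUSES, n = as.numeric(n),
             stringsAsFactors = FALSE)
}

#' Library cloning efficiency
#'
#' Ratio of distinct peptides observed at least once in the input sample to
#' the number of distinct peptides in the designed library.
#'
#' @param input_table A [count_table()] for the unselected input library.
#' @param library A `designed_library`.
#' @return Proportion in `[0, 1]`.
#' @export
cloning_efficiency <- function(input_table, library) {
  n_designed <- length(library$distinct_peptides)
  if (n_designed == 0L) stop("library has no designed peptides", call. = FALSE)
  observed <- sum(input_table$count > 0)
  observed / n_designed
}

#' Full FASTQ-to-counts pipeline for one sample
#'
#' @inheritParams join_pairs
#' @inheritParams count_sample
#' @return List: `table` ([count_table()]), `status` (attrition summary),
#'   `n_unpaired`.
#' @export
count_fastq_sample <- function(fastq1, fastq2, library, sample_id = "sample") {
  pairs <- join_pairs(fastq1, fastq2)
  obs <- extract_inserts(pairs, library)
  list(table = count_sample(obs, library, sample_id),
       status = status_summary(obs),
       n_unpaired = attr(pairs, "n_unpaired"))
}
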