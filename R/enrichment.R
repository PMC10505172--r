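## Enrichment scoring: log2E with zero-count floor substitution, residue
## mapping with rolling-median smoothing, ROI detection, promiscuity
## filtering and mutational delta-log2E.

#' Compute peptide enrichment (log2E) for one selection campaign
#'
#' Enrichment E of a peptide is the ratio of its output frequency to its
#' input frequency; scores are reported as log2E. Zero counts are handled by
#' floor substitution so that every reported log2E is finite:
#'
#' * `mode = "selection"`: a peptide recovered in the output but unseen in
#'   the input has its input proportion replaced by the lowest non-zero input
#'   proportion in the experiment. Peptides not recovered in an output sample
#'   receive no entry for that chemokine.
#' * `mode = "mutagenesis"`: a peptide present in the input but unseen in the
#'   output has its output proportion replaced by the lowest non-zero output
#'   proportion in the experiment (the input floor also applies if needed).
#'
#' Peptides absent from both input and output are omitted.
#'
#' @param input_table [count_table()] of the unselected input library.
#' @param outputs One [count_table()] or a named list of them (one per
#'   selecting chemokine); names (or `sample_id` attributes) become
#'   `chemokine_id`.
#' @param mode `"selection"` or `"mutagenesis"`.
#' @return Data frame of class `enrichment_table`: `peptide_id`,
#'   `chemokine_id`, `log2E` (all finite).
#' @export
compute_log2E <- function(input_table, outputs,
                          mode = c("selection", "mutagenesis")) {
  mode <- match.arg(mode)
  if (inherits(outputs, "count_table")) {
    outputs <- stats::setNames(list(outputs),
                               attr(outputs, "sample_id") %||% "output")
  }
  if (all(input_table$count == 0)) stop("input table is all zero", call. = FALSE)
  floor_in <- min(input_table$frequency[input_table$frequency > 0])
  floor_out <- min(unlist(lapply(outputs, function(o)
    o$frequency[o$frequency > 0])))

  res <- lapply(names(outputs), function(chem) {
    out <- outputs[[chem]]
    fin <- input_table$frequency[match(out$peptide_id, input_table$peptide_id)]
    fin[is.na(fin)] <- 0
    fout <- out$frequency
    if (mode == "selection") {
      keep <- fout > 0
    } else {
      keep <- fout > 0 | fin > 0
      fout[fout == 0] <- floor_out
    }
    fin[fin == 0] <- floor_in
    data.frame(peptide_id = out$peptide_id[keep], chemokine_id = chem,
               log2E = log2(fout[keep] / fin[keep]), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  stopifnot(all(is.finite(res$log2E)))
  class(res) <- c("enrichment_table", class(res))
  res
}

#' Total log2E per peptide aggregated over chemokines
#'
#' @param table An `enrichment_table`.
#' @return Data frame `peptide_id`, `total_log2E` (missing peptide-chemokine
#'   combinations contribute 0).
#' @export
total_log2E <- function(table) {
  agg <- stats::aggregate(log2E ~ peptide_id, data = table, FUN = sum)
  names(agg)[2] <- "total_log2E"
  agg
}

#' Distribution-free confidence interval of the median
#'
#' Exact conservative interval from binomial order statistics: the bounds are
#' the j-th and (n - j + 1)-th order statistics with j the largest rank such
#' that the two-sided coverage `1 - 2 * pbinom(j - 1, n, 0.5)` is at least
#' `level`.
#'
#' @param values Numeric vector, `n >= 6` for the default level.
#' @param level Nominal coverage (default 0.95).
#' @return Named numeric `c(lower, upper)`.
#' @export
median_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  alpha <- 1 - level
  j <- stats::qbinom(alpha / 2, n, 0.5)
  ## qbinom gives smallest q with CDF >= alpha/2; step back while too large
  while (j >= 1 && stats::pbinom(j - 1, n, 0.5) > alpha / 2) j <- j - 1
  if (j < 1) {
    stop(sprintf("n = %d too small for a %.0f%% median CI", n, 100 * level),
         call. = FALSE)
  }
  s <- sort(values)
  c(lower = s[j], upper = s[n - j + 1])
}

#' Residue-level enrichment profile for one parent protein
#'
#' Maps enriched peptides (log2E > 0 only) back to the originating wild-type
#' protein: `rlog2E[i]` is the sum of log2E over all peptide-chemokine
#' entries whose tile interval covers residue i (mutant tiles map to the
#' parental start). The profile is smoothed with a centred rolling median
#' (window `k`, ends absent) and compared with the distribution-free CI of
#' the protein-wide median rlog2E to call regions of interest.
#'
#' @param table An `enrichment_table`.
#' @param library A `designed_library` (or a list with `$members`).
#' @param parent List/row with `id` and `sequence` of the parent protein.
#' @param k Rolling-median window (odd, default 7).
#' @param level CI level for the median (default 0.95).
#' @param use_smoothed Compare the smoothed profile (default) or the raw
#'   rlog2E with the CI upper bound when calling ROIs.
#' @return List of class `residue_profile`: `parent_id`, `sequence`,
#'   `rlog2E`, `smoothed`, `median_ci`, `roi` (data frame `start`, `end`,
#'   1-based inclusive).
#' @export
residue_profile <- function(table, library, parent, k = 7L, level = 0.95,
                            use_smoothed = TRUE) {
  members <- library$members
  members <- members[members$parent_id == parent$id, , drop = FALSE]
  if (nrow(members) == 0L) stop(sprintf("no library tiles for parent '%s'",
                                        parent$id), call. = FALSE)
  L <- nchar(parent$sequence)
  window <- nchar(members$sequence[1])
  entries <- table[table$log2E > 0, , drop = FALSE]
  entries <- entries[entries$peptide_id %in% members$peptide_id, , drop = FALSE]
  rl <- rep(0, L)
  if (nrow(entries) > 0L) {
    starts <- members$start[match(entries$peptide_id, members$peptide_id)]
    ends <- pmin(starts + window - 1L, L)
    for (e in seq_len(nrow(entries))) {
      idx <- starts[e]:ends[e]
      rl[idx] <- rl[idx] + entries$log2E[e]
    }
  }
  smoothed <- zoo::rollmedian(rl, k = k, fill = NA, align = "center")
  ci <- median_ci(rl, level = level)
  prof <- structure(list(parent_id = parent$id, sequence = parent$sequence,
                         rlog2E = rl, smoothed = smoothed, median_ci = ci,
                         roi = NULL),
                    class = "residue_profile")
  prof$roi <- detect_roi(prof, use_smoothed = use_smoothed)
  prof
}

#' Detect regions of interest in a residue profile
#'
#' Maximal runs of consecutive residues whose (smoothed, by default) rlog2E
#' strictly exceeds the upper bound of the median CI. Residues where the
#' smoothed value is absent (profile ends) never qualify.
#'
#' @param profile A `residue_profile`.
#' @param use_smoothed Use the smoothed profile (default) or raw rlog2E.
#' @return Data frame `start`, `end` (1-based inclusive), ordered by start;
#'   zero rows when no residue qualifies.
#' @export
detect_roi <- function(profile, use_smoothed = TRUE) {
  v <- if (use_smoothed) profile$smoothed else profile$rlog2E
  hit <- !is.na(v) & v > profile$median_ci[["upper"]]
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' @export
print.residue_profile <- function(x, ...) {
  cat(sprintf("residue_profile for %s (%d residues): median CI [%.3g, %.3g], %d ROI\n",
              x$parent_id, length(x$rlog2E), x$median_ci[["lower"]],
              x$median_ci[["upper"]], nrow(x$roi)))
  invisible(x)
}

#' @method as.data.frame residue_profile
#' @export
as.data.frame.residue_profile <- function(x, ...) {
  in_roi <- rep(FALSE, length(x$rlog2E))
  for (i in seq_len(nrow(x$roi))) in_roi[x$roi$start[i]:x$roi$end[i]] <- TRUE
  data.frame(parent_id = x$parent_id, position = seq_along(x$rlog2E),
             residue = strsplit(x$sequence, "")[[1]],
             rlog2E = x$rlog2E, smoothed = x$smoothed,
             ci_lower = x$median_ci[["lower"]],
             ci_upper = x$median_ci[["upper"]],
             in_roi = in_roi, stringsAsFactors = FALSE)
}

#' Promiscuous peptides: enriched against several chemokines
#'
#' Selects peptides with log2E strictly greater than `threshold` against at
#' least `min_chemokines` chemokines.
#'
#' @param table An `enrichment_table`.
#' @param min_chemokines Minimum number of chemokines (default 3).
#' @param threshold log2E cut-off, strict (default 5).
#' @return Character vector of peptide ids (possibly empty), sorted.
#' @export
promiscuous_peptides <- function(table, min_chemokines = 3L, threshold = 5) {
  hits <- table[table$log2E > threshold, , drop = FALSE]
  if (nrow(hits) == 0L) return(character(0))
  n_chem <- tapply(hits$chemokine_id, hits$peptide_id,
                   function(x) length(unique(x)))
  sort(names(n_chem)[n_chem >= min_chemokines])
}

parse_mutation_label <- function(label) {
  ok <- grepl("^[A-Z][0-9]+[A-Z]$", label)
  data.frame(
    position = ifelse(ok, as.integer(sub("^[A-Z]([0-9]+)[A-Z]$", "\\1", label)),
                      NA_integer_),
    wt_res = ifelse(ok, substr(label, 1L, 1L), NA_character_),
    mut_res = ifelse(ok, substring(label, nchar(label)), NA_character_),
    stringsAsFactors = FALSE)
}

#' Mutational change in enrichment (delta log2E)
#'
#' For every mutant-chemokine entry, the difference in log2E between the
#' mutant and the parental wild-type peptide selected by the same chemokine.
#' A positive delta means the mutation increased binding.
#'
#' @param table An `enrichment_table` over a mutagenesis campaign.
#' @param parent_peptide_id Peptide id of the parental wild-type peptide.
#' @param members Variant table carrying `peptide_id` and `mutation_label`
#'   (e.g. the output of [nnk_mutant_library()]); used to annotate position
#'   and residues.
#' @return Data frame: `peptide_id`, `position`, `wt_res`, `mut_res`,
#'   `chemokine_id`, `log2E`, `delta_log2E`. Chemokines without a parental
#'   entry are skipped with a warning.
#' @export
delta_log2E <- function(table, parent_peptide_id, members) {
  parent <- table[table$peptide_id == parent_peptide_id, , drop = FALSE]
  if (nrow(parent) == 0L) stop(sprintf("no entries for parental peptide '%s'",
                                       parent_peptide_id), call. = FALSE)
  missing_chem <- setdiff(unique(table$chemokine_id), parent$chemokine_id)
  if (length(missing_chem) > 0L) {
    warning(sprintf("parental peptide missing for chemokine(s) %s; skipped",
                    paste(missing_chem, collapse = ", ")), call. = FALSE)
    table <- table[!table$chemokine_id %in% missing_chem, , drop = FALSE]
  }
  base <- stats::setNames(parent$log2E, parent$chemokine_id)
  lab <- members$mutation_label[match(table$peptide_id, members$peptide_id)]
  ann <- parse_mutation_label(ifelse(is.na(lab), "", lab))
  out <- data.frame(peptide_id = table$peptide_id, ann,
                    chemokine_id = table$chemokine_id, log2E = table$log2E,
                    delta_log2E = table$log2E - base[table$chemokine_id],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
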