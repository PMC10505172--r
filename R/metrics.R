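## Recovery metrics for simulated campaigns.

#' Jaccard index of two closed integer intervals
#'
#' @param a,b Length-2 integer vectors `c(start, end)`, 1-based inclusive.
#' @return |intersection| / |union| in `[0, 1]`.
#' @export
interval_jaccard <- function(a, b) {
  inter <- max(0L, min(a[2], b[2]) - max(a[1], b[1]) + 1L)
  union <- (a[2] - a[1] + 1L) + (b[2] - b[1] + 1L) - inter
  inter / union
}

#' Top-ranked region of interest of a residue profile
#'
#' The ROI whose peak smoothed rlog2E is highest.
#'
#' @param profile A `residue_profile`.
#' @return Length-2 integer vector `c(start, end)`, or `NULL` if no ROI.
#' @export
top_roi <- function(profile) {
  roi <- profile$roi
  if (nrow(roi) == 0L) return(NULL)
  peak <- vapply(seq_len(nrow(roi)), function(i)
    max(profile$smoothed[roi$start[i]:roi$end[i]], na.rm = TRUE), numeric(1))
  i <- which.max(peak)
  c(roi$start[i], roi$end[i])
}
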