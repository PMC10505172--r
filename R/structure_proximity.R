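## Docked-pose ensemble aggregation: all-atom interface detection at a 5-A
## cutoff, per-pose weights, weighted proximity profiles normalised to a
## maximum of 100, and per-residue cross-chain contact counts.

POSE_SOURCES <- c("AF_MULTIMER", "ADCP", "NMR_HADDOCK")

#' Construct a two-chain docked pose
#'
#' @param pose_id Pose label.
#' @param source One of `"AF_MULTIMER"` (raw score = model confidence),
#'   `"ADCP"` (raw score = free energy, more negative is better) or
#'   `"NMR_HADDOCK"` (no score; poses weighted equally).
#' @param atoms Data frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z` (coordinates in Angstrom).
#' @param target_chain,binder_chain Chain ids of the target (e.g. chemokine)
#'   and binder (e.g. peptide) chains.
#' @param raw_score Numeric score (required unless `source` is
#'   `"NMR_HADDOCK"`).
#' @return List of class `pose_model`.
#' @export
pose_model <- function(pose_id, source, atoms, target_chain, binder_chain,
                       raw_score = NULL) {
  source <- match.arg(source, POSE_SOURCES)
  stopifnot(all(c("chain", "resno", "x", "y", "z") %in% names(atoms)))
  chains <- unique(atoms$chain)
  if (!all(c(target_chain, binder_chain) %in% chains)) {
    stop("target/binder chain not present in atom records", call. = FALSE)
  }
  structure(list(pose_id = pose_id, source = source, atoms = atoms,
                 target_chain = target_chain, binder_chain = binder_chain,
                 raw_score = raw_score),
            class = "pose_model")
}

#' Read docked poses from PDB files with a score sidecar
#'
#' @param pdb_files Character vector of PDB paths (one pose each).
#' @param scores Data frame `pose_id`, `source`, `raw_score`; `pose_id` must
#'   match the PDB file base names (without extension). `raw_score` may be
#'   NA for NMR poses.
#' @param target_chain,binder_chain Chain ids.
#' @return List of `pose_model`s.
#' @export
read_poses <- function(pdb_files, scores, target_chain = "A",
                       binder_chain = "B") {
  lapply(pdb_files, function(f) {
    id <- sub("\\.pdb$", "", basename(f))
    row <- scores[scores$pose_id == id, , drop = FALSE]
    if (nrow(row) != 1L) stop(sprintf("no unique score entry for pose '%s'", id),
                              call. = FALSE)
    pdb <- bio3d::read.pdb(f, verbose = FALSE)
    atoms <- pdb$atom[, c("chain", "resno", "resid", "elety", "x", "y", "z")]
    raw <- if (is.na(row$raw_score)) NULL else row$raw_score
    pose_model(id, row$source, atoms, target_chain, binder_chain, raw)
  })
}

## squared distances between two coordinate matrices (rows = atoms)
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
}

pose_chain_atoms <- function(pose, chain) {
  at <- pose$atoms[pose$atoms$chain == chain, , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) {
    bad <- at$resno[which(!is.finite(rowSums(xyz)))[1]]
    stop(sprintf("pose '%s': missing coordinates at chain %s residue %s",
                 pose$pose_id, chain, bad), call. = FALSE)
  }
  list(atoms = at, xyz = xyz)
}

#' Interface residues of a docked pose
#'
#' All-atom definition: a residue belongs to the interface when any of its
#' atoms lies within `cutoff` Angstrom of any atom of the other chain.
#'
#' @param pose A `pose_model`.
#' @param cutoff Distance cutoff in Angstrom (default 5.0).
#' @return Data frame `chain`, `resno` (both chains' interface residues,
#'   target chain first).
#' @export
interface_residues <- function(pose, cutoff = 5.0) {
  ta <- pose_chain_atoms(pose, pose$target_chain)
  ba <- pose_chain_atoms(pose, pose$binder_chain)
  d2 <- cross_dist2(ta$xyz, ba$xyz)
  close <- d2 <= cutoff^2
  t_res <- sort(unique(ta$atoms$resno[rowSums(close) > 0]))
  b_res <- sort(unique(ba$atoms$resno[colSums(close) > 0]))
  data.frame(chain = c(rep(pose$target_chain, length(t_res)),
                       rep(pose$binder_chain, length(b_res))),
             resno = c(t_res, b_res), stringsAsFactors = FALSE)
}

#' Weight of a docked pose for proximity aggregation
#'
#' AlphaFold-Multimer poses are weighted by their confidence score, ADCP
#' poses by the negated free energy floored at zero (so the lowest energy
#' gets the largest weight), and NMR/HADDOCK poses equally (weight 1).
#'
#' @param pose A `pose_model`.
#' @return Non-negative numeric weight.
#' @export
pose_weight <- function(pose) {
  if (pose$source == "NMR_HADDOCK") return(1)
  if (is.null(pose$raw_score)) {
    stop(sprintf("pose '%s' (%s) lacks a raw score", pose$pose_id, pose$source),
         call. = FALSE)
  }
  switch(pose$source,
         AF_MULTIMER = pose$raw_score,
         ADCP = max(0, -pose$raw_score))
}

#' Weighted proximity profile over a pose ensemble
#'
#' For each target-chain residue, sums the weights of the poses in which the
#' residue is an interface residue, then rescales the profile so the maximum
#' residue score is 100 (allowing comparison between models). An ensemble
#' with no interface residue anywhere returns an all-zero profile with a
#' warning.
#'
#' @param poses List of `pose_model`s sharing the target chain numbering.
#' @param cutoff Interface cutoff in Angstrom (default 5.0).
#' @return Named numeric vector (names = target residue numbers), values in
#'   `[0, 100]`.
#' @export
weighted_proximity <- function(poses, cutoff = 5.0) {
  stopifnot(length(poses) >= 1L)
  resnos <- lapply(poses, function(p)
    sort(unique(p$atoms$resno[p$atoms$chain == p$target_chain])))
  if (length(unique(lapply(resnos, identical, y = resnos[[1]]))) > 1L ||
      !all(vapply(resnos, identical, logical(1), y = resnos[[1]]))) {
    stop("poses disagree on target-chain residue numbering", call. = FALSE)
  }
  score <- stats::setNames(rep(0, length(resnos[[1]])),
                           as.character(resnos[[1]]))
  for (p in poses) {
    iface <- interface_residues(p, cutoff)
    t_iface <- iface$resno[iface$chain == p$target_chain]
    score[as.character(t_iface)] <- score[as.character(t_iface)] + pose_weight(p)
  }
  m <- max(score)
  if (m <= 0) {
    warning("no interface residues in any pose; returning all-zero profile",
            call. = FALSE)
    return(score)
  }
  score * 100 / m
}

#' Average cross-chain contact counts per binder residue
#'
#' For each binder-chain residue, counts the cross-chain atom pairs within
#' `cutoff` ("proximal" contacts) in each pose and averages over the
#' ensemble.
#'
#' @inheritParams weighted_proximity
#' @return Named numeric vector (names = binder residue numbers): average
#'   number of proximal contacts per pose.
#' @export
contact_profile <- function(poses, cutoff = 5.0) {
  stopifnot(length(poses) >= 1L)
  resnos <- sort(unique(unlist(lapply(poses, function(p)
    p$atoms$resno[p$atoms$chain == p$binder_chain]))))
  counts <- stats::setNames(rep(0, length(resnos)), as.character(resnos))
  for (p in poses) {
    ta <- pose_chain_atoms(p, p$target_chain)
    ba <- pose_chain_atoms(p, p$binder_chain)
    close <- cross_dist2(ta$xyz, ba$xyz) <= cutoff^2
    per_atom <- colSums(close)
    per_res <- tapply(per_atom, ba$atoms$resno, sum)
    counts[names(per_res)] <- counts[names(per_res)] + as.numeric(per_res)
  }
  counts / length(poses)
}

#' Carry a residue profile onto a gapped alignment row
#'
#' @param scores Named numeric profile (one value per ungapped residue, in
#'   sequence order).
#' @param gapped Gapped sequence string (gap character `-`).
#' @param sequence Ungapped sequence the profile refers to; must equal
#'   `gapped` with gaps removed.
#' @return Numeric vector over alignment columns; `NA` at gap columns.
#' @export
map_profile_to_alignment <- function(scores, gapped, sequence) {
  g <- strsplit(gapped, "")[[1]]
  ungapped <- paste(g[g != "-"], collapse = "")
  if (!identical(ungapped, sequence)) {
    mism <- which(strsplit(ungapped, "")[[1]] !=
                  strsplit(sequence, "")[[1]])[1]
    stop(sprintf("alignment does not match sequence (first mismatch at residue %s)",
                 mism %||% "length"), call. = FALSE)
  }
  if (length(scores) != nchar(sequence)) {
    stop("profile length does not match sequence length", call. = FALSE)
  }
  out <- rep(NA_real_, length(g))
  out[g != "-"] <- scores
  out
}
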