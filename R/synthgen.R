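## Seeded synthetic-data generator: evasin-like parent proteins with a
## planted binding interval, latent peptide affinities, three-round
## affinity-weighted multinomial panning, arm-flanked amplicon FASTQ
## emission, and synthetic docked pose ensembles. All randomness flows from
## explicit seeds; named substreams keep stages independently reproducible.

#' Derive a reproducible substream seed
#'
#' @param seed Master integer seed.
#' @param name Substream name (e.g. `"parents"`, `"panning"`).
#' @return Integer seed below 2^31.
#' @export
substream_seed <- function(seed, name) {
  s <- (as.numeric(seed) * 1000003 + sum(utf8ToInt(name)) * 7919) %% 2147483629
  as.integer(s + 1)
}

#' Generate Cys-rich synthetic parent proteins with planted binding intervals
#'
#' Emulates mature class-A evasin sequences: random standard-residue
#' sequences with a requested number of Cys residues and one planted
#' 16-residue chemokine-binding interval per parent (shared by all
#' chemokines of the simulated panel). Optionally the first parent carries
#' the HD2 hexadecapeptide verbatim as its planted interval.
#'
#' @param n Number of parents.
#' @param length_range Min/max mature length (default 70-90 residues).
#' @param cys_range Min/max Cys count (default 4-8).
#' @param seed Integer seed.
#' @param embed_hd2 Plant the HD2 sequence as parent 1's binding interval.
#' @return List: `parents` (data frame `id`, `sequence`), `truth` (data
#'   frame `parent_id`, `start`, `end`, 1-based inclusive).
#' @export
make_parents <- function(n, length_range = c(70L, 90L), cys_range = c(4L, 8L),
                         seed = 1L, embed_hd2 = FALSE) {
  if (min(length_range) < 16L) stop("parents must be at least 16 residues",
                                    call. = FALSE)
  if (min(cys_range) < 0L || max(cys_range) > min(length_range)) {
    stop("infeasible Cys count for requested lengths", call. = FALSE)
  }
  set.seed(seed)
  aa_non_cys <- setdiff(AA20, "C")
  parents <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    L <- length_range[1] + sample.int(length_range[2] - length_range[1] + 1L, 1L) - 1L
    n_cys <- cys_range[1] + sample.int(cys_range[2] - cys_range[1] + 1L, 1L) - 1L
    res <- sample(aa_non_cys, L, replace = TRUE)
    res[sample.int(L, n_cys)] <- "C"
    start <- sample.int(L - 15L, 1L)
    if (embed_hd2 && i == 1L) {
      res[start:(start + 15L)] <- strsplit(HD2, "")[[1]]
    }
    parents[[i]] <- data.frame(id = sprintf("EVSYN%02d", i),
                               sequence = paste(res, collapse = ""),
                               stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(parent_id = sprintf("EVSYN%02d", i),
                             start = start, end = start + 15L,
                             stringsAsFactors = FALSE)
  }
  list(parents = do.call(rbind, parents), truth = do.call(rbind, truth))
}

overlap_fraction <- function(start, window, iv_start, iv_end) {
  lo <- pmax(start, iv_start)
  hi <- pmin(start + window - 1L, iv_end)
  pmax(0, hi - lo + 1) / window
}

cys_intact <- function(members, parents) {
  vapply(seq_len(nrow(members)), function(i) {
    p <- parents$sequence[parents$id == members$parent_id[i]]
    if (length(p) == 0L || is.na(members$start[i])) return(1)
    wt <- substr(p, members$start[i], members$start[i] + nchar(members$sequence[i]) - 1L)
    cys <- which(strsplit(wt, "")[[1]] == "C")
    if (length(cys) == 0L) return(1)
    s <- strsplit(members$sequence[i], "")[[1]]
    as.numeric(all(s[cys] == "C"))
  }, numeric(1))
}

#' Assign latent relative affinities to library peptides
#'
#' Encodes the structure the screen assumes: peptides overlapping a parent's
#' planted binding interval are higher-affinity binders, with the log
#' affinity linear in the overlap fraction; peptides whose parental Cys
#' residues are mutated are attenuated; a seeded Gaussian term adds
#' peptide-by-chemokine noise:
#' `log a = alpha * overlap + beta * cys_intact + eps`,
#' `eps ~ N(0, sigma)`.
#'
#' @param members Variant table (rows with duplicate sequences are allowed;
#'   affinity is computed per row).
#' @param truth Planted-interval table from [make_parents()].
#' @param parents Parent table from [make_parents()].
#' @param chemokines Character vector of chemokine ids.
#' @param alpha Overlap coefficient on the natural-log scale
#'   (default `6 * log(2)`: a fully overlapping peptide is 2^6-fold enriched
#'   per unit affinity).
#' @param beta Intact-Cys coefficient (default `2 * log(2)`).
#' @param sigma Noise SD on the natural-log scale (default 0.5).
#' @param seed Integer seed.
#' @return Matrix of strictly positive affinities, rows named by
#'   `peptide_id`, columns by chemokine.
#' @export
assign_affinities <- function(members, truth, parents, chemokines,
                              alpha = 6 * log(2), beta = 2 * log(2),
                              sigma = 0.5, seed = 1L) {
  window <- nchar(members$sequence[1])
  iv <- truth[match(members$parent_id, truth$parent_id), , drop = FALSE]
  ov <- overlap_fraction(members$start, window, iv$start, iv$end)
  ci <- cys_intact(members, parents)
  set.seed(seed)
  eps <- matrix(stats::rnorm(nrow(members) * length(chemokines), 0, sigma),
                nrow(members), length(chemokines))
  loga <- alpha * ov + beta * ci + eps
  a <- exp(loga)
  dimnames(a) <- list(members$peptide_id, chemokines)
  a
}

#' Simulate affinity-weighted panning with multinomial sequencing
#'
#' Deterministic proportional enrichment over `rounds` selection rounds
#' (`p_{r+1} proportional to p_r * a`), with observation noise only at
#' sequencing: input and final-round pools are observed as multinomial draws
#' of `depth` reads.
#'
#' @param affinities Matrix from [assign_affinities()] (rows = peptides,
#'   columns = chemokines). Rows must be unique peptides.
#' @param rounds Number of selection rounds (default 3).
#' @param depth Reads per sample (default 200000).
#' @param seed Integer seed.
#' @return List: `input` ([count_table()]) and `outputs` (named list of
#'   [count_table()]s, one per chemokine).
#' @export
simulate_panning <- function(affinities, rounds = 3L, depth = 2e5, seed = 1L) {
  stopifnot(depth >= 1)
  ids <- rownames(affinities)
  p0 <- rep(1 / nrow(affinities), nrow(affinities))
  set.seed(seed)
  input_counts <- stats::setNames(
    as.numeric(stats::rmultinom(1, depth, p0)), ids)
  outputs <- lapply(colnames(affinities), function(chem) {
    pr <- p0 * affinities[, chem]^rounds
    pr <- pr / sum(pr)
    count_table(chem, stats::setNames(as.numeric(stats::rmultinom(1, depth, pr)),
                                      ids))
  })
  names(outputs) <- colnames(affinities)
  list(input = count_table("input", input_counts), outputs = outputs)
}

## amplicon carrying one 48-nt insert in the printed demux/constant context
build_amplicon <- function(insert) {
  paste0(DEMUX_FWD, CONST5, insert, CONST3, DEMUX_REV)
}

inject_errors <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  L <- nchar(reads[1])
  total <- length(reads) * L
  n_err <- stats::rbinom(1, total, error_rate)
  if (n_err == 0) return(reads)
  pos <- sample.int(total, n_err)
  ridx <- (pos - 1L) %/% L + 1L
  off <- (pos - 1L) %% L + 1L
  bases <- c("A", "C", "G", "T")
  for (e in seq_len(n_err)) {
    cur <- substr(reads[ridx[e]], off[e], off[e])
    substr(reads[ridx[e]], off[e], off[e]) <- sample(setdiff(bases, cur), 1L)
  }
  reads
}

write_fastq <- function(path, ids, seqs) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  qual <- strrep("I", nchar(seqs))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), con)
  invisible(path)
}

#' Emit paired FASTQ reads for a counted sample
#'
#' One read pair per counted molecule: read 1 is the amplicon top strand,
#' read 2 its reverse complement (standard paired-end orientation), both
#' truncated to `read_length`. Substitution errors are applied independently
#' per mate at `error_rate` per base. With `error_rate = 0` the pipeline
#' round-trips the count table exactly.
#'
#' @param table A [count_table()].
#' @param oligos Oligo table from [design_library()] (`peptide_id`,
#'   `insert_nt`).
#' @param fastq1,fastq2 Output paths (`.gz` suffix writes gzipped).
#' @param read_length Read length (default 250; must span the amplicon
#'   landmarks).
#' @param error_rate Per-base substitution rate (default 0).
#' @param seed Integer seed.
#' @return Invisible character vector of the two paths.
#' @export
emit_fastq <- function(table, oligos, fastq1, fastq2, read_length = 250L,
                       error_rate = 0, seed = 1L) {
  tab <- table[table$count > 0, , drop = FALSE]
  inserts <- oligos$insert_nt[match(tab$peptide_id, oligos$peptide_id)]
  if (anyNA(inserts)) stop("count table contains peptides without oligos",
                           call. = FALSE)
  amp <- build_amplicon(inserts)
  if (read_length < nchar(DEMUX_FWD) + nchar(CONST5) + 48L + 15L) {
    stop("read_length too short to span demux, constant regions and insert",
         call. = FALSE)
  }
  reads1 <- substr(rep(amp, tab$count), 1L, read_length)
  reads2 <- substr(rep(revcomp(amp), tab$count), 1L, read_length)
  set.seed(seed)
  reads1 <- inject_errors(reads1, error_rate)
  reads2 <- inject_errors(reads2, error_rate)
  ids <- sprintf("%s_r%07d", attr(table, "sample_id") %||% "sample",
                 seq_along(reads1))
  write_fastq(fastq1, ids, reads1)
  write_fastq(fastq2, ids, reads2)
  invisible(c(fastq1, fastq2))
}

#' Generate a synthetic docked pose ensemble around a planted epitope
#'
#' Builds idealised coordinates: the target chain as a straight backbone
#' (3.8-A residue spacing) with one pseudo side-chain atom per residue, and
#' the binder laid antiparallel over a designated epitope segment within
#' contact range. Each pose applies a seeded rigid-body jitter to the
#' binder; per-pose raw scores improve as the jitter displacement shrinks.
#' With zero jitter every pose has the same interface (the epitope and its
#' immediate neighbours).
#'
#' @param target_size Number of target residues.
#' @param binder_length Number of binder residues (default 16).
#' @param epitope Integer vector of contiguous target residues the binder
#'   covers.
#' @param n_poses Ensemble size.
#' @param jitter SD of the per-pose rigid translation in Angstrom.
#' @param seed Integer seed.
#' @param source Pose source label (controls how scores are drawn and later
#'   weighted).
#' @return List: `poses` (list of `pose_model`) and `truth` (epitope
#'   residues).
#' @export
make_poses <- function(target_size = 60L, binder_length = 16L,
                       epitope = 25L:40L, n_poses = 5L, jitter = 0.5,
                       seed = 1L, source = "AF_MULTIMER") {
  stopifnot(n_poses >= 1L, length(epitope) >= 1L,
            max(epitope) <= target_size, min(epitope) >= 1L)
  source <- match.arg(source, POSE_SOURCES)
  tx <- 3.8 * seq_len(target_size)
  target_atoms <- data.frame(
    chain = "A", resno = rep(seq_len(target_size), each = 2L),
    resid = "ALA", elety = rep(c("CA", "CB"), target_size),
    x = rep(tx, each = 2L), y = rep(c(0, 1.5), target_size), z = 0,
    stringsAsFactors = FALSE)
  bx <- 3.8 * (epitope[1] + seq_len(binder_length) - 1L)
  set.seed(seed)
  poses <- vector("list", n_poses)
  for (k in seq_len(n_poses)) {
    off <- stats::rnorm(3, 0, jitter)
    disp <- sqrt(sum(off^2))
    binder_atoms <- data.frame(
      chain = "B", resno = rep(seq_len(binder_length), each = 2L),
      resid = "ALA", elety = rep(c("CA", "CB"), binder_length),
      x = rep(bx, each = 2L) + off[1],
      y = rep(c(5.5, 4.0), binder_length) + off[2], z = off[3],
      stringsAsFactors = FALSE)
    raw <- switch(source,
                  AF_MULTIMER = max(0.2, 0.95 - 0.1 * disp),
                  ADCP = -(15 - 2 * disp),
                  NMR_HADDOCK = NULL)
    poses[[k]] <- pose_model(sprintf("pose%02d", k), source,
                             rbind(target_atoms, binder_atoms),
                             target_chain = "A", binder_chain = "B",
                             raw_score = raw)
  }
  list(poses = poses, truth = epitope)
}

#' Write a pose ensemble to PDB files with a score sidecar
#'
#' @param poses List of `pose_model`s.
#' @param dir Output directory.
#' @return Data frame `pose_id`, `source`, `raw_score`, `file` (also written
#'   to `dir/scores.tsv`).
#' @export
write_poses <- function(poses, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(poses, function(p) {
    f <- file.path(dir, paste0(p$pose_id, ".pdb"))
    at <- p$atoms
    bio3d::write.pdb(file = f, xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                     resno = at$resno, chain = at$chain, resid = at$resid,
                     elety = at$elety)
    data.frame(pose_id = p$pose_id, source = p$source,
               raw_score = p$raw_score %||% NA_real_, file = f,
               stringsAsFactors = FALSE)
  })
  scores <- do.call(rbind, rows)
  utils::write.table(scores[, c("pose_id", "source", "raw_score")],
                     file.path(dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  scores
}

#' Simulate a complete selection campaign
#'
#' Chains the generator through the analysis-ready stages: synthetic parents
#' with a planted binding interval, tiled library design, latent affinities,
#' three-round panning, optional FASTQ emission and re-counting, and
#' selection-mode enrichment scoring. Ground truth is carried alongside so
#' recovery can be measured.
#'
#' @param seed Master seed; stage seeds are derived via [substream_seed()].
#' @param n_parents,length_range,cys_range Passed to [make_parents()].
#' @param chemokines Chemokine ids of the panel.
#' @param depth Reads per sample.
#' @param rounds Selection rounds.
#' @param alpha,beta,sigma Affinity-model parameters
#'   (see [assign_affinities()]).
#' @param via_fastq Emit FASTQ and re-count through the read pipeline
#'   (default `FALSE`: use the simulated count tables directly).
#' @param error_rate Per-base substitution rate when `via_fastq`.
#' @param dir Directory for FASTQ files when `via_fastq`.
#' @param embed_hd2 Plant HD2 in parent 1.
#' @return List: `parents`, `truth`, `library`, `affinities` (distinct
#'   peptides x chemokines), `input`, `outputs`, `enrichment`
#'   (selection-mode `enrichment_table`).
#' @export
simulate_campaign <- function(seed = 1L, n_parents = 2L,
                              length_range = c(70L, 90L),
                              cys_range = c(4L, 8L),
                              chemokines = paste0("CK", 1:4),
                              depth = 2e5, rounds = 3L,
                              alpha = 6 * log(2), beta = 2 * log(2),
                              sigma = 0.5, via_fastq = FALSE,
                              error_rate = 0.001, dir = tempdir(),
                              embed_hd2 = FALSE) {
  gen <- make_parents(n_parents, length_range, cys_range,
                      seed = substream_seed(seed, "parents"),
                      embed_hd2 = embed_hd2)
  lib <- design_library(gen$parents)
  reps <- lib$members[!duplicated(lib$members$sequence), , drop = FALSE]
  aff <- assign_affinities(reps, gen$truth, gen$parents, chemokines,
                           alpha = alpha, beta = beta, sigma = sigma,
                           seed = substream_seed(seed, "affinities"))
  pan <- simulate_panning(aff, rounds = rounds, depth = depth,
                          seed = substream_seed(seed, "panning"))
  input <- pan$input
  outputs <- pan$outputs
  if (via_fastq) {
    rd_seed <- substream_seed(seed, "reads")
    recount <- function(tab, label, s) {
      f1 <- file.path(dir, sprintf("%s_R1.fastq", label))
      f2 <- file.path(dir, sprintf("%s_R2.fastq", label))
      emit_fastq(tab, lib$oligos, f1, f2, error_rate = error_rate, seed = s)
      count_fastq_sample(f1, f2, lib, sample_id = label)$table
    }
    input <- recount(input, "input", rd_seed)
    outputs <- lapply(seq_along(outputs), function(i)
      recount(outputs[[i]], names(outputs)[i], rd_seed + i))
    names(outputs) <- chemokines
  }
  enr <- compute_log2E(input, outputs, mode = "selection")
  list(parents = gen$parents, truth = gen$truth, library = lib,
       affinities = aff, input = input, outputs = outputs, enrichment = enr)
}

#' Simulate an NNK saturation-mutagenesis campaign
#'
#' Builds the single-peptide NNK library, penalises every substitution at
#' the designated key positions by `effect` log2 units of affinity, runs
#' panning against a chemokine panel and scores mutagenesis-mode enrichment.
#'
#' @param seed Master seed.
#' @param peptide Parental peptide sequence (default HD2).
#' @param chemokines Chemokine ids.
#' @param key_positions Positions whose substitution is penalised.
#' @param effect Penalty in log2 affinity units (default 3).
#' @param sigma Peptide-by-chemokine log-noise SD (default 0.5).
#' @param depth Reads per sample.
#' @param rounds Selection rounds.
#' @return List: `library` (NNK variant table), `entries` (from
#'   [delta_log2E()]), `enrichment`, `key_positions`,
#'   `parent_peptide_id`.
#' @export
simulate_mutscan <- function(seed = 1L, peptide = HD2,
                             chemokines = paste0("CK", 1:8),
                             key_positions = c(10L, 11L, 13L, 14L),
                             effect = 3, sigma = 0.5, depth = 1e5,
                             rounds = 3L) {
  parent <- new_variant_table("HD2_WT", "HD2", 1L, peptide, "WT", "")
  lib <- nnk_mutant_library(parent[1, ])
  ann <- parse_mutation_label(lib$mutation_label)
  penal <- !is.na(ann$position) & ann$position %in% key_positions
  set.seed(substream_seed(seed, "mutscan_affinities"))
  loga <- matrix(stats::rnorm(nrow(lib) * length(chemokines), 0, sigma),
                 nrow(lib), length(chemokines))
  loga <- loga - log(2) * effect * penal
  a <- exp(loga)
  dimnames(a) <- list(lib$peptide_id, chemokines)
  pan <- simulate_panning(a, rounds = rounds, depth = depth,
                          seed = substream_seed(seed, "mutscan_panning"))
  enr <- compute_log2E(pan$input, pan$outputs, mode = "mutagenesis")
  entries <- delta_log2E(enr, "HD2_WT", lib)
  list(library = lib, entries = entries, enrichment = enr,
       key_positions = key_positions, parent_peptide_id = "HD2_WT")
}
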