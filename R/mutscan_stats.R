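## Saturation-scan statistics: substitution classes, per-position group
## bookkeeping, Monte-Carlo Dunnett many-to-one test, one-way ANOVA,
## migration normalisation and the binding-function correlation.

#' Substitution class membership
#'
#' The residue classes used to analyse the saturation scan: anionic (E, D),
#' cationic (K, R), hydrophobic (L, I, M, V) and alanine. Classes are
#' evaluated independently, so one substitution may carry several labels.
#'
#' @return Named list of residue vectors.
#' @export
substitution_classes <- function() {
  list(ALANINE = "A", ANIONIC = c("E", "D"), CATIONIC = c("K", "R"),
       HYDROPHOBIC = c("L", "I", "M", "V"))
}

#' Dayhoff PAM250 substitution matrix
#'
#' The PAM250 log-odds matrix as shipped with Biostrings, restricted to the
#' 20 standard residues.
#' @return 20 x 20 integer matrix.
#' @export
pam250_matrix <- function() {
  e <- new.env()
  utils::data("PAM250", package = "Biostrings", envir = e)
  e$PAM250[AA20, AA20]
}

#' Classify a single-residue substitution
#'
#' Returns every class label that applies: `WILDTYPE` when the residue is
#' unchanged, `ALANINE`/`ANIONIC`/`CATIONIC`/`HYDROPHOBIC` by membership of
#' the mutant residue, and `CONSERVATIVE` when the residues differ but the
#' PAM250 score is strictly positive.
#'
#' @param wt,mut Single standard one-letter residues.
#' @param pam250 Substitution matrix (default [pam250_matrix()]).
#' @return Character vector of class labels (`OTHER` if none applies).
#' @export
classify_substitution <- function(wt, mut, pam250 = pam250_matrix()) {
  stopifnot_aa(c(wt, mut), "substitution")
  if (wt == mut) return("WILDTYPE")
  classes <- substitution_classes()
  labels <- names(classes)[vapply(classes, function(m) mut %in% m, logical(1))]
  if (pam250[wt, mut] > 0) labels <- c(labels, "CONSERVATIVE")
  if (length(labels) == 0L) labels <- "OTHER"
  labels
}

#' Expected group sizes for a saturation scan
#'
#' For each peptide position and substitution class, the number of
#' observations entering the class's box: (#class residues excluding the
#' parental identity at that position) x (#chemokines). The wild-type and
#' alanine groups use a single residue. With a 16-mer and 24 chemokines this
#' reproduces n = 48 for anionic/cationic groups, 96 for hydrophobic groups
#' (72 where the parental residue is itself hydrophobic, e.g. L11), and 24
#' for wild-type/alanine.
#'
#' @param peptide Parental peptide sequence (string).
#' @param n_chemokines Number of selecting chemokines.
#' @param pam250 PAM250 matrix for the conservative class.
#' @param top_conservative If not `NULL`, keep only the top-scoring
#'   conservative residues per position (ties broken alphabetically);
#'   `top_conservative = 1` reproduces a conservative group size equal to
#'   `n_chemokines`.
#' @return Data frame `position`, `wt_res`, `class`, `n_residues`, `n_obs`.
#' @export
group_sizes <- function(peptide, n_chemokines, pam250 = pam250_matrix(),
                        top_conservative = NULL) {
  res <- strsplit(toupper(peptide), "")[[1]]
  stopifnot_aa(res, "peptide")
  classes <- substitution_classes()
  rows <- list()
  for (pos in seq_along(res)) {
    wt <- res[pos]
    cons <- setdiff(AA20[pam250[wt, AA20] > 0], wt)
    if (!is.null(top_conservative) && length(cons) > top_conservative) {
      cons <- cons[order(-pam250[wt, cons], cons)][seq_len(top_conservative)]
    }
    groups <- c(list(WILDTYPE = wt, CONSERVATIVE = cons),
                lapply(classes, setdiff, y = wt))
    groups$WILDTYPE <- wt  # wild-type group is the parental peptide itself
    rows[[pos]] <- data.frame(
      position = pos, wt_res = wt, class = names(groups),
      n_residues = vapply(groups, length, integer(1)),
      n_obs = vapply(groups, length, integer(1)) * n_chemokines,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group saturation-scan observations by position and class
#'
#' Splits mutant log2E observations (one per mutant x chemokine) into
#' per-position substitution-class groups; the parental (wild-type)
#' observations form the control group.
#'
#' @param entries Data frame from [delta_log2E()] (columns `position`,
#'   `wt_res`, `mut_res`, `chemokine_id`, `log2E`; parental rows carry
#'   `position = NA`).
#' @param peptide Parental peptide sequence.
#' @param n_chemokines Number of chemokines (used to cross-check counts).
#' @inheritParams group_sizes
#' @return List: `control` (numeric vector of parental log2E) and `groups`,
#'   a data frame with `position`, `class`, `n_obs` and a list-column
#'   `values`.
#' @export
group_observations <- function(entries, peptide, n_chemokines,
                               pam250 = pam250_matrix(),
                               top_conservative = NULL) {
  control <- entries$log2E[is.na(entries$position)]
  muts <- entries[!is.na(entries$position), , drop = FALSE]
  sizes <- group_sizes(peptide, n_chemokines, pam250, top_conservative)
  sizes <- sizes[sizes$class != "WILDTYPE", , drop = FALSE]
  res <- strsplit(toupper(peptide), "")[[1]]
  classes <- substitution_classes()
  values <- vector("list", nrow(sizes))
  for (i in seq_len(nrow(sizes))) {
    pos <- sizes$position[i]
    wt <- res[pos]
    members <- if (sizes$class[i] == "CONSERVATIVE") {
      cons <- setdiff(AA20[pam250[wt, AA20] > 0], wt)
      if (!is.null(top_conservative) && length(cons) > top_conservative) {
        cons <- cons[order(-pam250[wt, cons], cons)][seq_len(top_conservative)]
      }
      cons
    } else {
      setdiff(classes[[sizes$class[i]]], wt)
    }
    values[[i]] <- muts$log2E[muts$position == pos & muts$mut_res %in% members]
  }
  sizes$values <- values
  sizes$n_obs <- vapply(values, length, integer(1))
  list(control = control, groups = sizes)
}

#' Dunnett many-to-one multiple comparison test (Monte Carlo)
#'
#' Compares each treatment group with a shared control under the classical
#' homoscedastic one-way model. Test statistics are the usual two-sample t
#' statistics on the pooled variance; the family-wise adjustment evaluates
#' the distribution of the maximum (absolute, if two-sided) component of the
#' equicorrelated multivariate t by seeded Monte Carlo integration, so
#' results are deterministic given `seed`.
#'
#' @param control Numeric vector of control observations (n >= 2).
#' @param groups List of numeric treatment vectors (each n >= 2).
#' @param sides 2 (default) for two-sided, 1 for upper-tailed.
#' @param mc_draws Monte-Carlo draws (default 200000).
#' @param seed Integer seed.
#' @return List: `statistic` (t per group), `estimate` (mean difference
#'   group - control), `p_adjusted`, `df`, `direction` (sign of estimate).
#' @export
dunnett_test <- function(control, groups, sides = 2, mc_draws = 2e5,
                         seed = 1L) {
  if (!is.list(groups)) groups <- list(groups)
  k <- length(groups)
  n0 <- length(control)
  ni <- vapply(groups, length, integer(1))
  stopifnot(n0 >= 2, all(ni >= 2), sides %in% c(1, 2))
  N <- n0 + sum(ni)
  df <- N - (k + 1L)
  ss <- sum((control - mean(control))^2) +
    sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ss <= 0) stop("zero pooled variance: Dunnett test is degenerate",
                    call. = FALSE)
  s2 <- ss / df
  est <- vapply(groups, mean, numeric(1)) - mean(control)
  tstat <- est / sqrt(s2 * (1 / ni + 1 / n0))
  lambda <- sqrt(ni / (ni + n0))

  set.seed(seed)
  z0 <- stats::rnorm(mc_draws)
  w <- sqrt(stats::rchisq(mc_draws, df) / df)
  Tmax <- rep(-Inf, mc_draws)
  for (i in seq_len(k)) {
    Ti <- (lambda[i] * z0 + sqrt(1 - lambda[i]^2) * stats::rnorm(mc_draws)) / w
    Ti <- if (sides == 2) abs(Ti) else Ti
    Tmax <- pmax(Tmax, Ti)
  }
  obs <- if (sides == 2) abs(tstat) else tstat
  p_adj <- vapply(obs, function(t) mean(Tmax >= t), numeric(1))
  list(statistic = tstat, estimate = est, p_adjusted = p_adj, df = df,
       direction = sign(est))
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition under equal variances.
#'
#' @param groups List of numeric vectors (>= 2 groups, total n > #groups).
#' @return List: `F`, `df` (numerator, denominator), `p`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(length(groups) >= 2L, all(vapply(groups, length, integer(1)) >= 1L))
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (length(values) <= length(groups)) stop("total n must exceed #groups",
                                             call. = FALSE)
  within_ss <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  means <- vapply(groups, mean, numeric(1))
  if (within_ss <= 0 && max(means) - min(means) <= 0) {
    stop("degenerate data: zero within-group variance with equal means",
         call. = FALSE)
  }
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), df = unname(fit$parameter),
       p = unname(fit$p.value))
}

#' Normalise migrated cell counts to the chemokine-alone median
#'
#' Rescales raw migrated cell counts so the median of the chemokine-alone
#' group equals 10000 cells, making experiments comparable.
#'
#' @param counts Numeric vector of raw migrated cell counts.
#' @param chemokine_alone_counts Raw counts of the chemokine-alone group of
#'   the same experiment (non-empty, positive median).
#' @param target Normalised chemokine-alone median (default 10000).
#' @return Numeric vector of normalised counts.
#' @export
normalise_migration <- function(counts, chemokine_alone_counts,
                                target = 10000) {
  if (length(chemokine_alone_counts) == 0L) {
    stop("chemokine-alone group is empty", call. = FALSE)
  }
  med <- stats::median(chemokine_alone_counts)
  if (med <= 0) stop("chemokine-alone median must be positive", call. = FALSE)
  counts * target / med
}

#' Correlation of functional and binding effects of mutations
#'
#' Spearman rank correlation (average ranks for ties) between the change in
#' migrated cell count and the change in enrichment for mutant
#' peptide-chemokine pairs, with a two-sided p-value from the t
#' approximation.
#'
#' @param delta_migrated,delta_log2E Paired numeric vectors (n >= 4).
#' @return List: `rho`, `p`, `n`.
#' @export
correlate_function_binding <- function(delta_migrated, delta_log2E) {
  ok <- is.finite(delta_migrated) & is.finite(delta_log2E)
  x <- delta_migrated[ok]; y <- delta_log2E[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  list(rho = rho, p = p, n = n)
}
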