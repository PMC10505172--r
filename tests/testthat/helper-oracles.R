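# Independent brute-force oracles used across the suite. These deliberately
# use different algorithms/code paths from the package implementations.

# OSA distance by memoised recursion over suffix indices.
osa_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (i == 0L) j else if (j == 0L) i else {
      cost <- as.integer(x[i] != y[j])
      best <- min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L,
                  rec(i - 1L, j - 1L) + cost)
      if (i > 1L && j > 1L && x[i] == y[j - 1L] && x[i - 1L] == y[j]) {
        best <- min(best, rec(i - 2L, j - 2L) + 1L)
      }
      best
    }
    memo[[key]] <- v
    v
  }
  rec(length(x), length(y))
}

# Centred rolling median with explicit sorted windows; NA outside.
rollmedian_oracle <- function(v, k) {
  h <- (k - 1L) / 2L
  out <- rep(NA_real_, length(v))
  for (i in seq_along(v)) {
    if (i > h && i + h <= length(v)) {
      out[i] <- median(sort(v[(i - h):(i + h)]))
    }
  }
  out
}

# Residue-level enrichment by an explicit (entry, residue) double loop.
rlog2E_oracle <- function(entries, members, L, window = 16L) {
  out <- rep(0, L)
  for (i in seq_len(L)) {
    for (e in seq_len(nrow(entries))) {
      if (entries$log2E[e] <= 0) next
      st <- members$start[members$peptide_id == entries$peptide_id[e]]
      if (length(st) == 1L && i >= st && i <= min(st + window - 1L, L)) {
        out[i] <- out[i] + entries$log2E[e]
      }
    }
  }
  out
}

# Interface residues by an explicit residue-pair / atom-pair loop.
interface_oracle <- function(atoms, target_chain, binder_chain, cutoff = 5) {
  ta <- atoms[atoms$chain == target_chain, ]
  ba <- atoms[atoms$chain == binder_chain, ]
  hit_t <- integer(0); hit_b <- integer(0)
  for (rt in unique(ta$resno)) {
    for (rb in unique(ba$resno)) {
      a1 <- ta[ta$resno == rt, c("x", "y", "z")]
      a2 <- ba[ba$resno == rb, c("x", "y", "z")]
      close <- FALSE
      for (i in seq_len(nrow(a1))) {
        d <- sqrt((a1$x[i] - a2$x)^2 + (a1$y[i] - a2$y)^2 + (a1$z[i] - a2$z)^2)
        if (any(d <= cutoff)) { close <- TRUE; break }
      }
      if (close) { hit_t <- c(hit_t, rt); hit_b <- c(hit_b, rb) }
    }
  }
  list(target = sort(unique(hit_t)), binder = sort(unique(hit_b)))
}

# One-way ANOVA F from hand sums of squares.
anova_oracle <- function(groups) {
  grand <- mean(unlist(groups))
  k <- length(groups)
  n <- vapply(groups, length, integer(1))
  ssb <- sum(n * (vapply(groups, mean, numeric(1)) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  F <- (ssb / (k - 1)) / (ssw / (sum(n) - k))
  list(F = F, df1 = k - 1, df2 = sum(n) - k,
       p = pf(F, k - 1, sum(n) - k, lower.tail = FALSE))
}

# Order-statistic median CI ranks straight from the binomial CDF.
median_ci_oracle <- function(values, level = 0.95) {
  n <- length(values)
  alpha <- 1 - level
  j <- 0L
  for (cand in seq_len(n)) {
    if (pbinom(cand - 1, n, 0.5) <= alpha / 2) j <- cand else break
  }
  s <- sort(values)
  c(lower = s[j], upper = s[n - j + 1])
}

random_peptide <- function(n = 16L) {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# Tiny two-parent fixture library used by several suites.
fixture_library <- function(seed = 101L) {
  gen <- make_parents(2, length_range = c(40L, 50L), cys_range = c(2L, 4L),
                      seed = seed)
  list(gen = gen, lib = design_library(gen$parents))
}
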