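## Optimal string alignment (restricted Damerau-Levenshtein) distance.

#' Optimal string alignment distance
#'
#' Edit distance with unit-cost insertions, deletions, substitutions and
#' adjacent transpositions, under the restriction that no substring is edited
#' more than once (the "osa" distance). Used to pick maximally scrambled
#' control peptides.
#'
#' @param a,b Character strings.
#' @return Non-negative integer distance.
#' @export
osa_distance <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  ## d[i+1, j+1] = distance between x[1..i] and y[1..j]
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (x[i] == y[j]) 0L else 1L
      v <- min(d[i, j + 1L] + 1L,      # deletion
               d[i + 1L, j] + 1L,      # insertion
               d[i, j] + cost)         # substitution / match
      if (i > 1L && j > 1L && x[i] == y[j - 1L] && x[i - 1L] == y[j]) {
        v <- min(v, d[i - 1L, j - 1L] + 1L)  # adjacent transposition
      }
      d[i + 1L, j + 1L] <- v
    }
  }
  as.integer(d[n + 1L, m + 1L])
}
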