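# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the segmentation DP enumerates transitions over
# raw strings, and the clustering oracle scores distances with utils::adist.

# Minimum decomposition score over ALL segmentations of `seq` into motif
# runs (cost 0) and interrupt segments (cost = length + 1), by dynamic
# programming over suffixes. Adjacent interrupts merge for free in the
# optimum, so no adjacency constraint is needed.
dp_min_score <- function(seq, motifs) {
  n <- nchar(seq)
  if (n == 0L) return(0L)
  k <- nchar(motifs[1])
  dp <- rep(Inf, n + 1L)
  dp[n + 1L] <- 0
  for (i in n:1) {
    # interrupt covering i..j
    for (j in i:n) {
      cost <- (j - i + 1L) + 1L + dp[j + 1L]
      if (cost < dp[i]) dp[i] <- cost
    }
    # motif run starting at i
    for (m in motifs) {
      t <- 0L
      while (i + (t + 1L) * k - 1L <= n &&
             substr(seq, i + t * k, i + (t + 1L) * k - 1L) == m) {
        t <- t + 1L
        if (dp[i + t * k] < dp[i]) dp[i] <- dp[i + t * k]
      }
    }
  }
  dp[1L]
}

# substitution-only distance: number of mismatching positions for
# equal-length strings, Inf otherwise (adist with prohibitive indel costs)
sub_dist_oracle <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  drop(utils::adist(a, b, costs = list(ins = 1000, del = 1000, sub = 1)))
}

# reference implementation of the greedy one-substitution clustering, driven
# by a precomputed all-pairs distance matrix
cluster_oracle <- function(core_seqs) {
  tab <- table(core_seqs)
  uniq <- names(tab)[order(-as.integer(tab), names(tab))]
  d <- utils::adist(uniq, uniq, costs = list(ins = 1000, del = 1000, sub = 1))
  len <- nchar(uniq)
  reps_idx <- integer(0)
  assign_of <- integer(length(uniq))
  for (i in seq_along(uniq)) {
    hit <- 0L
    for (c in seq_along(reps_idx)) {
      r <- reps_idx[c]
      if (len[i] == len[r] && d[i, r] <= 1) { hit <- c; break }
    }
    if (hit == 0L) { reps_idx <- c(reps_idx, i); hit <- length(reps_idx) }
    assign_of[i] <- hit
  }
  sizes <- vapply(seq_along(reps_idx), function(c)
    sum(as.integer(tab[uniq[assign_of == c]])), 0L)
  data.frame(representative = uniq[reps_idx], sn = sizes)[order(-sizes, uniq[reps_idx]), ]
}

# deterministic random DNA for fixtures
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
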