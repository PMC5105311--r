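# Independent brute-force oracles used to cross-check the implementation.

# Full affine-gap Smith-Waterman best local score (match +1, mismatch -1,
# gap of length k costs open + k * ext), row-vectorised with a prefix-scan
# for the horizontal gap state. Independent of Biostrings.
sw_oracle_score <- function(q, t, open = 2, ext = 1) {
  qv <- utf8ToInt(q); tv <- utf8ToInt(t)
  n <- length(qv); m <- length(tv)
  Hprev <- numeric(m + 1L)             # H[i-1, 0..m]
  Fprev <- rep(-Inf, m)                # F[i-1, 1..m]
  best <- 0
  for (i in seq_len(n)) {
    s <- ifelse(tv == qv[i], 1, -1)
    diag <- Hprev[seq_len(m)] + s
    Fcur <- pmax(Fprev - ext, Hprev[2:(m + 1L)] - open - ext)
    H0 <- pmax(0, diag, Fcur)
    # E[j] = max_{k<j} H0[k] - open - (j-k) ext  (gap-after-gap never wins)
    g <- H0 + seq_len(m) * ext
    E <- c(-Inf, cummax(g)[seq_len(m - 1L)]) - open - seq_len(m) * ext
    Hcur <- pmax(H0, E)
    best <- max(best, max(Hcur))
    Hprev <- c(0, Hcur)
    Fprev <- Fcur
  }
  best
}

# Best clip-vs-consensus local score over both strands (mirrors the
# decision realignClip makes, computed by exhaustive DP).
sw_oracle_best <- function(clip, targets) {
  best <- 0
  for (t in targets) {
    best <- max(best,
                sw_oracle_score(clip, t),
                sw_oracle_score(revcomp(clip), t))
  }
  best
}

# Longest duplicated string: suffix of a equal to prefix of b, by
# exhaustive enumeration of all overlap lengths.
dup_oracle <- function(a, b) {
  na <- nchar(a)
  ks <- seq_len(min(na, nchar(b)))
  hits <- ks[vapply(ks, function(k)
    substring(a, na - k + 1L, na) == substring(b, 1L, k), logical(1L))]
  if (length(hits)) max(hits) else 0L
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Deterministic substitution at given positions (cycles A->C->G->T->A).
mutate_positions_test <- function(x, pos) {
  v <- strsplit(x, "")[[1]]
  cyc <- c(A = "C", C = "G", G = "T", T = "A")
  v[pos] <- cyc[v[pos]]
  paste(v, collapse = "")
}
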