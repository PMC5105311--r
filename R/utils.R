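#' @import methods
#' @importFrom stats rbinom runif setNames t.test
#' @importFrom utils head tail write.table read.table
NULL

# Alphabet used throughout; simulations are strictly A/C/G/T.
DNA_BASES4 <- c("A", "C", "G", "T")

#' Reverse complement of a plain character string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on
#' length-1 character vectors, used where sequences travel as strings.
#'
#' @param x A character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA of length n with given GC fraction (positions iid).
random_dna <- function(n, gc = 0.41) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES4, n, replace = TRUE, prob = p), collapse = "")
}

# Substitute bases at `pos` (1-based) of string `x` with random different bases.
mutate_positions <- function(x, pos) {
  if (length(pos) == 0L) return(x)
  v <- strsplit(x, "", fixed = TRUE)[[1L]]
  for (p in pos) {
    v[p] <- sample(setdiff(DNA_BASES4, v[p]), 1L)
  }
  paste(v, collapse = "")
}

# Per-base iid substitution errors at rate `rate` on a vector of sequences.
apply_substitution_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- rbinom(1L, n, rate)
    if (k == 0L) return(s)
    mutate_positions(s, sample.int(n, k))
  }, character(1L), USE.NAMES = FALSE)
}

hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Integer codes for fast per-position comparison of equal-length strings.
s2i <- function(x) utf8ToInt(x)

# Longest common prefix length of two strings.
lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  d <- which(utf8ToInt(substr(a, 1L, n)) != utf8ToInt(substr(b, 1L, n)))
  if (length(d) == 0L) n else d[1L] - 1L
}

# Derive a reproducible stream of sub-seeds from one integer seed.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max %/% 2L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
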