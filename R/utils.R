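# Small shared helpers: sequences, phred scores, k-mers, N50.

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert a base quality to the probability the call is correct
#'
#' `p = 1 - 10^(-Q/10)`, clamped to `[0.51, 0.9999]` so that downstream
#' likelihoods never treat a call as certain or as worse than a coin flip.
#'
#' @param qual Phred-scaled base quality (numeric vector).
#' @return Numeric vector of probabilities in `[0.51, 0.9999]`.
#' @examples
#' phred_to_pcorrect(30) # 0.999
#' @export
phred_to_pcorrect <- function(qual) {
  pmin(pmax(1 - 10^(-qual / 10), 0.51), 0.9999)
}

# All k-mers of a sequence as a character vector (positions 1..L-k+1).
seq_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  starts <- seq_len(L - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

# N50 of a set of lengths.
n50 <- function(lengths) {
  if (length(lengths) == 0) return(0)
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)
  csum <- cumsum(lengths)
  lengths[which(csum >= sum(lengths) / 2)[1]]
}

# Longest strictly-increasing subsequence (indices), O(n log n).
# Used for anchor chaining in the built-in contig aligner.
lis_indices <- function(x) {
  n <- length(x)
  if (n == 0) return(integer(0))
  tails <- numeric(0)   # smallest tail value of an increasing subseq of len i
  tails_idx <- integer(0)
  prev <- integer(n)
  for (i in seq_len(n)) {
    j <- findInterval(x[i] - 1, tails) + 1L  # first tail >= x[i]
    tails[j] <- x[i]
    tails_idx[j] <- i
    prev[i] <- if (j > 1L) tails_idx[j - 1L] else 0L
  }
  out <- integer(length(tails))
  k <- tails_idx[length(tails_idx)]
  for (j in rev(seq_along(tails))) {
    out[j] <- k
    k <- prev[k]
  }
  out
}

`%||%` <- rlang::`%||%`
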