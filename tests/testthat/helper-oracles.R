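# Shared helpers and independent oracles used across the test files.
# Oracles deliberately avoid the package's own code paths: brute-force
# enumeration, pair counting, and direct arithmetic.

BASES <- c("A", "C", "G", "T")

# Consensus sequence (per-column argmax) of a PFM.
consensus_of <- function(p) {
  paste(BASES[apply(pfm_matrix(p), 2L, which.max)], collapse = "")
}

# Brute-force AUC: explicit pair counting with half credit for ties.
auc_by_pairs <- function(pos, neg) {
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  sum(cmp) / (length(pos) * length(neg))
}

# Brute-force sum occupancy: explicit window products over the sequence
# and (optionally) its reverse complement, using prod() per window.
occupancy_by_enumeration <- function(seq, p, both = TRUE) {
  m <- pfm_matrix(p)
  L <- ncol(m)
  score_one <- function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(vapply(seq_len(nchar(s) - L + 1L), function(st) {
      prod(vapply(seq_len(L), function(i) {
        b <- ch[st + i - 1L]
        if (b == "N") 0.25 else m[b, i]
      }, numeric(1)))
    }, numeric(1)))
  }
  total <- score_one(seq)
  if (both) {
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]),
                                       collapse = ""))
    total <- total + score_one(rc)
  }
  total
}

# Exact word scores of all 4^L words of a PFM, as a named numeric vector
# (names are the words), by full enumeration in code space.
enumerate_word_scores <- function(p) {
  logp <- log(pfm_matrix(p))
  L <- ncol(logp)
  codes <- 0:(4^L - 1)
  sc <- numeric(length(codes))
  for (i in seq_len(L))
    sc <- sc + logp[(codes %/% 4^(L - i)) %% 4 + 1L, i]
  names(sc) <- word_from_code(codes, L)
  sc
}

# Words (strings) from integer codes, most significant digit first.
word_from_code <- function(codes, L) {
  out <- rep("", length(codes))
  for (i in seq_len(L))
    out <- paste0(out, BASES[(codes %/% 4^(L - i)) %% 4 + 1L])
  out
}

# Reverse-complemented PFM built directly (independent of the package's
# internal helper): reverse columns, swap A<->T and C<->G rows.
revcomp_pfm_oracle <- function(p) {
  m <- pfm_matrix(p)[4:1, ncol(pfm_matrix(p)):1, drop = FALSE]
  pfm(m, paste0(motif_id(p), "_rc_oracle"))
}

# A quick regularized random motif.
rpfm <- function(L, conc = 0.5, seed = NULL, id = "m") {
  regularize_pfm(random_pfm(L, conc, seed = seed, matrix_id = id))
}
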