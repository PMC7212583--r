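# Sequence scoring (sum occupancy) and performance metrics shared by the
# three benchmarking protocols.

# Integer encoding of DNA: A=1, C=2, G=3, T=4, N=0 (scored as background).
# Other IUPAC ambiguity codes are rejected.
.DNA_LUT <- local({
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut[utf8ToInt("N")] <- 0L; lut[utf8ToInt("n")] <- 0L
  lut
})

.encode_dna <- function(seq) {
  code <- .DNA_LUT[utf8ToInt(seq)]
  if (anyNA(code))
    stop("sequence contains characters outside {A,C,G,T,N}")
  code
}

# Encode equal-length sequences as an n x len integer matrix.
.encode_dna_matrix <- function(seqs) {
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("sequences must all have the same length")
  code <- .DNA_LUT[utf8ToInt(paste(seqs, collapse = ""))]
  if (anyNA(code))
    stop("sequence contains characters outside {A,C,G,T,N}")
  t(matrix(code, nrow = len))
}

# Reverse complement in code space (N maps to N).
.revcomp_codes <- function(codes) {
  rc <- codes[, ncol(codes):1, drop = FALSE]
  (5L - rc) %% 5L
}

# Per-window log probabilities for every row of an n x len code matrix.
# Returns an n x (len - L + 1) matrix.
.window_logprobs <- function(codes, logp, bg_log) {
  n <- nrow(codes); len <- ncol(codes); L <- ncol(logp)
  nw <- len - L + 1L
  S <- matrix(0, n, nw)
  for (i in seq_len(L)) {
    v <- c(bg_log[i], logp[, i])
    S <- S + matrix(v[codes[, i:(i + nw - 1L), drop = FALSE] + 1L], n, nw)
  }
  S
}

# Sum occupancy for every row of a code matrix (the batch kernel behind
# sum_occupancy(); used directly by the benchmark drivers).
.occupancy_codes <- function(codes, logp, strand = "both",
                             bg = rep(0.25, 4)) {
  L <- ncol(logp)
  if (ncol(codes) < L)
    stop("sequence shorter than the motif (", ncol(codes), " < ", L, ")")
  bg_log <- rep(log(0.25), L)  # N positions contribute background 0.25
  occ <- rowSums(exp(.window_logprobs(codes, logp, bg_log)))
  if (strand == "both") {
    occ <- occ +
      rowSums(exp(.window_logprobs(.revcomp_codes(codes), logp, bg_log)))
  }
  occ
}

# Zero probabilities are tolerated in scoring (log 0 = -Inf makes the
# window probability 0); only PWM weight conversion demands positivity.
.pfm_logprobs <- function(x) {
  stopifnot(inherits(x, "pfm"))
  log(pfm_matrix(x))
}

#' Probability of a sequence window under a PFM
#'
#' Product over motif positions of the probability of the observed base.
#' `N` contributes the background probability 0.25 at its position.
#'
#' @param window DNA string whose length equals the motif length.
#' @param x A regularized `pfm`.
#' @return A single probability.
#' @export
window_probability <- function(window, x) {
  logp <- .pfm_logprobs(x)
  code <- .encode_dna(window)
  if (length(code) != ncol(logp))
    stop("window length ", length(code),
         " does not match motif length ", ncol(logp))
  v <- vapply(seq_along(code), function(i) {
    if (code[i] == 0L) log(0.25) else logp[code[i], i]
  }, numeric(1))
  exp(sum(v))
}

#' Sum occupancy score of sequences under a PFM
#'
#' The sum over all sliding windows of the window probability under the
#' motif, by default accumulated over both the sequence and its reverse
#' complement. This is a soft, threshold-free binding score for a
#' sequence longer than the motif, used by all three benchmarking
#' protocols. `log_sum_occupancy()` returns its natural logarithm, a
#' rank-preserving transform used for correlation with log intensities.
#'
#' @param seqs Character vector of DNA sequences (equal or varying
#'   lengths), or a [Biostrings::DNAStringSet].
#' @param x A regularized `pfm`.
#' @param strand `"both"` (default) to also scan the reverse complement,
#'   or `"forward"` for single-strand scanning.
#' @return Numeric vector of occupancy scores, one per sequence.
#' @export
sum_occupancy <- function(seqs, x, strand = c("both", "forward")) {
  strand <- match.arg(strand)
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  logp <- .pfm_logprobs(x)
  L <- ncol(logp)
  if (any(nchar(seqs) < L))
    stop("sequence(s) shorter than the motif length ", L)
  lens <- nchar(seqs)
  out <- numeric(length(seqs))
  for (len in unique(lens)) {
    idx <- which(lens == len)
    codes <- .encode_dna_matrix(seqs[idx])
    out[idx] <- .occupancy_codes(codes, logp, strand)
  }
  names(out) <- names(seqs)
  out
}

#' @rdname sum_occupancy
#' @export
log_sum_occupancy <- function(seqs, x, strand = c("both", "forward")) {
  log(sum_occupancy(seqs, x, match.arg(strand)))
}

#' Area under the ROC curve by the rank (Mann-Whitney) method
#'
#' Computed tie-aware from ranks, so it equals the Mann-Whitney statistic:
#' the fraction of (positive, negative) score pairs where the positive
#' outscores the negative, counting ties half.
#'
#' @param pos,neg Numeric score vectors for the positive and negative
#'   sets; both must be non-empty and finite.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(pos, neg) {
  if (!length(pos) || !length(neg))
    stop("roc_auc requires non-empty positive and negative score sets")
  if (any(!is.finite(pos)) || any(!is.finite(neg)))
    stop("roc_auc requires finite scores")
  np <- length(pos); nn <- length(neg)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Pearson correlation with validity checks
#'
#' Standard product-moment correlation, erroring on degenerate input
#' (fewer than 3 observations or zero variance) instead of returning NA.
#'
#' @param x,y Equal-length numeric vectors, length at least 3.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("pearson requires at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(x, y)
}

#' Top fraction of a score set
#'
#' Returns the `ceiling(q * n)` highest scores. Ties at the boundary are
#' kept only up to the count, broken by stable input order, so the result
#' is deterministic.
#'
#' @param scores Numeric vector.
#' @param q Fraction in `(0, 1]`.
#' @return The selected scores (in decreasing order).
#' @export
top_fraction <- function(scores, q) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 1)
    stop("q must be a single fraction in (0, 1]")
  k <- ceiling(q * length(scores))
  scores[order(-scores)[seq_len(k)]]
}
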