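# ChIP-seq peak-list benchmarking protocol: extract fixed-width sequences
# around the anchors of the top-scoring peaks, score them and same-length
# control windows at a fixed genomic offset, and report the AUC ROC.

#' Parameters of the ChIP-seq benchmarking protocol
#'
#' Defaults follow the large-scale study conditions: region half-width
#' `w = 250` bp, `n_top = 2000` top-ranked peaks, negative control windows
#' at a fixed signed offset `d = +500` bp from the peak anchors, and a
#' minimum list size of 5000 peaks.
#'
#' @param w Half-width of the extracted regions in bp; a region spans
#'   `2 * w + 1` bases centred on the anchor.
#' @param n_top Number of top-scoring peaks used.
#' @param d Signed offset (bp) of the negative control window relative to
#'   the anchor; must be non-zero.
#' @param min_peaks Minimum number of peaks a list must contain to be
#'   benchmarked.
#' @return A list of class `"chip_params"`.
#' @export
chip_params <- function(w = 250, n_top = 2000, d = 500, min_peaks = 5000) {
  stopifnot(w > 0, n_top > 0, min_peaks > 0)
  if (d == 0) stop("d must be non-zero (negatives must not equal positives)")
  structure(list(w = as.integer(w), n_top = as.integer(n_top),
                 d = as.integer(d), min_peaks = as.integer(min_peaks)),
            class = "chip_params")
}

#' Read a BED-like peak list with scores
#'
#' Expects at least 5 whitespace-separated columns: chrom, start, end
#' (0-based half-open), name, score. If 10 or more columns are present the
#' 10th is taken as the summit offset from the peak start (narrowPeak
#' convention; -1 means no summit).
#'
#' @param path Path to the peak file.
#' @return Data frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `summit` (NA when absent).
#' @export
read_peaks <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          stringsAsFactors = FALSE,
                          colClasses = "character",
                          comment.char = "#")
  if (ncol(df) < 5L)
    stop("peak file must have at least 5 columns (chrom start end name score)")
  start <- suppressWarnings(as.numeric(df[[2L]]))
  end <- suppressWarnings(as.numeric(df[[3L]]))
  score <- suppressWarnings(as.numeric(df[[5L]]))
  bad <- which(is.na(start) | is.na(end) | is.na(score))
  if (length(bad))
    stop("peak file line ", bad[1L], ": non-numeric start/end/score")
  bad <- which(start >= end)
  if (length(bad))
    stop("peak file line ", bad[1L], ": start >= end")
  summit <- rep(NA_real_, nrow(df))
  if (ncol(df) >= 10L) {
    s <- suppressWarnings(as.numeric(df[[10L]]))
    summit <- ifelse(!is.na(s) & s >= 0, s, NA_real_)
  }
  data.frame(chrom = df[[1L]], start = start, end = end,
             name = df[[4L]], score = score, summit = summit,
             stringsAsFactors = FALSE)
}

#' Minimum peak-count filter
#'
#' Only peak lists with at least `min_peaks` peaks are benchmarked.
#'
#' @param peaks Peak data frame from [read_peaks()].
#' @param params A [chip_params()] object.
#' @return `TRUE` (accepted) or `FALSE` (rejected).
#' @export
check_min_peaks <- function(peaks, params = chip_params()) {
  nrow(peaks) >= params$min_peaks
}

#' Single-position anchor of each peak
#'
#' The protocol represents each peak by one position: the summit if the
#' peak file provides one, otherwise the midpoint `floor((start + end)/2)`.
#'
#' @param peaks Peak data frame from [read_peaks()].
#' @return Integer vector of absolute genomic anchor positions (0-based).
#' @export
anchor_point <- function(peaks) {
  has_summit <- !is.na(peaks$summit)
  bad <- which(has_summit &
                 (peaks$summit < 0 | peaks$start + peaks$summit >= peaks$end))
  if (length(bad))
    stop("peak ", bad[1L], ": summit outside [start, end)")
  ifelse(has_summit,
         peaks$start + peaks$summit,
         floor((peaks$start + peaks$end) / 2))
}

# Extract positive/negative window pairs as character sequences,
# dropping pairs that leave chromosome bounds or are >50% N.
.chip_window_pairs <- function(peaks, genome, params) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (inherits(genome, "DNAStringSet")) {
    chrs <- as.character(genome)
    names(chrs) <- sub("\\s.*$", "", names(genome))
  } else if (is.character(genome)) {
    chrs <- genome
  } else stop("genome must be a DNAStringSet, FASTA path, or named character")
  ord <- order(-peaks$score, peaks$chrom, peaks$start)
  peaks <- peaks[ord[seq_len(min(params$n_top, nrow(peaks)))], , drop = FALSE]
  a <- anchor_point(peaks)
  w <- params$w; d <- params$d
  pos <- neg <- character(0)
  for (i in seq_len(nrow(peaks))) {
    if (!peaks$chrom[i] %in% names(chrs))
      stop("chromosome '", peaks$chrom[i], "' absent from the genome")
    chr <- chrs[[peaks$chrom[i]]]
    len <- nchar(chr)
    ps <- a[i] - w; pe <- a[i] + w          # 0-based inclusive
    ns <- a[i] + d - w; ne <- a[i] + d + w
    if (ps < 0 || ns < 0 || pe >= len || ne >= len) next
    p <- substr(chr, ps + 1L, pe + 1L)
    n <- substr(chr, ns + 1L, ne + 1L)
    nfrac <- function(s) {
      lengths(regmatches(s, gregexpr("[Nn]", s))) / nchar(s)
    }
    if (nfrac(p) > 0.5 || nfrac(n) > 0.5) next
    pos <- c(pos, p); neg <- c(neg, n)
  }
  list(pos = pos, neg = neg)
}

#' Run the ChIP-seq peak benchmarking protocol
#'
#' Takes the `n_top` top-scoring peaks (ties at the cut broken by
#' chromosome then start coordinate), extracts the `2w + 1` bp sequences
#' centred on their anchors as positives and same-length windows offset by
#' `d` bp as negatives, scores both sets with the sum occupancy score, and
#' returns the AUC ROC of the discrimination. Pairs whose positive or
#' negative window exceeds chromosome bounds, or is more than 50% N, are
#' dropped together.
#'
#' @param peaks Peak data frame from [read_peaks()].
#' @param genome A [Biostrings::DNAStringSet], path to a FASTA file, or a
#'   named character vector of chromosome sequences.
#' @param pfms A regularized `pfm` or a list of them.
#' @param params A [chip_params()] object.
#' @param strand Strand policy passed to [sum_occupancy()].
#' @param enforce_min_peaks Set `FALSE` to benchmark short (e.g.
#'   synthetic) peak lists that fail the `min_peaks` filter.
#' @return A single AUC, or a named vector of AUCs when `pfms` is a list.
#'   The number of usable pairs is attached as attribute `n_pairs`.
#' @export
run_chipseq_benchmark <- function(peaks, genome, pfms,
                                  params = chip_params(),
                                  strand = c("both", "forward"),
                                  enforce_min_peaks = TRUE) {
  strand <- match.arg(strand)
  if (enforce_min_peaks && !check_min_peaks(peaks, params))
    stop("peak list rejected: fewer than ", params$min_peaks, " peaks")
  pairs <- .chip_window_pairs(peaks, genome, params)
  if (length(pairs$pos) < 10L)
    stop("fewer than 10 usable peak/control pairs (",
         length(pairs$pos), ")")
  single <- inherits(pfms, "pfm")
  if (single) pfms <- list(pfms)
  pos_codes <- .encode_dna_matrix(pairs$pos)
  neg_codes <- .encode_dna_matrix(pairs$neg)
  auc <- vapply(pfms, function(p) {
    logp <- .pfm_logprobs(p)
    roc_auc(.occupancy_codes(pos_codes, logp, strand),
            .occupancy_codes(neg_codes, logp, strand))
  }, numeric(1))
  names(auc) <- vapply(pfms, motif_id, character(1))
  out <- if (single) unname(auc[1L]) else auc
  attr(out, "n_pairs") <- length(pairs$pos)
  out
}
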