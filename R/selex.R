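# HT-SELEX benchmarking protocol: read filtering, cycle pooling,
# deduplication and subsampling, barcode/primer insert extension, shuffled
# negatives, and top-percentile AUC computation.

#' Constant sequences of the HT-SELEX library design
#'
#' The 5' and 3' primer sequences flanking the barcoded random insert in
#' the HT-SELEX experiments, and the flank truncation length: after
#' extension with barcodes and primers, reads are truncated to the 20 bp
#' adjacent to the random insert on each side.
#'
#' @param primer5,primer3 Constant primer sequences on the 5' and 3' side.
#' @param flank_len Number of flanking bases kept on each side.
#' @return A list of class `"selex_constants"`.
#' @export
selex_constants <- function(
    primer5 = "TCCATCACGAATGATACGGCGACCACCGAACACTCTTTCCCTACACGACGCTCTTCCGATC",
    primer3 = "ATCGTATGCCGTCTTCTGCTTGCCGACTCCG",
    flank_len = 20L) {
  stopifnot(flank_len > 0)
  structure(list(primer5 = primer5, primer3 = primer3,
                 flank_len = as.integer(flank_len)),
            class = "selex_constants")
}

#' Parse a metadata-bearing HT-SELEX library name
#'
#' Library names follow the grammar `GENE_{bc5}{len}N{bc3}[_batch]`, e.g.
#' `ELK3_TCGGGG20NGGT_AG`: gene symbol, 5' barcode, random insert length,
#' 3' barcode, and an optional batch suffix. Barcodes are the letters
#' between the first underscore and the digit run (5') and between the
#' `N` and the next underscore or end (3'); either may be empty.
#'
#' @param name Library name string.
#' @return A list of class `"selex_library_name"` with fields
#'   `gene_symbol`, `barcode5`, `insert_len`, `barcode3`, `batch`.
#' @export
parse_library_name <- function(name) {
  m <- regexec("^([^_]+)_([ACGT]*)([0-9]+)N([ACGT]*)(?:_(.+))?$", name)
  g <- regmatches(name, m)[[1]]
  if (!length(g))
    stop("cannot parse SELEX library name '", name,
         "': expected GENE_{barcode5}{len}N{barcode3}[_batch]")
  structure(list(gene_symbol = g[2L],
                 barcode5 = g[3L],
                 insert_len = as.integer(g[4L]),
                 barcode3 = g[5L],
                 batch = if (nzchar(g[6L])) g[6L] else NA_character_),
            class = "selex_library_name")
}

#' Filter SELEX reads to clean full-length inserts
#'
#' Retains only reads exactly `insert_len` long and composed exclusively
#' of A, C, G, T. The number of discarded reads is reported as a message
#' and attached as attribute `n_dropped`.
#'
#' @param reads Character vector of read sequences or a
#'   [Biostrings::DNAStringSet] (e.g. from a FASTQ file).
#' @param insert_len Insert length indicated by the library name.
#' @return Character vector of retained reads.
#' @export
filter_reads <- function(reads, insert_len) {
  if (inherits(reads, "XStringSet")) reads <- as.character(reads)
  keep <- nchar(reads) == insert_len & grepl("^[ACGT]*$", reads)
  dropped <- sum(!keep)
  if (dropped > 0)
    message("filter_reads: dropped ", dropped, " of ", length(reads),
            " reads (wrong length or non-ACGT)")
  structure(unname(reads[keep]), n_dropped = dropped)
}

#' Pool cycles, remove duplicates, and subsample
#'
#' Reads from different cycles of the same experiment are pooled,
#' duplicates (presumed PCR copies) are removed keeping the first
#' occurrence, and libraries larger than `cap` are reduced to a uniform
#' random subset of exactly `cap` sequences drawn with the given seed.
#'
#' @param cycles List of character vectors of reads, one per cycle.
#' @param cap Maximum library size after subsampling (default one million).
#' @param seed Integer seed for the subsampling draw.
#' @return Character vector of pooled, unique, possibly subsampled reads.
#' @export
pool_dedup_subsample <- function(cycles, cap = 1e6, seed = 1) {
  pooled <- unlist(cycles, use.names = FALSE)
  pooled <- pooled[!duplicated(pooled)]
  if (length(pooled) > cap) {
    set.seed(seed)
    pooled <- pooled[sort(sample.int(length(pooled), cap))]
  }
  pooled
}

# Left/right 20 bp flanks implied by a library name: the last flank_len
# characters of primer5 + barcode5 and the first flank_len of
# barcode3 + primer3.
selex_flanks <- function(libname, consts = selex_constants()) {
  left_full <- paste0(consts$primer5, libname$barcode5)
  right_full <- paste0(libname$barcode3, consts$primer3)
  fl <- consts$flank_len
  left <- substr(left_full, max(1L, nchar(left_full) - fl + 1L),
                 nchar(left_full))
  right <- substr(right_full, 1L, min(fl, nchar(right_full)))
  c(left = left, right = right)
}

#' Extend random inserts with barcode and primer flanks
#'
#' Reconstructs the sequence context physically present during the
#' binding reaction: each insert is flanked by the last `flank_len`
#' characters of (5' primer + 5' barcode) on the left and the first
#' `flank_len` characters of (3' barcode + 3' primer) on the right.
#' Binding sites straddling the insert boundary are missed if only
#' inserts are scanned; extension makes them visible to the scorer.
#'
#' @param inserts Character vector of insert sequences, each exactly
#'   `libname$insert_len` long.
#' @param libname Parsed library name from [parse_library_name()].
#' @param consts Library constants from [selex_constants()].
#' @return Character vector of extended reads.
#' @export
extend_insert <- function(inserts, libname, consts = selex_constants()) {
  stopifnot(inherits(libname, "selex_library_name"))
  if (any(nchar(inserts) != libname$insert_len))
    stop("insert length differs from the library name's insert_len (",
         libname$insert_len, ")")
  fl <- selex_flanks(libname, consts)
  paste0(fl[["left"]], inserts, fl[["right"]])
}

#' Mononucleotide-shuffled negative controls for extended reads
#'
#' For each extended read, permutes the central insert uniformly at
#' random while leaving the primer and barcode flanks unchanged, so the
#' per-read mononucleotide composition of the insert is preserved
#' exactly.
#'
#' @param extended Character vector of reads from [extend_insert()].
#' @param libname Parsed library name from [parse_library_name()].
#' @param consts Library constants from [selex_constants()].
#' @param seed Integer seed making the shuffle reproducible.
#' @return Character vector of shuffled reads (same flanks, permuted
#'   inserts).
#' @export
shuffle_negatives <- function(extended, libname,
                              consts = selex_constants(), seed = 1) {
  stopifnot(inherits(libname, "selex_library_name"))
  fl <- selex_flanks(libname, consts)
  nl <- nchar(fl[["left"]])
  il <- libname$insert_len
  expected <- nl + il + nchar(fl[["right"]])
  if (any(nchar(extended) != expected))
    stop("reads do not have the extended length ", expected,
         "; run extend_insert() first")
  set.seed(seed)
  inserts <- substr(extended, nl + 1L, nl + il)
  shuffled <- vapply(strsplit(inserts, ""), function(ch)
    paste(ch[sample.int(length(ch))], collapse = ""), character(1))
  paste0(fl[["left"]], shuffled, fl[["right"]])
}

#' Run the HT-SELEX benchmarking protocol
#'
#' Scores the positive (selected) and negative (shuffled or input)
#' libraries with the sum occupancy score, keeps only the top fraction
#' `q` of each score list separately (SELEX libraries are often only
#' weakly enriched with true binding sequences, so a top-percentile
#' cut-off sharpens the contrast), and returns the AUC ROC between the
#' two truncated sets.
#'
#' @param pos_lib,neg_lib Character vectors of (typically extended)
#'   positive and negative reads.
#' @param pfms A regularized `pfm` or a list of them.
#' @param q Top fraction of scores used on each side (default 0.10; the
#'   study also used 0.50).
#' @param strand Strand policy passed to [sum_occupancy()].
#' @return A single AUC, or a named vector of AUCs when `pfms` is a list.
#' @export
run_selex_benchmark <- function(pos_lib, neg_lib, pfms, q = 0.10,
                                strand = c("both", "forward")) {
  strand <- match.arg(strand)
  if (!length(pos_lib) || !length(neg_lib))
    stop("positive and negative libraries must be non-empty")
  single <- inherits(pfms, "pfm")
  if (single) pfms <- list(pfms)
  pos_codes <- .encode_dna_matrix(pos_lib)
  neg_codes <- .encode_dna_matrix(neg_lib)
  auc <- vapply(pfms, function(p) {
    logp <- .pfm_logprobs(p)
    roc_auc(top_fraction(.occupancy_codes(pos_codes, logp, strand), q),
            top_fraction(.occupancy_codes(neg_codes, logp, strand), q))
  }, numeric(1))
  names(auc) <- vapply(pfms, motif_id, character(1))
  if (single) unname(auc[1L]) else auc
}
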