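# PBM benchmarking protocol: correlation between log sum occupancy scores
# and normalized log probe intensities on UniPROBE-style probe tables.

#' Read a UniPROBE-style normalized probe table
#'
#' Two whitespace- or tab-delimited columns per row: a normalized
#' intensity and the probe sequence (including part of the fixed linker).
#' Which column holds the intensity is auto-detected by which field is
#' numeric. Rows with non-positive or missing intensities (whose log is
#' undefined) are dropped with a reported count.
#'
#' @param path Path to the probe table.
#' @return Data frame with columns `sequence` and `intensity`; the number
#'   of dropped rows is attached as attribute `n_dropped`.
#' @export
read_uniprobe_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          stringsAsFactors = FALSE,
                          colClasses = "character",
                          comment.char = "#")
  if (ncol(df) < 2L)
    stop("probe table must have two columns (intensity and sequence)")
  num1 <- suppressWarnings(as.numeric(df[[1L]]))
  num2 <- suppressWarnings(as.numeric(df[[2L]]))
  frac1 <- mean(!is.na(num1)); frac2 <- mean(!is.na(num2))
  if (frac1 == 0 && frac2 == 0)
    stop("probe table has no numeric intensity column")
  if (frac1 >= frac2) {
    intensity <- num1; sequence <- toupper(df[[2L]])
  } else {
    intensity <- num2; sequence <- toupper(df[[1L]])
  }
  keep <- !is.na(intensity) & intensity > 0
  dropped <- sum(!keep)
  if (dropped > 0)
    message("read_uniprobe_table: dropped ", dropped,
            " row(s) with missing or non-positive intensity")
  structure(data.frame(sequence = sequence[keep],
                       intensity = intensity[keep],
                       stringsAsFactors = FALSE),
            n_dropped = dropped)
}

#' Run the PBM benchmarking protocol
#'
#' For each probe the first `prefix_len` bases (41 by default, excluding
#' part of the fixed linker) are extracted and scored with the log sum
#' occupancy score; the Pearson correlation coefficient between these
#' scores and the natural-log intensities is the performance value.
#' Probes shorter than `prefix_len` are skipped with a warning.
#'
#' @param probes Data frame with columns `sequence` and `intensity`, as
#'   from [read_uniprobe_table()] or [synth_pbm()].
#' @param pfms A regularized `pfm` or a list of them.
#' @param prefix_len Number of leading probe bases scored.
#' @param strand Strand policy passed to [sum_occupancy()].
#' @return A single Pearson r, or a named vector when `pfms` is a list.
#' @export
run_pbm_benchmark <- function(probes, pfms, prefix_len = 41,
                              strand = c("both", "forward")) {
  strand <- match.arg(strand)
  long_enough <- nchar(probes$sequence) >= prefix_len
  if (any(!long_enough))
    warning("skipping ", sum(!long_enough), " probe(s) shorter than ",
            prefix_len, " nt")
  probes <- probes[long_enough, , drop = FALSE]
  if (nrow(probes) < 3L)
    stop("fewer than 3 usable probes")
  prefixes <- substr(probes$sequence, 1L, prefix_len)
  log_int <- log(probes$intensity)
  single <- inherits(pfms, "pfm")
  if (single) pfms <- list(pfms)
  codes <- .encode_dna_matrix(prefixes)
  r <- vapply(pfms, function(p) {
    pearson(log(.occupancy_codes(codes, .pfm_logprobs(p), strand)), log_int)
  }, numeric(1))
  names(r) <- vapply(pfms, motif_id, character(1))
  if (single) unname(r[1L]) else r
}
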