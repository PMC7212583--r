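# Position frequency matrices: construction, parsing, regularization,
# PFM <-> PWM conversion, and summary features.
#
# Base order is fixed as (A, C, G, T) throughout the package; every format
# reader maps its input onto this order.

.BASES <- c("A", "C", "G", "T")

#' Construct a position frequency matrix (PFM)
#'
#' A PFM holds per-position base probabilities for a binding motif: a
#' 4 x L numeric matrix with rows in the fixed order (A, C, G, T) and
#' columns summing to one. The PFM is the central scoring object of the
#' benchmarking protocols; the position weight matrix (PWM) of log-ratio
#' weights is derived from it via [pfm_to_pwm()].
#'
#' @param mat Numeric 4 x L matrix of base probabilities, rows in
#'   (A, C, G, T) order, each column summing to 1 (tolerance `1e-3`).
#' @param matrix_id Identifier of the matrix (e.g. a JASPAR accession).
#' @param gene_symbol Optional gene symbol of the transcription factor the
#'   matrix is assigned to in its source database.
#' @param source Origin of the matrix.
#' @return An object of class `"pfm"`: the probability matrix with
#'   attributes `matrix_id`, `gene_symbol`, `source` and `regularized`.
#' @seealso [regularize_pfm()], [pfm_to_pwm()], [motif_features()]
#' @examples
#' p <- pfm(matrix(0.25, 4, 3), "uniform3")
#' motif_length(p)
#' @export
pfm <- function(mat, matrix_id,
                gene_symbol = NA_character_,
                source = c("synthetic", "JASPAR", "HOCOMOCO", "CISBP")) {
  source <- match.arg(source)
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L)
    stop("a PFM must have 4 rows in (A, C, G, T) order")
  if (ncol(mat) < 1L)
    stop("a PFM must have at least one column")
  storage.mode(mat) <- "double"
  if (anyNA(mat) || any(!is.finite(mat)) || any(mat < 0))
    stop("PFM entries must be finite and non-negative")
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-3))
    stop("PFM column(s) ", paste(which(abs(cs - 1) > 1e-3), collapse = ", "),
         " do not sum to 1 (max deviation ",
         format(max(abs(cs - 1))), ")")
  dimnames(mat) <- list(.BASES, NULL)
  structure(mat,
            class = "pfm",
            matrix_id = as.character(matrix_id),
            gene_symbol = as.character(gene_symbol),
            source = source,
            regularized = all(mat > 0))
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("PFM %s (%s)%s, length %d, %s\n",
              motif_id(x), attr(x, "source"),
              if (is.na(attr(x, "gene_symbol"))) ""
              else paste0(" gene ", attr(x, "gene_symbol")),
              motif_length(x),
              if (isTRUE(attr(x, "regularized"))) "regularized"
              else "not regularized"))
  print(round(pfm_matrix(x), 4))
  invisible(x)
}

#' @rdname pfm
#' @param x A `pfm` object.
#' @export
pfm_matrix <- function(x) {
  stopifnot(inherits(x, "pfm"))
  m <- unclass(x)
  attributes(m) <- list(dim = dim(m), dimnames = dimnames(m))
  m
}

#' @rdname pfm
#' @export
motif_id <- function(x) attr(x, "matrix_id")

#' @rdname pfm
#' @export
motif_length <- function(x) ncol(x)

#' Uniform mononucleotide background
#'
#' Background base probabilities \eqn{q_b} used when converting a PFM into
#' log-ratio weights and when scoring ambiguous (N) bases. The default is
#' uniform (0.25 per base).
#'
#' @param probs Probability 4-vector over (A, C, G, T) summing to 1.
#' @return Named numeric 4-vector.
#' @export
background <- function(probs = rep(0.25, 4)) {
  probs <- as.numeric(probs)
  if (length(probs) != 4L || any(probs <= 0) || abs(sum(probs) - 1) > 1e-6)
    stop("background must be 4 positive probabilities summing to 1")
  names(probs) <- .BASES
  probs
}

#' Regularize a PFM with a small additive correction term
#'
#' Adds a correction term `epsilon` to every matrix element and renormalizes
#' each position-specific probability distribution:
#' \eqn{p' = (p + \epsilon) / (1 + 4\epsilon)}. This guarantees strictly
#' positive probabilities so that logarithms (PWM weights, log occupancy
#' scores) are defined.
#'
#' @param x A `pfm`.
#' @param epsilon Correction term added to each element; default `1e-4`.
#' @return The regularized `pfm` (attribute `regularized` set accordingly).
#' @export
regularize_pfm <- function(x, epsilon = 1e-4) {
  stopifnot(inherits(x, "pfm"))
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0)
    stop("epsilon must be a single non-negative number")
  m <- pfm_matrix(x)
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-6))
    stop("cannot regularize: column(s) ",
         paste(which(abs(cs - 1) > 1e-6), collapse = ", "),
         " do not sum to 1 within 1e-6")
  m2 <- (m + epsilon) / (1 + 4 * epsilon)
  out <- pfm(m2, motif_id(x), attr(x, "gene_symbol"))
  attr(out, "source") <- attr(x, "source")
  attr(out, "regularized") <- all(m2 > 0)
  out
}

#' Convert a PFM into position weight matrix (log-ratio) form
#'
#' Each weight is the logarithm of the base probability over the background
#' probability, \eqn{w_{b,i} = \log(p_{b,i} / q_b)}; a weight is zero
#' wherever the motif probability equals the background. The default
#' logarithm is natural: benchmark results depend only on score ranks,
#' which any log base preserves.
#'
#' @param x A regularized `pfm` (all entries strictly positive).
#' @param bg Background probabilities, see [background()].
#' @param log_base Base of the logarithm; default `exp(1)`.
#' @return A 4 x L matrix of class `"pwm_weights"` with attributes
#'   `matrix_id`, `log_base` and `background`.
#' @export
pfm_to_pwm <- function(x, bg = background(), log_base = exp(1)) {
  stopifnot(inherits(x, "pfm"))
  m <- pfm_matrix(x)
  if (any(m <= 0))
    stop("PFM contains zero probabilities; regularize_pfm() it first")
  w <- log(m / bg) / log(log_base)
  structure(w, class = "pwm_weights",
            matrix_id = motif_id(x), log_base = log_base, background = bg)
}

#' @rdname pfm_to_pwm
#' @param w A `"pwm_weights"` matrix produced by [pfm_to_pwm()].
#' @return `pwm_to_pfm()` returns the `pfm` recovered from the weights.
#' @export
pwm_to_pfm <- function(w) {
  stopifnot(inherits(w, "pwm_weights"))
  bg <- attr(w, "background")
  b <- attr(w, "log_base")
  m <- bg * b^unclass(w)
  attributes(m) <- list(dim = dim(w))
  m <- sweep(m, 2L, colSums(m), "/")  # remove floating-point drift
  pfm(m, attr(w, "matrix_id"))
}

#' Basic motif features: length, GC content, information content
#'
#' GC content is the mean over positions of \eqn{p(C) + p(G)}. Information
#' content per position is the mean of \eqn{2 - H} where \eqn{H} is the
#' Shannon entropy of the column in bits (the quantity visualized by
#' sequence logos).
#'
#' @param x A `pfm`.
#' @return A list with elements `length`, `gc_content` and
#'   `ic_per_position` (bits).
#' @export
motif_features <- function(x) {
  stopifnot(inherits(x, "pfm"))
  m <- pfm_matrix(x)
  plogp <- ifelse(m > 0, m * log2(m), 0)
  ic <- 2 + colSums(plogp)
  list(length = ncol(m),
       gc_content = mean(m["C", ] + m["G", ]),
       ic_per_position = mean(ic))
}

.renorm_columns <- function(m, where) {
  # Public motif files carry rounded probabilities; columns off by <= 1e-3
  # are renormalized with a warning, worse deviations are errors.
  cs <- colSums(m)
  dev <- abs(cs - 1)
  if (any(dev > 1e-3))
    stop(where, ": column(s) ", paste(which(dev > 1e-3), collapse = ", "),
         " deviate from sum 1 by more than 1e-3")
  if (any(dev > 1e-6)) {
    warning(where, ": renormalized ", sum(dev > 1e-6),
            " column(s) with rounding deviations up to ",
            format(max(dev)), call. = FALSE)
    m <- sweep(m, 2L, cs, "/")
  }
  m
}

#' Read a MEME minimal-format motif collection
#'
#' Parses MEME minimal motif format: an optional header (`MEME version`,
#' `ALPHABET= ACGT`, background lines) followed by `MOTIF` blocks, each
#' with a `letter-probability matrix:` section whose rows give the
#' probabilities of A, C, G, T at one motif position. Probabilities are
#' stored exactly as printed (no regularization); columns deviating from
#' sum 1 by more than rounding error are renormalized with a warning.
#'
#' @param path Path to a MEME-format motif file.
#' @param source Source label attached to every parsed matrix.
#' @return Named list of `pfm` objects, in file order.
#' @export
read_meme <- function(path, source = "synthetic") {
  lines <- readLines(path, warn = FALSE)
  motif_at <- grep("^MOTIF\\b", lines)
  if (!length(motif_at))
    stop("no MOTIF blocks found in ", path)
  out <- vector("list", length(motif_at))
  ids <- character(length(motif_at))
  bounds <- c(motif_at, length(lines) + 1L)
  for (k in seq_along(motif_at)) {
    header <- strsplit(trimws(lines[motif_at[k]]), "\\s+")[[1]]
    if (length(header) < 2L)
      stop("MOTIF line ", motif_at[k], " has no identifier")
    id <- header[2L]
    block <- lines[seq(motif_at[k] + 1L, bounds[k + 1L] - 1L)]
    lpm <- grep("^\\s*letter-probability matrix", block)
    if (!length(lpm))
      stop("motif ", id, ": no letter-probability matrix section")
    rows <- list()
    for (j in seq(lpm[1L] + 1L, length(block))) {
      ln <- trimws(block[j])
      if (ln == "" || grepl("^(URL|MOTIF)\\b", ln)) break
      fields <- strsplit(ln, "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(fields))
      if (length(vals) != 4L || anyNA(vals) || any(vals < 0))
        stop("motif ", id, ", file line ", motif_at[k] + j,
             ": malformed probability row '", ln, "'")
      rows[[length(rows) + 1L]] <- vals
    }
    if (!length(rows))
      stop("motif ", id, ": empty letter-probability matrix")
    m <- .renorm_columns(t(do.call(rbind, rows)), paste("motif", id))
    out[[k]] <- pfm(m, id, source = source)
    ids[k] <- id
  }
  names(out) <- ids
  out
}

#' Write motifs in MEME minimal format
#'
#' @param pfms A `pfm` or list of `pfm` objects.
#' @param path Output file path.
#' @param digits Decimal places for probabilities (default 6).
#' @return `path`, invisibly.
#' @export
write_meme <- function(pfms, path, digits = 6) {
  if (inherits(pfms, "pfm")) pfms <- list(pfms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (p in pfms) {
    m <- pfm_matrix(p)
    writeLines(sprintf("MOTIF %s", motif_id(p)), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      ncol(m)), con)
    fmt <- paste0("%.", digits, "f")
    writeLines(apply(m, 2L, function(col)
      paste(sprintf(fmt, col), collapse = "  ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a CIS-BP per-matrix text file
#'
#' CIS-BP distributes one matrix per text file as position rows with four
#' probability columns (A, C, G, T), usually preceded by a header row and
#' a leading position-index column; a header row is detected by a
#' non-numeric first field.
#'
#' @param path Path to the matrix file.
#' @param matrix_id Identifier for the matrix; defaults to the file name
#'   without extension.
#' @return A `pfm`.
#' @export
read_cisbp_matrix <- function(path, matrix_id = NULL) {
  if (is.null(matrix_id))
    matrix_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != ""]
  if (!length(lines)) stop("empty CIS-BP matrix file: ", path)
  first <- strsplit(lines[1L], "\\s+")[[1]][1L]
  if (is.na(suppressWarnings(as.numeric(first))))
    lines <- lines[-1L]
  rows <- lapply(seq_along(lines), function(j) {
    fields <- strsplit(lines[j], "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) == 5L && !is.na(vals[1L])) vals <- vals[-1L]
    if (length(vals) != 4L || anyNA(vals) || any(vals < 0))
      stop("CIS-BP matrix ", matrix_id, ", row ", j,
           ": expected 4 probability columns, got '", lines[j], "'")
    vals
  })
  m <- .renorm_columns(t(do.call(rbind, rows)),
                       paste("CIS-BP matrix", matrix_id))
  out <- pfm(m, matrix_id, source = "CISBP")
  out
}

#' Read a matrix-to-gene/family annotation table
#'
#' Tab-separated table with columns `matrix_id`, `gene_symbol`,
#' `tfclass_family`, `cisbp_family` mapping each matrix to the factor it
#' is assigned to and the structural families of that factor's DNA
#' binding domain. Families are treated as opaque labels.
#'
#' @param path Path to the TSV file (header required).
#' @return A data frame with the four annotation columns.
#' @export
read_motif_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("matrix_id", "gene_symbol", "tfclass_family", "cisbp_family")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  df[need]
}
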