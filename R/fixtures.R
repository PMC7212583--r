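# Seeded synthetic-data generators with planted ground truth. These
# produce every input format the benchmarking protocols consume (genome
# FASTA + peak BED, SELEX FASTQ libraries, PBM probe tables) so the whole
# pipeline is testable offline, with known generating motifs.

#' Random PFM from a symmetric Dirichlet
#'
#' Each column is drawn independently from a symmetric Dirichlet
#' distribution. Small concentration values give peaked, information-rich
#' columns; large values approach the uniform matrix.
#'
#' @param L Motif length.
#' @param concentration Dirichlet concentration parameter (> 0).
#' @param seed Optional integer seed.
#' @param matrix_id Identifier for the generated matrix.
#' @return An (unregularized) `pfm`.
#' @export
random_pfm <- function(L, concentration = 0.5, seed = NULL,
                       matrix_id = "random_pfm") {
  stopifnot(L >= 1, concentration > 0)
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(stats::rgamma(4L * L, shape = concentration), nrow = 4L)
  m <- sweep(g, 2L, colSums(g), "/")
  pfm(m, matrix_id, source = "synthetic")
}

#' Noisy copy of a PFM
#'
#' Resamples each column from a Dirichlet distribution centred on the
#' template column (`shape = concentration * p + 0.05`). Large
#' concentrations give near-identical copies, small ones heavily
#' degraded variants; a set of copies at decreasing concentrations
#' emulates a motif family whose member matrices differ in quality.
#'
#' @param x Template `pfm`.
#' @param concentration Dirichlet concentration scaling (> 0).
#' @param matrix_id Identifier for the copy.
#' @param seed Optional integer seed.
#' @return An (unregularized) `pfm`.
#' @export
noisy_pfm <- function(x, concentration, matrix_id = "noisy_copy",
                      seed = NULL) {
  stopifnot(inherits(x, "pfm"), concentration > 0)
  if (!is.null(seed)) set.seed(seed)
  m <- pfm_matrix(x)
  g <- matrix(stats::rgamma(length(m), shape = concentration * m + 0.05),
              nrow = 4L)
  pfm(sweep(g, 2L, colSums(g), "/"), matrix_id, source = "synthetic")
}

#' Random DNA sequences from a mononucleotide background
#'
#' @param n Number of sequences.
#' @param len Sequence length.
#' @param probs Background base probabilities over (A, C, G, T).
#' @return Character vector of length `n`.
#' @export
random_dna <- function(n, len, probs = rep(0.25, 4)) {
  cols <- lapply(seq_len(len), function(i)
    sample(.BASES, n, replace = TRUE, prob = probs))
  do.call(paste0, cols)
}

# One sequence sampled per column of a PFM, n times.
.sample_words <- function(x, n) {
  m <- pfm_matrix(x)
  cols <- lapply(seq_len(ncol(m)), function(i)
    sample(.BASES, n, replace = TRUE, prob = m[, i]))
  do.call(paste0, cols)
}

#' Synthetic ChIP-seq experiment with a planted motif
#'
#' Generates a background genome from a mononucleotide model, places
#' `n_peaks` evenly spaced peak anchors, plants a sample from the true
#' motif at each anchor with probability `planting_rate`, and assigns
#' peak scores correlated with planting (planted peaks score higher, so
#' the top-ranked peaks are enriched for true sites). The negative
#' control windows at offset `d` see only background. Optionally writes
#' a FASTA genome and a 10-column BED peak file (summit in column 10).
#'
#' @param true_pfm Generating `pfm`.
#' @param n_peaks Number of peaks.
#' @param params [chip_params()] describing the geometry the benchmark
#'   will use; anchors are spaced so that positive and control windows
#'   never collide or leave the chromosome.
#' @param planting_rate Probability that a peak carries a motif instance.
#' @param background_probs Mononucleotide background probabilities.
#' @param seed Integer seed.
#' @param fasta,bed Optional output paths.
#' @return List with `genome` (named character), `peaks` (data frame as
#'   from [read_peaks()]), `planted` (logical vector), `anchors`.
#' @export
synth_chipseq <- function(true_pfm, n_peaks = 300,
                          params = chip_params(w = 50, n_top = 200,
                                               d = 150, min_peaks = 1),
                          planting_rate = 0.7,
                          background_probs = rep(0.25, 4),
                          seed = 1, fasta = NULL, bed = NULL) {
  set.seed(seed)
  L <- ncol(true_pfm); w <- params$w; d <- abs(params$d)
  spacing <- 2L * (w + d) + L + 50L
  glen <- spacing * (n_peaks + 1L)
  gvec <- sample(.BASES, glen, replace = TRUE, prob = background_probs)
  anchors <- spacing * (seq_len(n_peaks) - 1L) + w + d + 25L  # 0-based
  planted <- stats::runif(n_peaks) < planting_rate
  words <- .sample_words(true_pfm, n_peaks)
  for (i in which(planted)) {
    st <- anchors[i] - floor(L / 2)           # 0-based start of the site
    gvec[(st + 1L):(st + L)] <- strsplit(words[i], "")[[1]]
  }
  genome <- c(chrS = paste(gvec, collapse = ""))
  score <- stats::rnorm(n_peaks, mean = 5 + 3 * planted, sd = 1)
  peaks <- data.frame(chrom = "chrS",
                      start = anchors - w,
                      end = anchors + w + 1,
                      name = sprintf("peak%04d", seq_len(n_peaks)),
                      score = score,
                      summit = w,
                      stringsAsFactors = FALSE)
  if (!is.null(fasta))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), fasta)
  if (!is.null(bed))
    utils::write.table(
      data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                 peaks$score, ".", 0, -1, -1, peaks$summit),
      bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  list(genome = genome, peaks = peaks, planted = planted,
       anchors = anchors)
}

#' Synthetic HT-SELEX experiment by iterative selection
#'
#' Cycle 0 is a uniform random insert library; each subsequent cycle
#' resamples reads (with replacement) with probability proportional to
#' the sum occupancy of the extended read under the true motif,
#' emulating one round of binding selection and giving geometric
#' enrichment over cycles. Optionally writes one FASTQ file per cycle.
#'
#' @param true_pfm Generating `pfm`.
#' @param libname Parsed library name from [parse_library_name()].
#' @param n_reads Reads per cycle.
#' @param rounds Number of selection rounds after cycle 0.
#' @param seed Integer seed.
#' @param fastq_dir Optional directory for per-cycle FASTQ files.
#' @return List of character vectors of inserts, one per cycle
#'   (`cycle0` ... `cycleR`).
#' @export
synth_selex <- function(true_pfm, libname, n_reads = 1000, rounds = 2,
                        seed = 1, fastq_dir = NULL) {
  set.seed(seed)
  cycles <- vector("list", rounds + 1L)
  cycles[[1L]] <- random_dna(n_reads, libname$insert_len)
  for (r in seq_len(rounds)) {
    wgt <- sum_occupancy(extend_insert(cycles[[r]], libname), true_pfm)
    idx <- sample.int(n_reads, n_reads, replace = TRUE, prob = wgt)
    cycles[[r + 1L]] <- cycles[[r]][idx]
  }
  names(cycles) <- paste0("cycle", 0:rounds)
  if (!is.null(fastq_dir)) {
    for (nm in names(cycles)) {
      reads <- Biostrings::DNAStringSet(cycles[[nm]])
      names(reads) <- sprintf("read%06d", seq_along(reads))
      qual <- Biostrings::PhredQuality(
        rep(strrep("I", libname$insert_len), length(reads)))
      Biostrings::writeQualityScaledXStringSet(
        Biostrings::QualityScaledDNAStringSet(reads, qual),
        file.path(fastq_dir, paste0(nm, ".fastq")))
    }
  }
  cycles
}

#' Synthetic weakly enriched SELEX library with planted sites
#'
#' A fraction `plant_rate` of the inserts carries one instance sampled
#' from the true motif; the rest are pure background. `plant_offset`
#' places the motif start relative to the insert start (0-based); a
#' negative offset makes the site straddle the 5' insert boundary, in
#' which case only the in-insert part of the site is written (the
#' flanking part is expected to be supplied by the barcode, emulating
#' binding sites completed by the constant library context).
#'
#' @param true_pfm Generating `pfm`.
#' @param libname Parsed library name from [parse_library_name()].
#' @param n_reads Number of inserts.
#' @param plant_rate Fraction of inserts carrying a site.
#' @param plant_offset Site offset, or `NULL` for a uniform random
#'   in-insert position per read.
#' @param seed Integer seed.
#' @return List with `inserts` (character) and `planted` (logical).
#' @export
synth_selex_planted <- function(true_pfm, libname, n_reads = 1000,
                                plant_rate = 0.10, plant_offset = NULL,
                                seed = 1) {
  set.seed(seed)
  il <- libname$insert_len
  L <- ncol(true_pfm)
  if (il < L && (is.null(plant_offset) || plant_offset >= 0))
    stop("insert shorter than the motif; use a negative plant_offset")
  inserts <- random_dna(n_reads, il)
  planted <- stats::runif(n_reads) < plant_rate
  words <- .sample_words(true_pfm, n_reads)
  for (i in which(planted)) {
    off <- if (is.null(plant_offset))
      sample.int(il - L + 1L, 1L) - 1L else plant_offset
    word <- words[i]
    if (off < 0) {                 # site starts in the 5' flank
      word <- substr(word, 1L - off, L)
      off <- 0L
    }
    word <- substr(word, 1L, il - off)
    substr(inserts[i], off + 1L, off + nchar(word)) <- word
  }
  list(inserts = inserts, planted = planted)
}

#' Synthetic PBM probe table
#'
#' Random probes whose log intensity equals the log sum occupancy of the
#' probe's first `prefix_len` bases under the true motif plus Gaussian
#' noise; intensities are exponentiated back to a positive scale.
#' Optionally writes a two-column (intensity, sequence) TSV readable by
#' [read_uniprobe_table()].
#'
#' @param true_pfm Generating `pfm`.
#' @param n_probes Number of probes.
#' @param probe_len Probe length (must be at least `prefix_len`).
#' @param noise_sd Standard deviation of the Gaussian noise on the log
#'   intensity.
#' @param seed Integer seed.
#' @param prefix_len Scored prefix length (default 41).
#' @param path Optional output TSV path.
#' @return Data frame with columns `sequence` and `intensity`.
#' @export
synth_pbm <- function(true_pfm, n_probes = 200, probe_len = 60,
                      noise_sd = 0.5, seed = 1, prefix_len = 41,
                      path = NULL) {
  if (probe_len < prefix_len)
    stop("probe_len must be at least prefix_len (", prefix_len, ")")
  set.seed(seed)
  seqs <- random_dna(n_probes, probe_len)
  mu <- log_sum_occupancy(substr(seqs, 1L, prefix_len), true_pfm)
  intensity <- exp(mu + stats::rnorm(n_probes, sd = noise_sd))
  df <- data.frame(sequence = seqs, intensity = intensity,
                   stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(df[, c("intensity", "sequence")], path,
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  df
}

#' Synthetic benchmarking cohort with planted generating motifs
#'
#' The full-pipeline recovery fixture: one true motif per gene plus a
#' pool of decoy matrices, and per gene a set of ChIP-seq, HT-SELEX and
#' PBM experiments generated from the gene's true motif. All candidate
#' matrices are benchmarked on all experiments, yielding a long-format
#' [performance_table()] from which [best_matrix_per_gene()] should
#' recover the generating matrix.
#'
#' @param n_genes Number of synthetic factors.
#' @param n_decoys Number of unrelated decoy matrices.
#' @param n_chip,n_selex,n_pbm Experiments per gene and assay.
#' @param motif_len Length of all generated motifs.
#' @param concentration Dirichlet concentration for motif columns.
#' @param seed Integer seed controlling everything.
#' @return List with `perf` (a `performance_table`), `truth` (data frame
#'   mapping `gene_symbol` to the generating `matrix_id`), and
#'   `matrices` (named list of all candidate `pfm`s, regularized).
#' @export
synth_cohort <- function(n_genes = 8, n_decoys = 32, n_chip = 3,
                         n_selex = 2, n_pbm = 1, motif_len = 10,
                         concentration = 0.3, seed = 1) {
  set.seed(seed)
  genes <- sprintf("GENE%02d", seq_len(n_genes))
  truths <- lapply(seq_len(n_genes), function(g)
    random_pfm(motif_len, concentration,
               matrix_id = sprintf("TRUE_%02d", g)))
  decoys <- lapply(seq_len(n_decoys), function(k)
    random_pfm(motif_len, concentration,
               matrix_id = sprintf("DECOY_%02d", k)))
  matrices <- lapply(c(truths, decoys), regularize_pfm)
  names(matrices) <- vapply(matrices, motif_id, character(1))
  cp <- chip_params(w = 50, n_top = 100, d = 150, min_peaks = 1)
  rows <- list()
  add <- function(id, gene, assay, values) {
    rows[[length(rows) + 1L]] <<- data.frame(
      experiment_id = id, gene_symbol = gene, assay = assay,
      matrix_id = names(values), value = unname(values),
      stringsAsFactors = FALSE)
  }
  sub_seed <- function(g, k, what) seed * 7919L + g * 101L + k * 13L + what
  for (g in seq_len(n_genes)) {
    truth <- matrices[[sprintf("TRUE_%02d", g)]]
    for (k in seq_len(n_chip)) {
      sim <- synth_chipseq(truth, n_peaks = 150, params = cp,
                           seed = sub_seed(g, k, 1L))
      auc <- run_chipseq_benchmark(sim$peaks, sim$genome, matrices,
                                   cp, enforce_min_peaks = FALSE)
      add(sprintf("%s_chip%02d", genes[g], k), genes[g], "chipseq", auc)
    }
    for (k in seq_len(n_selex)) {
      set.seed(sub_seed(g, k, 2L))
      bc5 <- paste(sample(.BASES, 6, replace = TRUE), collapse = "")
      bc3 <- paste(sample(.BASES, 3, replace = TRUE), collapse = "")
      lib <- parse_library_name(
        sprintf("%s_%s20N%s", genes[g], bc5, bc3))
      sim <- synth_selex_planted(truth, lib, n_reads = 300,
                                 plant_rate = 0.3,
                                 seed = sub_seed(g, k, 3L))
      pos <- extend_insert(sim$inserts, lib)
      neg <- shuffle_negatives(pos, lib, seed = sub_seed(g, k, 4L))
      auc <- run_selex_benchmark(pos, neg, matrices, q = 0.10)
      add(sprintf("%s_selex%02d", genes[g], k), genes[g], "selex10", auc)
    }
    for (k in seq_len(n_pbm)) {
      probes <- synth_pbm(truth, n_probes = 120, noise_sd = 0.5,
                          seed = sub_seed(g, k, 5L))
      r <- run_pbm_benchmark(probes, matrices)
      add(sprintf("%s_pbm%02d", genes[g], k), genes[g], "pbm", r)
    }
  }
  all <- do.call(rbind, rows)
  perf <- performance_table(all$experiment_id, all$gene_symbol,
                            all$assay, all$matrix_id, all$value)
  list(perf = perf,
       truth = data.frame(gene_symbol = genes,
                          matrix_id = sprintf("TRUE_%02d",
                                              seq_len(n_genes)),
                          stringsAsFactors = FALSE),
       matrices = matrices)
}
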