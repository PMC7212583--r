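# All-against-all performance table: within-experiment ranks, aggregate
# rank scores (geometric mean of ranks, lower = better), best matrix per
# gene, quality filters, family-level cross-performance tables, and the
# non-redundant library.

.ASSAYS <- c("chipseq", "selex10", "selex50", "pbm")
.AUC_ASSAYS <- c("chipseq", "selex10", "selex50")

#' Assemble a long-format performance table
#'
#' One row per (experiment, matrix) combination carrying the performance
#' value: AUC ROC for ChIP-seq and HT-SELEX assays, Pearson r for PBM.
#' Missing combinations are simply absent (never imputed).
#'
#' @param experiment_id Experiment identifiers.
#' @param gene_symbol Gene symbol of the factor each experiment targets.
#' @param assay One of `"chipseq"`, `"selex10"`, `"selex50"`, `"pbm"`.
#' @param matrix_id Matrix identifiers.
#' @param value Performance values (AUC in `[0,1]`; r in `[-1,1]`).
#' @return A validated data frame of class `"perf_table"`.
#' @export
performance_table <- function(experiment_id, gene_symbol, assay,
                              matrix_id, value) {
  df <- data.frame(experiment_id = as.character(experiment_id),
                   gene_symbol = as.character(gene_symbol),
                   assay = as.character(assay),
                   matrix_id = as.character(matrix_id),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$assay), .ASSAYS)
  if (length(bad))
    stop("unknown assay(s): ", paste(bad, collapse = ", "))
  if (anyNA(df$value) || any(!is.finite(df$value)))
    stop("performance values must be finite")
  auc <- df$assay %in% .AUC_ASSAYS
  if (any(df$value[auc] < 0 | df$value[auc] > 1))
    stop("AUC values must lie in [0, 1]")
  if (any(abs(df$value[!auc]) > 1))
    stop("correlation values must lie in [-1, 1]")
  if (anyDuplicated(df[c("experiment_id", "matrix_id")]))
    stop("duplicated (experiment, matrix) combination")
  class(df) <- c("perf_table", "data.frame")
  df
}

#' Convert one experiment's performance values into ranks
#'
#' The best (highest) value gets rank 1; ties receive the average of the
#' spanned ranks; missing values get no rank.
#'
#' @param values Numeric vector of performance values for one experiment
#'   (one row of the experiments x matrices table), `NA` for matrices
#'   without a value.
#' @return Numeric vector of ranks (NA preserved).
#' @export
ranks_within_experiment <- function(values) {
  if (all(is.na(values)))
    stop("cannot rank an experiment with no performance values")
  rank(-values, ties.method = "average", na.last = "keep")
}

# Add a 'rnk' column: within-experiment ranks over all matrices evaluated
# on that experiment.
.perf_with_ranks <- function(perf) {
  perf$rnk <- stats::ave(perf$value, perf$experiment_id,
                         FUN = ranks_within_experiment)
  perf
}

#' Aggregate rank score of a matrix for a gene
#'
#' Performance values are converted to within-experiment ranks, and the
#' overall performance of a matrix over all experiments attributed to a
#' gene (within one assay group) is the geometric mean of those ranks:
#' the aggregate rank score. Lower is better; the minimum 1 means the
#' matrix ranked first in every experiment.
#'
#' @param perf A [performance_table()].
#' @param matrix_id Matrix to score.
#' @param gene Gene symbol whose experiments are aggregated.
#' @param assays Assay group; experiments of other assays are ignored.
#'   Different assay types are analyzed separately by default in the
#'   study design, but a vector may be given for a global score.
#' @return The aggregate rank score (>= 1).
#' @export
aggregate_rank_score <- function(perf, matrix_id, gene,
                                 assays = .ASSAYS) {
  perf <- .perf_with_ranks(perf)
  rows <- perf$matrix_id == matrix_id & perf$gene_symbol == gene &
    perf$assay %in% assays
  if (!any(rows))
    stop("matrix ", matrix_id, " has no ", paste(assays, collapse = "/"),
         " performance values for gene ", gene)
  exp(mean(log(perf$rnk[rows])))
}

#' Best-performing matrix for each gene by aggregate rank score
#'
#' For every gene with experiments in the assay group, picks the matrix
#' with the best (lowest) aggregate rank score over all experiments
#' attributed to that gene. Ties are broken by higher mean raw
#' performance, then by lexicographic matrix id.
#'
#' @param perf A [performance_table()].
#' @param assays Assay group (see [aggregate_rank_score()]).
#' @param genes Genes to report; default all genes present in the group.
#' @return Data frame with one row per gene: `gene_symbol`, `matrix_id`,
#'   `aggregate_rank`, `mean_value`, `n_experiments`.
#' @export
best_matrix_per_gene <- function(perf, assays = .ASSAYS, genes = NULL) {
  perf <- .perf_with_ranks(perf)
  perf <- perf[perf$assay %in% assays, , drop = FALSE]
  if (is.null(genes)) genes <- sort(unique(perf$gene_symbol))
  res <- lapply(genes, function(g) {
    sub <- perf[perf$gene_symbol == g, , drop = FALSE]
    if (!nrow(sub)) stop("gene ", g, " has no experiments in this group")
    agg <- vapply(split(sub, sub$matrix_id), function(s)
      c(score = exp(mean(log(s$rnk))),
        mean_value = mean(s$value),
        n = nrow(s)), numeric(3))
    ord <- order(agg["score", ], -agg["mean_value", ], colnames(agg))
    best <- ord[1L]
    data.frame(gene_symbol = g,
               matrix_id = colnames(agg)[best],
               aggregate_rank = agg["score", best],
               mean_value = agg["mean_value", best],
               n_experiments = agg["n", best],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Quality-filter a best-matrix report
#'
#' Keeps only (gene, matrix) pairs whose best raw performance passes the
#' assay-appropriate strict threshold: AUC ROC > `auc_min` for ChIP-seq
#' or HT-SELEX experiments, or Pearson r > `r_min` for PBM experiments
#' ("or" semantics across assays).
#'
#' @param report Data frame from [best_matrix_per_gene()].
#' @param perf The [performance_table()] the report was derived from.
#' @param auc_min AUC threshold (default 0.75, strict inequality).
#' @param r_min Pearson threshold (default 0.35, strict inequality).
#' @return The filtered report.
#' @export
quality_filter <- function(report, perf, auc_min = 0.75, r_min = 0.35) {
  pass <- vapply(seq_len(nrow(report)), function(i) {
    sub <- perf[perf$gene_symbol == report$gene_symbol[i] &
                  perf$matrix_id == report$matrix_id[i], , drop = FALSE]
    auc <- sub$value[sub$assay %in% .AUC_ASSAYS]
    r <- sub$value[sub$assay == "pbm"]
    (length(auc) && max(auc) > auc_min) || (length(r) && max(r) > r_min)
  }, logical(1))
  report[pass, , drop = FALSE]
}

#' Family-level cross-performance table
#'
#' Cell (F1, F2) is the mean performance of all matrices annotated to
#' family F1 over all experiments whose target factor belongs to family
#' F2. Rows with fewer than `min_pwms` distinct matrices and columns with
#' fewer than `min_datasets` distinct experiments are omitted, mirroring
#' the display filters of family heatmaps.
#'
#' @param perf A [performance_table()], typically restricted to one assay.
#' @param annotation Data frame from [read_motif_annotation()] (or with
#'   the same columns).
#' @param family_col Which annotation column defines families
#'   (`"tfclass_family"` or `"cisbp_family"`).
#' @param min_pwms,min_datasets Minimum counts for a family row/column.
#' @return Numeric matrix (PWM families x experiment families) of mean
#'   performance values; `NA` where no data contribute.
#' @export
family_cross_table <- function(perf, annotation,
                               family_col = "tfclass_family",
                               min_pwms = 2, min_datasets = 2) {
  mat_fam <- annotation[[family_col]][match(perf$matrix_id,
                                            annotation$matrix_id)]
  gene_map <- annotation[!duplicated(annotation$gene_symbol), ]
  exp_fam <- gene_map[[family_col]][match(perf$gene_symbol,
                                          gene_map$gene_symbol)]
  keep <- !is.na(mat_fam) & !is.na(exp_fam)
  perf <- perf[keep, , drop = FALSE]
  mat_fam <- mat_fam[keep]; exp_fam <- exp_fam[keep]
  pwm_counts <- tapply(perf$matrix_id, mat_fam,
                       function(x) length(unique(x)))
  ds_counts <- tapply(perf$experiment_id, exp_fam,
                      function(x) length(unique(x)))
  rows <- names(pwm_counts)[pwm_counts >= min_pwms]
  cols <- names(ds_counts)[ds_counts >= min_datasets]
  out <- matrix(NA_real_, length(rows), length(cols),
                dimnames = list(rows, cols))
  means <- tapply(perf$value, list(mat_fam, exp_fam), mean)
  common_r <- intersect(rows, rownames(means))
  common_c <- intersect(cols, colnames(means))
  out[common_r, common_c] <- means[common_r, common_c]
  out
}

#' Small non-redundant motif library from benchmarking
#'
#' The union over genes of the best-performing matrix per gene; the same
#' matrix is often best for many factors of a family, so duplicates
#' collapse and the library is much smaller than the input collection.
#'
#' @param perf A [performance_table()].
#' @param assays Assay group used for the per-gene selection.
#' @param quality Apply [quality_filter()] before taking the union.
#' @param auc_min,r_min Thresholds passed to [quality_filter()].
#' @return Character vector of matrix ids (sorted, unique).
#' @export
nonredundant_library <- function(perf, assays = .ASSAYS, quality = FALSE,
                                 auc_min = 0.75, r_min = 0.35) {
  report <- best_matrix_per_gene(perf, assays)
  if (quality)
    report <- quality_filter(report, perf, auc_min, r_min)
  sort(unique(report$matrix_id))
}
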