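# Small literal performance tables exercising rank conversion, geometric
# mean aggregation, tie-breaking, quality filtering and family tables.

toy_perf <- function() {
  # two genes, two assays, three matrices; M1 is best for G1, M2 for G2
  performance_table(
    experiment_id = rep(c("e1", "e2", "e3"), each = 3),
    gene_symbol = rep(c("G1", "G1", "G2"), each = 3),
    assay = rep(c("chipseq", "chipseq", "pbm"), each = 3),
    matrix_id = rep(c("M1", "M2", "M3"), 3),
    value = c(0.9, 0.7, 0.8,
              0.85, 0.8, 0.6,
              0.2, 0.5, 0.4))
}

test_that("performance tables validate assays, ranges, and duplicates", {
  expect_s3_class(toy_perf(), "perf_table")
  expect_error(performance_table("e", "g", "rnaseq", "m", 0.5), "assay")
  expect_error(performance_table("e", "g", "chipseq", "m", 1.2), "AUC")
  expect_error(performance_table("e", "g", "pbm", "m", -1.5), "correlation")
  expect_error(performance_table(c("e", "e"), "g", "chipseq",
                                 c("m", "m"), c(0.5, 0.6)), "duplicated")
})

test_that("within-experiment ranks put the best value first and average ties", {
  expect_equal(ranks_within_experiment(c(0.9, 0.7, 0.8)), c(1, 3, 2))
  expect_equal(ranks_within_experiment(c(0.9, 0.9)), c(1.5, 1.5))
  expect_equal(ranks_within_experiment(0.4), 1)
  expect_equal(ranks_within_experiment(c(0.9, NA, 0.8)), c(1, NA, 2))
  expect_error(ranks_within_experiment(c(NA_real_, NA_real_)), "no performance")
})

test_that("aggregate rank score is the geometric mean of within-experiment ranks", {
  perf <- toy_perf()
  # M1 ranks 1 and 1 in G1's two ChIP experiments
  expect_equal(aggregate_rank_score(perf, "M1", "G1", "chipseq"), 1)
  # M3 ranks 2 and 3 -> sqrt(6)
  expect_equal(aggregate_rank_score(perf, "M3", "G1", "chipseq"), sqrt(6))
  # single experiment: the rank itself
  expect_equal(aggregate_rank_score(perf, "M1", "G2", "pbm"), 3)
  expect_error(aggregate_rank_score(perf, "M1", "G2", "chipseq"),
               "no chipseq")
  # ranks 1 and 4 over two experiments give 2.0
  p2 <- performance_table(rep(c("a", "b"), each = 4), "G", "chipseq",
                          rep(c("m1", "m2", "m3", "m4"), 2),
                          c(0.9, 0.8, 0.7, 0.6, 0.1, 0.4, 0.3, 0.9))
  expect_equal(aggregate_rank_score(p2, "m1", "G", "chipseq"), sqrt(1 * 4))
})

test_that("aggregate rank score is bounded and order-invariant", {
  set.seed(41)
  for (k in 1:20) {
    nm <- sample(3:8, 1); ne <- sample(2:5, 1)
    ids <- paste0("m", seq_len(nm))
    perf <- performance_table(
      rep(paste0("e", seq_len(ne)), each = nm), "G", "chipseq",
      rep(ids, ne), runif(nm * ne))
    s <- aggregate_rank_score(perf, "m1", "G", "chipseq")
    expect_gte(s, 1); expect_lte(s, nm)
    shuf <- perf[sample.int(nrow(perf)), ]
    perf2 <- performance_table(shuf$experiment_id, shuf$gene_symbol,
                               shuf$assay, shuf$matrix_id, shuf$value)
    expect_equal(aggregate_rank_score(perf2, "m1", "G", "chipseq"), s)
  }
})

test_that("best matrix per gene minimizes aggregate rank with stated tie-breaks", {
  perf <- toy_perf()
  best <- best_matrix_per_gene(perf, "chipseq")
  expect_equal(best$matrix_id[best$gene_symbol == "G1"], "M1")
  # tie on aggregate rank broken by higher mean raw value
  p <- performance_table(c("a", "a", "b", "b"), "G", "chipseq",
                         c("m1", "m2", "m1", "m2"),
                         c(0.9, 0.8, 0.7, 0.9))
  # both have rank set {1, 2}; m2 mean 0.85 beats m1 mean 0.80
  expect_equal(best_matrix_per_gene(p, "chipseq")$matrix_id, "m2")
  # exact tie everywhere falls back to lexicographic id
  p2 <- performance_table(c("a", "a"), "G", "chipseq", c("mB", "mA"),
                          c(0.8, 0.8))
  expect_equal(best_matrix_per_gene(p2, "chipseq")$matrix_id, "mA")
  # a single matrix is trivially best
  p3 <- performance_table("a", "G", "chipseq", "only", 0.6)
  expect_equal(best_matrix_per_gene(p3, "chipseq")$matrix_id, "only")
})

test_that("adding a strictly dominated matrix never changes the winner", {
  set.seed(42)
  for (k in 1:10) {
    nm <- sample(3:6, 1); ne <- sample(2:4, 1)
    ids <- paste0("m", seq_len(nm))
    vals <- matrix(runif(nm * ne, 0.3, 0.9), ne, nm)
    perf <- performance_table(rep(paste0("e", 1:ne), each = nm), "G",
                              "chipseq", rep(ids, ne), as.vector(t(vals)))
    before <- best_matrix_per_gene(perf, "chipseq")$matrix_id
    dom <- apply(vals, 1, min) - 0.1  # worse in every experiment
    perf2 <- performance_table(
      c(rep(paste0("e", 1:ne), each = nm), paste0("e", 1:ne)), "G",
      "chipseq", c(rep(ids, ne), rep("zzz_dominated", ne)),
      c(as.vector(t(vals)), dom))
    expect_identical(best_matrix_per_gene(perf2, "chipseq")$matrix_id,
                     before)
  }
})

test_that("quality filter applies strict assay-appropriate thresholds with OR semantics", {
  perf <- performance_table(
    experiment_id = c("c1", "c2", "p1", "p2"),
    gene_symbol = c("G1", "G2", "G1", "G3"),
    assay = c("chipseq", "chipseq", "pbm", "pbm"),
    matrix_id = "M",
    value = c(0.75, 0.80, 0.36, 0.10))
  report <- data.frame(gene_symbol = c("G1", "G2", "G3"),
                       matrix_id = "M", stringsAsFactors = FALSE)
  kept <- quality_filter(report, perf)
  # G1: AUC exactly 0.75 fails the strict bound but r = 0.36 passes (OR)
  expect_setequal(kept$gene_symbol, c("G1", "G2"))
  # with only the failing assay the boundary case is excluded
  kept2 <- quality_filter(report[1, , drop = FALSE],
                          perf[perf$assay == "chipseq", ])
  expect_equal(nrow(kept2), 0L)
})

test_that("family cross tables average within family pairs and apply count filters", {
  ann <- data.frame(
    matrix_id = c("m1", "m2", "m3"),
    gene_symbol = c("gA1", "gA2", "gB1"),
    tfclass_family = c("FamA", "FamA", "FamB"),
    cisbp_family = c("ca", "ca", "cb"), stringsAsFactors = FALSE)
  perf <- performance_table(
    rep(c("e1", "e2", "e3", "e4"), each = 3),
    rep(c("gA1", "gA2", "gB1", "gB1"), each = 3),
    "chipseq",
    rep(c("m1", "m2", "m3"), 4),
    c(0.9, 0.9, 0.5, 0.9, 0.9, 0.5, 0.5, 0.5, 0.9, 0.5, 0.5, 0.9))
  tab <- family_cross_table(perf, ann, min_pwms = 2, min_datasets = 2)
  # FamB has a single PWM -> row omitted
  expect_identical(rownames(tab), "FamA")
  expect_equal(tab["FamA", "FamA"], 0.9)
  expect_equal(tab["FamA", "FamB"], 0.5)
  # diagonal beats off-diagonal on same-family-structured data
  expect_gt(tab["FamA", "FamA"], tab["FamA", "FamB"])
})

test_that("the non-redundant library collapses shared best matrices", {
  perf <- performance_table(
    c("e1", "e2", "e3"), c("G1", "G2", "G3"), "chipseq",
    rep("shared", 3), c(0.9, 0.8, 0.85))
  expect_identical(nonredundant_library(perf), "shared")
  perf2 <- performance_table(
    rep(c("e1", "e2"), each = 2), rep(c("G1", "G2"), each = 2),
    "chipseq", rep(c("m1", "m2"), 2), c(0.9, 0.5, 0.4, 0.8))
  expect_setequal(nonredundant_library(perf2), c("m1", "m2"))
})
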