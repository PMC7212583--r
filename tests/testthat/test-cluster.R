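test_that("score distributions match brute-force word enumeration", {
  # single sharp column: the three non-A bases share one score atom
  p1 <- pfm(matrix(c(0.97, 0.01, 0.01, 0.01), 4, 1), "sharp1")
  d1 <- score_distribution(p1)
  expect_equal(nrow(d1), 2L)
  expect_equal(d1$mass, c(0.75, 0.25))          # ascending score order
  expect_equal(sum(d1$mass), 1)
  # uniform PFM: a single atom of mass 1
  u <- pfm(matrix(0.25, 4, 3), "u")
  du <- score_distribution(u)
  expect_equal(nrow(du), 1L)
  expect_equal(du$mass, 1)
  # random L = 5 motif: binned distribution matches enumeration
  p <- rpfm(5, 0.5, seed = 601)
  d <- score_distribution(p, delta = 0.01)
  sc <- enumerate_word_scores(p)
  for (t in stats::quantile(sc, c(0.5, 0.9, 0.99))) {
    expect_equal(sum(d$mass[d$score >= t]),
                 mean(sc >= t),
                 tolerance = 0.05)  # binning can move atoms near t
  }
})

test_that("p-value thresholds bound the tail and behave monotonically", {
  p <- rpfm(5, 0.5, seed = 602)
  sc <- enumerate_word_scores(p)
  for (pv in c(1, 0.25, 0.05, 0.01)) {
    t <- threshold_for_pvalue(p, pv)
    expect_lte(mean(sc >= t - 1e-9), pv + 1e-12)
    expect_equal(attr(t, "tail_mass"), mean(sc >= t - 1e-9),
                 tolerance = 1e-9)
  }
  # pvalue 1 admits every word
  t1 <- threshold_for_pvalue(p, 1)
  expect_equal(length(word_set(p, t1)), 4^5)
  # thresholds are non-increasing in the p-value
  ts <- vapply(c(0.01, 0.05, 0.2, 1), function(pv)
    as.numeric(threshold_for_pvalue(p, pv)), numeric(1))
  expect_true(all(diff(ts) <= 0))
  # a p-value below the best word's probability falls back with a warning
  sharp <- regularize_pfm(pfm(matrix(c(1, 0, 0, 0), 4, 2), "sharp"))
  expect_warning(tb <- threshold_for_pvalue(sharp, 1e-9), "best word")
  expect_length(word_set(sharp, tb), 1L)
})

test_that("a concentrated 2-column motif yields only its consensus word", {
  m <- matrix(c(0.94, 0.02, 0.02, 0.02), 4, 2)
  p <- pfm(m, "aa")
  t <- threshold_for_pvalue(p, 1 / 16)
  expect_identical(as.character(word_set(p, t)), "AA")
})

test_that("branch-and-bound word sets equal brute-force enumeration", {
  set.seed(603)
  for (k in 1:100) {
    p <- rpfm(sample(3:8, 1), 0.5)
    sc <- enumerate_word_scores(p)
    t <- stats::quantile(sc, runif(1, 0.5, 0.999))
    ws <- word_set(p, t)
    expect_identical(as.character(ws), sort(names(sc)[sc >= t - 1e-9]))
  }
})

test_that("raising the threshold never adds words", {
  p <- rpfm(6, 0.5, seed = 604)
  sc <- enumerate_word_scores(p)
  ts <- stats::quantile(sc, c(0.8, 0.9, 0.99))
  sets <- lapply(ts, function(t) as.character(word_set(p, t)))
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("jaccard distance is zero on self, one on disjoint sets, and symmetric", {
  p <- rpfm(6, 0.4, seed = 605, id = "A")
  expect_equal(jaccard_distance(p, p, pvalue = 0.01), 0)
  # poly-A vs poly-C at a p-value admitting only the consensus word
  pa <- regularize_pfm(pfm(matrix(c(0.97, 0.01, 0.01, 0.01), 4, 4), "pa"),
                       0)
  pc <- regularize_pfm(pfm(matrix(c(0.01, 0.97, 0.01, 0.01), 4, 4), "pc"),
                       0)
  expect_equal(jaccard_distance(pa, pc, pvalue = 1 / 256, revcomp = FALSE),
               1)
  set.seed(606)
  for (k in 1:20) {
    a <- rpfm(sample(3:6, 1), 0.5, id = "a")
    b <- rpfm(sample(3:6, 1), 0.5, id = "b")
    dab <- jaccard_distance(a, b, pvalue = 0.05)
    expect_equal(dab, jaccard_distance(b, a, pvalue = 0.05),
                 tolerance = 1e-12)
    expect_gte(dab, 0); expect_lte(dab, 1)
  }
})

test_that("jaccard similarity maximization matches span-word enumeration", {
  # independent oracle: enumerate all words of the aligned span and test
  # membership of both subwords, at every offset and orientation
  brute_jaccard <- function(a, b, pvalue) {
    sets_codes <- function(p) {
      sc <- enumerate_word_scores(p)
      t <- threshold_for_pvalue(p, pvalue)
      which(sc >= t - 1e-9) - 1L      # 0-based word codes
    }
    LA <- motif_length(a); LB <- motif_length(b)
    SA <- sets_codes(a)
    best <- 0
    for (orient in 1:2) {
      bb <- if (orient == 1) b else revcomp_pfm_oracle(b)
      SB <- sets_codes(bb)
      for (s in (-LB + 1):(LA - 1)) {
        span <- max(LA, s + LB) - min(0, s)
        astart <- -min(0, s)          # 0-based position of A in the span
        bstart <- s - min(0, s)
        x <- 0:(4^span - 1)
        subcode <- function(p0, len)
          (x %/% 4^(span - p0 - len)) %% 4^len
        inA <- subcode(astart, LA) %in% SA
        inB <- subcode(bstart, LB) %in% SB
        uni <- sum(inA | inB)
        sim <- if (uni == 0) 0 else sum(inA & inB) / uni
        if (sim > best) best <- sim
      }
    }
    1 - best
  }
  set.seed(607)
  for (k in 1:12) {
    a <- rpfm(sample(3:5, 1), 0.4, id = "a")
    b <- rpfm(sample(3:5, 1), 0.4, id = "b")
    expect_equal(jaccard_distance(a, b, pvalue = 0.05),
                 brute_jaccard(a, b, 0.05), tolerance = 1e-12)
  }
})

test_that("UPGMA reproduces hand-computed merges and the halt rule", {
  d <- matrix(c(0, 0.2, 0.6,
                0.2, 0, 0.6,
                0.6, 0.6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cl <- upgma_cluster(d, cutoff = 0.95)
  expect_length(cl$clusters, 1L)
  expect_equal(cl$merges$height, c(0.2, 0.6))
  expect_identical(cl$merges$label1, c("A", "A"))
  # all distances at 0.96 with cutoff 0.95: only singletons
  d2 <- matrix(0.96, 3, 3, dimnames = dimnames(d)); diag(d2) <- 0
  expect_length(upgma_cluster(d2, 0.95)$clusters, 3L)
  # intermediate cutoff splits off the distant motif
  cl3 <- upgma_cluster(d, cutoff = 0.5)
  expect_length(cl3$clusters, 2L)
  expect_setequal(cl3$clusters[[which(lengths(cl3$clusters) == 2)]],
                  c("A", "B"))
})

test_that("UPGMA merge heights agree with hclust average linkage", {
  set.seed(608)
  for (k in 1:5) {
    n <- sample(5:9, 1)
    m <- matrix(runif(n * n), n)
    d <- (m + t(m)) / 2; diag(d) <- 0
    dimnames(d) <- list(paste0("x", 1:n), paste0("x", 1:n))
    ours <- upgma_cluster(d, cutoff = Inf)
    ref <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(sort(ours$merges$height), sort(ref$height),
                 tolerance = 1e-12)
  }
})

test_that("partitions are invariant under motif relabeling", {
  set.seed(609)
  n <- 8
  m <- matrix(runif(n * n, 0.1, 1), n)
  d <- (m + t(m)) / 2; diag(d) <- 0
  dimnames(d) <- list(paste0("m", 1:n), paste0("m", 1:n))
  cl <- upgma_cluster(d, cutoff = 0.6)
  perm <- sample.int(n)
  dp <- d[perm, perm]
  clp <- upgma_cluster(dp, cutoff = 0.6)
  canon <- function(cl) sort(vapply(cl$clusters, function(x)
    paste(sort(x), collapse = "+"), character(1)))
  expect_identical(canon(cl), canon(clp))
})

test_that("cluster count is monotonically non-increasing in the cutoff", {
  set.seed(610)
  n <- 10
  m <- matrix(runif(n * n), n)
  d <- (m + t(m)) / 2; diag(d) <- 0
  dimnames(d) <- list(paste0("m", 1:n), paste0("m", 1:n))
  counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9, 1),
                   function(h) length(upgma_cluster(d, h)$clusters),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("representatives minimize mean within-cluster distance", {
  d <- matrix(c(0, 0.1, 0.1,
                0.1, 0, 0.5,
                0.1, 0.5, 0), 3, 3,
              dimnames = list(c("med", "b", "c"), c("med", "b", "c")))
  expect_identical(cluster_representative(c("med", "b", "c"), d), "med")
  expect_identical(cluster_representative("solo", d), "solo")
  # an exact duplicate (distance zero twin) always wins over distant members
  d2 <- matrix(c(0, 0, 0.8,
                 0, 0, 0.8,
                 0.8, 0.8, 0), 3, 3,
               dimnames = list(c("t1", "t2", "far"), c("t1", "t2", "far")))
  expect_identical(cluster_representative(c("far", "t2", "t1"), d2), "t1")
})
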