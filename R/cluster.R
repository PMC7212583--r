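# Benchmark-blind motif clustering: score distributions under a uniform
# background, p-value-matched word-set thresholds, word-set Jaccard
# distances over all alignment offsets and orientations, UPGMA trees with
# a merge cutoff, and representative selection.

# Reverse complement of a PFM: reverse column order, swap A<->T and C<->G.
.revcomp_pfm <- function(x) {
  m <- pfm_matrix(x)[4:1, ncol(x):1, drop = FALSE]
  out <- pfm(m, paste0(motif_id(x), "_rc"))
  attr(out, "regularized") <- attr(x, "regularized")
  out
}

.cluster_logprobs <- function(x) {
  m <- pfm_matrix(x)
  if (any(m <= 0))
    stop("motif clustering requires a regularized PFM (no zero entries); ",
         "see regularize_pfm()")
  log(m)
}

#' Distribution of word log-probability scores under a background
#'
#' Exact distribution of the per-word log probability (sum of per-position
#' log probabilities) over all 4^L words, with word probabilities taken
#' from the background model. Computed by positionwise convolution with
#' scores binned at width `delta`, so the support size stays bounded for
#' long motifs; the binning error of a score is at most `L * delta / 2`.
#'
#' @param x A regularized `pfm`.
#' @param bg Background base probabilities, see [background()].
#' @param delta Bin width for the score axis (log units).
#' @return Data frame with columns `score` (ascending) and `mass`
#'   (summing to 1).
#' @export
score_distribution <- function(x, bg = background(), delta = 0.01) {
  logp <- .cluster_logprobs(x)
  keys <- 0; mass <- 1
  for (i in seq_len(ncol(logp))) {
    kb <- round(logp[, i] / delta)
    newk <- as.vector(outer(keys, kb, "+"))
    newm <- as.vector(outer(mass, bg, "*"))
    agg <- rowsum(newm, group = newk)
    keys <- as.numeric(rownames(agg))
    mass <- unname(agg[, 1L])
    ord <- order(keys)
    keys <- keys[ord]; mass <- mass[ord]
  }
  data.frame(score = keys * delta, mass = mass)
}

# Exact per-word scores and probabilities by full enumeration (4^L words).
.enumerate_word_scores <- function(logp, bg) {
  L <- ncol(logp)
  codes <- 0:(4^L - 1)
  score <- numeric(length(codes))
  lprob <- numeric(length(codes))
  logbg <- log(bg)
  for (i in seq_len(L)) {
    digit <- (codes %/% 4^(L - i)) %% 4
    score <- score + logp[digit + 1L, i]
    lprob <- lprob + logbg[digit + 1L]
  }
  list(score = score, prob = exp(lprob))
}

#' Score threshold matching a word-set p-value
#'
#' The smallest threshold `t` such that the probability of a word scoring
#' at least `t` under the background does not exceed `pvalue`; this makes
#' word-set sizes comparable across motifs. For motifs up to
#' `exact_max_length` positions the threshold is computed exactly by
#' enumerating all words; longer motifs use the binned score
#' distribution.
#'
#' @param x A regularized `pfm`.
#' @param pvalue Target tail probability (word-set size fraction under
#'   the background); default 5e-4.
#' @param bg Background base probabilities.
#' @param delta Bin width for the binned path, see [score_distribution()].
#' @param exact_max_length Maximum motif length for the exact
#'   enumeration path.
#' @return The threshold (log-probability units) with the achieved tail
#'   mass attached as attribute `tail_mass`. If even the single best word
#'   exceeds `pvalue`, its score is returned with a warning.
#' @export
threshold_for_pvalue <- function(x, pvalue = 5e-4, bg = background(),
                                 delta = 0.01, exact_max_length = 8L) {
  if (pvalue <= 0 || pvalue > 1)
    stop("pvalue must lie in (0, 1]")
  if (ncol(x) <= exact_max_length) {
    ws <- .enumerate_word_scores(.cluster_logprobs(x), bg)
    agg <- rowsum(ws$prob, group = round(ws$score, 9))
    score <- as.numeric(rownames(agg)); mass <- unname(agg[, 1L])
    ord <- order(score); score <- score[ord]; mass <- mass[ord]
  } else {
    d <- score_distribution(x, bg, delta)
    score <- d$score; mass <- d$mass
  }
  tail <- rev(cumsum(rev(mass)))  # P(score >= score[i])
  ok <- which(tail <= pvalue + 1e-12)
  if (!length(ok)) {
    warning("pvalue ", pvalue, " smaller than the best word's probability; ",
            "returning the top score")
    ok <- length(score)
  }
  i <- min(ok)
  structure(unname(score[i]), tail_mass = unname(tail[i]))
}

#' Words recognized by a motif above a score threshold
#'
#' Enumerates all words of the motif's length whose log-probability score
#' is at least `t`, by depth-first search with best-possible-suffix
#' pruning (a prefix is abandoned as soon as even the best completion
#' cannot reach `t`). A tolerance of 1e-9 guards threshold comparisons
#' against floating-point round-off.
#'
#' @param x A regularized `pfm`.
#' @param t Score threshold, typically from [threshold_for_pvalue()].
#' @param max_words Error out if the set would exceed this size (pick a
#'   smaller `pvalue` in that case).
#' @return Character vector of words (sorted), with attribute
#'   `threshold`.
#' @export
word_set <- function(x, t, max_words = 250000L) {
  logp <- .cluster_logprobs(x)
  L <- ncol(logp)
  t <- t - 1e-9
  suffix_best <- c(rev(cumsum(rev(apply(logp, 2L, max)))), 0)
  acc <- new.env(parent = emptyenv())
  acc$words <- character(0)
  bases <- c("A", "C", "G", "T")
  dfs <- function(prefix, score, i) {
    if (i > L) {
      if (length(acc$words) >= max_words)
        stop("word set exceeds max_words = ", max_words,
             "; use a smaller pvalue")
      acc$words[length(acc$words) + 1L] <- prefix
      return(invisible())
    }
    for (b in 1:4) {
      s2 <- score + logp[b, i]
      if (s2 + suffix_best[i + 1L] >= t)
        dfs(paste0(prefix, bases[b]), s2, i + 1L)
    }
  }
  dfs("", 0, 1L)
  structure(sort(acc$words), threshold = t + 1e-9)
}

# Jaccard similarity of the two aligned word sets at one offset:
# B is shifted by `s` columns relative to A. The aligned span covers the
# union of both motifs' columns; a span word belongs to a motif's
# extended set iff its subword over that motif's columns is in the
# motif's word set (columns outside a motif's span are unconstrained).
.alignment_similarity <- function(SA, SB, LA, LB, s) {
  span <- max(LA, s + LB) - min(0L, s)
  nA <- length(SA) * 4^(span - LA)
  nB <- length(SB) * 4^(span - LB)
  if (nA == 0 || nB == 0) return(0)
  ov_start <- max(0L, s); ov_end <- min(LA, s + LB)  # 0-based in A coords
  ka <- substr(SA, ov_start + 1L, ov_end)
  kb <- substr(SB, ov_start - s + 1L, ov_end - s)
  ca <- table(ka); cb <- table(kb)
  common <- intersect(names(ca), names(cb))
  inter <- sum(as.numeric(ca[common]) * as.numeric(cb[common]))
  inter / (nA + nB - inter)
}

#' Word-set Jaccard distance between two motifs
#'
#' Word sets are computed for both motifs at the same p-value. For every
#' relative offset at which the motifs overlap by at least one column,
#' and for both orientations of the second motif, the Jaccard index of
#' the two aligned (freely extended) word sets is evaluated; the distance
#' is one minus the maximum similarity.
#'
#' @param a,b Regularized `pfm` objects.
#' @param pvalue Word-set p-value shared by both motifs.
#' @param bg Background base probabilities.
#' @param delta Score-distribution bin width.
#' @param revcomp Also consider the reverse-complement orientation of
#'   `b` (default `TRUE`).
#' @param max_words Passed to [word_set()].
#' @return Distance in `[0, 1]`.
#' @export
jaccard_distance <- function(a, b, pvalue = 5e-4, bg = background(),
                             delta = 0.01, revcomp = TRUE,
                             max_words = 250000L) {
  .jaccard_from_sets(.motif_word_sets(a, pvalue, bg, delta, revcomp,
                                      max_words),
                     .motif_word_sets(b, pvalue, bg, delta, revcomp,
                                      max_words),
                     revcomp)
}

# Word sets of a motif (forward and, when needed, reverse complement) at
# its p-value-matched threshold; precomputed once per motif so that
# all-pairs distance matrices do not re-enumerate sets per pair.
.motif_word_sets <- function(x, pvalue, bg, delta, revcomp, max_words) {
  t <- threshold_for_pvalue(x, pvalue, bg, delta)
  list(L = ncol(x),
       fwd = word_set(x, t, max_words),
       rc = if (revcomp) word_set(.revcomp_pfm(x), t, max_words))
}

.jaccard_from_sets <- function(wa, wb, revcomp) {
  orientations <- list(wb$fwd)
  if (revcomp) orientations <- c(orientations, list(wb$rc))
  best <- 0
  for (SB in orientations) {
    for (s in seq(-wb$L + 1L, wa$L - 1L)) {
      sim <- .alignment_similarity(wa$fwd, SB, wa$L, wb$L, s)
      if (sim > best) best <- sim
    }
  }
  1 - best
}

#' Pairwise motif distance matrix
#'
#' Symmetric matrix of [jaccard_distance()] values with zero diagonal,
#' ready for [upgma_cluster()].
#'
#' @param pfms List of regularized `pfm` objects.
#' @inheritParams jaccard_distance
#' @return Symmetric numeric matrix with matrix ids as dimnames.
#' @export
motif_distance_matrix <- function(pfms, pvalue = 5e-4, bg = background(),
                                  delta = 0.01, revcomp = TRUE,
                                  max_words = 250000L) {
  n <- length(pfms)
  ids <- vapply(pfms, motif_id, character(1))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  sets <- lapply(pfms, .motif_word_sets, pvalue = pvalue, bg = bg,
                 delta = delta, revcomp = revcomp, max_words = max_words)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d[i, j] <- d[j, i] <- .jaccard_from_sets(sets[[i]], sets[[j]],
                                                 revcomp)
      }
    }
  }
  d
}

#' UPGMA clustering with a merge cutoff
#'
#' Standard unweighted pair group method with arithmetic mean: repeatedly
#' merge the two clusters at minimal average distance, updating distances
#' as size-weighted averages. Aggregation halts before any merge whose
#' inter-cluster average distance reaches `cutoff` or more; the returned
#' partition is the state at that point, while the merge history covers
#' the full tree. Ties in the minimal distance are broken by the
#' lexicographically smallest pair of cluster labels (a cluster is
#' labelled by its smallest member id) for determinism.
#'
#' @param d Symmetric distance matrix with dimnames (e.g. from
#'   [motif_distance_matrix()]) or a [stats::dist] object.
#' @param cutoff Halt threshold on the merge distance (default 0.95).
#' @return List with `clusters` (list of member-id vectors at the
#'   cutoff), `membership` (named integer vector), and `merges` (data
#'   frame of the full merge history: `label1`, `label2`, `height`,
#'   `size`).
#' @export
upgma_cluster <- function(d, cutoff = 0.95) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d)) || any(diag(d) != 0))
    stop("d must be a symmetric distance matrix with zero diagonal")
  n <- nrow(d)
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  members <- as.list(ids)
  labels <- ids
  sizes <- rep(1L, n)
  D <- unname(d)
  merges <- data.frame(label1 = character(0), label2 = character(0),
                       height = numeric(0), size = integer(0),
                       stringsAsFactors = FALSE)
  partition <- NULL
  while (length(members) > 1L) {
    m <- length(members)
    best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        cand <- list(i = i, j = j, h = D[i, j],
                     pair = sort(c(labels[i], labels[j])))
        if (is.null(best) || cand$h < best$h ||
            (cand$h == best$h &&
             (cand$pair[1] < best$pair[1] ||
              (cand$pair[1] == best$pair[1] && cand$pair[2] < best$pair[2]))))
          best <- cand
      }
    }
    if (is.null(partition) && best$h >= cutoff)
      partition <- members
    i <- best$i; j <- best$j
    merges <- rbind(merges, data.frame(
      label1 = best$pair[1], label2 = best$pair[2],
      height = best$h, size = sizes[i] + sizes[j],
      stringsAsFactors = FALSE))
    new_row <- (sizes[i] * D[i, ] + sizes[j] * D[j, ]) /
      (sizes[i] + sizes[j])
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], new_row[keep]),
               c(new_row[keep], 0))
    members <- c(members[keep], list(c(members[[i]], members[[j]])))
    labels <- c(labels[keep], min(labels[c(i, j)]))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
  }
  if (is.null(partition)) partition <- members
  membership <- integer(n)
  names(membership) <- ids
  for (k in seq_along(partition)) membership[partition[[k]]] <- k
  list(clusters = partition, membership = membership, merges = merges)
}

#' Representative motif of a cluster
#'
#' The member minimizing its average distance to the other members of
#' the cluster (the medoid); a singleton represents itself; ties are
#' broken by lexicographic id.
#'
#' @param cluster Character vector of member ids.
#' @param d Distance matrix whose dimnames cover the members.
#' @return The representative member id.
#' @export
cluster_representative <- function(cluster, d) {
  if (!length(cluster)) stop("empty cluster")
  if (length(cluster) == 1L) return(cluster)
  sub <- d[cluster, cluster, drop = FALSE]
  avg <- rowSums(sub) / (length(cluster) - 1L)
  cluster[order(avg, cluster)][1L]
}
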