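---
title: "Benchmarking TF binding motifs against ChIP-seq, HT-SELEX and PBM data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking TF binding motifs against ChIP-seq, HT-SELEX and PBM data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwmbench)
```

## The problem

Position weight matrices (PWMs) are the community-standard model of
transcription factor (TF) DNA binding specificity. Public collections
contain thousands of matrices, many of them redundant or of uneven
quality, and the matrix labelled with a TF's name is frequently *not*
the matrix that best predicts that TF's binding data. `pwmbench`
implements an all-against-all benchmarking workflow: every candidate
matrix is evaluated on every experiment, performance values are
aggregated into per-gene rankings, and the resulting selections can be
contrasted with what benchmark-blind motif clustering would pick.

## The scoring model

A motif of length $L$ is stored as a base probability matrix (PFM)
$p_{b,i}$ with columns over $(A, C, G, T)$. The equivalent position
weight matrix holds log-ratio weights against a background $q_b$:

$$w_{b,i} = \log \frac{p_{b,i}}{q_b}.$$

Before any scoring, matrices are regularized by adding a correction
term $\varepsilon = 10^{-4}$ to every element and renormalizing each
column, $p' = (p + \varepsilon)/(1 + 4\varepsilon)$, which keeps all
logarithms finite.

A sequence $S$ longer than the motif is scored with the **sum occupancy
score**: the sum over all sliding windows (on both strands by default)
of the window probability $\prod_i p_{S_{j+i},i}$. This is a soft,
threshold-free aggregate of predicted binding over the whole sequence.
Ambiguous `N` bases contribute the background probability 0.25; other
IUPAC codes are rejected. Strand handling is exposed as a parameter
(`strand = "both"` or `"forward"`) because only the both-strand
convention is standard for occupancy scoring; for palindromic motifs the
two differ exactly by a factor of two.

## The three protocols

**ChIP-seq** (`run_chipseq_benchmark()`). Each peak is reduced to a
single anchor: its summit if the peak file provides one, otherwise the
floor midpoint. The `n_top` top-scoring peaks are used; positives are
the $2w + 1$ bp sequences centred on the anchors, negatives same-length
windows at a fixed signed offset $d$. Both sets are scored by sum
occupancy and compared with the AUC ROC. Defaults follow the large-scale
study conditions: $w = 250$, $N = 2000$, $d = +500$, and a minimum list
size of 5000 peaks. Coordinates are 0-based half-open BED throughout;
"$\pm w$" is interpreted symmetrically inclusive, giving $2w+1$ bp
windows. Window pairs leaving chromosome bounds, or with more than 50%
`N`, are dropped together so the two sets always stay paired. Negative
windows are *not* screened against overlapping other peaks; on real,
densely bound genomes this is a known caveat of the fixed-offset
control.

**HT-SELEX** (`run_selex_benchmark()`). Library names such as
`ELK3_TCGGGG20NGGT_AG` encode gene, 5' barcode, insert length, 3'
barcode and batch. Reads are filtered to clean full-length inserts,
cycles pooled, exact duplicates removed (presumed PCR copies), and
libraries above one million reads subsampled with a seed. Crucially,
inserts are then **extended** into the constant context that was
physically present during selection: the last 20 bp of
(5' primer + 5' barcode) on the left, the first 20 bp of
(3' barcode + 3' primer) on the right. Binding sites straddling the
insert boundary are invisible to insert-only scanning; extension
recovers them. Negatives default to per-read mononucleotide shuffling of
the insert with flanks left intact, which preserves composition exactly
and is always constructible (an input/zero-cycle library can be supplied
instead). Because selected libraries are often only weakly enriched,
only the top fraction `q` of positive and of negative scores (applied to
each list separately) enters the AUC; the study conventions are
`q = 0.10` and `q = 0.50`.

**PBM** (`run_pbm_benchmark()`). For each probe the first 41 bases are
extracted (dropping most of the fixed linker), scored with the *log*
sum occupancy score, and correlated (Pearson) with the natural-log
normalized intensities. Probes shorter than the prefix are skipped with
a warning; non-positive intensities are dropped at parse time since
their log is undefined. Log bases are irrelevant to Pearson r, so
natural logs are used throughout.

## Rank aggregation and selection

Within each experiment the performance values of all evaluated matrices
are converted to ranks (1 = best, ties averaged, missing values
unranked — never imputed). The **aggregate rank score** of a matrix for
a gene is the geometric mean of its ranks over all experiments
attributed to that gene within one assay group; assay types
(`chipseq`, `selex10`, `selex50`, `pbm`) are analyzed separately by
default, with a pooled run giving a globally best matrix per gene. The
phrase "highest aggregate rank" is implemented as the *best* (minimal)
geometric-mean rank, consistent with rank 1 being best. Ties are broken
by higher mean raw performance, then lexicographic matrix id.

Quality filters use strict inequalities — AUC ROC > 0.75 for ChIP-seq
and HT-SELEX, Pearson r > 0.35 for PBM — combined with OR semantics
across assays. `nonredundant_library()` collapses the per-gene winners
into a small motif set, and `family_cross_table()` averages performance
over (matrix family, experiment family) cells, omitting families with
fewer than 2 matrices or 2 datasets.

## Benchmark-blind clustering

The alternative, benchmark-free route to a compact library clusters
motifs by the similarity of the **word sets** they recognize. For each
motif a score threshold is chosen so that the probability of a random
word reaching it under a uniform background is at most a shared p-value
(default $5 \times 10^{-4}$, configurable — the convention is a tool
parameter, not a published constant, and all tests pin it explicitly).
For motifs up to 8 positions the threshold is derived from the exact
enumeration of all $4^L$ word scores; longer motifs use a positionwise
convolution of the score distribution binned at $\delta = 0.01$ log
units (binning displaces a score by at most $L\delta/2$). Enumerating
all $4^L$ words exactly is quadratic-exponential and was capped at
$L \le 8$ (65,536 words) to keep threshold computation effectively
instantaneous; the binned path bounds the support size for arbitrary
lengths. Word sets themselves are enumerated exactly at any length by
depth-first search with best-possible-suffix pruning, with a $10^{-9}$
tolerance guarding threshold comparisons against floating-point
round-off.

The distance between two motifs is one minus the maximal Jaccard index
of their aligned word sets over all relative offsets with at least one
overlapping column and both orientations of the second motif (reverse
complement consideration is a parameter, on by default, since the
convention is not fixed by any published value). Columns outside a
motif's span are unconstrained, i.e. each set is freely extended over
the aligned span; the Jaccard index is then computed by counting
word-pairs that agree on the overlap, which avoids materializing the
extended sets.

Motifs are clustered by UPGMA on these distances. Merging halts before
the first merge whose average-linkage distance reaches 0.95 ("distance
between merging clusters" is read as the UPGMA linkage value at the
proposed merge); ties in the minimal distance are broken by the
lexicographically smallest label pair for determinism. Each cluster is
represented by its medoid — the member minimizing the mean distance to
the others.

## Synthetic data with planted truth

All protocols are exercised on seeded generators
(`synth_chipseq()`, `synth_selex()`, `synth_selex_planted()`,
`synth_pbm()`, `synth_cohort()`) that emit the standard input formats
(FASTA + BED, FASTQ, two-column probe tables) with known generating
motifs:

* ChIP fixtures plant a motif sample at each peak anchor with a given
  probability and give planted peaks higher scores, so top-N selection
  is enriched for true sites; the control windows at offset $d$ see
  pure background.
* SELEX fixtures either run explicit selection rounds (resampling reads
  proportionally to occupancy, which enriches geometrically) or plant a
  site in a fraction of inserts; a negative `plant_offset` places the
  site across the 5' insert boundary so that only barcode-aware
  scanning sees it whole.
* PBM fixtures set log intensity to log occupancy plus Gaussian noise.

Default fixture scales (hundreds of peaks/reads/probes, motif length
8–10, Dirichlet concentration 0.3 for generating motifs, ChIP planting
rate 0.7, SELEX planting rate 0.3, PBM noise SD 0.5) were chosen once
as a realistic desk-scale miniature of the study conditions: strong but
imperfect enrichment, weakly informative single experiments, and enough
replication (3 ChIP + 2 SELEX + 1 PBM experiments per gene, 8 genes, 40
candidate matrices in the recovery cohort) for rank aggregation to be
meaningfully tested. The recovery experiment in the test suite runs
five such cohorts in about a minute on one core.

What the generators deliberately do **not** model: read errors and
quality values, nucleosome occupancy and chromatin accessibility,
sequence-composition biases of real genomes (a GC-skewed background is
available but uniform is the default), PCR duplication structure, and
de Bruijn probe design. Passing tests therefore demonstrate the
correctness and calibration of the *machinery* — not that any particular
public matrix collection will reach a particular performance level on
real data.

## Numerical choices and degenerate inputs

* AUC is computed by the tie-aware rank method, guaranteeing the
  Mann–Whitney identity (ties count half); it is checked against
  explicit pair counting in the tests.
* `top_fraction()` takes exactly $\lceil qn \rceil$ scores, breaking
  boundary ties by stable input order.
* Motif file columns deviating from sum 1 by $\le 10^{-3}$ (rounding in
  public files) are renormalized with a warning; worse deviations are
  errors.
* Degenerate cases error loudly rather than returning NA: empty score
  sets, zero-variance correlation inputs, all-missing rank rows,
  sequences shorter than the motif, fewer than 10 usable peak pairs.
* Identical positive and negative sets yield AUC exactly 0.5 under the
  tie rule.

## Known limitations

The package benchmarks mononucleotide PWMs only — no dinucleotide or
k-mer models. The ChIP-seq negative-control strategy is the fixed-offset
genomic window; matched-accessibility controls are out of scope. Motif
clustering representatives are selected, never averaged into consensus
matrices. The t-SNE embedding of performance profiles and interactive
visualization of the published study are likewise out of scope here.
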