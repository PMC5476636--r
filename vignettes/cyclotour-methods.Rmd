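---
title: "Recovering circular cell-cycle pseudotime: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering circular cell-cycle pseudotime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cyclotour` reconstructs a circular pseudotime from unsynchronized
single-cell transcriptomes and segments it into cell-cycle stages. This
vignette is the package's own account of the underlying models, the
parameters that matter, and the places where the design was genuinely open
— including the choices we made and why.

## The model chain

### Preprocessing

Cells are kept when strictly more than `min_genes` genes exceed
`min_expr` (defaults 4000 and 2, appropriate for TPM/FPKM; counts data
need platform-specific thresholds, which is why both are arguments rather
than constants). Genes with mean expression below `min_mean = 2` are
dropped — the boundary is inclusive, since the rule deletes genes *lower*
than the threshold. Depth is normalized by median-of-ratios size factors
whose reference set is the genes positive in *every* cell, without
pseudo-counts. In sparse single-cell data this reference set can be empty;
`deseq_size_factors()` then errors with advice, while the
`preprocess_expression()` convenience chain degrades to unnormalized
log2(x+1) with a loud warning rather than silently inventing
pseudo-counted factors. All downstream modelling operates on
log2(x + 1), which tames the right tail of expression and makes the
lognormal-Gaussian approximation of negative-binomial noise reasonable.

### Clustering and the consensus tour

Cells are clustered by a Gaussian mixture fit with EM, k-means-seeded with
`n_init` restarts. Covariances are **diagonal with a variance floor of
1e-6** by default: with a few hundred catalog genes and clusters of tens
of cells, full covariances are singular, and the floor keeps degenerate
clusters (k close to n) well-defined. The EM trace is retained and tested
for monotonicity.

Ordering cluster means is a Euclidean TSP, attacked with the
arbitrary-insertion heuristic: grow a sub-tour from a random edge,
inserting uniformly-chosen nodes at the cheapest position (ties break
toward the smallest insertion index so runs are reproducible). For each k
in `k_min..k_max` the best of `n_fold * k` seeded restarts is kept; on
instances small enough to enumerate, that budget reaches the exhaustive
optimum in our tests.

The merge of per-k cycles into one consensus is the one step whose
published description we could not consult in detail, so the scheme here
is our own and is stated as such: every per-k circular position vector is
aligned to the first usable k by the rotation/reflection maximizing the
resultant `|Σ exp(2πi(ref − s·p))|` (a closed form — no search), and the
consensus position is the per-cell circular mean of the aligned vectors.
The scheme is a fixed point when all tours agree and degrades gracefully
under disagreement. Within a cluster's arc, cells are spread uniformly in
the order of their projection onto the direction from the previous to the
next cluster mean — deterministic, and using only local geometry.

Defaults: `k_min = 7`, `k_max = min(floor(n/10), 30)` so clusters average
at least 10 cells, `n_fold = 2`. A master seed spawns per-(k, restart)
child seeds through a fixed integer scheme, so runs are reproducible and
embarrassingly parallel in principle.

### Stage scores

Two score families describe stage membership. The supervised
**Bayes-scores** use binary gene-pair comparisons (is gene a at least as
expressed as gene b in this cell?) as features of a Naive Bayes model with
a uniform prior over G1/S/G2M. Pair selection is our concretization:
pairs are ranked per stage by the margin between their own-stage
concordance frequency and the best other-stage frequency, the top
`pairs_per_stage = 100` per stage are unified, and probabilities are
Laplace (+1/+2) smoothed so no score is ever infinite. Equal expression
counts as the "1" outcome deterministically — with sparse data, random
tie-breaking would make scores irreproducible. Because only within-cell
comparisons enter, the scores are invariant to any monotone per-cell
transform, which is the point: they are robust to depth and scaling.

The unsupervised **mean-scores** are the mean log2 expression of the six
peak-stage marker sets (G1, G1/S, S, G2, G2/M, M) from the gene catalog.
A pre-trained pair model shipped with the package
(`inst/extdata/gene_pair_model_synthetic.json`) is trained on the
synthetic generator — it is a synthetic stand-in, labelled as such, and
`train_gene_pairs()` retrains on any labelled matrix in seconds.

### HMM segmentation and the start search

The ordered 9-dimensional score track is segmented by a left-to-right HMM
(states G0 → G1 → S → G2M, or three states without G0) with diagonal
Gaussian emissions floored at 1e-6. The chain is open — no wrap
transition — because circularity is handled by trying every rotation and
both orientations of the track and keeping the highest-likelihood start.

Two design points deserve emphasis:

* **G0's position.** The stages list G0 without placing it; biologically
  G0 branches off G1. The simplest chain consistent with
  "transitions only to a physiologically subsequent stage" puts G0 first
  (G0 → G1 → S → G2M), and that is what we implement. It is an
  interpretation, not a claim about the underlying biology.
* **Identifiability of the start.** Baum–Welch refits emissions freely,
  so the likelihood of a rotated track is (nearly) invariant to rotating
  the state labels by a block — likelihood alone cannot tell G1's block
  from S's. We therefore anchor the emission initialization to the score
  semantics: each cell gets a provisional stage from its argmax
  Bayes-score (G0, when modelled, from the bottom 15% of summed
  mean-scores — G0 cells depress every mean-score), and state means start
  at the provisional groups' means. The anchor is computed once,
  rotation-invariantly, which makes the rotation search identifiable. For
  bare matrices without score columns the initialization falls back to
  positional quantile slices.

`find_start(refit = TRUE)` refits the HMM at every rotation;
`refit = FALSE` scans all rotations with the anchored initial parameters
and refits once at the winner. In our simulations the fast path is as
accurate and roughly 20x cheaper; the pipeline uses it by default.

### Kalman smoothing and gene ranking

Per-gene series along the order follow a scalar random-walk-plus-noise
model; variances are estimated by maximum likelihood (diffuse start, first
observation's contribution dropped) from a method-of-moments
initialization. Crucially, the two **boundary models** — white noise
around a constant (σ_z = 0) and a pure random walk (σ_e = 0) — are
evaluated explicitly, and the interior fit is kept only when it beats the
better boundary in a likelihood-ratio test at the boundary (5% level,
half-χ²(1)). Pure ML never returns exactly zero; without this parsimony
rule a noise gene gets a tiny positive σ_z and its smooth becomes a
low-amplitude trend. The Rauch–Tung–Striebel pass then reproduces the
textbook limits exactly: observations when σ_e = 0, the series mean when
σ_z = 0.

Association with the cycle is measured by distance correlation and
Kraskov (type 1, max-norm, k = 3) k-NN mutual information between a
gene's series and the ordinal index 1..T — the ordinal index, not θ,
because ranking only needs the order. The MI estimator standardizes both
marginals first (max-norm neighbourhoods are meaningless across scales)
and breaks ties with an infinitesimal seeded jitter.

**Why the test statistics default to the raw series.** Both statistics
are scale-invariant. The RTS smooth of a pure-noise gene that escapes the
boundary test is a low-amplitude but perfectly smooth trend, and its
distance correlation with time is as high as a genuine oscillation's — we
verified that no ranking of smoothed statistics separates one sinusoidal
signal gene from surviving noise genes, at any of the sizes we simulated.
Testing the raw series keeps amplitude in the statistic and ranks
cleanly; the smoother remains the right tool for *estimating and
plotting* expression along the cycle (`plot_smoothed_genes()`), which is
what it is for. `smooth = TRUE` remains available, and in that mode every
permutation re-runs the fit + smooth pipeline so observed and null stay
exchangeable (p-values remain valid, just conservative, because pruned
null statistics tie at zero).

Permutation p-values shuffle the order; genes are ranked by p, ties by
the permutation z-score, then gene id; Benjamini–Hochberg q-values are
reported across genes (the multiplicity rule is ours — the choice was
open).

### Methylation overlay

Single-cell bisulfite coverage is too shallow for per-site rates, so a
CpG is called methylated when methylated reads outnumber unmethylated
ones, unmethylated in the reverse case, and **missing on ties** (including
0/0) — assigning ties to either class would bias shallow sites. Genome
levels are methylated fractions of measured sites. Promoter windows are
TSS ± 3000 bp, strand-aware, clipped at position 1; BED input is 0-based
half-open and CpG tables 1-based (the conversion is centralized in the
readers). Region-set levels are **site-pooled** across regions rather
than averaged per region — pooling is robust to regions holding a single
CpG; per-region averaging is available behind `per_region = TRUE`. Tracks
along the cycle are smoothed with a 9-point centered moving average whose
edge windows truncate, preserving length and range.

### Evaluation metrics

The correlation-score enumerates all 2k cut/reversal linearizations of a
cycle and reports the maximum Pearson correlation with the experimental
labels; cell-level orders use k = n. One boundary case is worth knowing:
even a perfectly sorted cell-level order cannot reach 1.0 against blocky
stage labels (the PCC of three blocks of 10 against ranks 1..30 is about
0.95) — only cluster-level cycles whose clusters coincide with label
blocks score exactly 1. The change-index `1 − (s_c − 2)/(N − 3)` assumes
at least the two ideal transitions; degenerate series with fewer changes
are clamped to 1 with a warning. G0 merges into label 1 by default
(configurable), matching how labelled datasets group G0 with G1.

## The synthetic generator

`simulate_expression()` emulates the statistical structure the method
assumes: phases uniform on the circle; stage arcs G1 [0, 0.40), S
[0.40, 0.70), G2M [0.70, 1); per-gene mean curves
`baseline + amplitude · exp(κ(cos 2π(φ − peak) − 1))` — a von-Mises-style
bump, chosen over a sinusoid so "peak time" is a well-defined point;
peak phases drawn as two waves centred on the G1 and G2 arcs (sd 0.07)
with a 20% uniform minority, and one gene pinned per annotated peak stage
so all six marker sets are always non-empty; negative-binomial counts
(dispersion 0.2), log-normal library sizes (sdlog 0.2), 10% dropout; and
an optional G0 arc whose cells multiply all cycle-gene means by 0.4 —
the depressed-mean-score signature the HMM exploits. Defaults are 300
cells x 200 genes. `simulate_methylome()` adds per-cell CpG tables whose
global methylation probability is elevated around a chosen phase arc.

What the generator does **not** emulate: batch effects, doublets,
cell-size confounding, gene-gene correlation beyond the shared phase, or
any real dataset's moments. Passing tests on synthetic data therefore
demonstrates the machinery recovers structure it assumes, not performance
on any particular real dataset.

## Problem sizes and numerical choices

The test suite and examples run the generator at 50-300 cells and 20-200
genes, the consensus sweep at k = 4..12, tour-oracle instances at up to 8
nodes, and the MI oracle at n = 5000 — sizes chosen so every oracle can
be computed exactly (exhaustive enumeration for tours and HMM paths,
closed forms for the smoother and Gaussian MI) while the full suite stays
in the minutes range. Variance floors are 1e-6 throughout; EM and
Baum-Welch stop on absolute log-likelihood changes (1e-8 and 1e-6); the
tie-break for hard assignments is always the lowest index.

## Known limitations

* The consensus merge is our interpretation of a published idea whose
  details were not available to us; other order-preserving merges exist.
* Orientation and start of the recovered circle are unidentifiable from
  expression alone; the HMM start search resolves them via the score
  semantics, so grossly mis-trained pair models can flip the direction.
* Exact equivariance of `consensus_order()` to permuting input cells
  holds for the deterministic steps but not across seeded k-means
  restarts (restart draws depend on cell indices).
* Bayes-scores transfer across datasets only as far as gene identifiers
  and relative expression patterns do; `subset_pair_model()` drops
  uncovered pairs but cannot repair a distribution shift.
* No batch correction: if stage labels confound with batches, scores and
  orders inherit that confounding.
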