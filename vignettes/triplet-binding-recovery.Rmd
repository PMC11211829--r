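---
title: "Triplet regulatory scoring and motif-free TF binding recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triplet regulatory scoring and motif-free TF binding recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peaktriplet)
```

# The problem

Single-cell multiome assays measure gene expression and chromatin
accessibility in the same cells. A central task in regulatory genomics is
to turn these measurements into *triplet* hypotheses — a transcription
factor (TF) binds an accessible peak and thereby regulates a target gene —
and, more ambitiously, to predict TF binding genome-wide. The standard
entry point, scanning peak sequences for TF binding motifs, has known
blind spots: motif databases are incomplete, many TFs share similar
motifs, motif presence does not imply an active binding event, and a TF
can bind (for example through a partner or a non-canonical site) where no
motif is detected at all. `peaktriplet` implements a two-stage approach
that first scores triplets within motif-bearing peaks and then uses those
calls as *pseudo-labels* to train a per-TF classifier that scores **every**
peak, motif or not.

All matrices are metacell-aggregated: transcriptionally similar cells are
pooled, counts are summed per metacell, scaled to a fixed total (default
1e4) and natural-log1p transformed (`aggregate_metacells()`). Metacells
reduce the sparsity and noise of single-cell counts while retaining the
covariation across cell states that both stages rely on.

# Stage 1 — triplet scoring

For TF $j$ with expression $X_j$, peak $i$ with accessibility $C_i$, and
candidate target gene $g$ with expression $Y_g$ (all vectors over $N$
metacells), two complementary scores are computed for every candidate
triplet in which peak $i$ carries the motif of TF $j$:

$$s^{(1)}_{ig,j} = \left(w\,\rho_{X_j,C_i} + w\,\rho_{X_j,Y_g;C_i}\right)\,
  \mathrm{minmax}(\tilde\theta_{ij}\,\tilde\pi_i)$$

$$s^{(2)}_{ij,g} = \left(w\,\rho_{Y_g,C_i} + w\,\rho_{X_j,Y_g;C_i}\right)\,
  \mathrm{minmax}(\tilde\theta_{ij}\,\tilde\pi_i)$$

Score 1 asks "does TF $j$ bind peak $i$, given the peak–gene link?";
score 2 asks "is gene $g$ the target of the peak–TF pair?". All
correlations are Spearman; the conditional term is the first-order
Spearman partial correlation, computed by the recursion formula on rank
correlations (mathematically identical to correlating the residuals of
rank-on-rank least-squares fits, which is the oracle the tests check
against to 1e-10). Rank correlations make both scores invariant under
strictly monotone transforms of the expression and accessibility values —
a useful robustness property for data whose normalization is somewhat
arbitrary.

The weight $w$ is $+0.5$ when $\rho_{X_j,C_i} \ge 0$ (inferred
activation) and $-0.5$ otherwise (inferred repression), so a coherent
repressive association (negative correlation throughout) still receives a
positive score. The sign rule is per-triplet and can be overridden.

The regularizer multiplies two quantile-transformed quantities — the
motif-match score $\tilde\theta_{ij}$ (per-TF column over positive
scores) and the peak's maximal accessibility over metacells $\tilde\pi_i$
(across peaks) — and min-max scales the product across the TF's candidate
peaks. It damps triplets whose motif evidence or accessibility is weak
relative to the TF's other candidates. Degenerate conventions: if every
product in the scope is equal, the regularizer is 1 for all peaks (no
discrimination implies no penalty); a single-peak scope gets 1. Min-max
scaling is per TF, not global, so each TF's scores use its own dynamic
range.

**Peak–gene assignment** (`assign_peaks_to_genes()`) precedes scoring:
candidate pairs must lie within `window_bp` (default ±500 kb) of the
gene's TSS and pass `rho_min` (default 0.1) on $|\rho_{Y_g,C_i}|$; then,
per peak, competing genes within `delta_rho` (default 0.05) of the peak's
best $|\rho|$ are retained and the rest dropped, which resolves most
ambiguous assignments while keeping near-ties.

**Link calling** (`call_tf_links()`): a peak joins the TF's link set when
its best score 1 over genes reaches the per-TF quantile threshold
(default: the median, i.e. the top half of motif-bearing candidates).
Ties at the threshold are kept. The link set is by construction a subset
of the TF's motif-bearing peaks.

# Stage 2 — pseudo semi-supervised binding recovery

The assumption: peaks bound by the same TF share accessibility patterns
(the cell states the TF defines) and sequence patterns (the motif content
of co-regulated peaks), so they are close in suitable latent spaces even
when the TF's own motif went undetected.

**Dual embeddings.** Truncated SVD gives each peak a $d_1$-dimensional
accessibility embedding (peak × metacell matrix, row-centered) and a
$d_2$-dimensional sequence embedding (binary peak × motif matrix,
uncentered to preserve sparsity); defaults $d_1 = d_2 = 50$, capped at
the matrix rank. Row centering is used for the continuous accessibility
profiles; the binary motif matrix is factored raw, as is standard for
binary incidence data. A deterministic sign convention (largest-magnitude
loading positive per component) makes embeddings reproducible.

**Clustering and paired groups.** Each embedding is clustered
PhenoGraph-style: a brute-force Euclidean kNN graph (default `knn = 30`),
edges weighted by the Jaccard overlap of the endpoints' neighbor sets,
partitioned with Leiden community detection (modularity objective,
seeded). Every peak then carries a pair of labels $(k, l)$; peaks sharing
both labels form the paired group $S_{kl}$. For each TF, a one-sided
Fisher exact test (the hypergeometric tail) asks whether its link set is
over-represented in each $S_{kl}$ versus all other peaks, with
Benjamini–Hochberg correction across groups and `alpha = 0.05` on the
q-value. Enrichment of a paired group is treated as corroborating
evidence of binding for its members.

**Pseudo-positives.** Over the TF's linked peaks, two scores are
quantile-normalized to [0, 1]: the accessibility–TF-expression
correlation ($s_1$) and the triplet score 1 ($s_2$). A peak is selected
when either score strictly exceeds the threshold of its group —
permissive `tau1 = 0.25` in enriched groups, stringent `tau2 = 0.75`
elsewhere.

**Pseudo-negatives** come from two pools — motif-bearing peaks without a
link (pool 1) and motif-less peaks (pool 2) — after three exclusions:
(a) peaks picked up by the "link + feature group" expansion (all
motif-less members of any paired group containing a linked peak),
(b) peaks in enriched paired groups, and (c) the union of the linked
peaks' K nearest neighbors in both embeddings (default `K = 100`). From
the surviving pools, `round(r1 * n1)` and `round(r2 * n1)` peaks are
sampled uniformly without replacement (defaults `r1 = 0.25`,
`r2 = 1.5`, giving 1.75 negatives per positive), where `n1` is the
pseudo-positive count. Rounding is half-away-from-zero, so tiny `n1`
still yields at least one pool-1 negative; a short pool is taken whole
with a warning.

**Classifier.** Features are the concatenated embeddings
($d_1 + d_2$ values per peak), standardized with training-sample
statistics. An L2-regularized logistic regression (glmnet, `alpha = 0`)
is fit on the pseudo-labels with penalty strength `l2 = 1` on the
unscaled log-likelihood (glmnet `lambda = l2 / n_train`), and applied to
all $L$ peaks, producing a binding probability for every peak — the
motif-free predictions are simply the probabilities of peaks outside the
motif set. Peaks that are neither pseudo-labeled nor excluded remain
unlabeled; prediction is transductive over the full peak set.

TFs with fewer than `min_positives` (default 20) seed links or usable
pseudo-positives are skipped with a logged reason rather than fit
unreliably. The seed links default to stage-1 output but any per-TF peak
set (e.g. raw motif hits or an external method's calls) can be supplied
to `recover_binding()`.

# Evaluation

`label_by_overlap()` labels a peak positive when it overlaps a ChIP-seq
style interval by ≥1 bp under half-open BED semantics. Metrics:

* **AUPR** is computed as average precision — the sum of precision ×
  recall increments over decreasing score thresholds with tied scores
  grouped — not trapezoidal interpolation, which is optimistic for PR
  curves.
* **Precision at fixed recall** (15% and 20%) reads the precision at the
  largest threshold whose recall reaches the target.
* **F1** of binary calls, with the convention F1 = 0 when there are no
  predicted or no recallable positives.
* **Shuffle null for F1**: predicted positive calls are reassigned
  uniformly at random within a domain (here: peaks lacking the TF's
  motif), F1 recomputed per shuffle (default 100), and the mean reported
  as the expected F1 of an uninformed predictor with the same call rate.
* **Enrichment**: one-sided Fisher exact and Pearson chi-squared
  (uncorrected) tests on the 2×2 call-by-label table.

# Association discovery

Three follow-up analyses consume the recovered motif-free binding:

* `gene_tf_gain()` asks whether adding a newly linked TF to a gene's
  previously estimated regulators improves out-of-fold linear prediction
  of the gene's expression (5-fold CV, seeded folds) by at least 0.05
  Pearson correlation. Out-of-fold prediction was chosen so the gain
  reflects generalization rather than in-sample fit; constant predictors
  are dropped, so adding one gives a gain of exactly 0. Singular normal
  equations fall back to a tiny ridge (1e-6).
* `tf_pair_interaction()` compares, per peak, the correlation of
  accessibility with each single linked TF's expression against the
  correlation with the expression *product* of each TF pair, flagging
  peaks where the best pair beats every single TF and involves the new
  TF. Spearman is the default for consistency with stage 1 (Pearson
  available); note the product of expressions is *not* invariant to
  monotone transforms of the individual TF expressions, so this analysis
  is sensitive to the expression scale in a way the triplet scores are
  not.
* `motif_coenrichment()` contrasts the motif content of peaks where
  binding was called with a detected motif (group 1) versus without one
  (group 2), one Fisher test per other motif, BH-corrected — the pattern
  of partner motifs enriched in group 2 suggests co-binding factors that
  explain motif-free binding.

# The synthetic data generator

`simulate_multiome()` plants a known truth so every stage is testable
without external data. Latent cell-state activities (one Gaussian vector
per state across metacells) drive everything: each TF's expression loads
on one state (softplus link plus Gaussian noise); each truly bound peak's
accessibility follows its TF's state through the softplus link, signed
for repressors, scaled by a per-peak amplitude drawn from U(0.5, 1.5)
(real peaks differ in dynamic range — without this, all of a TF's bound
peaks would share one maximum and the accessibility quantile transform
would rank them as a block); background peaks get independent profiles.
Each bound peak maps to one target gene whose expression is the weighted
sum of its peaks' accessibility × the linked TF's expression, plus noise.
The motif scan is the truth matrix with a fraction `motif_mask_rate` of
bound entries hidden (Bernoulli per entry) and `false_motif_rate`
spurious motifs added in unbound peaks; motif scores are uniform positive
values. Peaks occupy distinct 1 kb bins within `peak_gene_window_bp`
(50 kb) of their gene's TSS on a synthetic chromosome with genes every
50 kb, so peaks never overlap and ChIP-style intervals emitted from the
truth (`chipseq_from_truth()`) relabel it exactly. An optional
co-binding mode pairs TFs on shared states to exercise the TF-pair
analysis.

Reference conditions: 300 metacells, 10 TFs on 10 states, 5000 peaks,
500 genes, 5% of peaks bound per TF, mask rate 0.3, false-motif rate
0.05, noise SD 0.3, 20% repressors. The packaged demo pipeline uses the
same conditions at 3000 peaks and 300 genes. These sizes keep a full
end-to-end run under half a minute on one CPU while leaving ~75 masked
bound peaks per TF for the motif-free analysis.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: no sequence-level realism (motifs are planted
at the matrix level, so there is no motif similarity structure between
TFs); one dominant TF per peak by default; linear peak→gene effects with
a single gene per bound peak; no batch effects, no doublets, no
metacell-inference artifacts; ChIP-seq labels are noise-free by
construction. Performance numbers on the simulation are therefore upper
bounds: they validate the machinery (selection rules, invariants,
determinism, recovery of planted signal), not field performance on real
multiome data.

# Numerical choices

* Quantile transforms use `rank(ties = "max") / n`: tied values share
  the upper quantile, the maximum maps to 1, and an all-tied vector maps
  to all 1. One convention is used everywhere a quantile appears
  ($\tilde\theta$, $\tilde\pi$, pseudo-label scores).
* Spearman quantities use average ranks; degenerate inputs (constant
  vectors, rank-collinear conditioning) return flagged zeros, never NaN,
  and propagate as zero scores.
* Threshold comparisons in pseudo-positive selection are strict
  ($s > \tau$); link calling keeps ties ($\ge$ the quantile).
* Sampling counts round half away from zero; all sampling is without
  replacement.
* One master seed drives every stochastic step (simulation, Leiden,
  negative sampling, CV folds) through per-stage derived seeds; reruns
  with the same config and seed write byte-identical outputs, which the
  pipeline manifest (md5 per artifact) makes checkable.

# Known limitations

* The triplet scores are correlation-based: TFs whose regulatory effect
  is uncorrelated with their expression (e.g. activity controlled
  post-translationally) are invisible to stage 1 and can only enter
  stage 2 through externally supplied seed links.
* Per-TF models ignore combinatorial binding; the co-binding simulation
  mode and the TF-pair analysis only probe pairwise products.
* The classifier is linear in the embedding coordinates; strongly
  non-linear manifold structure would require a different model.
* Fisher enrichment treats paired groups as fixed; uncertainty in the
  clustering itself is not propagated.
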