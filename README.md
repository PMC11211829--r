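# peaktriplet

Peak–TF–gene triplet inference and motif-free transcription factor
binding prediction from single-cell multiome (RNA + ATAC) data.

## What it does, and for whom

Multiome assays profile gene expression and chromatin accessibility in
the same cells. For anyone reconstructing gene regulation from such data
— which transcription factor (TF) binds which accessible peak, and which
gene that peak controls — the usual starting point is motif scanning,
and its blind spots are well known: motifs are missed, shared between
TFs, or present without an actual binding event, and a TF cannot be
linked at all to a peak lacking its motif. `peaktriplet` addresses this
in two stages:

1. **Triplet scoring.** For every candidate (peak *i*, TF *j*, gene *g*)
   with the TF's motif in the peak, two complementary scores combine TF
   expression *X<sub>j</sub>*, peak accessibility *C<sub>i</sub>*, and
   target expression *Y<sub>g</sub>* across metacells:

   *s*₁ = (*w* ρ(*X<sub>j</sub>*, *C<sub>i</sub>*) + *w* ρ(*X<sub>j</sub>*, *Y<sub>g</sub>* ; *C<sub>i</sub>*)) · minmax(θ̃<sub>ij</sub> π̃<sub>i</sub>)

   *s*₂ = (*w* ρ(*Y<sub>g</sub>*, *C<sub>i</sub>*) + *w* ρ(*X<sub>j</sub>*, *Y<sub>g</sub>* ; *C<sub>i</sub>*)) · minmax(θ̃<sub>ij</sub> π̃<sub>i</sub>)

   with Spearman correlations and first-order Spearman partial
   correlation, weights *w* = ±0.5 by the inferred activation/repression
   sign, and a regularizer built from the normalized motif score and the
   peak's maximal accessibility. High-confidence peak–TF links are the
   top-scoring half of each TF's motif-bearing candidates.

2. **Binding recovery.** Those links become *pseudo-labels* for a per-TF
   classifier over dual SVD embeddings of the peaks (accessibility space
   and binary motif space, d₁ = d₂ = 50). PhenoGraph-style clustering of
   both embeddings yields paired peak groups; Fisher enrichment of the
   link set across groups guides the selection of pseudo-positives
   (quantile scores above τ₁ = 0.25 in enriched groups, τ₂ = 0.75
   elsewhere) and pseudo-negatives (ratios r₁ = 0.25 and r₂ = 1.5 from
   motif-bearing and motif-less pools, after excluding expanded
   candidates, enriched groups, and the links' K = 100 nearest
   neighbors). An L2-regularized logistic regression then assigns a
   binding probability to **every** peak — including peaks with no
   detected motif, which is where the method earns its keep.

The package also ships a synthetic multiome generator with planted
ground truth (including masked motifs), ChIP-seq-style evaluation
(AUPR as average precision, precision at 15%/20% recall, F1 with a
shuffle null, enrichment tests), downstream association discovery
(expression-prediction gain of new gene–TF links, TF-pair interaction
correlations, motif co-enrichment), and a seeded end-to-end pipeline.

## Worked example

```r
library(peaktriplet)

cfg <- simulation_config(n_metacells = 150, n_tfs = 5, n_peaks = 1000,
                         n_genes = 100, seed = 42)
sim <- simulate_multiome(cfg)

cand <- assign_peaks_to_genes(sim$peaks, sim$genes, sim$accessibility,
                              sim$expression)
trip <- score_triplets(cand, sim$motifs, sim$accessibility, sim$expression)
head(trip[order(-trip$score1),
          c("peak_id", "tf_id", "gene_id", "rho_tf_peak", "rho_partial",
            "regularizer", "score1")], 3)
#>                  peak_id tf_id gene_id rho_tf_peak rho_partial regularizer    score1
#> 814 chrS:4866250-4866750  TF05   G0097   0.7583288   0.7301057   0.7901348 0.5880320
#> 304 chrS:4910250-4910750  TF02   G0099   0.7678119   0.7198914   0.7807805 0.5807849
#> 718 chrS:2425250-2425750  TF05   G0049   0.7844811   0.4052158   0.9142618 0.5438472

links <- call_tf_links(trip)
lengths(links)
#> TF01 TF02 TF03 TF04 TF05
#>   43   38   41   36   38

rec <- recover_binding(links, trip, sim$accessibility, sim$expression,
                       sim$motifs, seed = 7)
chip <- chipseq_from_truth(sim$truth, sim$peaks, "TF01")
ev <- evaluate_tf(rec$results[["TF01"]]$prediction, sim$peaks, chip,
                  scan = sim$motifs, tf = "TF01", seed = 7)
round(ev[, c("aupr", "f1", "aupr_nonmotif", "prevalence_nonmotif",
             "f1_nonmotif", "expected_f1_null")], 3)
#>    aupr    f1 aupr_nonmotif prevalence_nonmotif f1_nonmotif expected_f1_null
#> 1 0.821 0.628         0.096               0.009       0.133            0.009
```

Reading the output: the top triplets pair strong TF–peak correlation
with strong gene-conditional partial correlation and solid motif/
accessibility support. For TF01, genome-wide AUPR is 0.821 against the
planted truth, and among the ~800 peaks *without* a detected TF01 motif
— where motif-based methods predict nothing — the classifier reaches an
AUPR of 0.096 versus a positive-class prevalence of 0.009 (an ~11×
enrichment), with a motif-free F1 of 0.133 against a shuffle-null
expectation of 0.009.

The full pipeline (simulate → triplets → binding → evaluate → associate)
with one master seed:

```r
run_pipeline(default_config(seed = 1), "out/")   # or:
# Rscript inst/scripts/run_pipeline.R --out out/ --seed 1
```

writes per-stage TSV/BED artifacts plus a manifest of md5 checksums;
reruns with the same config and seed are byte-identical.

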