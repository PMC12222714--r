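# complexforge

Protein complex map construction from proteomic co-occurrence networks.

Large-scale pulldown and co-fractionation experiments observe thousands of
proteins across thousands of purifications, but the objects cell biologists
reason about are *complexes*: stable assemblies of co-functioning subunits.
`complexforge` implements a complete, reusable pipeline from raw
protein-presence tables to an interpreted, confidence-tiered complex map:

1. **Co-occurrence features (WMM).** For a pair of proteins seen in `n` and
   `m` of `N` experiments and co-observed in `k`, the weighted matrix model
   scores the upper hypergeometric tail

   `p(#shared >= k | n, m, N) = sum_{i=k}^{min(n,m)} C(n,i) C(N-n, m-i) / C(N,m)`

   evaluated in log space; the features per pair are `-ln p` and the pair
   count, computable at several abundance stringencies.
2. **Gold standard.** Curated complex lists are redundancy-reduced (Jaccard
   >= 0.6 removes the larger complex; complexes > 30 subunits and their
   subcomplexes are dropped) and split 50:50 into leak-free train/test sets
   of positive (within-complex) and negative (cross-complex) pairs.
3. **Classifier.** A pluggable backend (default: ridge logistic regression
   via glmnet) is trained on positives plus 10,000 subsampled negatives and
   scores every pair, yielding a confidence-weighted interaction network.
   Evaluation is precision-recall (step-integrated AUPRC), permutation
   feature importance, and feature-group ablation.
4. **Clustering.** Two-stage clustering — cohesiveness-based dense-region
   growth (ClusterOne-style, cohesiveness `W_in / (W_in + W_bound + 2|V|)`)
   followed by Markov clustering within each region — swept over score
   threshold, density, overlap, and inflation grids; parameter sets are
   ranked by weighted k-clique precision against the training gold standard
   and assembled into confidence tiers (tier 1 = highest precision), then
   reduced to a non-redundant map (Jaccard >= 0.7 keeps the larger complex).
5. **Interpretation.**
   - *Mutual exclusivity*: paired dimer models sharing a common subunit are
     quality-gated (pDockQ > 0.23, interface pLDDT > 70), superposed on the
     common chain (Kabsch, RMSD < 10 A), and called mutually exclusive when
     their common-chain interfaces overlap by > 10 residues at 4 A,
     structurally consistent at 0 overlapping residues (with a summed
     chain-clash pLDDT < 500 screen), inconclusive in between.
   - *ALL-IN score*: four expression sub-scores (bicor across cell lines,
     bicor of lineage means, a top/bottom-50 differential-abundance score
     with N(-4, 0.3) imputation of non-detections, and lineage-wise
     complex-coherence correlation) are z-scored, averaged, and negated, so
     high values flag likely mutually exclusive pairs; the Jaccard
     Interactome score (partner-set Jaccard at confidence >= 0.8) guards
     against annotation artifacts.
   - *Annotation transfer*: hypergeometric term enrichment per complex
     against a background with a shuffled-complex null; terms transfer to an
     understudied member (annotation score < 4) when >= 50% of members share
     the term at corrected p <= 0.01.

A synthetic-data module generates all inputs with planted ground truth
(complexes, noisy pulldowns, scored networks, lineage-structured expression
with anti-correlated mutually exclusive pairs, and toy CA-only trimer
geometries with controllable interface overlap), so the entire pipeline is
testable offline.

## Worked example

```r
library(complexforge)

# a planted world: 20 complexes, noisy pulldowns, WMM features
truth <- make_planted_complexes(20, c(3, 8), overlap_fraction = 0.1, seed = 11)
obs   <- simulate_pulldowns(truth, n_baits_per_complex = 6, detect_prob = 0.8,
                            background_rate = 0.01, seed = 12)
feats <- compute_wmm(obs)
head(feats, 3)
#>     id_a   id_b pair_count neg_ln_pval
#> 1 BG0001  P0001          1    2.720735
#> 2 BG0001  P0002          1    2.323817
#> 3 BG0001  P0003          1    1.739374

# cluster a scored network and compare to the planted truth
net <- simulate_scored_network(truth, seed = 12)
clusters <- two_stage_cluster(net, cluster_params(0.5, 0.2, 0.7, 2))
kclique_eval(as_complex_list(clusters, "pred"), truth$complexes, seed = 1)
#> <clique_eval> weighted precision 0.984, recall 1.000, F1 0.992

# structural mutual-exclusivity call on a toy trimer
classify_trimer(make_toy_trimer(overlap = TRUE, seed = 5))$verdict
#> [1] "mutually_exclusive"
```

The k-clique evaluation compares every fully connected sub-group (clique) of
each predicted cluster against the gold-standard complexes, size by size, and
weight-averages precision and recall by the number of clusters/complexes at
least that large — so one oversized cluster cannot dominate the score.

The full demonstration pipeline (synthesize → features → gold standard →
train → score → sweep → tiers → exclusivity → ALL-IN → annotation) runs from
one JSON config:

```r
manifest <- run_pipeline(demo_config("demo_run", seed = 1))
validate_outputs("demo_run")
```

or from the CLI dispatcher `inst/cli/complexforge.R`
(`Rscript inst/cli/complexforge.R run --config demo.json`).

## Acceptance script

`scripts/acceptance.R` executes the full pipeline on the synthetic fixture
bundle for the given seed, re-checks every output invariant
(pair-set leak-freedom, cluster edge post-filter, score ranges, verdict
consistency), and writes the report JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

- `R/` — modules: synthetic data, WMM features, benchmark, interaction
  model, clustering, k-clique metrics, mutual exclusivity, expression
  scores, annotation transfer, pipeline.
- `vignettes/complexforge-methods.Rmd` — the methods vignette: models,
  assumptions, parameter choices, limitations.
- `tests/testthat/` — unit, property, and acceptance suites.
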