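---
title: "complexforge: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{complexforge: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its methods: what each stage
computes, why the defaults are what they are, what the synthetic-data
generator does and does not emulate, and where design decisions were
genuinely open. It states no empirical result that the test suite does not
itself compute.

## 1. The problem

High-throughput proteomics observes protein *presence* — a bait pulls down
preys, a fraction contains co-eluting proteins — but the biological unit of
interest is the complex. `complexforge` turns presence tables into a tiered
complex map in five stages: co-occurrence features, a leak-free gold
standard, a pairwise co-complex classifier, two-stage graph clustering
selected by weighted k-clique precision/recall, and three interpretation
layers (structural mutual exclusivity, expression-based ALL-IN scoring,
annotation transfer).

## 2. Weighted matrix model features

For proteins seen in $n$ and $m$ of $N$ experiments sharing $k$, the WMM
feature is the upper hypergeometric tail

$$p(\#\text{shared} \ge k \mid n, m, N) \;=\;
\sum_{i=k}^{\min(n,m)} \frac{\binom{n}{i}\binom{N-n}{m-i}}{\binom{N}{m}},$$

reported as $-\ln p$ together with the raw pair count. The sum is evaluated
in log space (log-gamma binomials, shifted exponentiation) because $N$ can
reach tens of thousands of experiments; the implementation is checked in the
tests against both exhaustive subset-pair enumeration (all $N \le 8$) and
`stats::phyper`. Two conventions matter:

- **Enumeration floor.** Pairs sharing no experiment are not enumerated by
  default (`min_pair_count = 1`): materializing all-zero pairs is a
  quadratic blow-up carrying no signal. `min_pair_count = 0` emits them at
  $-\ln 1 = 0$ when a dense table is wanted.
- **$N$ per partition.** $N$ is the number of experiments in the supplied
  matrix. Whether prey-only proteins should count toward a different
  per-dataset $N$ is not derivable from the data model; using the matrix's
  own experiment count is the only self-consistent choice.

Auxiliary per-entry scores (e.g. abundance Z-scores) can gate presence at
several cutoffs (`threshold_observations`), producing nested feature
variants named `wmm_negln_<tag>_<cutoff>` so stringencies coexist in one
table.

## 3. Gold standard

Curated complex lists are first redundancy-reduced: complexes above 30
subunits are removed along with any complex fully contained in a removed
one (otherwise the ribosome's subcomplexes quietly re-introduce it), then
the larger of any pair with Jaccard $\ge 0.6$ is removed iteratively.
Because "remove the larger" is ambiguous on ties, ties remove the
lexicographically later complex; the procedure is therefore deterministic
and idempotent, which the tests assert directly.

The split is 50:50 by complex under a seed. We resolve train/test complex
pairs sharing a protein pair *before* generating labeled pairs (removing one
of the two at random), rather than generating first and patching after: the
end state — no pair present in more than one of the six output sets — is the
same, but it holds by construction rather than by repair. Negatives are
cross-complex pairs within a split that are co-complexed in *neither* split;
negatives arising in both splits are assigned to one side uniformly at
random under the split seed. All six disjointness invariants are checked by
`check_split_invariants` and exercised over 1000 seeds in the acceptance
suite.

## 4. Interaction classifier

The classifier is a pluggable backend behind a fit / predict-score / save /
load contract with a recorded feature schema (prediction refuses mismatched
columns). The default backend is ridge-regularized logistic regression
(`glmnet`, $\alpha = 0$, $\lambda = 10^{-3}$ reached along a 40-step
decreasing path — jumping directly to a small penalty stalls coordinate
descent on separable data); a plain `glm` backend is included. Gradient
boosting, the obvious alternative, has no installable R implementation in
this environment; the backend interface is the extension point and the
choice is recorded in the model artifact.

Training data follows the published recipe: all positives plus at most
10,000 negatives subsampled without replacement under a seed. Missing
features are zero-filled with companion `obs_<feature>` indicator columns,
because in pulldown data *absence of evidence is informative* — a pair never
co-observed is not a random missing value. Raw backend probabilities are
reported without recalibration; `score_vs_precision_table` exists to audit
calibration empirically.

Evaluation: precision–recall over all distinct score thresholds with
step integration (average precision), so AUPRC of a constant ranking equals
prevalence and of a perfect ranking equals 1 — both asserted analytically.
Permutation importance reports the mean performance drop over seeded
shuffles (accuracy at 0.5 by default, AUPRC by flag; negative values mean
the shuffle helped). Feature-group ablation zeroes named columns in the test
matrix, mirroring how grouped contributions are measured.

## 5. Two-stage clustering and tier assembly

The scored network is thresholded (strictly greater than the cutoff,
following the stated filter wording), dense regions are grown greedily by
cohesiveness
$$h(V) = \frac{W_{in}}{W_{in} + W_{bound} + 2\,|V|},$$
with seeds in descending weighted-degree order, single add/remove moves
accepted only on strict improvement (which guarantees termination), groups
merged at overlap score $\omega(A,B) = |A \cap B|^2 / (|A||B|) \ge$ the
max-overlap parameter, and groups below the density floor or smaller than 3
discarded. The penalty constant 2 and the seeding rule follow the original
cohesiveness-clustering publication, since the upstream description
delegates them to that tool; both are arguments, not constants.

Within each region we run Markov clustering: self-loops at each node's
maximum incident weight, column normalization, expansion (matrix square),
inflation (element-wise power, renormalize), pruning below $10^{-8}$ with a
guard that re-seeds a column emptied by pruning at its own node. Iteration
stops when the matrix stops changing ($\max$ entry change $< 10^{-6}$) or at
200 iterations (returned with a warning flag). Clusters are read from
attractor rows and overlapping attractor systems merged, so the output is a
partition — a property the tests check on random graphs. Inflation 1 reduces
to the random-walk limit: one cluster per connected component.

Post-filters per the published procedure: members whose maximum
within-cluster edge weight is not strictly above the score threshold are
removed (an MCL artifact), and clusters must have 2–100 members. Dimers are
retained even though the region stage discards size < 3: they can only arise
from MCL splitting, and published maps contain them.

The sweep grid (14 thresholds x 2 overlaps x 4 densities x 9 inflations =
1008 combinations; `paper_sweep_grids()`) is config, not code — the source
description mentions 1080 combinations while its printed grids multiply to
1008, so the driver takes whatever grid it is given. Sweep rows are ranked
by weighted k-clique precision; `select_tier_sets` picks sets spaced across
the precision range (the published maps use six hand-picked sets; spacing is
the automated analogue), `assemble_tiers` numbers tiers from 1 (highest
precision) and records a complex seen in several tiers once, at its best
tier. `reduce_map` removes the smaller of any pair at Jaccard $\ge 0.7$ to a
fixed point.

## 6. Weighted k-clique evaluation

Complexes are sets, treated as fully connected, so the size-$s$ cliques of a
cluster are its $s$-subsets. For each $s$ from 2 to the largest complex or
cluster: precision$_s$ is the fraction of predicted $s$-cliques contained in
some gold complex, recall$_s$ the fraction of gold $s$-cliques contained in
some predicted cluster. Sizes are averaged with weights equal to the number
of predicted clusters (precision) or gold complexes (recall) of size
$\ge s$; this damps the contribution of the largest complexes, and is the
reading consistent with that stated intent — the alternative symmetric
weighting is available by flag because the description does not fully pin
the weighting side down. Enumeration is exact (unique cliques) while the
per-size clique count is small (default cap 20,000) and falls back to
seeded sampling above it: a cluster is drawn proportional to its clique
count, then a uniform subset, and — because a clique shared by $m$
overlapping clusters is drawn $\propto m$ — each draw is weighted $1/m$
(Horvitz–Thompson) so the ratio estimates the same unique-clique fraction
that exact enumeration computes. Exact-vs-sampled agreement within 0.02 is
an acceptance property.

## 7. Structural mutual exclusivity

Two proteins that bind the same face of a common partner cannot occupy the
complex simultaneously. Given two dimer models sharing a common subunit:

1. **Quality gates** (all strict, matching their printed forms): pDockQ
   $> 0.23$; interface pLDDT $> 70$, averaged over the interface residues of
   *both* chains (the averaging scope is unstated upstream; both-chain
   averaging uses all positioned interface residues and is config-exposed);
   provider-reported inter-chain clashes $\le 5$ when that count exists.
2. **Superposition** of dimer 2 onto dimer 1 by least-squares rigid
   superposition (Kabsch with proper-rotation enforcement) on common-chain
   residues matched by residue number; candidates at RMSD $\ge 10$ Å are
   discarded rather than retried with the other reference — retrying would
   make the verdict depend on labeling order, which the tests forbid.
3. **Interface overlap**: interface = common-chain residues within 4.0 Å of
   the unique chain, identified independently in each dimer; the overlap is
   the residue-number intersection. $> 10$ overlapping residues ⇒ mutually
   exclusive; $0$ ⇒ structurally consistent; $1$–$10$ ⇒ inconclusive
   (tolerating model error).
4. **Chain-clash screen** for structurally consistent candidates: residue
   clashes between the two unique chains (inter-atom distance < 2.5 Å, or
   < 3.0 Å for CA-only models — the clash definition is inherited from
   model providers upstream, so ours is explicit and config-exposed), sum
   the per-residue pLDDT of the lower-confidence chain's clashing residues,
   and fail at $\ge 500$.
5. **Consolidation**: calls through common subunits known to
   homomultimerize are dropped (they can present the same interface twice);
   pairs with conflicting verdicts across common subunits are dropped;
   consistent verdicts keep their support count.

All geometry is invariant to global rigid transforms and to dimer order;
the acceptance suite drives 50 overlapping and 50 non-overlapping generated
trimers through the full pipeline and requires 100% correct verdicts.

## 8. ALL-IN and related expression scores

Inputs are z-scored log protein intensities ("relative abundances") across
cell lines labeled by cancer lineage. Robust correlation throughout is the
biweight midcorrelation (bicor, tuning constant 9 on the MAD scale,
pairwise-complete); zero-MAD vectors fall back to Pearson with a flag. The
four sub-scores per within-complex pair:

1. bicor across all shared cell lines;
2. bicor of per-lineage means (lineages with < 2 detected lines yield
   missing means), removing lineage-size bias;
3. a differential-abundance score: proteins detected in $\ge 50$ lines have
   missing values imputed from $\mathcal{N}(-4, 0.3)$ (non-detection means
   low abundance), then for each direction the mean of one protein in the
   other's top 50 lines minus its bottom 50 (ranking includes imputed
   values, per the stated procedure), averaged over both directions;
4. per-lineage mean bicor of each protein to the other complex subunits,
   then correlation of the two proteins' lineage vectors (outer correlation
   defaults to bicor for consistency; Pearson by flag).

Each sub-score is z-scored across the pair population of the invoked run
(the population choice is config-exposed since the upstream text does not
state it), averaged over available sub-scores, and negated — "reversed" is
implemented as negation, the minimal reading — so high ALL-IN means likely
mutual exclusivity. Pairs with fewer than two sub-scores are excluded.
Sub-score 3 uses one imputation draw per run under the module seed.

The Jaccard Interactome score is the Jaccard of the two proteins' partner
sets at network confidence $\ge 0.8$, requiring $\ge 3$ partners each;
`complex_covariation_summary` reports per-complex median pairwise
covariation after size/tier/coverage filters; `thresholded_pearson`
correlates two pairwise score vectors above a joint 0.2 floor.

## 9. Annotation enrichment and transfer

Per-complex term enrichment is the same hypergeometric tail as the WMM,
over the supplied background universe, BH-corrected within the annotation
set. This replaces an external enrichment web service; the correction method
is config-exposed because that service's default correction differs from
BH. Terms annotating exactly one complex member are excluded, as are
blocklisted ontology roots. The empirical null shuffles protein ids across
cluster slots preserving both the cluster-size multiset and the per-protein
membership counts exactly (duplicate memberships repaired by seeded swaps).
Transfer to an understudied member (annotation score < 4) requires term
share $\ge 50\%$ of complex members — counting the receiving protein in the
denominator; excluding it is the noted alternative — and corrected
$p \le 0.01$.

## 10. Synthetic data: what it emulates, what it does not

The generator is a stated world, not a tuning knob:

- **Complexes**: sizes uniform on the requested range (defaults 3–8, the
  typical size range of curated stable complexes once oversize assemblies
  are filtered); an overlap fraction shares one subunit with an earlier
  complex. Disjoint within-complex pairs can be flagged mutually exclusive
  or structurally consistent.
- **Pulldowns**: one experiment per sampled bait; co-complex preys detected
  with probability 0.8 and background proteins at 0.01 by default —
  detection efficiencies and contaminant rates in the range practitioners
  report for well-behaved AP-MS. Background proteins never belong to
  complexes, so every cross-complex co-occurrence is attributable noise.
  There is no peptide/spectral-level simulation and no intensity model.
- **Scored networks**: within-complex confidences at $0.9 \pm 0.05$,
  background edges at rate 0.05 with confidences uniform on
  $[0.05, 0.35]$ — classifier false positives are low-confidence by
  construction, which is what a calibrated classifier produces.
- **Expression**: each complex has a latent lineage profile
  ($\mathcal{N}(0, 1.5)$ per lineage) plus shared line-level effects whose
  spread varies by lineage (uniform scale 0.5–1.5) — without within-lineage
  co-variation, sub-score 4 would be measuring noise. Member values add
  $\mathcal{N}(0, 0.3)$ noise. Anticorrelated ME pairs negate one member's
  latent signal; lineage-exclusive ME pairs get disjoint lineage support
  with missing values outside it. The default panel (8 lineages x 15 lines
  = 120 lines) is the smallest layout that keeps the top/bottom-50 rule of
  sub-score 3 meaningful. Note a deliberate consequence: hard
  lineage-exclusive pairs share no observed line, so only sub-score 3 is
  computable and such pairs fall below the two-sub-score floor — real data,
  with partial detection everywhere, does not behave this starkly, which is
  why the discrimination acceptance check runs in the anticorrelated world.
- **Toy trimers**: CA-only chains; the common chain is a helix-like arc
  (2.3 Å radius, 100°/residue, 1.5 Å rise), unique chains are 12-residue
  patches pushed 3.9 Å off its surface, on the same segment (overlap) or
  disjoint segments (no overlap). Only distances matter downstream, so no
  side chains, no realistic torsions. pLDDT is 90 and pDockQ 0.5 unless
  overridden.

A green test on this world establishes internal correctness — the
algorithms do what their definitions say on data with known structure. It
does not establish performance on real compendia, whose noise is neither
independent nor homogeneous.

## 11. Numerical choices and degenerate inputs

- Fixed seeds pin the RNG (Mersenne-Twister, inversion normals, rejection
  sampling) and every generator restores the caller's RNG state, so fixture
  output is byte-identical across platforms.
- Hypergeometric tails are clamped to $[0,1]$; $-\ln p$ caps at 745
  (double underflow).
- MCL: non-convergence returns the current interpretation with a warning
  flag; emptied columns are re-seeded at the node itself.
- Cohesiveness growth accepts moves only above a $10^{-12}$ improvement,
  preventing add/remove cycles.
- bicor needs $\ge 3$ complete pairs; zero-MAD input falls back to Pearson
  with a flag rather than returning an undefined ratio.
- Empty predicted sets evaluate to weighted precision 0 with an explicit
  flag, not NaN; empty score bins are flagged, not NaN.
- Pair keys canonicalize lexicographically; self-pairs are rejected
  everywhere.

## 12. Pipeline and configuration

`run_pipeline` executes the stages in dependency order from one JSON config
(JSON rather than YAML: the deployment environment provides a JSON parser
but no YAML parser; the schema-validated, unknown-keys-rejected contract is
unchanged). Every published constant — 0.6, 30, 10000, 0.23, 70, 4.0, 10,
500, 0.7, 50, −4, 0.3, 0.8, 3, 0.2, 0.01, 0.5, 100 — appears once in
`demo_config()` and nowhere in the code paths. Stages are cached by a hash
of their config section and input files; unchanged re-runs skip, corrupted
inputs re-execute. `validate_outputs` re-checks the module invariants on
the written files. The CLI (`inst/cli/complexforge.R`) is a thin dispatcher
over these functions; per-module operations not given a CLI verb are used
through their exported R functions.

## 13. Known limitations

- The default classifier is linear; interactions between features (e.g.
  pair count x stringency) are not modeled. The backend interface exists
  precisely so a boosted-tree backend can be dropped in where available.
- The dense-region and MCL implementations follow the published algorithm
  descriptions, not the reference binaries; conformance against the
  original tools on shared inputs is future work.
- Structural calls use residue-number intersection after alignment (with a
  spatial sanity check via the alignment RMSD gate); a fully spatial
  overlap re-test is an alternative mode left to configuration.
- The annotation module's multiple-testing correction (BH within ontology)
  is not identical to external enrichment services' defaults.
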