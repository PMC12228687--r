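# petminer

Structure-guided enzyme mining in R: representation-tree clustering of
protein language model (PLM) embeddings, annotation-guided clade
selection, a staged candidate-screening cascade, an EC-retrieval
benchmark, and molecular-dynamics stability observables.

## The problem

Wild-type PET hydrolases (PETases, EC 3.1.1.101) with both high activity
and high thermostability are rare, and sequence-based mining misses
functional homologues in low-identity regions of sequence space.
Structure-aware PLM embeddings place proteins with similar predicted
folds close together in Euclidean space, so candidates retrieved from
large databases can be organised by *structural* similarity using only
their sequences. `petminer` implements the computational core of such a
mining pipeline for users who already have per-protein embeddings and
per-candidate property predictions (melting temperature, solubility,
model confidence) from external predictors.

## Methods at the core

- **Representation tree.** Ward agglomerative clustering over embedding
  rows: at each step the merge minimising the within-cluster variance
  increase, via the Lance–Williams recurrence on squared Euclidean
  distances. Reported heights are square roots of the recurrence values,
  so two singletons merge at their Euclidean distance. A flat cut into
  *k* clades undoes the last *k* − 1 merges; clades containing at least
  one validated-positive reference are selected for screening.
- **Screening cascade.** Stage order: predicted T_m > query, predicted
  solubility > query (both strict), mean pLDDT ≥ 75, TM-score vs the
  reference structure ≥ 0.5, catalytic-triad conservation; survivors are
  ranked by predicted T_m and the top *k* retained. TM-score uses the
  standard length-normalised definition
  `TM = (1/L_target) Σ_i 1/(1 + (d_i/d0)²)` with
  `d0 = 1.24 (L_target − 15)^{1/3} − 1.8` (clamped at 0.5 Å) after a
  single Kabsch fit of sequence-aligned Cα pairs. Ser-His-Asp triads are
  detected geometrically (heavy-atom contacts ≤ 4 Å) and mapped through a
  global BLOSUM62 alignment.
- **Retrieval benchmark.** Per EC group with ≥ 50 annotated members:
  sample 10 query seeds, score the remaining pool by minimum embedding
  distance to the queries, and report AUROC and average precision with
  same-EC members as positives.
- **MD observables.** Radius of gyration, per-residue RMSF (after
  iterated Kabsch superposition onto the mean structure), salt-bridge
  counts, and hydrogen-bond lifetimes via the occupancy autocorrelation
  `C(t) = ⟨h(t₀)h(t₀+t)⟩ / ⟨h²⟩` integrated over the analysis window,
  `τ = Σ_t C(t)·dt`.

Every module has a seeded synthetic-fixture generator with planted
ground truth (Gaussian embedding clusters, helical decoys with planted
triads, telegraph-process bond occupancies, harmonic trajectories), so
the whole pipeline is testable offline.

## Worked example

```r
library(petminer)

fx <- make_gaussian_embedding_clusters(k = 3, n_per = 40, d = 8,
                                       separation = 30, spread = 3,
                                       seed = 42)
tree <- ward_tree(fx$embeddings)
tree
#> <pm_tree> 120 leaves, 119 merges, max height 272.3

cut_to_k(tree, 3) |>
  enrich_and_select(fx$annotations$id[fx$annotations$validated_positive])
#> # A tibble: 3 × 5
#>   cluster n_members n_positives positive_fraction selected
#>     <int>     <int>       <int>             <dbl> <lgl>
#> 1       1        40          40                 1 TRUE
#> 2       2        40           0                 0 FALSE
#> 3       3        40           0                 0 FALSE
```

All 40 validated positives fall in clade 1, so only that clade is
selected for screening. The cascade then filters a candidate table and
ranks survivors by predicted melting temperature:

```r
cand <- make_candidate_table(n = 24, seed = 42)
report <- apply_cascade(cand$records, cand$config)
report
#> <pm_screening_report> 24 candidates in
#>   tm_filter          20 survivors
#>   solubility_filter  18 survivors
#>   plddt_filter       16 survivors
#>   tmscore_filter     14 survivors
#>   triad_filter       12 survivors
#>   ranked_top_k       12 survivors
head(report$ranked, 3)
#> # A tibble: 3 × 3
#>    rank id      predicted_tm
#> 1     1 cand015         79.3
#> 2     2 cand017         78.9
#> 3     3 cand001         75.9
```

Each stage's survivor counts shrink monotonically; the final list is the
surviving candidates in descending predicted T_m (°C). On the same
planted clusters the EC-retrieval benchmark separates groups perfectly
(`mean_auroc = 1`), and a telegraph-process hydrogen bond with per-step
rates 0.05/0.05 at dt = 10 ps yields `tau_ps ≈ 4778` over a 10 ns
analysis window — within sampling error of the closed-form expectation
of the estimator.

A command-line front end (`inst/cli/petminer`) exposes the same steps as
`fixtures`, `tree`, `select`, `screen`, `benchmark` and `md`
subcommands.

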