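---
title: "Structure-guided enzyme mining with petminer: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-guided enzyme mining with petminer: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petminer)
```

## Overview

`petminer` implements the computational core of a structure-guided
enzyme-mining workflow. The inputs are artefacts of external predictors —
per-protein embeddings from a structure-aware protein language model,
per-candidate predictions of melting temperature and solubility, predicted
or experimental structures — and the package organises, screens and
benchmarks them. This vignette documents the models and the numerical
decisions behind each stage.

## The representation tree

Proteins are points in the embedding space; the working assumption is that
Euclidean proximity of embeddings tracks structural similarity, so clades
of an agglomerative tree group candidates with similar folds (and,
hopefully, similar function).

`ward_tree()` implements Ward linkage through the Lance–Williams
recurrence on squared Euclidean distances:

$$d^2(k,\, i \cup j) = \frac{(n_i + n_k)\,d^2_{ik} + (n_j + n_k)\,d^2_{jk}
  - n_k\, d^2_{ij}}{n_i + n_j + n_k}.$$

Reported merge heights are square roots of the recurrence values, so two
singletons merge at their Euclidean distance — the convention shared by
`hclust(method = "ward.D2")` and scipy's `ward`. Because the criterion
value at a merge equals twice the within-cluster variance increase, the
implementation is tested against an exhaustive greedy
minimal-variance-increase oracle (all pairs scored from scratch at every
step) on small random sets, and cross-checked against `hclust` on larger
ones. Ties on the merge criterion are broken lexicographically on node
creation indices, which makes the tree fully deterministic; the same rule
is implemented in the oracle.

`cut_to_k()` undoes the last $k-1$ merges. $k$ is a free parameter: no
principled default exists for mining runs, because the granularity that
isolates a functional family depends on the embedding model and database
composition. The demo configuration uses the planted component count of
the fixture (3); real runs should inspect the tree (`autoplot()`, Newick
export) before choosing. Clade labels follow first appearance in input row
order (the `cutree` convention), so label identity is reproducible but not
meaningful across different inputs.

`enrich_and_select()` selects every clade containing at least one
validated-positive reference. This containment rule is deliberately
minimal — selecting the clades that hold all known high-activity reference
enzymes — and reports member counts and positive fractions for all clades
so a user can apply a stricter enrichment threshold if their reference set
is large.

## The screening cascade

`apply_cascade()` applies five filters in a fixed order, then ranks:

1. predicted melting temperature strictly greater than the query enzyme's;
2. predicted solubility strictly greater than the query's;
3. mean pLDDT ≥ 75 (below 75 discarded; the boundary is retained);
4. TM-score against the reference structure ≥ 0.5 (boundary retained);
5. catalytic triad conserved;
6. survivors ranked by predicted T_m descending (ties by id), top *k* kept.

"Exceeding the query" is read as a strict inequality: a candidate exactly
matching the query's predicted stability offers no expected improvement.
A record missing the datum a stage needs is excluded *at that stage* and
flagged `missing_data` rather than passed through: silent gaps in
prediction tables are a real failure mode of mining runs and should be
visible in the report. The default `top_k = 34` reflects a realistic
wet-lab validation budget; `plddt_min = 75` and `tm_min = 0.5` are the
conventional "confident model" and "same fold" thresholds.

## Structural comparison

The TM-score stage needs a residue correspondence. Full structure-aligner
behaviour (iterative fragment search with correspondence refinement) is
out of scope; instead the correspondence comes from an optimal global
sequence alignment (BLOSUM62, affine gaps, open 10 / extend 1, a gap of
length $L$ costing $10 + L$), and the standard length-normalised score

$$\mathrm{TM} = \frac{1}{L_\mathrm{target}} \sum_i
\frac{1}{1 + (d_i/d_0)^2}, \qquad
d_0 = 1.24\,(L_\mathrm{target} - 15)^{1/3} - 1.8 \;(\ge 0.5\ \text{Å})$$

is evaluated after a **single** Kabsch fit of the aligned Cα pairs. For
clearly homologous candidates (the ≥ 0.5 screening regime) the sequence
correspondence is close to the structural one and the single-pass score is
adequate; for remote pairs it *underestimates* the score an iterative
aligner would report, making the filter conservative. This divergence is
intentional and documented here. `tm_score(superpose = FALSE)` evaluates
the formula in the current frames, which the tests use to pin anchor
values (all pairs at exactly $d_0$ with full coverage gives TM = 0.5).

Kabsch superposition corrects reflections to proper rotations by a sign
flip on the smallest singular direction, requires ≥ 3 non-collinear
pairs (collinearity detected at a relative singular-value threshold of
1e-8), and is verified by construct-and-recover to 1e-6.

Triad detection scans all Ser-His-Asp triples and keeps the one with the
shortest Ser:OG–His ring-N contact subject to both contacts (Ser:OG to
His NE2/ND1, His NE2/ND1 to Asp OD1/OD2) being ≤ 4.0 Å. The cutoff is the
canonical serine-hydrolase hydrogen-bond geometry, not a fitted value, and
is configurable. Absence of a qualifying triple is an empty result, not an
error — it is a legitimate screening outcome. Residue positions use the
author numbering of the source file, so positions quoted for deposited
structures line up; alignment indices, in contrast, are 1-based sequence
positions (the idiomatic R convention, applied consistently).

## The retrieval benchmark

`ec_retrieval_benchmark()` scores embedding-distance retrieval per EC
group: 10 query members sampled per group (one seeded RNG stream across
groups, seed recorded in the result), the pool scored by minimum distance
to any query, same-EC members positive, everything else negative. Groups
under 50 annotated members are skipped and reported as such. Queries are
*removed* from the evaluation pool: retrieving the seeds themselves is
trivial and would inflate both metrics. AUROC is the tie-aware
Mann-Whitney pair statistic; average precision is the step-wise rank scan
with ties broken by id so the value is deterministic. Per-group values and
an unweighted mean are reported; no claim is made about other aggregation
choices. Both metrics are tested for exact agreement with brute-force
pair-counting and rank-scan oracles.

## MD observables

The hydrogen-bond lifetime statistic is implemented exactly as defined:

$$C(t) = \frac{\langle h(t_0)\,h(t_0+t)\rangle}{\langle h^2\rangle},
\qquad \tau = \int_0^{T} C(t)\,dt \approx \sum_{t} C(t)\,\Delta t,$$

with $h(t)$ the binary occupancy indicator, the numerator averaged over
all valid time origins per lag ($F - \mathrm{lag}$ terms), and the
denominator the full-series mean (for binary $h$, the occupancy fraction).
Two properties of this definition deserve emphasis:

- **No mean subtraction.** For a persistent bond $C(t)$ plateaus at the
  occupancy rather than decaying to zero, so $\tau$ grows with the
  analysis window. Every `hbond_lifetime()` result therefore records
  `window_ps`; lifetimes are only comparable at equal windows.
- **Full-series denominator.** The numerator averages over $F - t$
  origins while the denominator uses all $F$ frames, so $C(t) > 1$ is
  possible at large lags: `c(1,1,0,0)` gives $C(1) = (1/3)/(1/2) = 2/3$,
  but `c(1,0,1)` gives $C(2) = 1/(2/3) = 1.5$. The estimator is tested
  against a brute-force double loop on *every* binary series of
  length ≤ 8.

Integration uses the left-rectangle rule (lag 0 included), so an all-on
series of $F$ frames gives $\tau = F\,\Delta t$ exactly; a trapezoid
option differs by $O(\Delta t)$. The telegraph-process fixture provides a
closed-form oracle: for a stationary two-state chain with occupancy $p$
and per-step eigenvalue $\lambda$, the estimator's expectation over
$n$ lags is $\Delta t\,[n p + (1-p)(1-\lambda^n)/(1-\lambda)]$, and the
estimator is required to match it within three standard errors (estimated
from replicate series) at $F = 20{,}000$ frames for three rate settings.
The lifetime checks truncate the lag window at 1000 frames (10 ns at the
10 ps sampling interval used throughout), keeping ≥ 19,000 time origins
per lag so the comparison is statistically meaningful.

Hydrogen-bond *detection* criteria are a convention, not a fitted choice:
donor–acceptor heavy-atom distance ≤ 3.5 Å and, when a donor hydrogen is
present, D–H···A angle ≥ 150°; without a hydrogen the criterion is
distance-only. Both are configurable (`hbond_criteria()`). Which atoms
constitute donors and acceptors is left to the caller (`charged_groups()`
helps for salt bridges; His ring nitrogens count as basic only on
request), because protonation assignments are force-field specific.

RMSF removes global rigid-body motion by superposing every frame onto the
mean structure, iterating mean and fits twice from a first-frame
initialisation. The harmonic fixture shows the residual bias of this
estimator: fitting onto the sample mean absorbs six rigid degrees of
freedom, deflating RMSF by roughly $\sqrt{1 - 6/(3A)}$ (about 3% at
$A = 30$ atoms), which is why the isotropic-recovery check
($\mathrm{RMSF} \approx \sigma\sqrt{3}$) uses a 5% band at 5000 frames
rather than a tighter one. Rg and RMSF are exactly invariant under a
global rigid motion applied to every frame (tested at 1e-9 and 1e-6).

Salt bridges count residue *pairs* (any basic-N to acidic-O contact
≤ 4.0 Å), never atom contacts, so bidentate arginine interactions count
once.

## Synthetic fixtures: what they do and do not show

The generators are statistical stand-ins, not physical models:

- `make_gaussian_embedding_clusters()` plants isotropic Gaussian
  components (means on coordinate axes at multiples of `separation`).
  Real embedding clouds are anisotropic, curved and unevenly populated;
  passing tests show the tree and benchmark machinery are correct, not
  that any particular PLM separates enzyme families.
- `make_toy_structure()` builds an ideal α-helix Cα trace (radius 2.3 Å,
  rise 1.5 Å, 100°/residue) with triad side-chain pseudo-atoms placed
  *geometrically* at 3.0 Å contacts near the trace centroid. It validates
  detector logic and numbering, not stereochemistry. The stand-ins used
  for the two deposited crystal structures (triads planted at the
  published positions S128/H206/D176 and S131/H208/D177) are synthetic:
  agreement demonstrates position bookkeeping, not re-detection on the
  real coordinates.
- `make_telegraph_occupancy()` and `make_harmonic_trajectory()` provide
  closed-form oracles for the lifetime and RMSF estimators. Real bond
  kinetics are neither Markovian nor stationary, and real protein motion
  is neither isotropic nor harmonic.

All generators are deterministic under a fixed seed (each scopes its own
RNG state), and every fixture can be serialised to the same plain-text
formats the readers consume.

## Numerical and scale choices

- Distances and linkage run in double precision with exact (not
  approximate) nearest-neighbour search; determinism outweighs speed at
  the representative-sequence scale the tree is meant for.
- Oracle suites run at deliberately small sizes — Ward against exhaustive
  agglomeration on 50 random sets with $n \le 8$, $d \le 3$; metric
  oracles on 100 pools of ≤ 200 items; autocorrelation on all 502 binary
  series of length ≤ 8 — where brute force is exact and fast. Estimator
  recovery uses 5000-frame (RMSF) and 20,000-frame (lifetime)
  simulations, sizes at which sampling error is well below the assertion
  bands.
- Degenerate inputs error with classed conditions
  (`petminer_format_error`, `petminer_missing_input`,
  `petminer_usage_error`) rather than producing NaN: all-zero occupancy
  series, collinear superposition sets, empty query sets, single-class
  pools, out-of-range cuts.

## Limitations

- TM-scores are sequence-correspondence, single-pass values; they are not
  interchangeable with iterative structure-aligner scores for remote
  pairs.
- Only single-chain models without insertion codes are supported; waters
  and heteroatoms are dropped on read.
- Binary trajectory formats are out of scope; trajectories are exchanged
  as multi-frame XYZ or multi-model PDB text.
- Embeddings are opaque inputs: how per-residue representations were
  pooled into per-protein vectors is upstream of this package.
- Hydrogen-bond lifetimes depend on the analysis window by construction;
  compare them only at matching windows and sampling intervals.
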