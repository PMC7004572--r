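---
title: "Models and methods behind screg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind screg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screg)
```

# The inference model

`screg` reconstructs a transcription factor (TF) → gene regulatory network
from single-cell UMI counts in two linear-model stages.

**Stage 1 — latent TF activities.** mRNA levels of a TF are a poor proxy
for its regulatory activity (activation is often post-transcriptional), so
activities are estimated from the behaviour of known targets. With X the
genes × cells log2(count+1) matrix and P the genes × TFs prior
connectivity, we posit X = P A and take the least-squares minimiser
Â = argmin ‖P A − X‖². The system is overdetermined (many more genes than
TFs) and can be rank-deficient — two TFs with identical prior target sets
produce duplicate columns — so the solver is the SVD pseudoinverse, which
returns the minimum-norm solution instead of failing. This system is
ill-conditioned in general; duplicated or near-duplicated prior columns
share their activity estimate, which downstream sparsity then arbitrates.
A TF with no prior targets keeps its own expression as an activity proxy.
Expression is used as-is (not centred) for this stage: the prior carries
signed connectivity, and centring would discard the baseline component of
activity that the intercept-free model attributes to each TF.

**Stage 2 — sparse regression per gene.** Each gene's expression is a
sparse linear combination of regulator activities. Two engines are
provided.

## Single-task: best-subset regression scored by BIC

Exhaustive subset search is only feasible over a small candidate set, so
candidates are preselected: mutual information (MI) between every TF
activity and the gene, computed on 10 equal-width bins per variable (the
conventional choice for context-likelihood-of-relatedness scoring; the bin
count is a parameter), is standardised against its regulator-row and
gene-column backgrounds, negative z-scores are clamped at zero, and the two
are combined as a root sum of squares (CLR). The candidate set is the ten
top-CLR TFs plus every prior regulator of the gene, minus the gene's own
TF. All 2^|R| subsets are fitted by OLS on centred response and predictors
(no intercept) and scored by BIC = n·ln(RSS/n) + q·ln(n). Ties (at 1e-9)
go to the smaller subset, then to the lexicographically first regulator
set, so results are deterministic. Beyond 14 candidates (16384 fits) the
set is trimmed, keeping prior regulators first and then the highest-CLR
TFs; the cap is configurable. A Zellner g-prior hook exists in the design
but is deliberately not applied — priors enter only through candidate
seeding, never as coefficient shrinkage.

The edge score of a chosen regulator is its explained-variance fraction:
1 − RSS_full / RSS_drop, where RSS_drop refits the chosen model without
that regulator, clamped to [0, 1]. An alternative (`score =
"var_exp_r2"`) multiplies by the model's total R², down-weighting edges
from poorly fitting genes; the default keeps the two notions separate.

## Multitask: W = S + B with l1/l1 and l1/l∞ penalties

Cells from different growth conditions are different *tasks*: batch
effects and condition-specific biology both argue against pooling, and
normalising conditions to equal depth risks erasing true biological
variation. For each gene the regulators × tasks coefficient matrix W is
split as W = S + B and fitted by

argmin_{S,B} Σ_d ‖X_i^(d) − Â_d^T (S_{·,d} + B_{·,d})‖² + λs Σ|Φ S| + λb ‖B‖_{1,∞}

with Φ ≡ 1 (adaptive prior weights are supported as a hook but unused, so
priors do not bias coefficients here either). The l1/l∞ penalty charges a
row of B only for its largest entry across tasks, making conserved edges
cheap; the l1/l1 penalty on S accommodates task-specific edges.

**Penalty grid.** λb = c_b·sqrt(d·ln p / n) with c_b on a 20-point log
grid over [0.1, 10.0] (d tasks, p predictors, n mean samples per task);
λs = c_s·λb with c_s on a 10-point linear grid over [1/d + 0.01, 0.99],
so every pair satisfies 1/d < λs/λb < 1 — putting a conserved coefficient
in B (cost λb) is always cheaper than spreading it over S (cost d·λs >
λb), while a single-task coefficient is cheaper in S (λs < λb). The
scaling of λb in d and n admits a second algebraic reading,
c_b·d·sqrt(ln p / n), exposed via `scaling = "linear"`; the 100-fold
range of the c_b grid absorbs the difference, and we default to the
square-root form, under which λb is proportional to the usual
sqrt(ln p / n) lasso rate per task.

**Solver.** The objective is jointly convex with block-separable
penalties, so block-coordinate descent converges to a global minimiser.
The B block is minimised by iterated proximal gradient steps (step 1/L
with L twice the largest Gram eigenvalue across tasks; the l1/l∞ prox is
computed row-wise via Moreau decomposition as the complement of an l1-ball
projection), and the S block by exact coordinate-descent soft-thresholding
sweeps. B is updated first so conserved structure lands in B before the
task-specific sweep; both block updates are monotone, so the recorded
objective trace is non-increasing — a property the tests assert on every
fitted gene. Iteration stops when the relative objective change falls
below 1e-2 (the selection step is rank-based downstream, so tighter
convergence buys nothing) or after 1000 alternations. Across the λ grid
the solver warm-starts from the neighbouring fit, which changes nothing
about the minimiser but speeds the sweep several-fold. Grid points are
scored by EBIC = n·ln(RSS/n) + q·ln(n) + 2γ·q·ln(p) with γ = 1 (the
standard high-dimensional choice; γ = 0 recovers BIC) and q the nonzero
count of W.

One behaviour worth knowing: within a selected row of B, entries smaller
in magnitude than the row maximum are penalty-free, so a regulator that is
strongly active in one task may carry a noise-scale coefficient in others.
Task-specific edges are therefore read from coefficient *magnitude*
(through the explained-variance score), not from the literal zero pattern.
Because tasks differ in depth and scale, responses and activities are
centred and unit-scaled within each task before fitting, which is what
makes a single λ grid meaningful across tasks; with d = 1 the grid's c_s
interval degenerates and the model collapses to a single-task sparse fit.

## Bootstrap rank combination and the global network

Each engine runs on bootstrap resamples of the cells (default 20 in
`run_bbsr_task()`/`run_amusr()`; the end-to-end `infer_network()` defaults
to 5, the value used throughout the package's benchmark studies, where the
gain from more resamples was not worth the runtime). Per (bootstrap, task)
the genes × TFs score matrix is converted to ranks (average rank for
ties), rank sums are min-max normalised to [0, 1], and the same mechanics
combine task-level matrices into the global confidence. Rank combination
makes the result invariant to any strictly monotone rescaling of any
input — only orderings matter. Zero-confidence edges are treated as
absent; ties in the final ordering break lexicographically by (TF, gene).
Edge signs are the sign of the mean coefficient sign across resamples and
tasks, and never contradict a unanimous sign.

The published-network cut keeps the longest confidence-ranked prefix whose
precision against the prior standard is ≥ 0.5. Precision is computed
within the standard's gene × TF universe (the conservative reading:
recovery is only measurable where the standard has an opinion); edges
outside that universe are kept whenever they rank above the cutoff
confidence.

## Evaluation and cross-validation

AUPR is computed as average precision — the mean of precision at each
positive-recovering rank — rather than trapezoidal interpolation, because
it matches exact prefix counting on small instances and is the standard
for ranked-retrieval GRN benchmarks. Cross-validation splits the gold
standard by *gene* (not by edge): half the genes are held out, their rows
removed from the prior (circularity control), and scoring is restricted to
(held-out genes) × (gold-standard TFs) with remaining prior edges excluded
from both the ranked list and the positive set. With an odd gene count the
retained half receives the extra gene (a deterministic choice; the
direction is arbitrary). Genes absent from the gold standard are kept in
the prior — the control targets circularity with the evaluation set, not
prior information per se.

Two negative controls calibrate the harness. *Shuffled priors* permute
gene labels of the prior uniformly at random, preserving every column sum;
the resulting AUPR should match a random ranking's expectation, which is
the positive fraction of the candidate universe. *Null counts* keep every
cell's metadata and total UMI count but redraw its gene counts
multinomially from one fixed transcriptome-wide frequency distribution.
The package estimates that distribution from the observed count matrix
itself (pooled gene frequencies); this stands in for an external absolute
mRNA-abundance reference and matters only through its heavy-tailed shape.
Null counts erase gene-specific covariation, so prior-guided recovery on
them measures pure circular prior leakage.

# The synthetic benchmark

`make_benchmark()` composes three generators so every stage is testable
without downloads:

* `generate_truth()` — a sparse signed genes × TFs network with fixed TF
  out-degree (defaults 200 genes, 20 TFs, 14 targets/TF — matching the
  density of a curated gold standard of ~1400 interactions over 998 genes
  × 98 TFs, at a size a laptop test suite can afford), 80% activators, no
  self-loops; gene base rates drawn log-normal (σ = 1.5) and normalised,
  reproducing the heavy-tailed shape of absolute mRNA abundances.
* `simulate_expression()` — per condition, TF activities are drawn around
  condition-specific means (N(0,1) means, within-condition spread 0.3);
  latent log-expression is truth·activity + base level + N(0, 0.25) noise;
  rates are exponentiated, normalised per cell and downsampled
  multinomially to a log-normal depth around a condition-linked median
  (2250 UMIs, the depth scale of a typical yeast droplet experiment).
  Defaults are 3 conditions × 300 cells.
* the cross-validation split applied to the truth, so the prior half and
  the evaluation half are disjoint by construction.

What the generator does *not* emulate: cell-cycle structure, doublet
transcript mixing, genotype-specific expression effects, batch-dependent
capture efficiency beyond a per-condition depth shift, and dropout beyond
what multinomial thinning produces. Passing recovery tests on this
benchmark therefore demonstrates that the machinery identifies planted
linear structure through realistic count noise — not that real-data AUPRs
of any particular magnitude are attainable; published real-data results
additionally depend on prior quality and condition diversity that no
simulation certifies.

Problem sizes in the test suite (200 genes, 20 TFs, 900 cells, 5
bootstraps, 10 seeds for the recovery study; smaller for unit tests) were
chosen so the full suite runs comfortably on one CPU; all are arguments,
and scale up linearly in cells and genes.

# Numerical choices and degenerate inputs

* Best-subset ties: smaller subset, then lexicographic order (exact
  determinism over floating-point BIC ties).
* RSS = 0 (perfect fit): BIC uses a 1e-12 floor, EBIC returns −Inf, and
  the explained variance of a regulator whose removal still fits
  perfectly is 0.
* Constant vectors: MI is 0 by convention (single occupied bin); CLR
  z-scores against a zero-variance background are 0; a predictor constant
  within a task is dropped from that task's scaled design (zero column).
* Bootstrap seeds derive deterministically from (master seed, index), so
  any single resample is reproducible in isolation; all derived seeds stay
  below 2^31.
* Gene/cell alignment is always by identifier; the TFA stage logs dropped
  genes as an attribute rather than failing on a partial overlap.
* Doublet detection defaults to flagging any second detected barcode
  (min_umi = 1), matching a pooled design where any cross-genotype UMI
  support is disqualifying; the doublet composition model draws both cells
  independently and uniformly from the strain pool, giving the (n−1)/n
  detectable fraction.

# Known limitations

* TFA estimation is a global linear solve; no non-negativity, no
  network-constrained variants, no smoothing over cell neighbourhoods.
* AMuSR fits genes independently; no information is shared across genes
  beyond the common λ grid.
* The precision walk assumes the standard's universe is representative of
  the ranked list's quality outside it.
* The multinomial count model ignores overdispersion beyond what the
  latent log-normal layer induces.
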