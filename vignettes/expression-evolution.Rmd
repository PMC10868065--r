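---
title: "Models and methods: cross-species expression evolution in a polyploid clade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: cross-species expression evolution in a polyploid clade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xprevo)
```

This vignette is the package's own account of the science it implements:
the models, the tunable parameters and their defaults, the synthetic world
used for validation, and the numerical and design choices made where the
methods left room. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## The organism model

All analyses run over a set of "organisms": diploid species, the two
subgenomes of each allotetraploid, and at most one outgroup. Treating
subgenomes as independent organisms is what makes a single framework cover
both species divergence and post-polyploidization expression change: each
subgenome contributes its own expression column, and the tetraploid as a
whole re-enters the analysis only as the *sum* of its two homoeolog
columns. `organism_set()` enforces the structural invariants (unique ids,
exactly two subgenomes per tetraploid, at most one outgroup); missing genes
are kept distinct from observed zeros throughout, because orthogroup
occupancy logic needs the difference.

## Trimming orthogroups to 1:1 sets

Species-complete orthogroups (at least one gene in every organism) may
carry extra paralogous copies. Copies are first screened by homology:
a copy survives only if some hit to a gene of a *different* organism in the
same orthogroup has identity strictly above 50 percent, E-value at most
1e-3, and coverage at least 0.5. Numerical conventions:

* **Coverage denominator** is `min(query length, subject length)` — the
  symmetric, stricter choice for length-mismatched pairs, and the reason
  the hit format must carry `qlen`/`slen` (14-column tabular dialect).
* **Boundary conventions** mirror the rule as stated: identity is strict
  (`>`), E-value and coverage inclusive.
* Orthogroups already 1:1 skip the filter entirely: there is no trimming
  decision to make for them, so an empty hit graph keeps them (with
  assignment score 0) rather than discarding data.

Among surviving copies, the 1:1 assignment maximizes the total bit score,
summed over unordered organism pairs. The pair score is the larger of the
two directional bit scores (insensitive to which search direction scored
better), and 0 when no qualifying hit links the pair — a missing edge in
the hit graph weakens an assignment but does not disqualify it. All
candidate assignments are enumerated exhaustively up to a cap (default
10,000 candidates = the product of per-organism copy counts); beyond the
cap, iterated conditional maximization started from the per-organism
highest-scoring copies, restarted from every single-organism swap, takes
over and the output row is flagged `exact = FALSE`. Ties break
deterministically on the lexicographically smallest gene tuple in sorted
organism order, so reruns are byte-identical. The test suite holds the
optimizer to an independent brute-force enumeration oracle on hundreds of
random orthogroups.

## Expression matrices

"Average TPM" always means the arithmetic mean over an organism's
replicates, computed on the raw TPM scale before any transform. Expressed
calls use an inclusive cutoff (average TPM ≥ 1 by default; 0.1 as the
sensitivity alternative), orthogroup-level calls are any-member-expressed,
and content similarity is the Pearson correlation of the resulting 0/1
columns. Undefined correlations (constant columns) are reported missing
with a warning, never imputed.

For expression-level similarity, rows below 1 average TPM in *every*
organism are dropped, and the log layer is log₂(average + 0.01). The
pseudocount 0.01 bounds the log at about −6.64 for silent genes. Further
choices the underlying methods leave open:

* **Clustering linkage** is average (UPGMA) on the distance 1 − r; no
  linkage is canonical for this analysis, and UPGMA matches how such
  expression dendrograms are usually drawn.
* **PCA input** defaults to the same log layer as the correlation analysis
  (gene-centered, not unit-scaled), for internal consistency; a flag
  switches to raw average TPM, since either reading of "matrix of average
  TPM" is defensible.

## The stationary-OU expression distance and tree

Under a stationary Ornstein–Uhlenbeck model of expression evolution, the
correlation of expression profiles between two organisms decays
exponentially with their divergence, so divergence is recovered as
d = −ln ρ̂, with ρ̂ the Pearson correlation of the two organisms' log
columns over the kept rows. This realization is additive in expectation on
the tree and is the package's concrete instantiation of the sOU distance;
the floor ρ̂ ≥ 1e-9 (configurable) keeps distances finite, and ρ̂ ≥ 1 maps
to distance 0.

Trees are built by standard Saitou–Nei neighbor joining. Negative NJ
branch lengths — an artifact of noisy distance matrices — are set to zero
with the deficit transferred to the adjacent descendant branches, so path
lengths through the node are preserved; the tree is then rooted on the
outgroup edge. Supports come from resampling *rows* (genes/orthogroups)
with replacement, rebuilding distances and the tree each time, and counting
how often each full-data clade recurs among the rooted replicates. Because
every tree (full-data and resampled) is rooted on the same outgroup, clade
counting is done in rooted mode; unrooted counting would report the trivial
outgroup split as never present.

## Ancestral transcriptome estimation

Per-gene ancestral values at an internal node are generalized least
squares estimates under Brownian motion, computed by recursive pruning:
a node joining subtrees with estimates x₁, x₂ at branch distances b₁, b₂
gets (x₁/b₁ + x₂/b₂)/(1/b₁ + 1/b₂), and the merged node carries the branch
correction b₁b₂/(b₁+b₂). Information flows to the target node from *all*
directions, which makes the estimate equal to the profile maximum
likelihood solution of the joint Brownian model (the test suite verifies
this against an independent linear-system solve and against `ape`'s
restricted-ML ancestral estimator). Brownian pruning is used rather than a
full OU fit because topology plus tip expression do not identify OU
parameters gene by gene; this is recorded as an approximation, the
vanishing-selection limit of the OU model.

Conventions: zero branch lengths are replaced by 1e-6; the A₀ ancestor is
defined as the most recent common ancestor of the two A-genome diploids on
the tree restricted to diploids (and outgroup), excluding subgenomes to
avoid polyploidy noise; estimates are made on the log₂ scale and
back-transformed as max(2ᵛ − 0.01, 0) so they can enter dominance analysis
on the TPM scale.

## Expression-level dominance

For each orthogroup the tetraploid's expression P is the sum of its two
homoeolog averages on the raw TPM scale (dominance is about expression
*levels*, so no log transform here). With parents A and D,
d = P − (A+D)/2 and a = (A−D)/2, and |d/a| falls into additive (≤ 0.2),
partial dominance (≤ 0.8), dominance (≤ 1.2) or over-dominance (> 1.2) —
upper bounds inclusive, exactly as the bins are defined. Two guards:

* When the parents are numerically equal (|a| below 1e-9 TPM), the ratio
  is undefined; the call is additive if P also sits at the mid-parent
  value, otherwise over-dominance (the limit of |d/a| as a → 0).
* Orthogroups where P, A and D are all below the expressed threshold are
  excluded and reported, to avoid 0/0 comparisons inflating the additive
  bin.

Category counts from alternative parent configurations evaluated on the
same orthogroup universe are compared by a Pearson χ² test on the 2×2
in/out-of-category table, df = 1, without continuity correction (at the
magnitudes involved the correction does not change any conclusion).

An identifiability caveat, visible in the synthetic world: when the two
parents express a gene at nearly equal levels, |a| ≈ 0 and the bin of
|d/a| is unstable under any measurement noise — the category is simply not
identifiable for such genes. Noiseless classification is exact; noisy
accuracy should be judged within the region of meaningful parental
separation, and the tests do exactly that.

## Bayesian expression conservation

The conservation model is this package's concrete instantiation of a
pipeline usually described only by function names. The full probability
model: organism columns have correlation matrix R (estimated from the log
layer, inverted with a ridge `1e-6·trace(R)/m` added only if the condition
number exceeds 1e8); per gene, the centered cross-organism profile z gives
the divergence Q = zᵀR⁻¹z with ν = m − 1 degrees of freedom (one lost to
centering); Q | W ~ Gamma(ν/2, rate = W), so a conserved gene (large W)
has small expected divergence ν/(2W); and W ~ Gamma(α, rate = β) across
genes. The marginal density of Q,

f(q) = Γ(α+ν/2)/(Γ(ν/2)Γ(α)) · βᵅ q^(ν/2−1) / (β+q)^(α+ν/2),

is maximized numerically over (log α, log β) with moment-based starts from
E[Q] = νβ/(2(α−1)) and E[Q²] = ν(ν+2)β²/(4(α−1)(α−2)). The posterior is
conjugate, W | Q ~ Gamma(α + ν/2, β + Q), and the posterior mean
(α + ν/2)/(β + Q) — strictly decreasing in Q — is the reported
conservation. HSG/LSG are the genes above/below the empirical 95%/5%
quantiles of W, with realized thresholds reported. A fitted α ≤ 1 triggers
a warning (the prior on 1/W then has no finite mean).

The pathway relative-rate test contrasts, per gene, the squared
log-expression deviations of the two focal organisms from the shared
outgroup, Δ = mean(u) − mean(v); its two-sided p-value is a recentred
percentile bootstrap over genes. This outgroup-referenced squared-deviation
contrast was chosen over ancestor-referenced branch rates for transparency
and testable calibration (the type-I error is checked by simulation); both
the statistic's reference organism and the bootstrap size are arguments.
Pathways with fewer than 11 orthologs ("more than ten") are skipped with a
reason. For rate comparisons involving a tetraploid, its per-gene value is
the log₂ of total homoeolog TPM, consistent with the dominance analysis.

## The synthetic world

The generator's defaults *are* the stated validation conditions, chosen
once:

| parameter | default | meaning |
|---|---|---|
| tree | 11-organism cotton-like topology | branch lengths in sOU units; tip correlation e^(−distance) |
| `n_genes` | 6000 | orthogroup count, matching the scale of the real analysis |
| `w_alpha`, `w_beta` | 2, 4 | conservation prior W ~ Gamma(2, 4); stationary variance 1/(2W) |
| `baseline_mean`, `baseline_sd` | 3, 2 | gene baseline on log₂ TPM, a realistic dynamic range |
| `n_reps`, `rep_noise_sd` | 3, 0.2 | replicates per organism; lognormal noise on TPM |
| `eld_mixture` | 0.40/0.25/0.20/0.15 | additive/partial/dominance/over mixture of the grafted tetraploid |
| `split_shape` | Beta(2, 2) | homoeolog split of the tetraploid total |
| `paralog_rate` | 0.15 | probability of a decoy paralog copy per organism and orthogroup |

Log-expression deviations are simulated edge-by-edge as a stationary OU
process (child = parent·e^(−t) plus Gaussian innovation), which both
reproduces the exact tip law — correlation e^(−patristic distance) scaled
by 1/(2W) per gene — and records true internal-node states. The grafted
tetraploid sets its total P from the parents' noiseless values at exact
ratio targets (|d/a| = 0, 0.5, 1, 2 for the four categories; the
over-dominant direction flips upward when the downward target would be
negative TPM), so the classifier/generator round trip is exact at zero
noise. Decoy paralogs fail the homology filter by construction (identity
≤ 50 or coverage < 0.5) while carrying *high* bit scores, so they also
probe that filtering precedes score maximization.

What the generator does **not** emulate: mapping/quantification biases,
count-level sampling noise (TPM is treated as a continuous measurement),
expression correlated across genes (genes are independent draws),
regulatory divergence that violates the stationary-OU law, and real
paralog sequence evolution. A green test therefore establishes that the
estimators invert the stated model faithfully — not that the model captures
every property of real leaf transcriptomes.

Two honest limits of the stated world, documented rather than tuned away:
with W ~ Gamma(2, 4) the per-gene variance weights 1/(2W) are so
heavy-tailed (infinite variance) that gene-resampling bootstrap supports on
the shortest deep branches fluctuate and need not clear a uniform 95 at
6,000 genes; and the outgroup-referenced relative-rate contrast has
moderate power (around 0.6, not 0.8) against a 2× variance contrast with
50 genes — the calibration of its size is exact, the power against a 4×
contrast is high, and both facts are measured by the suite.

## Numerical choices, degenerate inputs

* Correlation floor 1e-9 in the sOU distance (configurable); constant
  expression profiles are an error, not a silent NA.
* Negative NJ branches floored at zero with length transfer (above).
* Zero branch lengths become 1e-6 in ancestral estimation.
* Gamma-prior fitting errors out on degenerate (constant) Q and requires
  at least 200 positive values; non-convergence is an error with the
  moment starts in the message.
* All tie-breaks (assignment tuples) are deterministic; every stochastic
  routine takes an explicit seed, and equal seeds give identical output.
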