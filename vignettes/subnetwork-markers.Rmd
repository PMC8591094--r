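---
title: "Subnetwork markers: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subnetwork markers: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subnetmark)
```

This vignette documents the statistical model behind each pipeline stage,
the parameters that matter, and the choices we made where the design was
genuinely open. Nothing here reports an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The marker model

The pipeline assumes a two-class study (tumor vs normal) in which the
disease signal is carried by small modules of interacting genes rather
than by isolated genes. A module becomes a *subnetwork marker* when it
(i) arises as a flow cluster of the interaction network expanded around
genes that are both differentially expressed and copy-number altered, and
(ii) contains at least one such seed gene and at least three nodes. The
two-omics seed requirement is the integration step: expression change
alone is noisy, copy-number change alone is often silent; their
conjunction marks genes likely to be drivers, and clustering recruits
their interaction partners.

## Differential expression and seeds

Per gene we fit a one-way two-group ANOVA, which with two groups is the
pooled-variance F-test (F = t²). There are no covariates: the design
contrasts tumor against normal only. Fold change is computed on the log2
scale and reported as a *signed linear* fold change,
sign(d)·2^|d| with d = meancase − meancontrol, so the conventional
"absolute FC > 2" cutoff is literal: ±2 means two-fold. Both selection
cutoffs are strict inequalities (`|FC| > 2`, BH-adjusted `p < 0.05`).
Genes with zero within-group variance are not silently dropped; they get
p = 0 when the means differ and p = 1 otherwise, with a warning, so a
degenerate simulated gene cannot vanish unnoticed.

Input expression is assumed log2-scale (as GC-RMA or level-3 array data
are); `linear_input = TRUE` applies log2(x+1) at load time. Multiple
probes mapping to one symbol are collapsed by keeping the highest-mean
row — a deterministic, widely used convention; how the original arrays
were collapsed is generally unknowable downstream, so we do not try to
emulate any particular vendor rule.

## Network expansion

Seeds are expanded one hop into the interaction database and the
*induced* subgraph is kept: every database edge among the retained nodes
survives, including neighbor–neighbor edges. One induced hop is the
standard reading of "expanding a network from seeds"; the depth is a
parameter (`hops`), with `hops = 0` giving the seed-only subgraph.
Interaction type and direction are ignored — the clustering operates on
an undirected, unweighted simple graph. Seeds missing from the database
are kept as isolated flagged nodes (with a warning) rather than dropped,
so coverage problems stay visible.

## Markov clustering

MCL simulates random-walk flow. With adjacency A and self-loops of weight
1 on the diagonal, the column-stochastic matrix M is iterated:

1. *Expand*: M ← M^e (default e = 2), spreading flow along paths;
2. *Inflate*: entry-wise power r (default 2.0) then column
   renormalization, sharpening strong flows;
3. *Prune*: entries below 10⁻⁵ are zeroed, then renormalized.

Iteration stops when the largest entry change drops below 10⁻⁸ (cap 200
iterations; hitting the cap returns the current clustering with a warning
flag rather than failing, since a near-converged flow matrix is still
usable). Clusters are the connected components of the nonzero pattern of
the converged matrix — every node lands in exactly one cluster, which the
downstream scoring requires. Self-loops damp the odd/even oscillations
that bipartite-ish structures otherwise produce. Inflation 2.0 is the
conventional default granularity; larger r dissolves the graph into more,
smaller clusters, and the suite checks this monotonicity. The
implementation is dense with pruning: target graphs here are at most a
few thousand nodes, where dense iteration is simpler and fast enough that
sparse machinery would buy nothing.

Survivor clusters (≥ 1 seed, ≥ 3 nodes — the size boundary inclusive) are
ordered by size, ties broken by lexicographically smallest member, and
numbered 1..n, so marker identities are reproducible across runs.

## Activity scores

Expression is z-transformed per gene (mean 0, n−1 SD 1 across samples;
zero-variance genes dropped with a warning). Every member of a subnetwork
is assigned up or down by the sign of its training class-mean difference
— not only the differentially expressed members, because expansion-added
genes are scored too and need a direction; a universal sign rule is the
only internally consistent choice. Exact ties are excluded from both
sets. The score is mean(z of up) − mean(z of down), an empty set
contributing zero.

Validation cohorts are z-scored *within themselves* (cross-platform
intensities are not comparable; the z-transform absorbs per-platform
location and scale, and the suite verifies this invariance) while up/down
assignments stay frozen from training — the marker definition travels,
the standardization does not. Members missing on a validation platform
are dropped from their sets; each subnetwork reports a coverage fraction
and anything under 50% is flagged.

## Classification and survival

The classifier is a linear SVM with C = 1 on the subnetwork scores, the
simplest defensible default when no kernel or tuning protocol is given;
features are not rescaled (they are already z-derived), keeping the fit
deterministic. `case` is the positive class throughout, so sensitivity is
detection of patients. AUC is the rank statistic of the decision values
with a DeLong 95% CI.

Cox models use Efron tie handling (more accurate than Breslow at no
desk-scale cost). The risk model fits the subnetwork scores as continuous
covariates in one multivariate model, giving one β per subnetwork — the
per-subnetwork coefficient form of the risk score Σᵢ SSᵢ·βᵢ. Clinical
covariates (age ≥50 vs <50, female vs male, stage III–IV vs I–II,
lymphatic invasion yes vs no) are fit separately for reporting.
Coefficients are used at full precision internally; a one-decimal
reference set of 15 coefficients ships as a package fixture
(`reference_risk_coefficients()`, summing to −5.4 with unit scores) for
worked examples. Median-split ties go to the *low* group — a convention
chosen once for determinism. Stratification of identical scores is an
error rather than an arbitrary split.

## Enrichment

Over-representation of marker genes in annotation sets uses the
hypergeometric upper tail with fold enrichment observed/expected, where
expected = |query|·|term|/|background|. The background defaults to all
genes in the annotation file and should be overridden with the assayed
gene universe when available. Raw p-values are reported with BH
adjustment alongside; only one-sided over-representation is tested.

## What the synthetic generators emulate

`gen_expression` draws per-gene baselines from Normal(7, 1) (typical
log2-intensity location for arrays) and plants a fraction of truly
differential genes — defaults: 500 genes, 10% differential at log2 effect
2.0, noise SD 0.5, 35 cases vs 24 controls, mirroring a modest two-class
microarray cohort. `gen_ppi` builds a planted-partition graph (5 blocks
of 8, within-block edge probability 0.6, between 0.05) whose first blocks
are filled with the differential genes, and a copy-number list containing
half of the true differential genes plus an equal number of non-
differential decoys — so the seed intersection lands inside planted
blocks and ground-truth "marker subnetworks" exist by construction.
`gen_survival` draws exponential event times with hazard
h₀·exp(β·z(risk)) (defaults h₀ = 0.1, β = 1) and independent uniform
censoring whose upper bound is solved numerically to hit the target
censoring fraction (default 20%). Exponential survival is the simplest
model satisfying the proportional-hazards assumption the pipeline tests;
clinical covariates are drawn independently of survival (P(age ≥ 50) =
0.7, P(female) = 0.5, P(stage III–IV) = 0.5, lymphatic invasion
0.4/0.5/0.1 yes/no/unknown).

What the generators do *not* emulate: batch effects, probe
cross-hybridization, correlated gene noise, scale-free interaction
topology, hub bias, or informative censoring. Passing the recovery tests
therefore shows the pipeline is correct and well-calibrated under its own
model assumptions — not that it will achieve comparable accuracy on real
cohorts, where effect sizes are smaller and noise is structured.

## Problem sizes and numerical choices

The test suite exercises clustering oracle-equivalence on every connected
graph with up to 7 nodes, block recovery on 200-node planted-partition
graphs (5 blocks of 40), differential-gene recovery at 500 genes ×
20 + 20 samples, classification on 400 genes × 30 + 30 with an
independent validation cohort, Cox recovery at n = 300 with 20%
censoring, and log-rank brute-force equivalence on 200 random small
datasets. These sizes were chosen as the smallest at which the relevant
asymptotics are visible.

Tolerances: column stochasticity is enforced to machine precision and
checked at 10⁻⁹; MCL convergence at 10⁻⁸ with idempotence verified at one
order looser; algebraic identities (BH, score antisymmetry, risk-score
linearity, metric formulas) at 10⁻¹². Pipeline reproducibility is exact:
one master seed fans out to per-stage seeds (stage-name hashed), the run
manifest carries no timestamps, and two identically configured runs are
byte-identical.

## Known limitations

- The MCL implementation is dense; graphs beyond ~5,000 nodes would need
  a sparse rewrite.
- Direction assignment requires class labels; unsupervised scoring of an
  unlabeled cohort is only possible with frozen training directions.
- The multivariate Cox fit needs events ≫ subnetworks; with small cohorts
  the per-subnetwork βs are noisy, and the external-cohort log-rank test
  may be underpowered at the default cohort sizes.
- Alias/identifier harmonization between the expression platform, the
  copy-number list and the interaction database is out of scope; symbols
  are matched exactly after whitespace trimming.
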