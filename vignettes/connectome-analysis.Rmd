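---
title: "Weighted structural connectomes and disease-effect inference: methods"
author: "ConnectomeStats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted structural connectomes and disease-effect inference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ConnectomeStats)
```

# Scope

`ConnectomeStats` implements a complete analysis chain for weighted
structural brain networks in a two-disease case-control design:

1. **construction** of each subject's network from streamline tallies,
   mean FA and regional volumes;
2. **measurement** of five local and nine global graph measures;
3. **normalization** of the global measures against degree-preserving
   random-graph ensembles;
4. **inference** on disease effects (ADCI, LBCI, their interaction) and on
   cognition, with covariate adjustment, AIC model screening and
   Benjamini–Hochberg FDR control;
5. a **synthetic cohort generator** that emulates the study design, so the
   whole chain is testable end-to-end without imaging data.

Image acquisition, preprocessing, tractography and voxelwise (TBSS)
analyses are out of scope: streamline tallies are consumed as inputs.

# Network construction

The node scheme is the AAL atlas — 45 regions per hemisphere, six of them
subcortical — extended with the bilateral substantia innominata, 92 nodes
in all (`aalParcellation()`). Two parcels are connected when at least
`minStreamlines = 3` streamlines join them end-to-end; this inclusive
threshold (counts ≥ 3) suppresses false-positive connections of
deterministic tractography. Retained edges are weighted
$w_{ij} = \mathrm{count}_{ij}\,\mathrm{FA}_{ij} / ((v_i+v_j)/2)$.

Two readings of "mean FA multiplied by the streamline count" are possible;
`buildNetwork(weighting =)` exposes both. The default, `"countTimesFA"`,
multiplies mean FA by the count (equivalently, sums per-streamline mean
FA); `"faOnly"` uses mean FA alone. Both divide by the average of the two
regional volumes, in subject-native units (mm³): ICV does **not** rescale
weights and enters the analysis only as a covariate. The choice is
isolated in one function so the variant is a single argument, not a fork.

# Graph measures

Local, per node: degree (on the binarized network), strength (sum of
incident weights), weighted clustering, nodal shortest path length, and
betweenness centrality. Choices the measure names leave open were fixed
as follows, matching Brain Connectivity Toolbox conventions:

* **Clustering** is the Onnela geometric-mean form: with
  $\hat w = w/\max(w)$,
  $C_i = \frac{1}{k_i(k_i-1)}\sum_{j,h}(\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3}$,
  and $C_i = 0$ for $k_i < 2$. The $\max(w)$ rescaling makes it invariant
  to global weight scaling.
* **Path-based measures** use edge lengths $d_{ij} = 1/w_{ij}$, the
  conventional mapping for FA-weighted connectomes (stronger connection =
  shorter distance). Distances and betweenness run through igraph
  (Dijkstra; weighted Brandes with fractional sharing of equal-length
  paths). Betweenness is left **unnormalized**, each unordered pair
  counted once (a 5-node star center scores 6); the group GLMs are
  invariant to any common normalization constant.
* **Disconnected pairs** are excluded from the characteristic path length
  (finite-pair mean) rather than propagating infinities; global efficiency
  $E_{glob} = \langle 1/d_{ij} \rangle$ handles them naturally as zero
  contribution. A node reaching no other node gets nodal path length 0
  with a warning; a network with no connected pair gets `NA` path length
  (flagged) and $E_{glob} = 0$.

The test suite validates every measure against brute-force oracles —
Floyd–Warshall distances, explicit triple products, and a path-count
dynamic program that is algorithmically independent of Brandes
accumulation — on 200 random networks of up to 8 nodes at $10^{-9}$
tolerance.

# Null-model normalization

Normalized measures scale the raw ones by their mean over
`nGraphs = 100` matched random graphs preserving nodes, edges and the
degree sequence (Maslov–Sneppen double-edge swaps). Decisions the
procedure leaves open:

* **Weights travel with rewired edges**, so the edge-weight multiset is
  preserved exactly — the common toolbox behavior for weighted nulls.
* **Mixing:** `swapsPerEdge = 10` swap attempts per edge, the standard
  heuristic. A swap is rejected if it would create a self-loop or
  multi-edge (or drew two edges sharing an endpoint); an attempt finding
  no legal swap in 100 random tries is skipped and counted
  (`skippedSwaps`). Networks with fewer than two edges are returned
  unchanged with a warning.
* **Reproducibility:** per-graph seeds derive deterministically from the
  ensemble seed; per-subject ensemble seeds derive from the cohort-level
  seed and subject index, so cohorts are reproducible and
  order-independent. The rewiring core is compiled (Rcpp) with its own
  small PRNG, so results do not depend on R's RNG state.
* An ensemble mean of zero (e.g. triangle-free graphs, where clustering
  is identically 0) yields a flagged-missing normalized value with a
  warning rather than an infinity.

$\sigma = \gamma/\lambda$ is computed from the returned $\gamma$ and
$\lambda$, so the identity holds to machine precision. Self-consistency
is tested by normalizing inputs drawn from the rewiring null itself: the
means of $\gamma$, $\lambda$ and normalized $E_{glob}$ over 100 such
inputs must lie in $[0.97, 1.03]$.

# Statistical inference

All models are ordinary least squares on an intercept plus predictors,
with the six covariates age (years), sex (0/1), education (years), DWMH
and PWMH (ordinal 1–3, entered numerically) and ICV (mm³). Disease flags
are binary: ADCI = 1 for pure ADCI and mixed subjects, LBCI = 1 for pure
LBCI and mixed; the interaction ADCI × LBCI is 1 for the mixed group
only. Rows with missing values are dropped listwise (count recorded).
Two-sided p-values come from the t distribution on residual df.

* **Interaction screening:** if the interaction term is significant at
  α = 0.05 the interaction model is kept; otherwise the lower-AIC model
  wins, with the model without the interaction preferred on an exact tie
  (parsimony). The AIC stored is the Gaussian-OLS form
  $n\ln(\mathrm{rss}/n) + 2k$; it differs from `stats::AIC` by constants
  common to same-$n$ models, so rankings are identical. For local
  measures the interaction is judged on the uncorrected p-value
  (pre-FDR); this is a documented choice where the procedure is silent.
* **Multiplicity:** BH-FDR across the 92 nodes for each local measure
  (per disease predictor), and across the 14 neuropsychological tests per
  cognition model. **No correction across the nine global measures** —
  deliberately mirrored from the original explorative analysis and tagged
  `scope = "none"` in the output.
* **Cognition:** Model 1 regresses each standardized score on the network
  predictor plus covariates; Model 2 additionally controls for the
  disease flag, guarding against association driven merely by disease
  presence.
* A rank-deficient design errors naming the collinear columns; a
  constant-valued node outcome (possible in tiny cohorts) contributes
  p = 1 to the local sweep rather than NaN.

The OLS engine shares one QR decomposition across any number of outcome
columns, which is what makes 92-node sweeps and thousand-replicate
calibration loops cheap. It is verified against `stats::lm` and a
normal-equations oracle at $10^{-8}$.

One calibration subtlety: under a global null with independent tests,
BH's expected false-discovery proportion equals $q\,m_0/m = q$ *exactly*.
A finite-replicate check of "mean FDP ≤ 0.05" would then fail about half
the time by Monte-Carlo noise alone, so the suite asserts the mean FDP is
within three Monte-Carlo standard errors of the 0.05 bound — the
statistically meaningful one-sided reading.

# The synthetic cohort generator

`cohortConfig()` defaults define the emulated study: 114 subjects in
groups 37 (control) / 22 (pure ADCI) / 19 (pure LBCI) / 36 (mixed);
per-group age, sex, education and WMH distributions loosely matched to
the published demographic table; ICV distributions (mean 1.45 × 10⁶ mm³,
SD 1.2 × 10⁵) are **invented**, since no per-group values are reported,
and are flagged as such.

The base connectome is a **distance-free modular random template**:
nodes are assigned to 4 modules (cycling over node order, which
segregates the interleaved hemispheres), with edge probability 0.45
within and 0.12 between modules; present edges receive heavy-tailed
streamline counts $1 + \mathrm{NB}(\mu = 9, \theta = 0.7)$ and Beta-
distributed FA on $[0.15, 0.70]$; volumes are log-normal around 8000 mm³.
This is a simulation device chosen for testability — not a claim about
brains. Subjects perturb the template with multiplicative log-normal
count noise (SD 0.2), additive FA noise (SD 0.025), and ICV-coupled
volumes.

**Planted effects** multiply counts and/or FA on designated edge sets
*before* integer rounding; scaled counts rounding below 1 remove the
edge. Defaults:

* LBCI: count scale **0.55** on left-caudate-incident edges, and
  **0.60** on between-module edges;
* ADCI: FA scale **0.93** diffusely — which moves strength and weights
  but leaves degree untouched, giving a clean negative control.

The between-module scaling deserves a note. A uniform *weight* rescaling
moves $L$ and its rewired-null mean in lockstep, leaving $\lambda$ flat;
a genuine integration deficit requires **topological shortcut loss**. At
0.60, enough low-count between-module edges fall below the 3-streamline
threshold that LBCI subjects lose shortcuts their degree-matched random
graphs would restore — raising $\lambda$ and lowering normalized
$E_{glob}$, the qualitative pattern the inference layer is designed to
detect. Weaker scalings that only thin weights do not produce it.

Cognition is generated from the subject's *realized* network (left-
caudate degree and one raw global measure, cohort-standardized, default
loadings 0.35 and 0.30 per score) plus age and education terms and
Gaussian noise (SD 0.8), so parameter-recovery tests have a known ground
truth. The 14 scores use the canonical battery order
(`cognitionScores()`).

What the generator does **not** emulate: spatial embedding and
distance-dependent connectivity, hemispheric asymmetries, measurement
floor/ceiling effects in cognitive scores, site or scanner effects, and
any longitudinal structure. Passing tests therefore demonstrate that the
pipeline recovers what it is pointed at under the stated noise model —
not that real dementia cohorts behave like the template.

# Problem sizes in the test suite

The suite exercises: oracle equivalence on 200 random ≤ 8-node networks;
null-ensemble contracts on 100-graph ensembles over 30-node graphs with
100-input self-normalization; FDR/type-I calibration at 1000 replicates
(92 null nodes; n = 200 single-predictor fits); planted-effect recovery
on 200 replicate 114-subject cohorts; and null-centering of disease betas
over 500 replicate 40-subject cohorts on a 30-node parcellation (the
centering property is size-free; the reduced size keeps the default test
run fast). These sizes are the package's own reproducibility choices and
are all driven by fixed seeds.

# Known limitations

* Only undirected, non-negative weighted networks; no signed or directed
  measures, community detection or rich-club analysis.
* The rewiring null preserves the degree sequence and weight multiset but
  not the strength sequence or any geometric constraint.
* OLS with listwise deletion; no mixed models, permutation inference or
  robust errors.
* Whether betweenness should be normalized, and whether interaction
  screening should use FDR-corrected p-values, are left as documented
  defaults (unnormalized; uncorrected) since the statistics used are
  invariant or the procedure silent, respectively.
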