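# ConnectomeStats

Graph-theoretic analysis of weighted structural brain networks for
case-control dementia studies, in R.

Deterministic tractography on diffusion MRI yields, for every subject, a
tally of streamlines connecting each pair of brain parcels, the mean
fractional anisotropy (FA) along those streamlines, and regional volumes.
`ConnectomeStats` turns those tallies into weighted structural connectomes,
computes local and global network measures with random-graph normalization,
and tests how two co-occurring disease processes — Alzheimer's
disease-related cognitive impairment (ADCI) and Lewy body-related cognitive
impairment (LBCI) — affect network organization and cognition. It is
written for neuroimaging researchers who have connectome tallies (or want
to simulate realistic ones) and need the full construction → measurement →
normalization → inference chain as tested, reproducible code.

## The model

**Network construction.** Nodes are the 92 parcels of an extended AAL
scheme (45 regions per hemisphere, including six subcortical regions, plus
the bilateral substantia innominata). A node pair is connected when at
least **3** streamlines link it end-to-end (guarding against
false-positive connections), and retained edges are weighted

```
w_ij = count_ij × FA_ij / ((v_i + v_j) / 2)
```

— streamline count times mean FA, divided by the average volume of the two
regions to correct for node size. Each subject's network is a symmetric
92 × 92 matrix.

**Graph measures.** Five local measures per node — degree `k_i`, strength
`s_i`, Onnela weighted clustering `C_i`, nodal shortest path length `L_i`,
and betweenness centrality `BC_i` — and nine global measures: mean degree,
mean strength, clustering coefficient `C`, characteristic path length `L`,
global efficiency `E_glob`, and the normalized measures
`γ = C/⟨C_rand⟩`, `λ = L/⟨L_rand⟩`, normalized `E_glob`, and
small-worldness `σ = γ/λ`. Path-based measures use edge lengths
`d_ij = 1/w_ij`; the normalizing ensembles are 100 Maslov–Sneppen
degree-preserving random graphs per subject (same nodes, edges, degree
sequence and edge-weight multiset).

**Inference.** Disease effects on every measure are estimated with general
linear models controlling for age, sex, education, deep and
periventricular white-matter hyperintensities, and intracranial volume.
ADCI and LBCI enter as binary flags (the mixed disease group has both);
an ADCI × LBCI interaction term is screened and, when non-significant,
the better-fitted model is chosen by AIC. Local-measure tests are
corrected by Benjamini–Hochberg FDR across the 92 nodes; models of the 14
standardized neuropsychological scores (Model 1, and Model 2 additionally
controlling for the disease flag) are FDR-corrected across the 14 tests.

**Synthetic cohorts.** Because the statistics need realistic inputs, the
package includes a generator that emulates the study design: 114 subjects
in groups of 37 controls / 22 pure ADCI / 19 pure LBCI / 36 mixed,
per-group covariate distributions, and plantable multiplicative disease
effects on designated edge sets (by default, LBCI thins
left-caudate-incident and between-module connections; ADCI diffusely
lowers FA). Every cohort is bitwise-reproducible from one seed.

## Worked example

```r
library(ConnectomeStats)

cfg <- cohortConfig(seed = 42L)        # the 37/22/19/36 study design
coh <- generateCohort(cfg)
net <- buildNetwork(coh$subjects[["S001"]])
net
#> WeightedNetwork: 92 nodes, 612 edges (density 0.146)

round(globalMeasures(net)[1:5], 4)
#>       meanDegree     meanStrength       clustering       pathLength
#>          13.3043           0.0085           0.0133        2516.4805
#> globalEfficiency
#>           0.0005

g <- normalizeGlobals(net, spec = nullEnsembleSpec(nGraphs = 100L, seed = 1L))
round(g[c("gamma", "lambda", "normEglob", "sigma")], 3)
#>     gamma    lambda normEglob     sigma
#>     1.157     0.985     1.014     1.175
```

The subject's network keeps ~13 edges per node after the 3-streamline
rule; weights are small because volumes are in mm³, so raw path lengths
are large — which is why the normalized measures are the interpretable
ones. `γ > 1` with `λ ≈ 1` (`σ > 1`) is small-world organization:
clustering well above degree-matched random graphs at comparable path
length.

Cohort-level inference:

```r
ce  <- simulateExperiment(cfg, nullSpec = nullEnsembleSpec(100L, seed = 7L))
diseaseEffectModel("lambda", ce)
#> GlmFit for 'lambda' (n = 114, df = 105, AIC = -1130.90)
#>    predictor       beta        se       t         p
#>  (Intercept)  9.984e-01 1.021e-02 97.8000 6.04e-105
#>         adci  2.844e-04 1.350e-03  0.2110  8.34e-01
#>         lbci  2.569e-02 1.538e-03 16.7000  2.43e-31
#>          ...
```

The planted LBCI integration deficit shows up exactly where it should:
LBCI subjects have a higher normalized path length (β = +0.026,
p ≈ 1e-31) while the ADCI coefficient is null. Per-node sweeps
(`localEffects(ce, "degree")`) likewise flag the left caudate's degree
reduction after FDR correction, and `cognitionModels(ce, "lambda",
model2Flag = "lbci")` returns the 14-test battery for both models.

A full run — simulate (or load TSV/CSV inputs), build, measure,
normalize, infer, write CSV reports plus a JSON manifest — is one call:

```r
runPipeline(list(simulate = list(seed = 1L)), "results/run1")
```

or from a shell via `inst/scripts/connectome-pipeline.R`.

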