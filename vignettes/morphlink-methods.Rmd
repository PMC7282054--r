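---
title: "Methods: surface GLMs, RFT cluster inference, and brain–behaviour CCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surface GLMs, RFT cluster inference, and brain-behaviour CCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphlink)
```

`morphlink` implements a two-track analysis of cortical morphometry in a
2×2 factorial autism cohort (22q11.2 deletion × ASD diagnosis), plus the
synthetic-cohort machinery needed to validate every stage. This vignette
is the package's own account of the models, the tunable parameters, the
numerical choices, and what the passing tests do and do not establish.

## The synthetic cohort

`simulate_cohort()` draws 131 subjects in four groups (22q11.nonASD
n = 25, 22q11.ASD n = 25, idiopathic ASD n = 40, TD n = 41) with exact
cell sizes. Site and gender are sampled with the observed group-wise
allocation probabilities (the idiopathic ASD group is scanned at a
single site — deliberately kept, because this site–group confound is a
real feature of the design that the GLM must absorb). Age (years), IQ,
total cortical volume (L), total surface area (m²), mean thickness (mm)
and SRS totals come from truncated normals with the published group
means/SDs; age is truncated to [6, 25], matching the published range.
The five SRS subdomains are drawn separately, each carrying a fixed
share of the group total (shares 0.12/0.18/0.34/0.16/0.20 for
SAW/SCG/SCM/SM/RRB, approximating the instrument's item allocation);
the SRS total is their sum by construction. Drawing subdomains jointly
as exact shares of one total would make the clinical matrix singular,
so each subdomain gets its own truncated-normal draw; the within-group
subdomain covariance is deliberately a free property of the generator,
not an assertion about the study population.

### The mesh

`make_toy_mesh()` builds a subdivided icosahedral sphere (radius 80 mm,
total area ≈ 80,000 mm², the order of a human cortex), split into
hemispheres at x = 0 and parcellated into 34 contiguous regions per
hemisphere by farthest-point seeding and round-robin breadth-first
growth. RFT and aggregation depend only on topology and metric, so
anatomical shape is irrelevant for validity; geodesics are approximated
by Dijkstra paths over edge lengths, adequate at the mesh resolutions
used.

### Vertex maps and planted effects

`simulate_vertex_metrics()` composes, per metric: a subject baseline
derived from the subject's global measure (so the total-brain covariate
is structurally linked to the maps, as in real data), optional covariate
slopes on mean-centred covariates, planted group/interaction effects,
and spatially correlated Gaussian noise — white noise passed through the
mesh smoother and rescaled so the marginal SD equals `noise_sd` exactly.
Default noise SDs (CV 30 mm³, SA 8 mm², CT 0.25 mm) are of the order of
between-subject vertex variability in FreeSurfer data. Planted effects
taper linearly from `amplitude` at the seed to zero at
`geodesic_radius`; the `plateau` argument holds the full amplitude out
to a fraction of the radius, giving lesion-like extended effects whose
2×2 cell-mean contrast at the seed equals the amplitude exactly.

## Track 1: the vertex GLM and RFT cluster correction

Every vertex is fitted independently by OLS with terms intercept,
del22q11, asd, interaction, gender, site (dummies), IQ, age, age²,
and the metric-matched total-brain measure (total CV for CV, total SA
for SA, area-weighted mean CT for CT — area weighting is our choice;
an unweighted mean differs negligibly on a near-uniform mesh).
The two experimental factors use ±½ sum-to-zero coding, so β1/β2 are
main effects averaged over the other factor and β3 is the classical
interaction contrast; with this coding β1 equals the carrier vs
non-carrier marginal mean difference in a balanced noiseless cohort
(asserted in the tests). Continuous covariates are mean-centred across
groups. Zero residual variance yields non-finite t values rather than
fabricated statistics.

### Smoothing

`smooth_metric()` iterates a lumped-mass heat-diffusion step
`S = (I − τ·Da⁻¹L)^k` (L the graph Laplacian, Da vertex areas), which
preserves constants and conserves area-weighted mass to machine
precision. The iteration count k is set so the accumulated random-walk
variance matches the Gaussian `(fwhm/2.355)²` given the mean edge
length, with a per-step neighbour weight capped at 0.3 to keep the
iterated kernel close to Gaussian. The impulse-response tests verify
the realised FWHM within 20% by a geodesic half-maximum measurement.

### Smoothness estimation and cluster p-values

`estimate_resels()` normalizes the residual vector across subjects at
each vertex to unit norm; the edge sum of squared differences of these
normalized residuals equals 2(1 − r), giving a per-edge gradient
variance λ, a local FWHM `sqrt(4·log 2 / λ)`, and per-triangle resel
density area/FWHM² — the non-isotropic smoothness field. Cluster
extents are measured in resel units by *linear interpolation of the
excursion set within each triangle*: counting whole vertex shares
would systematically overstate the extent of small clusters at their
boundaries and measurably inflates the family-wise error rate (we
observed ≈ 0.09–0.12 at nominal 0.05 with vertex-share counting,
against ≈ 0.06 with interpolated extents). Corrected p-values use the
standard 2-D random-field results for t fields: expected cluster count
`E[m] = R·ρ₂(t*)` from the Euler-characteristic density, expected
supra-threshold resel mass `E[n] = R·P(T > t*)`, and an exponential
extent tail `P(K ≥ k) = exp(−k·E[m]/E[n])` (the D = 2 case), so
`p = 1 − exp(−E[m]·P(K ≥ k))`. A cluster with zero resel extent is
never significant (p = 1). The two-tailed α = 0.05 procedure runs each
tail at 0.025 with a primary threshold of p = 0.001 per tail; the
primary threshold is not fixed by the source study and is exposed as
configuration, 0.001 being the common surface-RFT convention.

### Calibration conditions

The Monte-Carlo calibration and power tests run on a 2,562-vertex mesh
with noise smoothed to three mean edge lengths — the canonical minimum
smoothness for the RFT lattice approximation to hold. The null FWER
over 500 simulations must land in [0.02, 0.09]; the detection test
plants an interaction effect of 1.5 noise SDs over a 40 mm disc
(plateau 0.8) in the n = 131 cohort and requires corrected detection in
≥ 90% of runs, using the pure factorial design so the measurement
isolates cluster inference rather than covariate deconfounding (the
default cohort's complete site–group confound inflates the interaction
SE by ~25% and is exercised elsewhere).

## Track 2: regional features and CCA

`aggregate_regions()` produces 2 × 34 × 3 = 204 features;
`residualize_features()` regresses each on age, age², gender, site, IQ
and the metric-matched total-brain measure across *all* subjects —
residualizing within groups would remove the group differences the
analysis is about — then standardizes. `stepwise_aic_select()` runs an
independent greedy both-direction stepwise regression per SRS subdomain
from the intercept-only model with `AIC = n·log(RSS/n) + 2k`, and the
selected set is the union of the five final models — the only reading
of a per-outcome selection that can exceed any single model's size.
The greedy loop is hand-written to control the model-size cap and to
record full paths; `stats::step` serves as an independent oracle in the
tests.

`fit_cca()` is computed on correlation matrices (the features mix mm,
mm² and mm³, and loadings-as-correlations are scale-free) via Cholesky
whitening and SVD of `Cx⁻ᵀ Sxy Cy⁻¹`, which guarantees unit-variance,
within-side-uncorrelated variate scores. Signs are fixed per variate so
the dominant clinical loading is positive. The significance apparatus
(`wilks_lambda`, `rao_f`, `pillai_trace`, `bartlett_chi2`,
`rv_coefficient`, `adequacy_redundancy`, `sort_variates`) follows the
classical formulas; `rho_sq = 1 − λ` holds identically, clinical
adequacies sum to 100% when s = q, and redundancy equals adequacy times
the squared canonical correlation (all asserted, with regression-based
oracles). Rao's df2 uses the floor convention
`floor(w·t − pq/2 + 1)`; agreement with the published worked example
(λ = 0.015, F(315, 319) = 1.35, Pillai 2.81 / F(315, 335) = 1.36,
χ²(315) = 402.24, χ²(248) = 294.58) is within the rounding of the
printed correlations. Variates are sorted by ascending Bartlett p with
clinical adequacy breaking ties.

### Group comparison

`forward_loadings()` computes within-group correlations of each
observed column with the *full-sample* variate scores — the pipeline
never refits CCA within groups. Tucker's φ compares the two groups'
loading columns per variate (> 0.95 "equal", 0.85–0.94 "fair", < 0.85
"low"); Fisher-Z tests compare individual loading pairs with no
multiplicity correction by default, mirroring the original reporting
(Benjamini–Hochberg values are carried alongside). The one-tailed
p-value is taken in the observed direction, which is anticonservative
(it doubles the nominal rate when no direction is prespecified); the
directional `alternative = "greater"` variant is exactly calibrated and
is what the type-I calibration tests exercise.

### Planted brain–behaviour structure

`simulate_latent_scores()` plants canonical correlations by pairing
each brain projection u with a clinical latent
`v = ρu + sqrt(1 − ρ²)e` and mapping `V` through orthonormal clinical
weights with additive noise (`noise_sd = 0.2`, a mild attenuation
keeping realized correlations within ±0.02 of ρ).
`simulate_group_divergent_data()` is the congruence ground truth: both
groups share clinical weights and canonical strengths, but the latents
express through disjoint single-feature brain patterns per group. The
loading of a feature on a variate always contains a shared
`w_j`-proportional term (a feature's own noise correlates with its
weight in the variate), so group loadings can only diverge when the
planted pattern dominates per-feature variance; `pattern_scale = 5`
(signal variance 25× noise on the supporting features) reproduces the
magnitude of dissociation reported in the source cohort (clinical
φ > 0.99 with mean brain φ ≈ 0.34).

## Cohort statistics

`contingency_chi2` is plain Pearson χ² without continuity correction —
the convention that reproduces the published site-by-group statistic
(105.03, df 6) from the printed counts. `oneway_anova` wraps the
standard one-way decomposition; `scheffe_posthoc` implements all
pairwise Scheffé contrasts against `(k−1)·F` (hand-coded; no installed
package provides it); `levene_test` uses the median-centred
Brown–Forsythe variant via `car::leveneTest` (the centring is not fixed
by the source description; the median variant is the robust default).

## Problem sizes, determinism, degenerate inputs

All simulation stages are seed-controlled and bit-reproducible; the
pipeline derives stage seeds as `seed·1000 + offset` and embeds the
seed and a config hash in every output bundle. Unit tests run on
162–642-vertex meshes; the calibration Monte-Carlos use the
2,562-vertex mesh with 500 null and 100 power simulations, chosen to
estimate a 0.05 rate with a binomial SE of ≈ 0.01. Degenerate inputs
fail loudly rather than silently: rank-deficient designs report the
offending columns, replicated residual fields are rejected for
smoothness estimation (rank < 2), zero-variance features are dropped
from standardization with a warning and excluded pairwise from
congruence and Fisher-Z tests, and collinear CCA inputs are rejected on
a correlation-matrix condition-number guard (default 1e10).

## Known limitations

* The generator emulates distributional structure, not anatomy: no
  folding geometry, no site intensity artifacts (site enters only as a
  categorical effect), no longitudinal structure.
* RFT cluster inference is asymptotic in smoothness and threshold; at
  smoothness below ~3 edge lengths the exponential extent tail is
  optimistic, which is a property of the method, not of this
  implementation.
* Stepwise AIC at n = 131 with 204 candidate features overfits (it
  selects more features than a cross-validated criterion would), and
  canonical correlations computed after selection on the same data are
  biased upward. The package reproduces this pipeline faithfully; it
  does not claim the pipeline is unbiased.
* Passing the planted-structure tests shows the implementation recovers
  what it plants under its own noise model; it cannot certify behaviour
  on real cortical data.
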