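---
title: "Methods: cortico-subcortical connectivity fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cortico-subcortical connectivity fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Within the cortico-basal-ganglia network, the striatum (STR) receives the
direct- and indirect-pathway projections from cortex, while the subthalamic
nucleus (STN) receives the monosynaptic hyperdirect pathway. A natural way
to compare the two input structures is the *connectivity fingerprint*: the
profile of connection strengths between each structure and a fixed set of
cortical areas — here the 17 frontal areas with established tracer evidence
of projections to both structures in non-human primates (M1, preM1, SMA,
preSMA, FEF, DLPFC, FPA, VMPFC, OFC, IFS, IFJ, POP, PTR, CIN, CMA, PGA,
SGA).

This package implements the fingerprint comparison itself — the metrics,
the functional-correlation profile and the Bayesian statistics — over
co-registered inputs. Everything upstream (acquisition, registration,
skull-stripping, motion/eddy correction, fiber-model fitting, the
probabilistic tractography run, manual parcellation) is a preprocessing
concern handled by established imaging tools and is out of scope: the
package consumes the *outputs* of that chain, namely ROI masks and
per-seed-voxel streamline sample counts on a shared voxel grid, plus
(optionally) BOLD series. A synthetic phantom generator stands in for the
scanner data, with every generative parameter known, so that the whole
analysis is testable end to end against ground truth.

## Structural metrics

Probabilistic tractography launches `n_samples` streamline samples (study
value 5000) from every voxel of a seed mask and records, per voxel, how
many reached the target mask. Two metrics summarise one directed map,
after removing spurious connections by keeping only voxels with **at least
50** samples (inclusive threshold):

* **Tract seed ratio** — the mean of `count / n_samples` over the
  *surviving* voxels: the average fraction of samples that reached the
  target, among voxels with evidence of any connection.
* **Tract strength** — the number of surviving voxels divided by the total
  seed-mask voxel count: the fraction of the seed region that is
  probabilistically connected at all. Because it is normalised by the seed
  volume it is comparable between the small STN and the much larger STR.

Both metrics are computed in each tracking direction (structure→area and
area→structure, each direction's strength normalised by its *own* seed
mask) and averaged; a missing direction is an error, never a silent
one-way fallback.

Two definitional choices were genuinely open:

* *Survivor-only averaging.* Thresholding before averaging strongly
  implies that sub-threshold voxels do not enter the seed-ratio mean, so
  survivor-only averaging is the default; whole-mask averaging (counting
  sub-threshold voxels as zero) is available via
  `seed_ratio_oneway(survivors_only = FALSE)`.
* *Empty survivor set.* A tract with no surviving voxel gets ratio 0
  rather than `NA`: an unconnected tract has zero measured connectivity,
  and this keeps the downstream statistics total.

For distance-corrected maps (real tractography output with path-length
weighting) the values are no longer counts; the threshold is applied to
the stored values as-is, the `[0, 1]` bound on the seed ratio no longer
holds, and the result carries a warning attribute. The phantom generator
does not emulate distance correction: uncorrected counts keep the metric
semantics exactly verifiable.

## Functional fingerprint

The resting-state fingerprint is the Pearson correlation between each
structure's mean BOLD series and each cortical area's series, per subject
and hemisphere. The module applies no detrending, filtering or nuisance
regression — the input is assumed fully preprocessed — and a constant
series raises an explicit undefined-correlation error rather than
returning `NA`.

## The phantom generator

`ground_truth_spec()` fixes the study conditions: 16 subjects, 5000
samples per voxel, 17 cortical areas × 2 structures × 2 hemispheres.
Masks are disjoint boxes on a 48³ grid, with the STR mask exactly ten
times the STN's volume (640 vs 64 voxels), emulating the real volume
asymmetry that motivates the volume-normalised strength metric.

Counts follow a two-component binomial model per seed voxel: a voxel is
truly connected with probability `f` (the *connected fraction*), a
connected voxel's count is Binomial(5000, `p`), an unconnected one's
Binomial(5000, `p0`) with `p0 = 1e-4` (about 0.5 expected spurious
samples, essentially never crossing the threshold of 50). Under this model
the expected tract strength is `f·P(Bin(5000, p) ≥ 50) + (1−f)·P(Bin(5000,
p0) ≥ 50) ≈ f` and the expected seed ratio is `≈ p`, which is what the
recovery tests check.

The packaged default truth encodes the qualitative pattern of the study
design: the STR is the more densely connected structure for 15 of the 17
areas, with the OFC and VMPFC as the two exceptions where the STN
connects more densely. The default reach probabilities `p` are the
published per-(structure, area) mean seed ratios. For the connected
fractions we follow the published strength means where the two structures
clearly separate, but widen three near-tie areas (preSMA, PGA, SGA) to a
minimum gap of 0.10 in the STR > STN direction: the phantom's purpose is
sign recovery of an *encoded* pattern, and a power analysis at the default
between-subject SD of 0.03 (expected paired t ≈ 7 at n = 16) shows a 0.10
gap is decisively recoverable while a 0.01 near-tie is not, at any
realistic cohort size. The generator is therefore a calibrated testbed,
not a reproduction of the published group means.

Resting-state series are zero-mean Gaussian with population correlation
matrix ρ, generated through the symmetric eigenvalue square root of ρ (so
exact rank deficiency — duplicated or anti-correlated ROIs with ρ = ±1 —
is reproduced to machine precision). The default ρ is a 19×19
per-hemisphere matrix: cortico-cortical 0.25, STR–cortex 0.50, STN–cortex
0.10, STN–STR 0.20; hemispheres are generated independently
(interhemispheric BOLD correlation is not modeled). Note the default
functional truth is purely additive — the STR is uniformly more correlated
with cortex — so the mixed-model interaction Bayes factor correctly favours
the reduced model on the functional fingerprint while decisively favouring
the full model on tract strength; the phantom thus exercises both
directions of the model comparison.

Between-subject variability applies the `subject_sd` jitter to the
connected fractions (clipped to `[0, 1]`) and to the Fisher-transformed
correlations. Because independent z-jitter can push a correlation matrix
marginally off the positive-semidefinite cone, the per-subject matrix is
repaired with `Matrix::nearPD(corr = TRUE)` when needed;
`generate_rsfmri_series()` itself still rejects non-PSD input.

What the phantom does **not** emulate: spatial autocorrelation of counts
(the metrics are voxelwise aggregations, so spatial structure cannot
affect their values), distance correction, scanner noise, head motion,
physiological confounds, registration error, and per-subject mask
geometry (masks are shared across subjects). Passing tests therefore
demonstrate correctness of the *computations* under known truth, not
robustness to real-data artefacts.

### Reproducibility scheme

One global integer seed expands into per-component substreams via the
affine counter map `substream(seed, c) = (48271·seed + 7919·c) mod
(2³¹−1)`, with disjoint counter blocks for subject-level jitter, count
maps (one counter per subject × tract × direction), series and
correlation jitter. Any part of a cohort can be regenerated in isolation,
and regenerating with the same seed is bit-exact — the pipeline's CSV
outputs are byte-identical across reruns.

## Statistical layer

### Outlier screen

Per tract (each structure × area vector of per-hemisphere values across
subjects), values outside `[Q1 − 3·IQR, Q3 + 3·IQR]` are removed listwise
from that tract only. Quartiles use linear interpolation (type 7), the
dominant convention. A zero IQR (near-constant vector) flags nothing —
otherwise the rule would discard entire tracts whose values happen to tie.
Every removal is logged in `outliers.csv` and the run manifest.

### JZS paired-t Bayes factor

Per-area comparisons use the default-prior (Jeffreys–Zellner–Siow) Bayes
factor for paired samples: a Cauchy(0, r) prior on the standardised
effect, r = √2/2 by default, against the point null. Using the
inverse-χ² mixture representation of the Cauchy, BF₁₀ reduces to a
one-dimensional integral over the mixing parameter g,

$$
\mathrm{BF}_{10}
 = \frac{\int_0^\infty (1+Ngr^2)^{-1/2}
   \bigl(1+\tfrac{t^2}{(1+Ngr^2)\,\nu}\bigr)^{-(\nu+1)/2}
   \pi(g)\,dg}
   {\bigl(1+\tfrac{t^2}{\nu}\bigr)^{-(\nu+1)/2}},
\qquad \pi(g) = \mathrm{InvGamma}(\tfrac12, \tfrac12),
$$

with N pairs, ν = N − 1 degrees of freedom and t the paired t statistic.
The integral is evaluated by adaptive quadrature on the log-g scale
(relative tolerance 1e-10), centred on the integrand's mode to avoid
underflow; the test suite checks it against an independent dense
Riemann-grid oracle to relative error below 1e-4 across a lattice of
(t, n, r) values, and checks strict monotonicity in |t| and the collapse
BF₁₀ → 1 as r → 0.

Paired tests enter hemisphere-averaged per-subject values — the dataflow
of the published summary tables — while the mixed model below keeps
hemispheres as data rows with hemisphere as a random factor. Both
dataflows exist and are labelled; the package does not assert which one
the original analysis used for the t-tests.

### Mixed-model Bayes factor

The fingerprint table is compared between a full model (structure, area
and structure × area fixed effects) and a reduced model without the
interaction, both with participant and hemisphere as random effect
classes. Each effect class is parameterised by an orthonormal sum-to-zero
contrast basis and carries one g parameter with an inverse-gamma(1/2,
r²/2) prior — the scaled inverse-χ² g-prior — with scales r = 1/2 for
fixed and r = 1 for random classes. These numeric scales, like the t-test
scale √2/2, are the long-standing documented defaults of the BayesFactor
R toolbox; the package pins them explicitly (overridable in
`bayes_prior_spec()`) so results stay reproducible independent of any
toolbox version.

Conditional on g, the intercept, coefficients and error variance are
integrated analytically (conjugate step with a Jeffreys prior on location
and scale), leaving a low-dimensional integral over the g's. That
integral is estimated by importance sampling: a Laplace fit (numerical
Hessian in log-g space) centres a multivariate-t proposal (df 5, scale
inflated 1.3×), and the conditional marginal — evaluated through the
Woodbury identity on the q-column design, never the N×N covariance — is
weighted against it. The estimate carries a batch-means relative standard
error (20 batches), which empirically tracks the theoretical
`mc_iterations^(-1/2)` scaling; the default budget of 10⁴ draws keeps the
relative error of the BFs reported here below ~3%, and the test suite
validates the whole construction against an independent dense-grid,
dense-matrix oracle on a small two-g design. Identical full and reduced
specifications short-circuit to BF = 1 exactly.

An incomplete design (missing cells after outlier removal) is an error
unless the caller passes `allow_incomplete = TRUE`, which the pipeline
does only after the logged outlier screen.

### Evidence categories

BF₁₀ is mapped onto the ten-step Jeffreys-type evidence scale (anecdotal
/ substantial / strong / very strong / decisive, for H₁ above 1 and
mirrored for H₀ below 1; exactly 1 is "No evidence"). The printed scale
uses open ranges, so a total rule is needed at the boundaries: each
boundary is assigned to the stronger-evidence side (30 → "Very strong",
100 → "Decisive", 1/3 → "Substantial evidence for H₀"). Display strings
censor at 1000 — any BF₁₀ ≥ 1000 renders as "≥1000" — but computation and
storage always keep the uncensored value, and because interaction Bayes
factors on strongly structured cohorts overflow double precision, the log
Bayes factor is the primary stored quantity.

## Pipeline and outputs

`run_pipeline()` chains simulate (or load-from-disk) → tractometry →
functional fingerprint → outlier screen → Bayesian comparisons, writing
`tract_metrics.csv`, `rsfmri_fingerprint.csv`, `summary.csv`,
`bf_vs_structure.csv`, `bf_anova.csv`, four 17×17 pairwise matrices,
`outliers.csv` and a `manifest.json` recording seed, prior settings,
removed outliers and stage timings. Numeric CSV columns are written with
fixed 6-decimal formatting and fixed column order, so regression tests
can diff outputs byte-for-byte. The numbered scripts under `analysis/`
run the same stages as a narrated sequence.

The disk interfaces are NIfTI-1 volumes plus a sidecar CSV
(`filename,label,hemisphere,role,...`) for masks and count maps — ROI
identity is never parsed from filenames — and per-subject CSV matrices
for ROI series. `write_phantom_cohort()` / `read_phantom_cohort()`
round-trip a cohort through this layout; full-grid 4-D BOLD volumes are
deliberately not written (ROI-level series are the functional interface;
`extract_mean_timeseries()` handles 4-D arrays for callers who have
them).

## Problem sizes in the test suite

The tests run the default 16-subject cohort for end-to-end checks and
smaller cohorts (2–8 subjects, T = 30–80) for unit-level checks; metric
oracles use up to 1000-voxel masks; the null-calibration study uses 1000
simulated 16-subject tracts; mixed-model replicate studies use 50
replicates at 2000 Monte-Carlo draws. These sizes were chosen so the full
suite exercises every claim at comfortable statistical margins while
staying fast enough to run routinely.

## Known limitations

* The phantom's independence assumptions (no spatial autocorrelation, no
  interhemispheric coupling, shared masks) mean the suite cannot detect
  errors that only manifest on spatially structured or misregistered
  data.
* The mixed-model marginal is estimated, not exact; with pathological
  designs (extreme imbalance after outlier removal) the importance
  proposal could fit poorly — the reported `mc_error` is the guard.
* Distance-corrected inputs are accepted but the package cannot undo the
  correction; thresholding is applied to stored values as-is, mirroring
  the upstream tool's behaviour.
* The evidence-category boundary rule and the type-7 quantile choice are
  conventions; both are documented and overridable where they matter.
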