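---
title: "Methods: multi-source genomic and multispectral yield prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-source genomic and multispectral yield prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its methods: the models and
their assumptions, the tunable parameters and defaults, what the synthetic
generator does and does not emulate, the numerical choices, and the design
decisions taken where several defensible options existed. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. Data model and units of analysis

The unit at which prediction happens is the **line-by-environment cell**:
a candidate line grown at a location in a season. Field plots are nested
inside cells (one or two replicates); pixels are nested inside plots.
The pipeline moves from plots to cells in two parallel streams — yields
via per-environment BLUEs, reflectance via calibration, indices and
plot/cell averaging — and joins them with a line-by-line genomic
relationship matrix into per-cell predictor sets.

## 2. Marker quality control and the GRM

SNPs coded 0/1/2 pass four simultaneous rules: missing rate < 50% (over
all lines), minor allele frequency > 0.05, heterozygosity < 5%, and
homozygosity > 80%. The homozygosity denominator is not defined by
convention everywhere; here the rule is the *fraction of non-missing calls
that are homozygous*, which is the natural reading for inbred wheat lines.
Imputation defaults to the SNP-mean fill; an iterative low-rank SVD
surrogate (`em_lowrank`) is available for users who want an
expectation-maximization-style reconstruction, and the choice is recorded
in the pipeline manifest. The genomic relationship matrix defaults to the
uncentered cross-product `G = M M'/r`, staying faithful to the printed
form used with 0/1/2 codes; column-centering by twice the allele frequency
is available as the conventional alternative (`center = TRUE`), and a test
checks its diagonal against the `2 sum p(1-p) / r` expectation.

Matrix square roots (`L_g = G^0.5`, `L_gE = K_gE^0.5`) use the symmetric
eigendecomposition with eigenvalues below zero clipped at zero; the
reconstruction tolerance asserted in tests is `1e-8` (Frobenius).

## 3. Radiometric calibration and the H / I feature vectors

Two sensor protocols are supported. In `panel` mode every band gets an
ordinary least-squares line `SR = DN x slope + intercept` from five
reference panels spanning 2–85% reflectance; the "±intercept" of the field
convention is treated as a signed intercept decided by the regression. In
`single2019` mode (one 85% panel) only the visible and red-edge bands are
calibrated directly and NIR is derived from quantum-efficiency
coefficients, `NIR = 2.921 Blue − 0.754 Red`, normalized by 3.07 on the
index-computation path. Calibrated reflectance is floored at zero; slopes
must be meaningfully positive or the panel set is rejected as degenerate.

The 11-variable `H` vector holds the 8 band means plus NDRE1, NDVI and
canopy cover; `I` is the (CanopyCover, NDRE1, NDVI) sub-vector, asserted
componentwise equal to the corresponding `H` entries. Index formulas use
the wavelength-to-band mapping R800→NIR, R680→Red, R700→RE1 (configurable,
since sensors name bands while index definitions name wavelengths).
NDVI and NDRE1 are computed from plot-mean reflectance by default;
per-pixel computation followed by averaging is available
(`per_pixel_indices`), since either reading is defensible and the two
differ only at second order. Canopy cover is implemented exactly as the
printed mean of pixel-level GNDVI; because "percent canopy coverage" more
commonly denotes a thresholded pixel fraction, that variant is available
(`canopy = "threshold"`, default cutoff 0.5) but is not the default.

## 4. BLUEs by EM-REML on Henderson's equations

Within each environment the design model is fitted with genotype and
check effects fixed and design factors random: trial, replicate within
trial and incomplete block for alpha-lattice trials; block for augmented
trials. Estimation is EM-REML on the mixed-model equations: it is
guaranteed monotone in the restricted likelihood (a property the tests
assert step by step), simple to audit, and entirely adequate at the
problem sizes involved; the faster average-information updates buy nothing
here. Convergence is declared at relative change `1e-6`, capped at 500
iterations; variance components are floored at `1e-10 x var(y)` so
boundary estimates cannot go negative. Genotype effects are reported as
intercept + effect under a sum-to-zero constraint over non-check entries,
with checks carrying their own fixed columns; a line appearing both as
check and as test entry is rejected as confounded. Random factors with a
single level are dropped and reported as `NA` rather than silently fitted.

Across environments, `value = mu + env (fixed) + g + gE + e` is fitted on
replicate-level values. With exactly one value per cell the gE and
residual components are confounded (`Z_gE` is the identity), so the
operation accepts repeated (line, env) rows and the recovery simulations
use two replicates per cell; single-environment tables report gE as not
estimable. Entry-mean heritability uses
`H2 = var_g / (var_g + var_ge/n_e + var_res/(n_e n_r))` with `n_e` and
`n_r` computed from the incidence; this is a documented convention — the
formula behind published per-season H2 tables is often unstated, and no
claim is made that any particular published value is reproduced by it.

## 5. Predictor sets

The nine predictor sets are reconstructed from the printed
concatenated-matrix list and mirrored as additive kernels: `K_g = Z_g G
Z_g'`, `K_gE = K_g ∘ (X_E X_E')` (Hadamard; the standard
relationship-by-incidence construction for the G-by-E term),
`K_H = H H'/11`, `K_I = I I'/3`, and Hadamard products for the
genomic-by-spectral interactions — whose PLS-view counterpart is the
row-wise Khatri–Rao product, the standard matched pair. `H` and `I`
columns are standardized (mean 0, sd 1) before concatenation and kernel
construction because both PLS and ridge-type shrinkage are scale-sensitive
and the bands and indices live on different scales; the 0/1 incidence
blocks are left untouched. Standardization records are stored and
round-trip the raw blocks exactly. All kernels are PSD-repaired by
eigenvalue clipping with tolerance `1e-8`, and the Schur product theorem
is verified numerically for the Hadamard kernels.

For leave-one-environment-out runs, the held-out environment's one-hot
column carries no training information, so the five LOEO predictor ids
(`g`, `H`, `I`, `gH`, `gI` — the last two adding the gE kernel) omit the
environment block and keep only the intercept. These five sets are a
reconstruction: figure-defined predictor lists are inherently ambiguous,
so the set is exposed as configuration rather than hard-coded.

## 6. Bayesian multi-kernel GBLUP

The sampler cycles: fixed effects from their conditional normal; each
kernel term in the eigenbasis of its kernel (precomputed once, directions
with relative eigenvalue below `1e-8` dropped), which makes the per-term
update O(n) conditional draws plus two matrix-vector products; variances
from scaled-inverse-chi-square conditionals; and masked responses imputed
from the current model state. Prediction of test rows is the standard
masked-response joint fit — test rows are present in the kernels, their
stored `y` values never read, a contract the tests verify by altering the
masked slots and asserting bit-identical chains.

Priors are scaled-inverse-chi-square with df = 5 and scales chosen so each
term's prior mode is an equal share of half the phenotypic variance (the
residual mode receives the other half), the common default family of
Bayesian GBLUP software. Chain defaults are 12,000 iterations, 2,000
burn-in, thinning 5; the test suite and the cross-validation drivers use
shorter chains (stated per call) after checking against closed-form BLUP
that 12,000 iterations are not needed for posterior means at these sizes.
The `fix_variances` switch freezes variances at their initial values (the
infinite-df limit), which is what makes the sampler directly comparable to
`K (K + lambda I)^{-1} y` in tests. The chain seed runs in a dedicated
RNG stream and the caller's generator state is restored on exit.

## 7. Kernel-algorithm PLS

The nine-step univariate kernel algorithm is implemented literally:
centering (scaling optional, off by default since the feature module
already standardizes the H/I blocks), `S = E'f`, weight from the dominant
eigenvector of `S S'` — which for a univariate response collapses to
`w = S/||S||`, the implemented default, with the general SVD retained as a
cross-check path (`w_method = "svd"`) — normalized scores, loadings,
deflation of both `E` and `f`, then `R = W (P'W)^{-1}`, `b = (T'T)^{-1}
T'y` and `B = R b`. The regression coefficients `b` use the *undeflated*
centered response: the printed formula admits either reading, and with
orthonormal scores the deflated and undeflated projections coincide
mathematically; the undeflated form is the numerically cleaner one.
Extraction stops early when the deflated cross-product is numerically
zero, recording the achieved number of components. Both printed prediction
routes (`X_new B` and `T_new b`) are implemented and asserted to agree to
`1e-10`.

Component tuning refits the model per candidate `a` over `k_inner = 10`
random folds and minimizes the mean validation NRMSE, ties broken toward
the smallest `a`. NRMSE is RMSE divided by the standard deviation of the
fold's observed values — the definition is not universal, so range and
mean denominators are available, and plain MSE can replace NRMSE (within a
fold the two rank components identically; only the averaging across folds
differs). Refitting per `a` was chosen over truncating a single
`a_max` fit for robustness; at these problem sizes the cost is
negligible.

## 8. Cross-validation protocols

7FCV folds are drawn uniformly at the observation (line-by-environment)
level, so a line can be trained in one environment and tested in another —
that is what "partially tested lines in tested environments" means; fold
sizes differ by at most one. Nested tuning only ever touches
outer-training rows (asserted by corrupting held-out responses and
checking predictions are unchanged). Per-environment accuracy is the mean
over folds of within-fold-within-environment Pearson correlations, with
fold-by-environment cells holding fewer than 3 test observations skipped
and counted; its standard error is taken over folds. The Global accuracy
correlates per-line averages of observed and held-out-predicted values
over whatever environments each line has, with a fold-wise SE.

LOEO holds each environment out once, so each per-environment correlation
comes from a single fold and the SE is only available across environments.
Whether the across-environment "Global" should pool all held-out
predictions or average the per-environment correlations is ambiguous in
common usage; both are computed (`global`, `global_mean_env`) with pooled
as the default. The pooled value can be far below the per-environment mean
— or even negative for genomics-only predictors — because the model has no
information about the held-out environment's mean level; this is a feature
of the scenario, not a bug. Fold assignment, tuning and chains each use
dedicated RNG streams derived from the scheme seed, so split and model
randomness are decoupled.

## 9. The synthetic-trial generator

`generate_dataset()` emulates the data-collection process of a
multi-location winter-wheat program: several hundred inbred lines
(homozygous 0/2 markers with ~1% residual heterozygous calls, independent
per-SNP allele frequencies in [0.05, 0.5] — no linkage disequilibrium,
which GRM-based methods do not require), a configurable fraction of
deliberately QC-failing SNPs (monomorphic, over-missing, over-het) to
exercise the filters, per-line environment subsets of
truncated-Poisson size (matching the ~1.3–1.7 environments per line of
real unbalanced programs), partial replication (`n_r < 2`), and plot yield
`mu + env + g + gE + design effects + residual` with genetic values
`g = M beta` rescaled to unit variance. `h2_target` fixes the residual
variance through `var_e = 1/h2 − 1 − var_ge`, so the target is the
within-environment plot-level ratio (environment main effects are fixed by
convention and excluded from the denominator). Default conditions —
`n_envs = 4`, `var_env = 2`, `var_ge = 0.3`, `h2_target = 0.66`,
`mean_envs_per_line = 1.5`, `replicate_fraction = 0.5` — were chosen once
to sit inside the realistic ranges of published per-season
variance-component tables (G:GE:residual on the order of 1:0.3:0.2 in
good years, heritabilities 0.7–0.87 with an occasional collapse) and are
not revisited.

Bands are generated as `base_b + load_b x latent` where `latent` mixes the
plot's standardized total value `(g + env + gE)` with independent noise at
weight `spectral_signal`; visible bands load negatively (denser canopies
absorb red), NIR-side bands positively. Pixels add small within-plot noise
and are encoded as digital numbers by inverting a known affine map per
band, with the matching 5-panel calibration table — so the spectral module
has to do real calibration work to recover them. What the generator does
**not** emulate: linkage disequilibrium and population structure, spatial
field trend, weather covariates, atmospheric or view-angle effects on
reflectance, and any nonlinearity between canopy state and yield. Passing
tests therefore demonstrate the statistical machinery under the stated
generative assumptions, not robustness to those real-data complications.

## 10. Problem sizes and known limitations

The test suite and acceptance script run at desk scale, chosen as the
smallest sizes at which the checked properties are statistically stable:
oracle comparisons at n = 10–100, variance-component recovery at 100–140
lines over 30 simulated trials, heritability recovery at 300–400 lines,
and the cross-validation comparisons at 150 lines x 3 environments over 5
seeds with the PLS model (deterministic given the seed, and fast enough to
repeat; the Gibbs sampler's correctness is established separately against
closed-form BLUP). The analysis scripts run the same workflow at larger,
season-like sizes.

Known limitations: EM-REML converges slowly when a variance component sits
near zero (the iteration cap then binds, with the estimate pinned at the
floor); the Gibbs sampler assumes Gaussian responses and a common residual
variance across environments; the uncentered default GRM conflates
relationship and allele-content scale (the centered option exists for
users who care); and LOEO with genomics-free predictors relies entirely on
the spectral features of the held-out environment being measured — the
package checks coverage and errors otherwise rather than silently
extrapolating.
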