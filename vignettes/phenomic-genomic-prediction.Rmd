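---
title: "Phenomic and genomic yield prediction in multi-environment wheat trials"
author: "phenogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenomic and genomic yield prediction in multi-environment wheat trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Genomic selection predicts line performance from genome-wide markers, but a
linear marker model cannot see genotype-by-environment interaction (GxE):
a model trained at one location can rank the same lines poorly at another.
High-throughput field phenotyping offers an alternative predictor set —
dozens to hundreds of plot-level "phenomic markers" (multispectral and
hyperspectral vegetation indices, visual scores, soil conductivity) that are
cheap to collect and, because they are expressions of the genotype *in that
environment*, carry environment-specific yield signal that DNA markers
cannot.

`phenogs` implements the complete analysis cycle for studying this
trade-off at the scale of a commercial wheat breeding trial: a synthetic
data generator with the relevant genetic and environmental structure,
marker quality control, trait-redundancy analysis and dimension reduction,
mixed-model BLUEs and (multivariate) GBLUP, penalized regression, and a
masking/resampling engine that reports prediction accuracy as the squared
Pearson correlation between predicted and observed yield.

# The simulated study

Because the package must be testable without any external dataset, the
generator is a first-class module. Its defaults emulate a two-location,
two-year elite wheat programme:

* **Germplasm.** 27 homozygous founder parents; 44 cross populations (39
  biparental, 5 three-way) of 68 F2:4 lines each (2,992 lines) in the
  `paper_shape` profile. Meiosis uses the Haldane map function with no
  crossover interference on a wheat-like map (21 chromosomes x 150 cM by
  default); the map serves only meiosis — no analysis step uses positions.
  Three-way crosses unite a (P1 x P2) F1 gamete with a P3 gamete before two
  generations of selfing, the conventional reading of "three-parental".
  Each line's dosage is the arithmetic mean over six sibling F4 plants
  (pooled-DNA codominant scoring), giving fractional dosages in [0, 2];
  a 2% per-call error rate and 2% sporadic missingness emulate relaxed
  array-calling thresholds on bulked early-generation material.
* **Trial design.** A modified alpha-lattice: per environment, two blocks
  split into sub-blocks of ten entries; twice-replicated entries and checks
  appear in both blocks, once-replicated entries are appended to the
  sub-blocks of one block. The replication layout assigns each line four
  plots across the four environments while keeping every environment at one
  plot per line in total — the accounting a large unbalanced multi-location
  trial actually uses.
* **Yield and GxE.** A marker-determined common genetic value u (unit
  variance, back-fitted onto 100 QTL) combines with environment-specific
  deviations: for the default compound-symmetric genetic correlation rho =
  0.3, the per-environment genetic value is sqrt(rho) u + sqrt(1 - rho) d_e.
  Every environment then carries the same marker-predictable share rho of
  its genetic variance, which is what makes cross-location genomic
  prediction weak by construction. A full correlation matrix is accepted
  and honoured through its Cholesky factor (the first factor is the
  marker-backed component; with a non-exchangeable matrix the
  marker-determined share then differs between environments — documented
  asymmetry). Plot yield (t/ha, 85% dry matter) is environment mean +
  genetic value + block + sub-block + residual; per-environment plot-level
  heritability defaults to h² = 0.4 with block/sub-block/residual variances
  0.05/0.05/0.4 (t/ha)². Environment means (11.0, 11.8, 10.5, 8.8 t/ha)
  span a realistic UK winter-wheat range with a drought-limited low
  environment. Grain moisture is drawn per plot (mean 18%, SD 1.5) and raw
  combine yield back-computed, so the 85%-dry-matter adjustment is a real
  pipeline step.
* **Traits.** Each plot has a latent crop-status signal: its genetic value
  plus half of its yield residual, standardized within environment (traits
  see micro-environment, not only genetics). Traits come in redundancy
  groups sharing a group latent whose correlation with the signal is set
  per category and flight: multispectral flights F1–F5 at (0.30, 0.55,
  0.75, 0.70, 0.40) — rising to flowering and falling with senescence —
  one post-flowering hyperspectral acquisition at 0.75, visual scores at
  0.12, soil conductivity at 0. Within a group, traits are the group latent
  (random sign) plus measurement noise with SD 0.2, so within-group
  correlations sit near 0.96 and pruning at |r| > 0.9 collapses the panel
  to the group count — the mechanism behind "~100 traits, ~40 distinct".
  Two features make locations genuinely different: group loadings are
  jittered per environment (multiplicative SD 0.2) and every
  (environment, trait) pair receives an additive offset (SD 0.25),
  emulating sensor calibration and crop-status differences. The jitter is
  what gives whole-location transfer a real cost and makes supplementing
  the training set with a small fraction of the test location genuinely
  informative; the additive offsets cancel in per-environment correlations
  but matter whenever environments are pooled.

What the generator does *not* emulate: spatial autocorrelation beyond
block/sub-block effects, raw spectral wavebands (traits enter as computed
indices), weather-driven growth dynamics, pedigree structure. Passing tests
therefore show that the *methods* behave as specified under the stated
covariance structure, not that real sensor data obey it.

Three profiles fix the problem sizes: `tiny` (4 crosses x 10 lines, 50
markers, 2 environments) for unit tests, `demo` (8 crosses x 40 lines, 300
markers, 4 environments) for full studies in minutes, and `paper_shape`
(2,992 lines). The test suite and the acceptance script run on `tiny` and
`demo`; these sizes are the package's choice of desk-scale study
conditions, with Monte-Carlo tolerances set accordingly.

```{r}
library(phenogs)
trial <- simulateTrial("demo", seed = 11)
trial
```

# Marker quality control

The QC chain is imputation, then informativeness filtering, then redundancy
pruning — in that order:

1. `imputeMean()` replaces sporadic missing dosages by the marker mean (a
   deliberate stand-in for haplotype imputation, adequate for low
   missingness); fully missing markers are dropped with a warning.
2. `filterPIC()` keeps markers with polymorphism information content
   strictly above 0.1, with PIC = 1 - (p² + q²) - 2p²q² and the allele
   frequency estimated as mean dosage / 2 (valid for pooled fractional
   scores).
3. `pruneCorrelated()` makes one greedy pass, dropping a marker whose
   absolute correlation with any already-retained marker exceeds 0.9 and
   recording the anchor. The pass order defaults to map/input order;
   `order = "pic_desc"` anchors the most informative markers first —
   retained sets differ, which is why both are explicit options. Absolute
   correlation is the default (sign-symmetric redundancy); signed pruning
   is available. Zero-variance markers correlate with nothing, are retained
   and flagged.

```{r}
qc <- markerQC(genotypes(trial))
qc$report
```

# Trait redundancy and dimension reduction

`uniqueTraitCount()` applies the same greedy rule to the trait panel
(column order = panel order) and, swept over thresholds, traces the
redundancy curve; counts are computed per environment, since pooling
environments would mix per-environment sensor offsets into the
correlations. `pcaCumvar()` and `selectPCO()` give the standardized-PCA
view (cumulative explained variance; first-k scores with their yield
correlations). `plsComponents()` is NIPALS PLS1 with yield as the
response; components are reported ordered by their contribution to the
fitted yield variance — the package's reading of "largest PLS regression
coefficients", exposed as an explicit `k` because the original selection
rule is informal. A trait category is flagged as dominating a component
when it carries more than 25% of the squared loading mass (a reporting
convention only). The PLS scores are checked in the tests against a
deflation-free Krylov/Gram-Schmidt second implementation and reproduce the
OLS fit at full rank.

# Mixed models

`remlBlocks()` fits yield = environment + line (fixed) + block + sub-block
(random) + residual by EM-REML. Fixed effects are absorbed once, so each
iteration costs small dense solves in the random-effect dimension;
convergence is declared when the REML log-likelihood changes by less than
1e-8 (500-iteration cap, warning and last iterate otherwise). Because
plain EM is sublinear near a variance boundary, an Aitken/Steffensen
extrapolation on the log-variance scale is attempted every few sweeps and
accepted only when the log-likelihood does not decrease — the monotone-EM
property is preserved, and balanced designs reproduce the nested-ANOVA
closed forms. Degenerate designs fail loudly: a single block, or one line
per block everywhere, is an identifiability error. `computeBlues()` then
produces per-line, per-environment generalized-least-squares estimates;
lines without plots in an environment get no row.

`grmVanRaden()` builds G = ZZ'/(2 sum p(1-p)) from dosages centered at
twice the allele frequency; monomorphic markers are excluded. The GRM is
marker-derived only — no pedigree information anywhere. `gblupFit()` solves
y = mu + u + e with u ~ N(0, sigmaG G) and returns mu + u for every line,
including unobserved ones; variance components come from EM-REML on
eigen-rotated error contrasts (an explicit orthonormal basis of the mean's
complement, so rank-deficient kernels cannot leak the fixed effect into
the contrasts), making each EM sweep O(n). `mvGblupFit()` extends this to
a response matrix with genetic covariance Gt (x) G and residual covariance
Rt (x) I: covariances are estimated by EM on the lines with all responses
observed and then held fixed for conditional prediction — joint estimation
under missingness is fragile, and the two-stage route is the package's
documented choice. Masked-yield predictions condition on both kinship and
the line's own co-responses (genetic covariance to all observed cells plus
cross-trait residual covariance within the line); with diagonal
covariance matrices the predictions provably collapse to the univariate
fit, which the tests assert to 1e-6.

# Penalized regression

The solver minimizes

$$\frac{1}{2n}\lVert y - Xb\rVert_2^2 + \lambda_1 \lVert b\rVert_1 +
\frac{\lambda_2}{2}\lVert b\rVert_2^2$$

by cyclic coordinate descent with soft-thresholding (compiled inner loop,
active-set sweeps between full sweeps). The 1/n scaling keeps lambda
values comparable across training-set sizes. The quadratic penalty is part
of the method definition — 0 for lasso, 0.1 for elastic net, 1 for ridge —
while the L1 strength is chosen per fit by internal 5-fold
cross-validation over a 50-point logarithmic path from lambda_max (the
smallest value zeroing all coefficients) down to 0.01 lambda_max,
minimizing validation MSE with warm starts; a fixed lambda1 can be passed
for exact reproducibility. Path fits use a looser tolerance (1e-4) than
the final fit (1e-7), since they only rank candidate penalties. Ridge
bypasses the path entirely via the closed form b = (X'X/n + lambda2
I)^-1 X'y/n, which doubles as a solver cross-check. Predictors are
centered and scaled on training rows only; the response can additionally
be centered/scaled per environment, with the stored inverse transform
returning predictions to t/ha per location (environments unseen in
training fall back to the global transform — harmless for
per-environment squared correlations, which are scale-invariant).
Combined models concatenate the per-column-standardized trait and marker
blocks with no block weighting.

# The resampling engine

A `MaskingScheme` declares one of three families: per-environment training
fractions from the grid (1, 0.75, 0.5, 0.25, 0.15, 0.10, 0.05, 0), explicit
whole-location train/test environment sets (three-train/one-test,
two-train across years, two-train within a year), or whole-location
training supplemented with a stated random fraction of the test location.
Units are raw plots or line BLUEs, evaluated as parallel tracks. Fraction
sampling is per-environment and independent. Every replicate derives a
deterministic child seed from the master seed, the scheme name and the
replicate index, so any record is reproducible in isolation; 100
replicates is the default.

Penalized methods fit on the training units and score the squared
correlation per test environment. Genomic BLUP methods run on line BLUEs:
under fraction schemes they mask whole lines and use the line-mean BLUE
over the scheme's environments as response (records carry environment
"pooled"); under whole-location schemes the response is the line mean over
the training environments and each test environment is scored against its
own BLUEs. Check varieties are generated and flagged but excluded from all
prediction analyses — how checks entered the original analyses is unknown,
and exclusion is the conservative default. `aggregateRecords()` reports
means and SDs per (scheme, method, predictor set, environment) plus pooled
within-year averages with locations equally weighted (test-set-size
weighting would be the alternative; equal weighting matches the "average
over both locations" convention and is documented here).

```{r}
study <- prepareStudy(trial, unit = "line_blues")
scheme <- maskingScheme("whole_location", trainEnvs = "Cam16",
                        testEnvs = "Dux16", unit = "line_blues",
                        nReps = 10)
phen <- runScheme(study, "enet", "traits", scheme, seed = 1)
geno <- runScheme(study, "enet", "markers", scheme, seed = 1)
aggregateRecords(rbind(phen, geno), environments(trial))
```

# Numerical choices, degenerate inputs, limitations

* Tolerances: coordinate descent 1e-7 on the largest coefficient change
  (1e-4 on CV path fits); EM-REML 1e-8 on the log-likelihood change, 500
  iterations; multivariate EM 1e-6 relative, 200 iterations. Non-converged
  fits warn and return the last iterate with a flag.
* Variance estimates are floored at a tiny positive multiple of the
  response variance; an estimate pinned at the floor is a boundary (zero)
  estimate.
* Singular mixed-model or ridge systems receive a 1e-8 diagonal jitter
  with a warning.
* Ties in Spearman correlations use average ranks. Accuracy is defined as
  0 (with a warning) when either vector has zero variance.
* Zero-variance predictor columns are dropped with a warning before
  standardization; trait columns unavailable (NA) on the rows of a scheme
  are dropped silently for that scheme, which is how year-restricted
  traits are handled.
* The greedy pruning/counting rules are order-dependent by construction;
  the order is part of the reported procedure, not a nuisance.
* Known limitations: mean imputation (not haplotype-aware), no spatial
  row-column modelling, no Bayesian whole-genome regression, no
  functional analysis of the flight time-series, and the generator's
  trait model is linear-Gaussian — real spectral indices are bounded and
  nonlinearly related to canopy state. At demo scale, single-environment
  GBLUP variance estimation on BLUEs is boundary-prone (few families,
  marker-determined share ~ rho h²); the acceptance checks therefore
  verify heritability recovery at the plot level, where the generator
  defines it.
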