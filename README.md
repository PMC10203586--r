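# phenogs

Phenomic and genomic prediction of grain yield in multi-environment wheat
trials.

## The problem

Genomic selection predicts line performance from genome-wide SNP markers,
but a linear marker model carries no information about
genotype-by-environment interaction (GxE): trained at one location, it can
rank the same lines poorly at another. High-throughput field phenotyping
produces an alternative predictor set — per-plot "phenomic markers" such as
multispectral and hyperspectral vegetation indices, visual crop scores and
soil conductivity — that are expressions of the genotype *in that
environment* and therefore carry location-specific yield signal.

`phenogs` is a toolkit for studying that trade-off at breeding-programme
scale, for quantitative geneticists and breeding analysts. It provides:

* a **synthetic trial generator** (biparental and three-way crosses from an
  elite parent pool, bulk-sampled fractional SNP dosages with call error,
  modified alpha-lattice designs, compound-symmetric GxE with configurable
  between-environment genetic correlation, and a redundant plot-level trait
  panel whose spectral categories carry the yield signal);
* **marker QC**: mean imputation, PIC filtering (PIC = 1 − Σp² − 2p²q²,
  markers kept when PIC > 0.1), greedy correlation pruning at |r| > 0.9;
* **trait reduction**: greedy distinct-trait counting, standardized PCA,
  NIPALS PLS1 with yield as response;
* **mixed models**: EM-REML for block/sub-block variance components,
  per-environment line BLUEs by GLS, the VanRaden GRM
  G = ZZ′/(2Σp(1−p)), and univariate / multivariate GBLUP
  (u ~ N(0, σ²_g G); multi-trait covariance G_t ⊗ G + R_t ⊗ I) with
  missing-response prediction;
* **penalized regression** by cyclic coordinate descent for
  (1/2n)‖y − Xb‖² + λ₁‖b‖₁ + (λ₂/2)‖b‖₂², with λ₂ fixed per method
  (lasso 0, elastic net 0.1, ridge 1) and λ₁ chosen by internal
  cross-validation;
* a **masking/resampling engine**: per-environment training-fraction
  grids, whole-location leave-out, and training-set supplementation, with
  accuracy reported as the squared Pearson correlation between predicted
  and observed yield.

## Worked example

Simulate a demo-scale study (8 crosses × 40 lines, 300 markers, two
locations × two years), run marker QC, and compare phenomic, genomic and
combined whole-location prediction:

```r
library(phenogs)
trial <- simulateTrial("demo", seed = 11)
trial
#> WheatTrial: 1296 plots, 322 lines, 4 environments
#>   traits: 60 ( hyperspectral:20, multispectral:30, soil:2, visual:8 )
#>   genotypes: 300 markers
#>   simulation truth attached

markerQC(genotypes(trial))$report
#> Marker QC report
#>   input            300
#>   imputed          300
#>   pic_filtered     273
#>   pruned           272
#>   pruned: 1 markers (anchors recorded)

study  <- prepareStudy(trial, unit = "line_blues")
scheme <- maskingScheme("whole_location", trainEnvs = "Cam16",
                        testEnvs = "Dux16", unit = "line_blues", nReps = 5)
phen <- runScheme(study, "enet", "traits",   scheme, seed = 1)
geno <- runScheme(study, "enet", "markers",  scheme, seed = 1)
comb <- runScheme(study, "enet", "combined", scheme, seed = 1)
aggregateRecords(rbind(phen, geno, comb))
#>              scheme method predictorSet   env      mean           sd n
#> 1 loc[Cam16->Dux16]   enet     combined Dux16 0.6712503 0.0024985860 5
#> 2 loc[Cam16->Dux16]   enet      markers Dux16 0.0782720 0.0016295509 5
#> 3 loc[Cam16->Dux16]   enet       traits Dux16 0.6700552 0.0003949368 5
```

The numbers are mean accuracies (squared correlations) for predicting an
entire unseen location from the other location of the same year: the trait
panel transfers well (R² ≈ 0.67), markers alone barely transfer under
strong GxE (R² ≈ 0.08), and combining both matches the phenomic model —
the qualitative behaviour such a study design is built to expose.

Whole studies can also be driven by one YAML/list configuration through
`runStudy(config, outDir)`, which writes the dataset, QC report, BLUEs,
per-replicate accuracy records, summaries and a manifest, and is
bit-identical on rerun.

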