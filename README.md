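# phenolflux

Extraction kinetics, intra-particle diffusion modelling and yield
prediction for ultrasound-assisted enzymatic recovery of plant
polyphenols.

`phenolflux` is aimed at food-process and natural-product researchers who
measure solid–liquid extraction curves (total phenolics in mg
gallic-acid-equivalents per g of solid, sampled over minutes) and want to

1. fit a mechanistic mass-transfer model to each processing condition and
   compare effective diffusion coefficients,
2. train a data-driven predictor of yield over temperature, time and
   enzyme dose, and
3. profile the extracted compounds (category proportions, PCA of a
   mean ± SD quantification table).

## The models

**Diffusion core.** Phenolics diffuse out of spherical particles
(radius *r*, default 24.5 µm) into a finite, well-mixed bath following
Fick's second law in spherical coordinates,

```
∂Cs/∂t = De (1/x²) ∂/∂x (x² ∂Cs/∂x),   0 ≤ x ≤ r,
```

with a symmetric centre, an interface in local equilibrium with the bath
(`Cs(r,t) = K·CL(t)`), and a liquid-phase balance
`−De·S·∂Cs/∂x|_r = VL·dCL/dt`. Internally everything is dimensionless
(τ = De·t/r², ξ = x/r, bath capacity α = VL/(K·Vs)), solved by a
conservative finite-volume discretisation (mass conserved to ~1e−15) and
cross-checked against the classical eigenfunction series for a sphere in a
stirred bath of limited volume (`crank_series_fraction()`), with agreement
to ~3e−5 at the default 101 cells. The effective diffusion coefficient is
estimated per condition by minimising the RMSE between simulated and
observed yield curves over log₁₀(De/r²); R² and the absolute average
deviation (AAD%) are reported alongside.

**Yield predictor.** A five-layer Takagi–Sugeno ANFIS
(fuzzification → product rules → normalization → first-order consequents →
sum), built by grid partitioning with two difference-of-sigmoids
(`dsigmf`) membership functions per input and trained by hybrid learning:
exact least squares for the consequents each epoch, normalized-gradient
descent for the membership parameters.

**Composition analytics.** A compound × condition mean ± SD table is
summarised into category counts and mass proportions, expanded into
simulated triplicates (truncated normal draws), and ordinated by
autoscaled (correlation-matrix) PCA with a biplot.

A seeded synthetic-data generator (`simulate_kinetics()`,
`simulate_compound_table()`) reproduces the statistical structure of a
48-run design (2 temperatures × 3 enzyme levels × 8 time points,
replicate SD 0.002–0.150 mg/g), so the whole pipeline is testable without
laboratory data.

## Worked example

Simulate the forward model at a realistic rate (De/r² = 0.00915 min⁻¹,
total content 7.90 mg/g, 1:10 solid-to-liquid):

```r
library(phenolflux)
par  <- diffusion_params(cs0_from_content(7.90), rate_per_min = 0.00915, K = 1)
prof <- solve_extraction(par, particle_spec(24.5), suspension_spec(6, 60),
                         c(0, 2.5, 5, 10, 20, 30, 40))
yield_curve(prof)
#>   time_min yield_mg_per_g
#> 1      0.0          0.000
#> 2      2.5          3.379
#> 3      5.0          4.417
#> 4     10.0          5.558
#> 5     20.0          6.568
#> 6     30.0          6.946
#> 7     40.0          7.091
```

Most of the yield appears within the first 10 minutes (the washing-like
fast phase), then the curve creeps toward the equilibrium
`7.90·α/(1+α) = 7.18` mg/g. Fit every condition of a seeded synthetic
dataset and inspect the diffusion coefficients:

```r
cfg  <- generator_config(seed = 42, noise_sd_range = c(0.05, 0.05))
ds   <- simulate_kinetics(cfg)
fits <- fit_all_conditions(ds, cs0_g_cm3 = ...)  # per-condition Cs0
fits[c("temperature_C", "enzyme_pct", "rate_per_min", "r_squared", "aad_pct")]
#>   temperature_C enzyme_pct rate_per_min r_squared aad_pct
#> 1            40        0.0      0.00944     0.995   1.150
#> 2            40        0.5      0.01445     0.994   1.149
#> 3            40        1.0      0.02053     0.995   0.668
#> 4            50        0.0      0.00433     0.999   0.677
#> 5            50        0.5      0.00579     0.999   0.905
#> 6            50        1.0      0.00717     0.999   0.792
```

The fitted rates recover the generator's structure: faster diffusion with
more cellulase at fixed temperature, and slower internal diffusion at
50 °C than at 40 °C even though the 50 °C equilibrium yield is higher.
Compound-profile analytics on the packaged 17-compound table:

```r
tbl <- read_compound_table(system.file("extdata", "table2_phenolics.csv",
                                       package = "phenolflux"))
category_summary(tbl)$counts
#>   phenolic acid dihydrochalcone        flavanol        flavonol
#>               9               2               3               3
condition_query(tbl, "Catechin", "max")
#> $value 855.66      $condition "50C_1"  ...
pca_autoscaled(expand_replicates(tbl, 3, seed = 1))
#> pca_result: 18 samples x 17 variables
#>   explained variance: PC1 66.6%, PC2 15.8%, PC3 9.5%
```

`run_pipeline(list(seed = 1, outdir = "out"))` chains all three stages and
writes CSVs, figures and a `manifest.json` that makes the run exactly
reproducible.

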