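# paleodelta

Two-stage downscaling and bias correction of palaeoclimate simulation
snapshots into high-resolution terrestrial climatologies, for ecologists and
palaeoclimatologists who need continuous-time, observation-consistent
climate fields over the last glacial cycle — as predictors for species
distribution models, dispersal and extinction analyses, or biogeography.

## The method

Coarse general-circulation-model snapshots X(m, t) (monthly temperature,
precipitation, cloudiness, relative humidity, wind speed) cover the last
120,000 years on a 72-point axis; high-resolution simulations exist only on
a 9-point sub-axis T_21k of the last 21,000 years; observations exist at
t = 0.

**Stage 1 — Dynamic Delta Method.** Fine-grid correction terms
ΔX(m, τ) = X_fine(m, τ) − X⊞(m, τ) (⊞ = Akima regridding to the fine grid)
are computed at each reference time τ ∈ T_21k, then combined by CO2
similarity:

    X'(m, t) = X⊞(m, t) + Σ_τ w(t, τ) ΔX(m, τ),
    w'(t, τ) = 1 / (CO2(t) − CO2(τ))²,  w = w'/Σw'

an inverse-square-distance interpolation of the correction terms in CO2
space. At τ ∈ T_21k the weights collapse to an indicator and stage 1 returns
the high-resolution simulation exactly. Unlike the classical Delta Method
(fixed modern correction, w(t, 0) = 1), the fine-scale heterogeneity applied
to time t varies with the climatic state.

**Stage 2 — classical additive Delta Method** against a gap-filled modern
observational climatology:

    X'(m, t) = X⊞(m, t) + X_obs(m, 0) − X⊞(m, 0)

so the present-day output is identical to the observations. After each
stage, values are capped at physical bounds (P, W ≥ 0; C, H in [0, 100] %)
with per-month diagnostics.

Downstream, the package reconstructs annual temperature extremes from
coldest/warmest-month anomalies, derives the 17 bioclimatic variables BIO1
and BIO4–BIO19, builds sea-level-driven land masks (with endorheic basins
kept as land), overrides vegetation fields under ice sheets, and computes
proxy-validation statistics (median and quartiles of absolute model−proxy
differences). A seeded synthetic-world generator stands in for the real
simulation/observation inputs so that every stage is testable end to end.

## Worked example

```r
library(paleodelta)

w <- makeWorld(worldSpec(seed = 1))            # synthetic input constellation
res <- twoStagePipeline(w@coarse$T, w@fine$T, w@obs$T, w@co2,
                        variableSpec("T"), times = c(21000, 6000, 0))
res
#> SnapshotStack 'T' [degC]: 3 snapshots, 21,000..0 BP, grid 144 x 60

mean(fieldValues(snapshotFields(res)[[1]])) -
  mean(fieldValues(snapshotFields(res)[[3]]))   # LGM minus present
#> -5.40
```

The reconstructed Last Glacial Maximum is ~5.4 °C colder than the present in
this world — the CO2-tied cooling the generator built into the truth. Does
the dynamic correction actually beat a fixed modern correction? Held-out
recovery over 5 worlds:

```r
re <- recoveryExperiment(nSeeds = 5)
colMeans(re[c("rmseDynamic", "rmseFixed")])
#> rmseDynamic   rmseFixed
#>   0.0793471   0.4598524
```

RMSE against the generator truth at held-out times is ~6× smaller with
CO2-weighted corrections. Validation statistics behave as theory predicts:
with synthetic proxies = truth + N(0, 1) noise,

```r
pts <- makeProxies(w, n = 2000, sigma = 1, seed = 2)
truth <- w@truthFun("T", gridOf(w@obs$T), 0)
annual <- climField(gridOf(w@obs$T),
                    apply(fieldValues(truth), c(1, 2), mean), variable = "T")
absDiffSummary(extractAtPoints(annual, pts))
#>      n lowerQuartile   median upperQuartile
#> 1 2000     0.3402654 0.668971      1.177803
```

the median absolute difference lands on the half-normal median
Φ⁻¹(0.75) ≈ 0.6745.

A command-line interface wraps the same functions
(`inst/cli/paleodelta.R`): subcommands `synth`, `downscale`, `extremes`,
`bioclim`, `landmask`, `validate`, `pipeline`, e.g.

```sh
Rscript inst/cli/paleodelta.R synth --out bundle --seed 11 --variables T,P
Rscript inst/cli/paleodelta.R pipeline --bundle bundle --out recon --times 21000,0
```

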