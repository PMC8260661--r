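# nirherit

Quantitative-genetic analysis of visible/near-infrared absorbance spectra
of meat, wavelength by wavelength.

Portable Vis-NIR spectrometers can record an absorbance spectrum directly
on the carcass surface in the abattoir, turning every wavelength into a
cheap population-scale phenotype. `nirherit` is for animal breeders and
quantitative geneticists who want to know how much of that spectral
variation is genetic: it decomposes the phenotypic variance of absorbance
at each wavelength into slaughter-batch, rearing-herd, additive-genetic
and residual components, and summarizes the decomposition by spectral band
(near-ultraviolet, the visible colors violet through red, and the
infrared sub-bands IR-A/NIR and IR-B/SWIR).

## The model

At each wavelength the package fits, by average-information REML, the
univariate animal model

```
y = Xb + W1 c + W2 q + Z u + e
c ~ N(0, I sigma2_c)    (herd)
q ~ N(0, I sigma2_q)    (slaughter batch/date)
u ~ N(0, A sigma2_a)    (additive genetic)
e ~ N(0, I sigma2_e)
```

where `A` is the numerator relationship matrix over the phenotyped
animals and their ancestors (tabular method, with inbreeding). Reported
per wavelength: the four variance proportions and the intra-herd/batch
heritability `h2 = sigma2_a / (sigma2_a + sigma2_e)`, with standard
errors from the inverse average-information matrix (delta method for
`h2`).

The package also contains a full synthetic-data generator (pedigreed
population with herd/batch structure, Mendelian-sampling breeding values,
replicate spectra with a configurable per-band variance architecture),
the standard preprocessing chain (absorbance `A = log10(1/R)`, replicate
averaging, Mahalanobis GH outlier editing, minimum-cell filtering,
per-wavelength standardization), and CSV ingestion for real pedigree /
design / spectra data.

## Worked example

Simulate a blue-green slice of the spectrum for 400 young bulls (25
sires, 12 herds, 15 batches), run the whole pipeline and summarize by
band:

```r
library(nirherit)

grid <- wavelength_grid(450, 560, 5)   # 23 wavelengths
cfg <- pipeline_config(
  mode = "simulate",
  sim = sim_config(n_animals = 400, n_sires = 25, n_dams = 380,
                   n_herds = 12, n_batches = 15, grid = grid,
                   instrument = "uvvisnir"),
  instrument = "uvvisnir", seed = 11)
res <- run_pipeline(cfg, "demo-out")
print(res$summary[, c("band", "n_wavelengths", "pct_batch", "pct_herd",
                      "pct_genetic", "pct_residual", "mean_h2")],
      digits = 3, row.names = FALSE)
```

```
    band n_wavelengths pct_batch pct_herd pct_genetic pct_residual mean_h2
    blue             7     13.20     8.36        34.8         43.7   0.432
    cyan             3      6.81     6.65        33.5         53.1   0.375
   green            13     10.12     8.00        23.4         58.5   0.285
 visible            23     10.63     7.93        28.2         53.3   0.342
     all            23     10.63     7.93        28.2         53.3   0.342
```

Each row averages, over that band's wavelengths, the estimated variance
proportions (in percent, summing to 100) and the intra-herd/batch
heritability. At this modest sample size single-wavelength estimates
carry standard errors around 0.10-0.15, so band means wobble by a few
hundredths around the simulated architecture (blue-green bands are
simulated with ~29-33% genetic variance and h2 near 0.36-0.40). The
per-wavelength detail lives in `res$scan`:

```r
head(res$scan[, c("wavelength_nm", "p_genetic", "h2", "se_h2",
                  "converged")], 3)
#>   wavelength_nm p_genetic        h2     se_h2 converged
#> 1           450 0.1264738 0.1919456 0.1191823      TRUE
#> 2           455 0.4385308 0.5638043 0.1393687      TRUE
#> 3           460 0.2017038 0.2970506 0.1486399      TRUE
```

`run_pipeline()` writes four artifacts to the output directory:
`scan.csv` (one row per wavelength), `band_summary.csv`,
`exclusions.csv` (every removed animal with stage and reason) and
`manifest.yaml` (configuration echo, seed, convergence counts, wall
time). The same config and seed reproduce the CSVs byte for byte. A thin
command-line wrapper is in `inst/scripts/nirherit-run.R`.

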