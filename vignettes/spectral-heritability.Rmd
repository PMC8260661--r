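---
title: "Estimating the genetic architecture of meat absorbance spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the genetic architecture of meat absorbance spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Portable visible/near-infrared spectrometers can record an absorbance
spectrum directly on the cut surface of a carcass in the abattoir. Each
wavelength's absorbance is then an inexpensive, population-scale phenotype.
Whether such phenotypes are useful for breeding depends on how much of
their variation is genetic rather than environmental. `nirherit` answers
that question wavelength by wavelength: it decomposes the phenotypic
variance of absorbance at every wavelength into slaughter batch, rearing
herd, additive genetic and residual components, and summarizes the result
by spectral band (near-ultraviolet, the visible colors, and the two
infrared sub-bands IR-A/NIR and IR-B/SWIR).

The package models a typical beef progeny-test structure: young bulls,
progeny of artificial-insemination sires, reared on many commercial farms
and slaughtered in batches at one abattoir, with replicate spectra per
animal (by default 5 probe positions x 3 replicate scans, as collected by
a broad-range instrument covering 350-1830 nm at 1 nm and a miniaturized
one covering 905-1649 nm at 6 nm).

## The model

For one wavelength, the analysis fits the univariate animal model

$$
\mathbf{y} = \mathbf{X}b + \mathbf{W}_1\mathbf{c} + \mathbf{W}_2\mathbf{q}
  + \mathbf{Z}\mathbf{u} + \mathbf{e},
$$

with $\mathbf{c} \sim N(0, \mathbf{I}\sigma^2_c)$ (herd),
$\mathbf{q} \sim N(0, \mathbf{I}\sigma^2_q)$ (slaughter batch/date),
$\mathbf{u} \sim N(0, \mathbf{A}\sigma^2_a)$ (additive genetic) and
$\mathbf{e} \sim N(0, \mathbf{I}\sigma^2_e)$. $\mathbf{A}$ is the
numerator relationship matrix over the pedigree of the phenotyped animals
and their known ancestors, built by the tabular recursion
$A_{ij} = \tfrac12 (A_{j,s(i)} + A_{j,d(i)})$,
$A_{ii} = 1 + \tfrac12 A_{s(i),d(i)}$, with unknown parents treated as
unrelated non-inbred founders. Inbreeding is $F_i = A_{ii} - 1$.

The model statement lists no fixed effects; because the spectra are
centered before analysis we still include a single intercept so that the
restricted likelihood is well defined regardless of which animals survive
filtering. Variance components are estimated by REML. Two derived
quantities are reported per wavelength:

* **variance proportions** — each component over the four-component total
  (on standardized phenotypes, the total is 1, so components are directly
  proportions);
* **intra-herd/batch heritability**
  $h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_e)$, i.e. heritability after
  herd and batch variance are removed from the denominator.

Each wavelength is fitted independently (1481 analyses for the broad-range
grid, 125 for the narrow one); no covariances between wavelengths are
estimated.

## The REML algorithm

The engine is average-information (AI) REML on the observation-space
covariance
$\mathbf{V} = \sigma^2_c \mathbf{W}_1\mathbf{W}_1' +
\sigma^2_q \mathbf{W}_2\mathbf{W}_2' + \sigma^2_a \mathbf{Z A Z}' +
\sigma^2_e \mathbf{I}$, evaluated through a Cholesky factorization (never
an explicit inverse of an unfactorized matrix). Design choices that
matter:

* **AI step with step-halving, EM-REML fallback.** If the AI direction
  fails to increase the restricted likelihood after 12 halvings, one
  EM-REML update is taken instead; EM steps are ascent steps, so the
  accepted iteration sequence is monotone (asserted in the test suite).
* **Non-negativity by pinning.** A component pushed below
  $10^{-8}\,\mathrm{var}(y)$ is pinned at that bound and flagged; it is
  released if its gradient later turns positive. Pinned components report
  no standard error.
* **Convergence** requires a relative parameter change below $10^{-8}$
  and a scaled gradient norm below $10^{-6}$; fits hitting `max_iter`
  (200) are returned with `converged = FALSE` rather than raised, so a
  scan never aborts.
* **Standard errors** come from the inverse AI matrix over the free
  components; the SE of $h^2$ follows by the delta method.
* **Warm starts.** Within a scan, each wavelength starts from its
  neighbour's converged estimates. Because the restricted likelihood has
  a unique interior optimum in well-conditioned problems, warm starts
  change the iteration path, not the estimates (tested to $10^{-6}$).

With ~1200 records an iteration costs one Cholesky factorization and
inverse of a 1200 x 1200 matrix (~0.2 s); a warm-started wavelength
typically converges in 4-8 iterations.

## Preprocessing

The pipeline order is fixed and mirrors standard NIRS practice:

1. **Absorbance**: $A = \log_{10}(1/R)$. The decadic log is the universal
   NIRS convention; a natural log would rescale every component equally
   and leave proportions and $h^2$ unchanged, so the base is not
   configurable.
2. **Replicate averaging**: grand mean of the 15 position x replicate
   spectra; animals with missing cells are averaged over what is present
   and flagged rather than dropped.
3. **Mahalanobis (GH) editing** on the animal-average spectra: principal
   components retaining 99.9% of variance (at most $n-1$), standardized
   distance $GH = D^2/k$, single pass, exclusion at $GH > 3$. Threshold,
   retained variance and iteration are configurable. One caveat is
   structural: an in-sample $GH$ cannot exceed $(n-1)/k$, so the editor
   only has power when the retained score space is small relative to the
   number of animals. Real spectra are strongly collinear (small $k$), so
   this is the regime that matters in practice.
4. **Minimum-cell filter**: herds or batches with fewer than 3 animals
   are dropped, re-applied to a fixpoint because removals can shrink
   other cells.
5. **Centering and standardization** per wavelength over the surviving
   animals.

Every removed animal is carried through to an exclusion report
(`animal,stage,reason,statistic`); survivors plus exclusions always sum to
the input.

## What the simulator emulates — and what it does not

`sim_config()` defaults describe the population the package targets: 200
sires, 1150 dams, 1185 phenotyped progeny on 93 herds and 115 slaughter
batches, each herd and batch guaranteed at least 3 animals, batches
cutting across herds as in a commercial abattoir. Breeding values are
drawn by the Mendelian-sampling recursion
$u_i = \tfrac12(u_s + u_d) + m_i$,
$\mathrm{var}(m_i) = \sigma^2_a\,(0.5 - 0.25(F_s + F_d))$, which
reproduces $\mathrm{cov}(\mathbf{u}) = \mathbf{A}\sigma^2_a$ without
factorizing $\mathbf{A}$ (verified against the Cholesky construction by
Monte Carlo in the tests).

Per wavelength, the animal-level phenotype adds standardized herd, batch,
genetic and residual realizations weighted by the square roots of the
target variance fractions; the default fractions come from
`reference_band_profile()`, the package's reference architecture for beef
spectra (strong batch and genetic variance in the ultraviolet/violet, the
most heritable absorbances between blue and yellow, low heritability and
dominant residual in the infrared). The animal value is then expanded
into replicate scans with position-level and replicate-level noise
(defaults 0.10 and 0.05 phenotypic SDs: repositioning the probe on the
muscle surface matters more than rescanning in place; after averaging 15
cells this inflates the residual by ~0.2% of phenotypic variance, i.e.
negligibly).

Two deliberate departures from real spectra:

* **Effect realizations are independent across wavelengths.** Real
  spectra are smooth and strongly correlated between neighbouring
  wavelengths; simulated smoothness here lives only in the mean and SD
  profiles. The reason is statistical: simulated multi-wavelength scans
  are used to check estimator calibration, and only independent
  realizations make $m$ wavelengths worth $m$ effective replicates. With
  fully shared realizations a 20-wavelength scan would estimate the same
  single draw 20 times, and no average-recovery tolerance of a few
  hundredths would be attainable at realistic sample sizes (the SE of one
  $h^2$ estimate at 1200 progeny of 60 sires is roughly 0.08). The cost
  is that simulated spectra are full-rank, which weakens in-sample GH
  editing (see above); outlier-editing tests therefore use fixtures with
  fewer wavelengths than animals.
* **No selection, no deeper family structure.** Founders are unrelated
  and a single progeny generation is simulated; real herd-book pedigrees
  carry more ties. This makes simulated standard errors slightly
  conservative.

Consequently, passing recovery tests demonstrate that the estimator is
calibrated under the stated architecture; they do not certify the edit
thresholds or the standard errors on any particular real dataset.

## Numerical conventions

* Wavelength grids are inclusive arithmetic sequences in physical nm
  (350-1830 step 1 gives 1481 points; 905-1649 step 6 gives 125).
* Band membership is half-open $[lo, hi)$ with the final band of each
  instrument closed; this is the unique simple closure reproducing the
  conventional band wavelength counts on both grids (e.g. violet 70,
  IR-B 431, narrow-grid IR-A 83, where the IR-A/IR-B boundary sits
  between the 6 nm grid points 1397 and 1403).
* Band summaries average proportions and $h^2$ on the per-wavelength
  ratio scale ("average of ratios"). The alternative ratio-of-averages
  differs whenever components vary across wavelengths — e.g. a band whose
  averaged percentages are 18 genetic and 47 residual implies
  $18/65 = 0.277$, while the mean per-wavelength $h^2$ can print 0.279 —
  and the suite asserts the two orderings disagree on heterogeneous
  scans. Aggregate rows (visible, infrared, whole spectrum) are computed
  over constituent wavelengths, never over sub-band means.
* The Table-style `sd_abs` column is the SD across wavelengths of the
  per-wavelength mean absorbance, consistent with mean ± SD envelope
  plots of spectra.
* A single master seed derives named substreams (pedigree, genetic,
  effects, noise, outliers), so each simulation stage is independently
  reproducible and a whole dataset is bit-for-bit repeatable.

## Problem sizes used in the shipped checks

The packaged checks run at reduced but statistically meaningful sizes,
chosen so the whole suite completes in minutes on one core while keeping
Monte-Carlo error well inside the asserted tolerances: recovery scans use
1200 animals (60 sires, 30 herds, 40 batches) and 20 wavelengths per
band; null calibration uses 1000 animals and 50 wavelengths; oracle
comparisons use 30-100 animals, where naive dense linear algebra is
exact and cheap.

## Known limitations

* Single-trait analyses only: no genetic correlations between
  wavelengths or with quality traits, and no BLUP breeding-value output.
* Dense $\mathbf{A}$ and dense $\mathbf{V}$ limit practical problem
  sizes to low tens of thousands of pedigree animals and a few thousand
  phenotyped records — ample for the target design, unsuitable for
  national evaluations.
* The Mahalanobis edit is a convention (single pass, $GH > 3$, 99.9%
  score space), not a reconstruction of any particular commercial
  software's editing.
* No scatter-correction pretreatments (SNV, MSC, derivatives) — the
  pipeline analyzes absorbance as recorded, which is the intended
  use-case; add-on pretreatments would change the phenotype definition.
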