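---
title: "FTIR chemometrics for fermentation monitoring: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FTIR chemometrics for fermentation monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-throughput screening of microbial bioprocesses is routinely bottlenecked
by the reference analytics: substrate and extracellular metabolites are
measured by HPLC, one sample at a time. Mid-infrared (FTIR) spectroscopy can
replace much of that load because a single spectrum encodes the
concentrations of every IR-active constituent of the growth medium. Two
sampling modes matter in practice:

* **ATR** (attenuated total reflection): the liquid supernatant is measured
  directly on a crystal. The optical path is highly controlled, so spectra
  are very reproducible, but strong water bands dominate.
* **HTS** (dry-film transmission on a silicon microplate): samples are
  diluted ten-fold, deposited and dried. Water bands essentially vanish, but
  film formation is irreproducible, so the effective pathlength varies
  between technical replicates.

`fermspec` implements the complete calibration workflow for this setting —
substrate (glucose) and extracellular metabolite (citric acid) quantification
from either mode — together with a synthetic data generator that emulates a
fungal screening study, so that every stage of the pipeline is testable
without access to proprietary instrument data.

## The simulated study

The generator reproduces the structure of a microtiter-plate screening
experiment: three oleaginous filamentous fungi (a *Mucor*-, an *Umbelopsis*-
and a *Penicillium*-type strain), cultivated at 20 and 30 °C for 12 days on
a medium starting at 80 g/L glucose, with 3 biological wells per condition
and 3 technical replicates per FTIR measurement. That yields 216 supernatant
samples plus 6 starting growth media — 648 + 18 spectra — and optionally a
biomass arm (210 samples / 630 spectra, two conditions unsampled on day 1
for insufficient growth).

```{r}
library(fermspec)
d <- screening_design()
table(d$sample_type)
```

**Kinetics.** Reference concentration curves are deterministic: glucose
follows an exponential decay to a residual floor (7.5 g/L; the decay rate
0.35–0.45/day varies by strain and is 15% faster at 30 °C), and citric acid,
produced only by the *Penicillium*-type strain, follows a logistic rise that
reaches ~99% of its plateau (7.5 g/L at 20 °C, 6.5 g/L at 30 °C) by day 6
and remains stable thereafter. The functional forms are a modelling choice —
only the qualitative course (monotone depletion; plateaued production by
day 6) is constrained by what such cultivations look like — and all
parameters are exposed in `simulate_fermentation()`.

**Spectra.** Absorbance follows the Beer–Lambert mixing model

$$A_i(\nu) = m_i \sum_c \frac{c_{ic}}{d\, c_\mathrm{ref}} s_c(\nu) + b_i(\nu) + \varepsilon_i(\nu),$$

with Gaussian (optionally Lorentzian) band profiles for each component.
Band positions and widths follow standard assignments: glucose bands in
1200–900 cm⁻¹ (principal peak 1035 cm⁻¹, FWHM 30–40 cm⁻¹), the citric-acid
carbonyl at 1725 cm⁻¹, water at 3300/2110/1635/580 cm⁻¹ with FWHM
100–400 cm⁻¹, lipid bands for biomass work, and one broad background lump
for the untracked medium constituents. Since no absolute absorbance values
are available for this kind of measurement without an instrument in hand,
the AU scale is a convention: heights are set so that undiluted 80 g/L
glucose peaks at ≈ 0.5 AU, and the citric-acid and glucose per-gram heights
are balanced so that at end-cultivation concentrations (≈ 8.8 vs ≈ 8 g/L)
the 1725 and 1035 cm⁻¹ peaks are of comparable magnitude, as observed in
dry-film spectra of such media.

**Acquisition defaults** (all overridable in `acquisition_config()`):

| parameter | ATR | HTS | why |
|---|---|---|---|
| dilution | 1 | 10 | dry films need dilution to stay in the linear range |
| pathlength jitter sd | 0 | 0.10 | controlled path vs irreproducible film formation |
| water component | yes (weight 1) | no | liquid vs dried sample |
| baseline drift amplitude | 1e-3 AU | 1e-3 AU | slow instrument drift, removable by offset/derivative |
| white noise sd | 1e-4 AU | 1e-4 AU | typical rms detector noise at 32–64 scans |
| grid | 4000–500 cm⁻¹, 2 cm⁻¹ | same | finer than the 4–6 cm⁻¹ instrument resolution so band shapes are well sampled |

The 10% film-thickness jitter is the dominant error source in HTS mode and
is what the preprocessing track has to defeat. Baseline drift is a random
quadratic in wavenumber (three coefficients uniform on ±amplitude/3), chosen
deliberately so that it is removable both by offset correction and by the
second derivative. Reference concentrations are recorded before any noise;
optional "HPLC error" on the reference table exists
(`reference_noise_sd`) but is off by default.

What the generator does **not** emulate: ATR penetration-depth physics,
scattering artifacts, atmospheric CO₂/water-vapour lines, wavenumber
calibration error, chemical interferents that co-vary with the analytes
(e.g. the unidentified pigment such cultures can develop), or error in the
reference analytics. Consequently the synthetic benchmark tests the
*statistical machinery* — leakage-free validation, preprocessing algebra,
latent-variable recovery under multiplicative and additive noise — not the
absolute error levels achievable on real fermentations; synthetic ATR
errors in particular come out near zero because the mode's dominant
real-world error sources are exactly the ones outside the model.

## Preprocessing tracks

Two frozen plans mirror the two modes (`preprocess_plan("atr_media")`,
`preprocess_plan("hts_media")`):

* **ATR**: select 1900–700 cm⁻¹ (the region holding both analytes' bands,
  and excluding the huge 3300/2110 cm⁻¹ water features), then per-spectrum
  baseline offset (subtract the minimum).
* **HTS**: select 1900–700 cm⁻¹, Savitzky–Golay second derivative with a
  15-point window and polynomial order 2, then average the technical
  replicates (648 + 18 → 222 spectra). The derivative annihilates additive
  and linear baseline structure exactly (to machine precision, a tested
  invariant); averaging shrinks the uncorrelated film noise by √3.

Numerical conventions worth stating:

* SG windows are counted in grid points, not cm⁻¹, and derivatives are
  scaled by the grid spacing to that power, so models are comparable across
  instruments with different sampling intervals.
* SG edge points without a complete centered window — 7 per edge at window
  15 — are dropped, not padded: padding invents data and biases derivatives
  exactly where baseline artifacts concentrate.
* No baseline step precedes the HTS derivative: the second derivative makes
  it redundant.
* SNV and EMSC are provided for absorbance-mode normalisation needs (e.g.
  biomass films) but are *not* in the media tracks: media spectra change
  total absorbance by an order of magnitude across a cultivation, which
  violates the constant-total-signal premise of per-spectrum normalisation.

## Latent-variable models

`fit_pca()` is SVD-based PCA on column-centered data; signs are fixed by
making the largest-magnitude loading element positive, so runs are
bit-reproducible. `fit_plsr()` is PLS1 by NIPALS (non-iterative for one
response) with mean centering only — no variance scaling, the standard
choice for spectra where the variables share units. The regression vector
is collapsed as \(b = W(P^\top W)^{-1} q\), and tests assert (a) exact
agreement between component-form and regression-vector predictions, (b)
equality with ordinary least squares at full rank, and (c) agreement to
1e-6 with an independently coded SIMPLS oracle on random problems.

**Metrics.** RMSE; R² as 1 − SSE/SST on the validation predictions (the
coefficient of determination; with a squared-correlation reading the two
can differ on held-out data, and the SSE/SST form is the stricter and more
common convention); relative RMSE as 100·RMSE divided by a reference scale
that defaults to the maximum calibration concentration (80 g/L for
glucose — under which a 3.59 g/L error reads 4.5%).

**Component selection.** `A_opt` is the smallest number of components whose
cross-validated RMSE is "insignificantly" above the minimum. Insignificance
needs an operational definition; the default is a 2% relative band
(`rmsecv(A) ≤ 1.02 · min`), with a segment-level one-standard-error rule
available as an alternative (`method = "one_se"`). The 2% figure is a
declared convention: small enough to not skip genuinely better models,
large enough to ignore noise-level differences between adjacent A.

## Validation design

Replicates — technical, and biological wells of the same condition — are
correlated, so random-split CV flatters the error. Folds are therefore
whole experimental conditions: supernatants segment by
strain × temperature × day, media by temperature, giving 74 segments for
the full design (9 spectra each unaveraged, 3 averaged). A property test
verifies the direction of the bias: on data with condition-correlated
noise, segment-wise CV reports systematically higher (more honest) error
than shuffled folds. Leakage — any condition straddling a fold — is
asserted on every run, and centering is recomputed per training fold.

The independent-test scheme holds out one whole strain × temperature
condition (by default the producer strain at 30 °C): 108 ATR / 36 HTS
spectra. Glucose models train on all strains; citric-acid models on the
producer only. Media spectra stay in the training set for citric acid but
are excluded for the glucose hold-out scheme; both policies are flags. The
number of components for the final ITV model is chosen by segmented CV
*within the training set*.

```{r, eval = FALSE}
bm <- benchmark_dataset("HTS", seed = 1)
run_calibration_workflow(bm$dataset, bm$reference, "glucose", "HTS")
```

On the seeded default benchmark this recovers glucose with CV R² ≈ 0.99 at
A_opt = 1 and citric acid with CV R² ≈ 0.99 at A_opt = 2, with ITV within
0.02 of CV — the expected behaviour for a two-analyte Beer–Lambert system
under multiplicative noise, and the quantitative pattern the acceptance
suite asserts (R² ≥ 0.95, A_opt ≤ 3 for glucose / ≤ 5 for citric acid).

## Problem sizes and runtime

The default benchmark (666 spectra × 1751 wavenumbers; 74-fold CV scanning
up to 10 components, both analytes, both modes) was chosen to match the
emulated study exactly; the full test suite and the acceptance script each
complete in well under a minute on a single CPU, so nothing was scaled
down.

## Known limitations

* Synthetic AU scales, noise magnitudes and kinetic forms are conventions;
  only the study's *structure* (design counts, replicate correlation,
  dilution, mode contrasts) is reproduced, so real-data error levels are
  not predicted — in particular synthetic ATR calibrations are nearly
  perfect because the mode's real error sources (reference-method error,
  matrix variability) are not modelled.
* PLS2 (multiple simultaneous responses), variable selection (iPLS, VIP),
  outlier diagnostics and nonlinear calibration are out of scope.
* The JCAMP-DX reader handles uncompressed AFFN/PAC tables only; SQZ/DIF
  compressed files are rejected explicitly.
* Biomass spectra are designed (sample counts, metadata) but not
  synthesized; the media workflow never needs them.
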