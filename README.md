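# fermspec

Chemometric quantification of fermentation substrates and extracellular
metabolites from mid-infrared (FTIR) spectra.

Screening many microbial strains in parallel is cheap; measuring what they
consumed and secreted is not, because each sample classically needs HPLC.
A single FTIR spectrum of the cell-free supernatant carries the
concentration information of every IR-active medium constituent at once.
`fermspec` implements the full calibration workflow for this setting, for
two sampling modes — ATR (liquid on a crystal: reproducible pathlength,
water-dominated spectra) and HTS dry films (10×-diluted samples dried on a
silicon microplate: water-free but with irreproducible film thickness) —
and ships a synthetic-data generator that emulates a three-strain,
two-temperature, twelve-day fungal screening study so the whole pipeline is
testable end to end.

## What is inside

* **Simulation** — Beer–Lambert band-model spectra
  (`build_pure_spectrum()`, `default_component_library()`), fermentation
  kinetics (`simulate_fermentation()`, `benchmark_profiles()`), the
  screening design with its 216 supernatant + 6 media samples
  (`screening_design()`), and acquisition models for both modes
  (`acquisition_config()`, `synthesize_dataset()`, `benchmark_dataset()`).
* **Preprocessing** — region selection, baseline offset, Savitzky–Golay
  smoothing/derivatives (edge-dropping, spacing-scaled), technical-replicate
  averaging, SNV and EMSC; frozen per-mode plans
  (`preprocess_plan("atr_media")`, `preprocess_plan("hts_media")`,
  `apply_plan()`).
* **Chemometrics** — SVD PCA (`fit_pca()`) and from-scratch NIPALS PLS1
  (`fit_plsr()`, `predict()`), with the regression vector
  b = W(PᵀW)⁻¹q, metrics RMSE / R² = 1 − SSE/SST / relative RMSE
  (`compute_metrics()`), and parsimonious component selection: A_opt is the
  smallest A with RMSECV(A) ≤ (1 + τ)·min RMSECV, τ = 0.02
  (`select_a_opt()`).
* **Validation** — segmented cross-validation with folds = whole
  strain × temperature × day conditions (74 segments on the full design;
  `build_segments()`, `segmented_cross_validation()`), independent-test
  hold-out of one strain × temperature condition
  (`independent_test_split()`), and the one-call orchestration
  `run_calibration_workflow()`.
* **I/O** — wide-CSV spectra read/write, a JCAMP-DX (AFFN) reader, JSON run
  manifests.

The `analysis/` directory holds the narrative drivers
(`01_simulate.R` … `04_calibrate.R`) that run the study end to end and
write tables under `results/`.

## Worked example

```r
library(fermspec)

bm <- benchmark_dataset("HTS", seed = 1)   # 648 + 18 spectra, dry-film mode
bm$dataset
#> <spectral_dataset> 666 spectra x 1751 wavenumbers (500-4000 cm-1)
#>   sample types: medium (18), supernatant (648)

run_calibration_workflow(bm$dataset, bm$reference, "glucose", "HTS")
#> Calibration report: glucose, HTS mode (222 spectra, scale 80 g/L)
#>        R2 (A_opt) RMSE (rel)     n
#>   CV   0.99 (1)   1.48 (1.9%)    222
#>   ITV  0.98 (1)   1.68 (2.1%)    36
```

Reading the report: after the frozen HTS preprocessing (1900–700 cm⁻¹,
Savitzky–Golay second derivative window 15 / order 2, replicate averaging to
222 spectra), a one-component PLS model predicts glucose with a
cross-validated R² of 0.99 and an error of 1.48 g/L (1.9% of the 80 g/L
calibration range); holding out the entire producer-strain-at-30 °C
condition (36 spectra) barely degrades it — the model generalises across
conditions rather than memorising replicates. The citric-acid workflow
(`analyte = "citric_acid"`) restricts to the producer strain (78 spectra,
26 segments) and behaves analogously at A_opt = 2.

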