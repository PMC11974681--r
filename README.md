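# dynphen

Cross-species dynamical phenotyping of anaesthesia: an R package and
analysis workflow asking whether the loss of consciousness under anaesthesia
has a shared signature in the statistics of regional neural dynamics, and
whether a whole-brain model reproduces it by lowering global coupling.

The package provides:

* a **synthetic multi-species study generator** (regional time series with
  planted timescale/synchrony axes, spatially autocorrelated gene-expression
  maps, distance-dependent weighted connectomes) with known ground truth;
* a **catalogue of univariate time-series features** (autocorrelations,
  automutual information, local forecast errors, and 22 canonical
  distribution/scaling/periodicity statistics);
* **Hedge's g contrasts** between wakefulness and anaesthesia, and strict
  **sign-consistency discovery** across contrasts against random-sign
  surrogate nulls;
* **intrinsic timescale** estimation and condition comparison;
* **functional connectivity**, **dynamical profile similarity**, and their
  **synchrony–dynamics coupling**;
* **PLS correlation** of dynamics-change maps with gene expression, with
  significance from **Moran spectral randomisation** spatial nulls;
* a compiled **dynamic mean-field model** with feedback inhibition control,
  balloon–windkessel haemodynamics, and **FCD-based fitting** of the global
  coupling G.

The scientific rationale, parameter choices, and numerical caveats are
documented in `vignettes/dynamical-phenotyping.Rmd`.

## Worked example

Generate a small two-species study and run the full pipeline (the defaults
are the frozen full-size study conditions; here region counts and recording
length are scaled down so the example runs in about 20 seconds):

```r
library(dynphen)

blocks <- default_species_blocks(n_regions = c(14L, 12L), n_subjects = 4L,
                                 n_contrasts = c(1L, 1L))
spec <- study_spec(blocks, n_timepoints = 150L, seed = 11)
config <- pipeline_config(spec, reduced_catalog = TRUE,
                          n_sign_surrogates = 1000L,
                          n_pls_surrogates = 200L, n_tau_surrogates = 200L,
                          seed = 11)
report <- run_pipeline(config)

report$consistency$observed_count   # 17 features shift the same way in both contrasts
#> [1] 17
report$consistency$p                # vs the random-sign surrogate null
#> [1] 0.005994006
head(report$consistency$feature_ids)
#> [1] "DN_HistogramMode_10"              "SB_BinaryStats_mean_longstretch1"
#> [3] "SB_BinaryStats_diff_longstretch0" "DN_OutlierInclude_n_001_mdrmd"
#> [5] "CO_f1ecac"                        "CO_FirstMin_ac"

report$timescales$human$mean_delta  # anaesthesia shortens intrinsic timescales (s)
#> [1] -3.246583
report$timescales$human$p
#> [1] 0.001097051

c(report$network$human$fc$mean_a, report$network$human$fc$mean_b)
#> [1] 0.312 0.076                     # synchrony collapses under anaesthesia

round(report$pls$cov_explained[1:3], 3)   # PLS of change maps vs expression
#> [1] 0.540 0.088 0.069
round(report$pls$p[1:3], 3)               # LV1 significant under spatial nulls
#> [1] 0.005 1.000 1.000
```

The numbered scripts under `analysis/` run the same stages at study scale
and write their tables to `results/`:

```sh
Rscript analysis/01_simulate_study.R
Rscript analysis/02_extract_features.R
Rscript analysis/03_consistency.R
Rscript analysis/04_timescales.R
Rscript analysis/05_network.R
Rscript analysis/06_pls.R
Rscript analysis/07_dmf.R
```

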