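# ifflcyto

Analysis toolkit for **endoRNase-based incoherent feedforward loop (iFFL)
gene-expression controllers** under transcriptional resource competition,
aimed at synthetic biologists quantifying controller robustness from
transient-transfection flow cytometry.

A genetic module's output in mammalian cells depends on how much plasmid a
cell took up and on how many shared transcriptional/translational resources
are left over — a strong Gal4 activator can knock down unrelated genes by
sequestering coactivators ("squelching"). In the iFFL design, one promoter
drives both the output gene and a Cas6-family endoRNase that cleaves the
output mRNA's 5' UTR, so perturbations that raise output production also
raise its repression. At steady state

```
y = V_y · D·R / (1 + D·R/ε),        R = R_TX · R_TL
```

with plasmid dose `D`, free resources `R`, output capacity `V_y` and
*feedforward impedance* `ε`. For `D·R ≫ ε` the output pins to
`Y_max = V_y·ε`, independent of dose and resources. Against a co-delivered
transfection marker `z = V_z·D·R`, the curve reaches half of `Y_max` at
`Z_50 = V_z·ε`; both landmarks scale with `ε`, which is tuned by adding
uORFs to the endoRNase transcript.

The package provides:

* closed-form steady-state models (iFFL, unregulated control, Gal4-TA
  resource-competition dose-response) — `iffl_output()`,
  `iffl_output_vs_marker()`, `ur_output()`, `resource_dose_response()`;
* a mass-action ODE simulator of iFFL dynamics during transient
  transfection with plasmid dilution — `simulate_iffl()`,
  `simulate_resource_step()`;
* a synthetic-data generator emulating transient-transfection cytometry
  (log-normal uptake over ~3 decades, measurement noise, spectral bleed,
  autofluorescence, untransfected cells, exponential event times) —
  `generate_transfection()`, `generate_beads()`, `generate_timestamps()`;
* the event-processing pipeline: MEFL bead calibration, autofluorescence
  subtraction + linear compensation, threshold gating, half-log binning,
  positive-value medians, scatter density, cell-density estimation —
  `calibrate_mefl()`, `build_compensation()`, `compensate()`,
  `threshold_gate()`, `assign_bins()`, `median_summary()`,
  `scatter_density()`, `estimate_cell_density()`;
* robustness metrics — `fold_change()`, `robustness_score()`,
  `relative_error_log()`, `cv_rmse()`, `adaptation_report()`,
  `accumulated_change()`;
* model fitting — `fit_iffl()`, `fit_ur()`, `fit_resource_model()` — and
  an end-to-end `run_pipeline()`.

See `vignettes/iffl-methods.Rmd` for the models, assumptions, numerical
choices and limitations.

## Worked example

Simulate a transfection of an iFFL with `V_y = 1000`, `ε = 10`, `V_z = 5`
(so `Y_max = 10000`, `Z_50 = 50` MEFL), process it and refit the model:

```r
library(ifflcyto)
p <- iffl_params(V_y = 1000, epsilon = 10, V_z = 5)
config <- list(
  transfection = transfection_config(n_cells = 8000, params = p),
  beads = bead_config(events_per_peak = 1000)
)
res <- run_pipeline(config, seed = 61)
print(res$fit)
```

```
[simulate] 8000 events in -> 8000 events out
[calibrate] 8000 events in -> 8000 events out
[compensate] 8000 events in -> 8000 events out
[gate] 8000 events in -> 5590 events out
[bin] 5590 events in -> 5073 events out
[fit] 5590 events in -> 5071 events out
iFFL marker-vs-output fit (V_z = 1 normalisation)
  Y_max  = 9350.44
  Z_50   = 52.0477
  slope0 = 179.651 (V_y/V_z)
  CV(RMSE) on log10 scale = 0.08306  (n = 5071 events)
```

The generating plateau (10000) and half-max marker level (50) are
recovered within ~7% and ~4% from 8000 noisy cells after background
subtraction and gating, and `res$adaptation$adaptation_range` reports
4 decades of marker bins whose median output stays within the 5%
log-scale window around the fitted `Y_max`.

Robustness to resource loading — compare a population at nominal
resources with one at a 3-fold drop:

```r
nom  <- generate_transfection(transfection_config(
  n_cells = 8000, params = p, R = 1,   seed = 1,
  transfected_fraction = 1, autofluor_mean = 0, autofluor_sd = 0))
load <- generate_transfection(transfection_config(
  n_cells = 8000, params = p, R = 1/3, seed = 2,
  transfected_fraction = 1, autofluor_mean = 0, autofluor_sd = 0))
lr <- loading_robustness(nom, load)
round(c(fold_change = lr$fold_change$fold_change,
        robustness = lr$robustness), 3)
```

```
fold_change  robustness
      0.717      71.715
```

A fold change of 0.717 means the median output retained 71.7% robustness
(`100·(1 − |1 − fold-Δ|)`); an unregulated module under the same drop
scores ~33%, and an iFFL with smaller `ε` scores higher still.

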