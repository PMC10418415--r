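# catrisk

Calcium-transient phenotyping and CiPA-style Torsade-de-Pointes (TdP) risk
classification for plate-based cardiomyocyte screening.

## What it does

Spontaneously beating cardiomyocyte cultures report drug effects on
excitation–contraction coupling through their calcium transients (CaT):
the cyclic rise and fall of a calcium-sensitive fluorescence signal with
each beat. `catrisk` turns per-well CaT time series into a TdP risk call
per compound:

1. **Phenotyping** — each well is reduced to six parameters: P80 (peak
   width at 80% recovery, s), the 8/2 ratio (width at 80% over width at
   20% recovery, an early-afterdepolarization indicator), CL (cycle
   length, s), AMP (amplitude), PN (peak count) and CSD (SD of cycle
   lengths, s); dosed wells are expressed as percent change from their own
   pre-dose baseline.
2. **Profiles** — dose-dependent radial ("spider") plots, with a logistic
   EAD indicator `1/(1+exp(-9(x-3)))` on the 8/2 axis and the log-modulus
   `L(x) = sign(x)·log10(|x|+1)` on the other axes.
3. **Predictors** — per compound × cell line: arrhythmia waveform type
   (NONE/OTHER/TYPE_A, ordinal 0/1/2), P80@Cmax (log-dose interpolation of
   P80 change at the clinical Cmax) and P80_Max (maximum P80 change),
   min–max normalized across the panel.
4. **Risk model** — a ridge-penalized three-class multinomial logistic
   model (deterministic L-BFGS-B fit, 1000-iteration cap) per cell line;
   the decision quantity is `P(high) + P(intermediate)` against a 0.8
   threshold.

An 11-compound CiPA reference registry (3 high / 4 intermediate / 4
low-risk compounds with Cmax and a four-dose grid, nM) is bundled, and a
seeded synthetic CaT generator emulates a control line (baseline
P80 ≈ 0.70 s) and an aged-phenotype progeria line (≈ 0.98 s, higher drug
sensitivity) with dose-dependent prolongation, amplitude suppression,
EAD humps, beat cessation and rhythm irregularity — so the entire
pipeline runs and is tested without instrument data.

**Honesty note:** the default risk prediction is *in-sample* — the model
predicts the same 11 compounds it was trained on, faithful to the source
analysis but circular by construction. A leave-one-out mode
(`mode = "loo"`) is provided as an extension.

## Worked example

```r
library(catrisk)

reg <- load_registry()
head(reg, 3)
#>         name risk_label   cmax dose1 dose2 dose3 dose4
#> 1 Dofetilide       high   2.14   0.3     1     3    10
#> 2   Bepridil       high  31.50  35.0   105   210   315
#> 3  Quinidine       high 843.00 100.0   300   900  2700

# one synthetic progeria well, undosed
tr <- simulate_trace(default_cell_profiles()$progeria, seed = 42)
phenotype(tr)
#> <phenotype> P80=0.978s 8/2=2.65 CL=1.600s AMP=1.024 PN=19 CSD=0.120s
```

P80 of 0.978 s sits on the progeria baseline target (0.98 s); the 8/2
ratio of 2.65 is below the EAD indicator's centre (3), i.e. no
arrhythmic morphology.

```r
# full synthetic pipeline: plate simulation -> phenotypes -> predictors
# -> per-line multinomial fit (in-sample)
res <- run_risk_pipeline(seed = 1)
subset(res$predictions, cell_line == "progeria")
#>          compound prob_high prob_intermediate prob_low combined_risk
#>        Dofetilide     0.552              0.34    0.107          0.89
#>          Bepridil     0.309              0.42    0.271          0.73
#>         Quinidine     0.605              0.30    0.095          0.90
#>       Terfenadine     0.316              0.51    0.178          0.82
#>       Chloroquine     0.315              0.52    0.161          0.84
#>    Chlorpromazine     0.088              0.39    0.527          0.47
#>         Cisapride     0.322              0.53    0.151          0.85
#>         Diltiazem     0.303              0.36    0.340          0.66
#>        Mexiletine     0.061              0.20    0.735          0.26
#>        Ranolazine     0.062              0.21    0.728          0.27
#>         Verapamil     0.067              0.23    0.707          0.29
```

All four low-risk compounds stay below the 0.8 combined-risk threshold in
both cell lines, while several intermediates (cisapride, chloroquine,
terfenadine) cross it only in the progeria line — the aged-phenotype
sensitivity contrast the assay is built to expose. Figures:
`plot_radial()` for dose-profile spider charts and
`plot_stacked_probabilities()` for the stacked risk bars with the 0.8
line.

## CLI

```sh
catrisk simulate   --out-dir out --seed 1
catrisk phenotype  --traces out/traces_post.csv --platemap out/platemap.csv --out wells.csv
catrisk radial     --phenotypes wells.csv --compound Dofetilide --line control --out dof.svg
catrisk predictors --phenotypes wells.csv --line control --out pred_control.csv
catrisk classify   --predictors pred_control.csv,pred_progeria.csv --out risk.csv
```

See `vignettes/catrisk-methods.Rmd` for the model, its assumptions,
calibration choices and known limitations.
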