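# notchbench

Simulation and benchmarking of the Orbitrap reporter-ion "notch" artifact
in tandem mass tag (TMT) quantification.

Orbitrap instruments running older acquisition software record almost no
TMT reporter intensities inside a band of the log2 intensity distribution
(the *notch*, approximately 4.25–5.75 log2 units): values that should fall
in the band are recorded below it, i.e. systematically underestimated.
`notchbench` is for proteomics methodologists who want to quantify what
this does to a differential-abundance experiment — and whether removing
sub-notch spectra ("notch filtering") is worth it — without access to raw
instrument files.

The package simulates a two-species spike-in benchmark with known ground
truth: yeast peptides at 1x/2x/6x (5, 10, 30 µg per channel) spiked into
human peptides filling each TMT 10-plex channel to 100 µg, giving
ground-truth fold changes from 1.06 (human 95/90) to 6 (yeast 30/5). A
controllable notch distortion, co-isolation interference (ratio
compression) and reporter noise are injected at the PSM level, and the full
analysis pipeline is implemented on top:

* PSM table I/O (Proteome Discoverer-style exports), species annotation
  and contaminant/ambiguous-PSM exclusion;
* log center-median normalization and the benchmark grid of **36 PSM
  filtering schemas** (Delta CN > {0, 0.2, 0.5} × co-isolation
  < {100, 50, 10}% × average reporter S/N ≥ {0, 10} × notch PSMs
  kept/removed);
* notch characterization: per-tag sub-notch fractions, automatic boundary
  detection, and redundant-PSM expected-intensity prediction
  (`r_j = Σ_c obs_j[c] / Σ_c top[c]`, predictions `r_j · top[c]`);
* aggregation to peptide/protein matrices (complete PSMs only, ≥ 2 PSMs
  per feature, summation);
* an empirical-Bayes moderated t-test with an intensity-dependent variance
  trend: posterior variance `s̃² = (d₀s₀² + d s²)/(d₀ + d)` with the prior
  df `d₀` from trigamma moment-matching and `s₀²(A)` from a robust loess
  of log s² on mean log2 intensity; Benjamini–Hochberg FDR;
* ground-truth scoring: TP = significant (q < 0.01) in the species'
  expected direction, FP = opposite direction, FN = non-significant,
  F1 = harmonic mean of precision and recall (no true negatives in a
  spike-in), plus paired with/without notch-filtering fold-change error
  comparisons.

## Worked example

```r
library(notchbench)

design <- build_mix_design()                       # 5/10/30 µg yeast per group
sim    <- simulate_experiment(design, sim_params(seed = 1234))
tab    <- center_median_normalize(sim$table)

filt <- apply_filters(tab, filter_schema(0.5, 10, 10), notch_region())
filt$report
#> $input_count
#> [1] 3216
#> $removed_by_metric
#>    delta_cn coisolation      avg_sn       notch
#>        1170         835         108           0
#> $output_count
#> [1] 1103

fm  <- aggregate_psms(filt$table, "protein")
res <- fit_moderated_test(fm)                       # 2x_vs_1x and 6x_vs_1x
classify_and_score(res, sim$truth)
#>   contrast n_features  tp fp  fn    f1 f1_human median_log2fc_yeast
#> 1 2x_vs_1x        274 148  0 126 0.701    0.577               0.773
#> 2 6x_vs_1x        274 274  0   0 1.000    1.000               2.194
```

Reading the output: under strict filtering, 274 proteins remain testable;
every 6-fold yeast change is recovered (F1 = 1), while the 1.06-fold human
change is the hard stratum (`f1_human` = 0.58 here, at this scaled-down
size). The median estimated yeast 6x/1x log2 fold change (2.19) sits below
the true log2 6 = 2.58 — the joint effect of co-isolation ratio
compression and median normalization on a strong spike-in, both discussed
in the methods vignette (`vignettes/notch-artifact-benchmarking.Rmd`).

The full study is scripted in `analysis/`:

| script | what it does |
| --- | --- |
| `01_simulate.R` | simulate the benchmark, write the PSM table + ground truth |
| `02_notch_characterization.R` | sub-notch fractions, boundary detection, redundant-PSM predictions, tag-vs-comparator differences |
| `03_filter_grid.R` | the 36-schema grid at protein and peptide level, F1 effect of notch removal |
| `04_notch_filtering_comparison.R` | paired fold-change error with vs without notch filtering on affected proteins |

Run them in order with `Rscript`; all tables land in `results/`. The same
chain is available as one call: `run_pipeline(default_config())`.

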