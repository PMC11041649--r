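# gazebias

Analysis of fixational eye movements as an index of covert attention to
items held in visual working memory.

When two items are encoded left and right of fixation and a non-spatial
retro-cue later indicates which one will be probed, microsaccades become
directionally biased toward the cued item's encoded location — a gaze
signature of the incidental use of space for memory selection. `gazebias`
implements the full analysis chain for this paradigm, for researchers who
work with 1000 Hz eye-tracking time series:

* a plain-text dialect for binocular gaze recordings with event markers,
  plus tidy CSV/JSON reporting;
* preprocessing: padded cubic-spline blink interpolation, seven-point
  calibration fitting, normalization to a ±100-unit stimulus frame
  (100 units ≡ 8°), epoching around the retro-cue with baseline
  correction, and the two trial-exclusion rules (gaze position beyond 50
  units; iterative mean + 4 SD response-onset outliers);
* microsaccade detection by adaptive velocity thresholding
  (median-based SD, elliptic criterion), toward/away classification, and
  rate / magnitude-resolved time courses in Hz;
* the **towardness** statistic,
  `T(t) = (mean_x_right-cued(t) − mean_x_left-cued(t)) / 2`
  (positive = gaze biased toward the cued side);
* group inference: cluster-based sign-flip permutation tests
  (maximum cluster mass, 0.025 per side), paired *t* with Cohen's
  *d* = |t|/√n, JZS (Cauchy-prior) Bayes factors for one-sample tests
  with prior-scale sensitivity (r = 0.5, 0.707, 1, 2), and a
  noncentral-*t* power-sensitivity solver;
* a synthetic session generator (drift + noise + direction-biased
  microsaccades + return saccades + blinks + calibration sweeps) with
  complete ground truth, so every stage is verifiable offline.

See `vignettes/gazebias-methods.Rmd` for the models, assumptions and
parameter choices.

## Worked example

Simulate a group, run the full pipeline and inspect the group statistics
(12 participants × 400 trials; allow a few minutes):

```r
library(gazebias)

cfg <- pipeline_config(
  experiment = 1, n_participants = 12,
  sim = sim_config(experiment = 1, n_trials = 400, block_size = 50),
  n_permutations = 2000, seed = 42)
bundle <- run_pipeline(cfg)
print(bundle)
#> <report_bundle> experiment 1, 12 participants
#> scalar condition contrasts:
#>        metric                   contrast         t df         p          d
#>    towardness sequential vs simultaneous 0.5372272 11 0.6018086 0.15508412
#>  saccade_rate sequential vs simultaneous 0.3206524 11 0.7544830 0.09256437

cl <- bundle$cluster_results[["towardness.sequential"]]$clusters
cl[cl$significant, ]
#>  start_ms end_ms sign     mass        p significant
#>       475    796    1 1684.266 0.001999        TRUE

bundle$bf_table[bundle$bf_table$metric == "towardness",
                c("r", "t", "bf01")]
#>        metric     r         t     bf01
#>    towardness 0.500 0.5372272 2.402084
#>    towardness 0.707 0.5372272 3.072251
#>    towardness 1.000 0.5372272 4.065346
#>    towardness 2.000 0.5372272 7.627695
```

Reading the output: the towardness time course carries a significant
positive cluster from 475 to 796 ms after the cue (permutation
p ≈ 0.002, the resolution of 2000 sign-flips) — gaze is reliably biased
toward the cued item's encoded side, emerging after ~300 ms and peaking
around 600 ms, exactly the structure the generator injects. The
condition contrast (sequential vs simultaneous encoding) shows no
significant clusters and Bayes factors of ~3–8 in favour of the null at
every prior scale: the spatial bias is equally present whether or not
the items could also be individuated by encoding order.

`write_bundle(bundle, "out/")` serialises the tidy tables
(`towardness.csv`, `saccade_effect.csv`, `behaviour.csv`,
`exclusions.csv`, `clusters.csv`, `bf_table.csv`) plus `summary.json`;
identical seeds give byte-identical output. A thin command-line wrapper
is included:

```sh
Rscript inst/cli/gazebias.R run-all --config cfg.yaml --out out/
Rscript inst/cli/gazebias.R simulate --config cfg.yaml --out out/
```

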