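# fretkin

Kinetic analysis of single-molecule FRET (smFRET) traces reporting on
aminoacyl-tRNA selection by the eukaryotic ribosome — the assay in which
the cyclic-peptide inhibitors didemnin B and ternatin-4 stall eEF1A in a
GTPase-activated (GA) intermediate state. The package is for
single-molecule biophysicists who want a tested, scriptable version of the
full analysis chain, and it ships a synthetic-trace generator so every
stage can be validated against known ground truth.

The reaction coordinate is modeled as a continuous-time Markov chain over
FRET states — codon recognition (CR, ~0.2 FRET), GTPase-activated
(GA, ~0.45) and accommodated (AC, ~0.7) — and the pipeline computes the
field's standard outputs:

* **Trace simulation**: Gillespie paths from labeled rate matrices
  `k_i→j` (s⁻¹), rendered into donor/acceptor intensities with camera
  frame integration, Gaussian FRET noise and single-step photobleaching.
  Presets carry the measured rate matrices for the control, didemnin and
  ternatin-4 conditions.
* **Idealization**: segmental k-means (SKM) training of a Gaussian-emission
  hidden Markov model with a compiled Viterbi decoder.
* **Dwell kinetics**: truncation before the first high-FRET dwell ≥ 150 ms,
  the count/occupancy estimator `k_i→j = N_i→j / T_i` with trace-level
  bootstrap errors (1,000 samples), a first-order missed-event (dead-time)
  correction, state lifetimes `1/k_i`, survival curves, and the
  GA→AC / GA→CR transition ratio.
* **Population summaries**: post-synchronized FRET contour histograms and
  transition density plots.
* **Dose–response**: accommodated fraction (high-FRET dwell ≥ 300 ms) per
  concentration and a Hill fit
  `f(c) = floor + (ceiling − floor) / (1 + (c/IC50)^h)` with bootstrap
  IC50 errors.
* **Slow kinetics**: censored exponential maximum likelihood
  (`k = events / summed observed time`) for minutes-timescale
  "sneak-through" accommodation and drug-washout rates from 1 Hz movies,
  with delta-method fold changes.

## Worked example

Simulate 500 molecules under saturating didemnin, idealize, truncate and
estimate the apparent rate matrix:

```r
library(fretkin)

scheme <- build_scheme("didemnin")
model  <- photophysics_model()        # 15 ms frames, FRET noise sd 0.06
traces <- simulate_traces(scheme, n_traces = 500, t_max = 10, model,
                          seed = 7, start_state = "low")

ideals    <- idealize_traces(traces)
truncated <- lapply(ideals, truncate_before_first_long_high)
dwells    <- dwell_table(truncated)

est <- estimate_rate_matrix(dwells, n_boot = 1000, seed = 8)
est <- correct_missed_events(est, dead_time = model$frame_period)
print(est)
#> Apparent rate matrix (s^-1) from 500 traces:
#>         low     mid   high
#> low  0.0000  2.2165 0.0039
#> mid  0.6030  0.0000 0.0648
#> high 0.2911 16.3994 0.0000
#> Per-state decay rates k_i (s^-1):
#>     low     mid    high
#>  2.2203  0.6678 16.6905

lt <- state_lifetimes(est)
cat(sprintf("GA lifetime: %.2f s; GA-to-AC / GA-to-CR ratio: %.3f\n",
            lt[["mid"]], transition_ratio(est)$ratio))
#> GA lifetime: 1.50 s; GA-to-AC / GA-to-CR ratio: 0.107
```

The generating didemnin matrix had `k_mid→low = 0.64`, `k_mid→high = 0.07`
(s⁻¹): the stalled GA state lives ~1.4 s and resolves toward accommodation
in only ~10% of its exits, and the 500-trace re-estimate reproduces both to
within a few percent. The same objects feed the ensemble views
(`postsynchronize()` + `contour_histogram()`, `transition_density()`), the
dose machinery (`simulate_dose_series()`, `accommodated_fraction()`,
`fit_dose_response()`), and the slow-rate fits
(`simulate_slow_process()`, `first_accommodation_times()`,
`fit_exponential_accumulation()`). `run_pipeline()` chains
simulate → idealize → truncate → estimate and writes a report bundle
(dwell TSV, rate JSON with provenance, TDP matrix);
`inst/scripts/fretkin-pipeline.R` is a command-line wrapper around it.

See the methods vignette (`vignettes/fretkin-methods.Rmd`) for the models,
conventions (censoring, truncation as a stopping time, missed-event
correction) and known limitations.

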