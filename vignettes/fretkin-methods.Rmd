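---
title: "fretkin: models and methods for smFRET kinetics of aa-tRNA selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fretkin: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretkin)
```

## The measurement and the model

During translation elongation, eEF1A delivers aminoacyl-tRNA to the
ribosomal A site. With a donor dye on the P-site tRNA and an acceptor on the
incoming ternary complex, single-molecule FRET reports the position of the
aa-tRNA along the selection reaction coordinate: codon recognition
(CR, ~0.2 FRET), the GTPase-activated state in which eEF1A docks at the
large-subunit GTPase activating center (GA, ~0.45), and the accommodated
classical state (AC, ~0.7). The cyclic peptides didemnin B and ternatin-4
trap the complex in the GA-like state; their kinetic signatures differ in
how often the trapped complex makes transient excursions toward
accommodation.

`fretkin` treats the reaction coordinate as a continuous-time Markov chain
over labeled FRET states. A `kinetic_scheme` is a rate matrix
$k_{i \to j}$ (s$^{-1}$) plus per-state FRET means; `build_scheme()`
provides the three measured condition presets (no drug, saturating
didemnin, saturating ternatin-4) with states indexed low (CR) / mid (GA) /
high (AC). These apparent rate matrices were measured on data restricted to
the interval before the first long high-FRET dwell, which matters for how
they should be compared against re-estimates (see *Truncation* below).

## Synthetic traces

No trace-level data accompany the published kinetics, so every downstream
stage is exercised on synthetic traces whose generating parameters are the
published rate constants. The generator has three layers:

1. **State path.** `simulate_state_path()` is an exact Gillespie
   simulation: the dwell in state $i$ is exponential with the total exit
   rate $k_i$, and the successor is $j$ with probability
   $k_{i \to j}/k_i$. Dwells occupy half-open intervals $[t_0, t_1)$ and
   tile the observation window; entering an absorbing state ends the
   stochastic part of the path.
2. **Frame integration.** A camera frame of period $\Delta t$ reports the
   occupancy-time-weighted mean of the state FRET means inside the frame
   (not the majority state) — this is what an integrating detector does,
   and it is the reason sub-frame excursions appear as intermediate FRET
   values rather than clean two-level steps.
3. **Photophysics.** Gaussian noise of sd $\sigma$ is added to the frame
   FRET, and donor/acceptor intensities are back-computed from a constant
   total so that `fret == acceptor/(acceptor + donor)` holds exactly (the
   standard uncorrected proximity ratio; no gamma or crosstalk corrections
   are modeled, since those add parameters the source data cannot
   constrain). Single-step photobleaching is modeled as independent
   exponential clocks per fluorophore; either bleach ends the usable trace,
   with no donor-only tail.

Defaults: $\Delta t = 15$ ms for the fast acquisitions and 1 s for the
slow-timescale movies — the two published acquisition settings; $\sigma =
0.06$, chosen so the simulated state distributions have widths comparable
to the ~0.25 FRET state separations seen in published population
histograms (the source reports no noise magnitude, so this is a package
default, configurable in `photophysics_model()`); ternary-complex arrival
is modeled, when requested, as a dark (zero-FRET) state exiting to CR at
0.5 s$^{-1}$, a realistic apparent pseudo-first-order rate for 20 nM
delivery (again not a published number). Reproducibility: one top-level
seed spawns per-trace integer substreams (`derive_seeds()`), so trace sets
are bit-identical under a fixed seed regardless of how they are split.

What the generator deliberately does **not** emulate: photon shot noise
(noise is Gaussian and state-independent), triplet blinking, spectral
crosstalk, intensity drift, or multi-step bleaching. Passing recovery tests
on these synthetics therefore demonstrates correctness of the estimation
pipeline under the stated noise model, not robustness to every artifact of
real recordings.

## Idealization (SKM)

Traces are idealized with the segmental k-means algorithm: alternate
Viterbi decoding (compiled, Gaussian emissions, ties toward the lower state
index) with maximum-likelihood re-estimation of the per-frame transition
matrix from the decoded path. Each half-step cannot decrease the joint
log-probability of path and data, so the iteration converges; it stops when
the decoded path is unchanged or the relative log-probability change falls
below $10^{-6}$ (cap 100 iterations, flagged if hit).

The default model has four states — dark (0), low (0.2), mid (0.45), high
(0.7) — so pre-arrival and post-bleach frames are absorbed by the dark
state instead of corrupting CR statistics; dark dwells are excluded from
all kinetics. Emission means and sds are *fixed* by default (the published
analysis reports fixed nominal FRET classes); re-estimation of emissions is
opt-in via `hmm_model(fixed_means = FALSE)`. The initial transition matrix
is weakly informative (self-transition 0.95, remainder split evenly) and
initial state probabilities are uniform; the initial distribution is not
re-estimated, which keeps the monotonicity argument exact. Frames with
non-positive summed intensity are masked (no emission term) rather than
decoded. A five-state variant with a hybrid-state mean (~0.3) can be built
through `hmm_model()` for steady-state pre-translocation data, but the
headline kinetics use the four-state model.

## Dwells, truncation and censoring

`extract_dwells()` run-length-encodes the idealized path into dwells with
`next_state` and a `censored` flag on the first and last dwell of every
trace (entry into the first dwell and exit from the last are not observed
in a real recording). The count/occupancy estimator
(`estimate_rate_matrix()`) computes

$$\hat k_{i \to j} = N_{i \to j} / T_i,$$

observed transitions over total occupancy. Censored dwells contribute
occupancy but no exit count. Two documented consequences:

* Right-censoring (last dwells) handled this way is unbiased for an
  exponential dwell.
* Dropping the *first* dwell's observed exit while keeping its occupancy is
  conservative and biases rates of states that often begin traces (CR when
  traces start at codon recognition) low by roughly one exit per trace —
  about $-15\%$ on $k_{1\to2}$ at the simulated trace lengths. The
  convention is kept because it matches the stated analysis convention;
  the truth-path tables produced by `truth_dwell_table()` do *not* flag
  first dwells (a simulated chain genuinely starts at $t=0$), which is what
  makes the estimator-only oracle exactly unbiased.

**Truncation.** The published rates describe dynamics *prior to the first
dwell in high FRET lasting 150 ms or more*.
`truncate_before_first_long_high()` implements this with an inclusive
threshold (10 frames at 15 ms) evaluated on idealized dwell durations. The
entry into the qualifying dwell is itself an observed mid-to-high
transition, and the truncation instant is a stopping time of the process,
so the truncated trace's final dwell keeps its observed exit into the high
state. Discarding that exit would bias $k_{2\to3}$ low by about the
fraction of mid-to-high transitions that commit (~10%), and would break the
martingale argument that makes the count/occupancy estimator unbiased on
truth paths. One caveat follows from the same argument: the truncation rule
conditions on *high-state* dwell durations, so high-state exit rates after
truncation are biased upward by construction (the long dwells are exactly
the ones removed) — on perfect paths by roughly +30%. The published
high-state rates were produced by the same protocol, so like-for-like
comparisons remain meaningful, but only the low/mid-state rates should be
read as estimates of the underlying chain.

**Missed events.** At 15 ms frames the high-FRET sojourns (mean 3–4
frames) are partially unresolvable: a sojourn much shorter than a frame
produces only an intermediate frame value that decoding attributes to the
surrounding state. Measured on synthetics, the raw pipeline recovers
$k_{2\to3}$ about 25% low for every preset, of which about 9 points are
the hard frame-integration limit and the rest the decoder's transition
penalty. `correct_missed_events()` applies the standard first-order
dead-time correction of dwell-time kinetics: a sojourn in destination
state $j$ survives detection with probability $e^{-k_j \tau_d}$, so

$$k^{\mathrm{corr}}_{i \to j} = k_{i \to j} \, e^{k_j \tau_d},$$

with dead time $\tau_d$ equal to one frame period and $k_j$ the apparent
decay rate of the destination state. There are no tunable constants. With
the correction the mid-state rates are recovered within ~5% for all three
presets (2,000 traces each); the fast high-state rates remain
frame-rate-limited and are only reliable to ~35%. Occupancy inflation from
absorbed short sojourns is second-order and neglected.

**Bootstrap.** All reported standard errors resample whole traces
(molecules) with replacement, 1,000 samples by default, matching the
published error model. `bootstrap_statistic()` exposes the same machinery
for arbitrary statistics; resamples on which a statistic is undefined are
dropped and counted, and more than 50% drops is an error rather than a
number.

## Population summaries

`postsynchronize()` aligns traces to the first appearance of FRET,
operationalized as the first non-dark idealized frame (fallback for models
without a dark state: first raw FRET > 0.12). `contour_histogram()` compiles
the 2-D occupancy of raw FRET versus time since synchronization,
column-normalized per time slice. `transition_density()` bins, for every
idealized transition, the dwell-mean *raw* FRET before and after the
transition — dwell means rather than model means so the emission noise
structure stays visible, matching the smeared appearance of published
transition density plots. Default grids: FRET in $[-0.1, 1]$ with 45 bins;
10 s contour window. The appearance threshold and bin widths are package
defaults (the source states neither).

## Dose–response

A molecule counts as accommodated when its idealized trace contains a
high-FRET dwell of at least 300 ms (inclusive; 20 frames at 15 ms).
`fit_hill()` fits

$$f(c) = \mathrm{floor} + \frac{\mathrm{ceiling} - \mathrm{floor}}
  {1 + (c/\mathrm{IC}_{50})^h}$$

by least squares on $\log_{10} c$ (a zero dose gets a surrogate one decade
below the smallest nonzero dose), with a multi-start grid — IC50 log-spaced
over the sampled range, $h \in \{0.5, 1, 2\}$ — and floor/ceiling fitted
rather than pinned, since drug-free escape is below 100%. Binomial
weighting is available but off by default (the published analysis states a
plain Hill fit). Working on $\log_{10} c$ makes the fit exactly
scale-equivariant: multiplying all doses by $\lambda$ multiplies the
fitted IC50 by $\lambda$. `fit_dose_response()` adds a trace-level
bootstrap (resample within each dose, refit from the point estimate) for
the IC50 standard error.

The dose-series *generator* needs one ingredient beyond the preset
matrices: the presets describe dynamics only before the first long
high-FRET dwell, so on their own they produce accommodated fractions of a
few percent and a nearly flat dose-response. Full accommodation
(peptide-bond formation) is irreversible, and
`build_accommodation_scheme()` models it as an absorbing `accommodated`
state (FRET mean 0.7, spectroscopically identical to transient AC) entered
from the transient high state at $k_{\mathrm{commit}} = 10$ s$^{-1}$ —
roughly two of five high-FRET excursions commit — chosen once so that
drug-free complexes accommodate within a few seconds, consistent with the
qualitative description of the uninhibited reaction, while didemnin-stalled
complexes rarely do within a 20 s window. Drug occupancy per molecule is
Bernoulli with the Hill probability $c^h/(c^h + \mathrm{IC}_{50}^h)$.

## Slow kinetics: sneak-through and washout

The minutes-timescale processes — accommodation under saturating drug
("sneak-through") and accommodation upon drug washout — are both modeled
as a single irreversible GA-to-AC conversion with hazard $k_{\mathrm{slow}}$,
rendered at 1 s frames (`simulate_slow_process()`); washout differs only in
the value of $k_{\mathrm{slow}}$, since dissociation is immediately
followed by fast accommodation and cycloheximide blocks the return path.
`first_accommodation_times()` reduces each trace to its first qualifying
high-FRET entry time, right-censored at the trace end; photobleaching is
censoring, never an event. A qualifying dwell must persist at least two
frames: at 1 s resolution a single-frame excursion is indistinguishable
from a noise outlier, and measured false single-frame events occur at a
rate comparable to the slowest true rates ($\sim 10^{-5}$–$10^{-4}$
s$^{-1}$), which would bias them badly — while true accommodation is
irreversible under cycloheximide and always persists to the movie end, so
the second frame costs nothing.

`fit_exponential_accumulation()` is the censored maximum-likelihood
estimator $\hat k = (\text{events})/(\text{summed observed time})$, with a
trace bootstrap SE; with zero events it reports only a 95% upper bound
($3/T$, the rule of three). `rate_fold_change()` propagates the two SEs by
the delta method.

## Numerical conventions

Times are seconds, rates s$^{-1}$, FRET dimensionless; frames are 0-based
and a dwell occupies $[\mathrm{start}, \mathrm{end})$. Duration thresholds
(150 ms, 300 ms) are inclusive and compared with a $10^{-9}$ s slack so
that integer frame counts hit them exactly despite binary floating point.
Transition matrices may contain exact zeros after re-estimation ($-\infty$
log-probabilities are handled by the decoder). States with zero occupancy
get `NA` rates, never zero. All randomness flows from explicit integer
seeds.

## Scale of the validation runs

The packaged tests and the acceptance script use problem sizes chosen to
give decisive statistics while staying desk-scale: 2,000 traces per
condition (10 s windows, 15 ms frames) for rate recovery; 8 doses × 500
traces (20 s windows) for the dose-response; 1,000 traces × 3,000 s at 1 s
frames for each slow-rate fit; 1,000 bootstrap samples throughout. The full
suite runs in a few minutes on one core.

## Known limitations

* Rates comparable to the frame rate ($k \gtrsim 0.3/\Delta t$) are
  recoverable only after the dead-time correction, and the high-state
  (AC) exit rates additionally carry the truncation selection effect;
  treat them as protocol-defined apparent rates.
* The Gaussian, state-independent noise model understates the
  heteroscedasticity of real proximity ratios at low total intensity.
* The dose-response generator's commitment rate is a modeling device with
  a stated default, not a measured constant; only quantities insensitive
  to it (the IC50 location, the Hill slope) should be read off the
  simulated dose series.
* No hybrid-state kinetics: the optional five-state emission model decodes
  hybrid FRET levels, but the kinetic presets do not include
  classical/hybrid exchange.
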