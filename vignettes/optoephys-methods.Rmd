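---
title: "Methods: quantifying optogenetic entrainment of hippocampal circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying optogenetic entrainment of hippocampal circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Sparse populations of long-range inhibitory, nNOS-expressing hippocampal
neurons project from CA1 to frontal regions such as the tenia tecta.
Driving them optogenetically changes three observable layers of the
system: the local field potential (power and phase of ongoing
oscillations, and coherence with downstream regions), the cellular layer
(firing patterns of the driven cells and the fast GABA~A~ / slow GABA~B~
currents they evoke in postsynaptic targets), and behavior (performance
on hippocampus-dependent object-location memory).  `optoephys`
implements the quantitative pipeline that connects a raw two-channel LFP
recording, a set of current-clamp sweeps, and a table of investigation
bouts to the summary statistics reported for such experiments: percent
change in band power and coherence at the stimulation frequency,
dominant theta frequency, the intrinsic-property battery, the
postsynaptic response classification, and the discrimination index with
its exclusion rules.

Because no raw recordings are available to ship, the package includes a
first-class synthetic-data generator with complete ground truth.  Every
stage of the pipeline is validated by parameter recovery against that
ground truth or against closed-form expectations.

# Multitaper spectral estimation

All spectral quantities are multitaper estimates.  Slepian (DPSS) tapers
of length $n$ and time–bandwidth product $NW$ are computed from the
standard tridiagonal eigenproblem; their concentrations are evaluated
exactly as quadratic forms with the sinc kernel
$S_{ij} = \sin(2\pi W (i-j)) / (\pi (i-j))$.  The power spectral density
is the mean of the $K$ per-taper eigenspectra, one-sided with interior
bins doubled, normalised so that $\sum_f S(f)\,\Delta f$ equals the mean
squared signal (Parseval).  There is no zero padding by default, so
$\Delta f = f_s/n$; padding is an explicit argument that changes the bin
centres and is recorded in the output attributes.

Magnitude-squared coherence pools tapered cross- and auto-spectra over
tapers and trials,

$$\mathrm{msc}(f) = \frac{\left|\overline{X_f Y_f^*}\right|^2}
 {\overline{|X_f|^2}\;\overline{|Y_f|^2}},$$

which is bounded in $[0,1]$, symmetric under channel exchange, and
invariant to linear rescaling of either channel.  With $m$ independent
cross-spectra the null bias is approximately $1/m$; the suite checks
this at 110 trials × 5 tapers.

## Choosing the time–bandwidth product

The tapers' spectral half-width is $W = NW/T$ Hz for a window of $T$
seconds.  Two different jobs require two different choices:

* **General spectra, spectrograms, and the theta/delta ratio** default
  to $NW = 3$, $K = 5$ — a conventional variance-reducing choice for
  exploratory spectra.  The ratio compares broad bands (5–12 Hz vs
  1–3 Hz), so the ±1 Hz smoothing is immaterial.
* **Stimulation-band measures** (`power_change_at_stim`,
  `coherence_change_at_stim`) default to $NW = 1.5$, $K = 2$ on the 3 s
  analysis windows, giving $W = 0.5$ Hz.  The analysis band is the 1 Hz
  interval centred on the stimulation frequency; with $W$ matched to the
  band half-width, a spectral line at the stimulation frequency delivers
  ~99% of its power inside the band.  With the $NW=3$ default instead,
  the line is smeared over ±1 Hz and only ~58% of its power lands in
  the band, biasing every percent-change estimate low by a factor of
  ~0.6.  Both settings are plain arguments; nothing is hard-wired.

The same resolution argument applies to localizing a spectral line in a
percent-increase spectrogram: on 1 s windows with 1 Hz bins, $NW = 3$
spreads the line over seven bins, and because the percent normalisation
divides by a $1/f$ baseline the resulting plateau tilts toward higher
frequencies.  The validation checks therefore localize with $NW = 1.5$,
$K = 2$ on the spectrogram windows; the default spectrogram settings are
unchanged.

## The theta bandpass

`bandpass_theta` is an even-order FIR design (Hamming window, ~1 s of
taps at 1 kHz, transition ≈ 3 Hz) applied forward–backward, giving
exactly zero phase — required for the phase-alignment visualisation of
averaged traces.  Edge transients are suppressed by symmetric reflection
padding.  The suite verifies unit passband gain (±5%), > 20 dB stopband
attenuation at 2 Hz, DC rejection, and zero lag.

# The in-vivo analysis chain

For each animal and stimulation frequency, traces are aligned to light
onsets into a 3 s pre-light (baseline) and a 3 s during-light window;
windows are half-open sample intervals and onsets whose windows fall
outside the recording are dropped and logged.

1. **Artifact rejection** (range rule): each trial's trace is the
   concatenated pre + during window; its range (max − min) is compared
   with a threshold of twice the mean range over *all* input trials.
   The threshold is computed once and trials are removed in a single
   pass — iterating would change the kept counts.  The full 6 s trial
   is used as "the trace" because removal is defined per trace before
   any window split; the multiplier and the window choice are
   configurable.
2. **Theta-state selection**: trials whose pre-window theta/delta ratio
   strictly exceeds 4.5 are theta-state trials.  The strict inequality
   is honoured exactly (a ratio of exactly 4.5 is not selected).
3. **Percent change in power**: band power in the 1 Hz band centred on
   the stimulation frequency (closed interval
   $[f-0.5, f+0.5]$) is computed per trial for both windows, averaged
   across trials, and the light value expressed as
   $100\,(P_\text{light}-P_\text{base})/P_\text{base}$.  Averaging
   precedes the ratio; per-animal results are aggregated afterwards,
   never pooled at the trial level.
4. **Coherence change**: trial-averaged msc over the trials common to
   both channels after QC (coherence needs paired trials; the
   per-channel kept sets are intersected), averaged over the band bins
   within ±0.5 Hz, expressed as percent change from baseline.
5. **Dominant theta frequency**: argmax of the trial-averaged PSD over
   5–12 Hz, refined by three-point parabolic interpolation around the
   peak bin and clamped to ±half a bin.  Exact ties break to the lower
   frequency and are logged; a flat spectrum returns a low-confidence
   flag.
6. **Differential spectrograms**: the trial-averaged 1 s / 0.1 s moving
   spectrogram of the baseline window is averaged over time per
   frequency bin; the during-window spectrogram is expressed as percent
   increase over that baseline vector.  Bins with zero baseline are
   flagged and excluded from maxima.  For identical pre/during input
   each frequency row averages to exactly 0%.

# The synthetic LFP generator

The generator emulates the statistical structure the analyses assume —
and only that structure:

* **Background**: $1/f^\alpha$ noise (default $\alpha = 1$) generated by
  spectral shaping of white Gaussian noise, with the target PSD known in
  closed form (`noise_scale` is $\sqrt{S(1\,\text{Hz})}$, default
  10 µV/√Hz).  The inverse-transform construction is exact under a
  seed.
* **Brain states**: a two-state renewal process with exponential dwell
  times (default mean 30 s in each state, matching extended theta bouts
  during exploration).  Theta states carry a 60 µV quasi-sinusoid at
  7.6 Hz; non-theta states a 40 µV slow oscillation at 2 Hz.  Both
  oscillators phase-diffuse at 0.9 rad²/s (Lorentzian half-width
  ≈ 0.07 Hz), so spectral peaks have a realistic nonzero linewidth.
  With these amplitudes the theta-state ratio sits near 17 and the
  non-theta ratio near 0.1, far from the 4.5 criterion on both sides.
* **Entrainment**: during light epochs of an opsin-positive session an
  additive sinusoid at the stimulation frequency is phase-zeroed at
  each pulse onset (for a pulse period of $1/f$ this is equivalent to
  phase-locking to epoch onset).  Its amplitude satisfies
  $A^2/2 = g \cdot B(f)$ where $g$ is `entrainment_gain` and $B(f)$ the
  *expected* baseline band power in the 1 Hz band (background integral
  plus Lorentzian line shares of the state oscillators weighted by
  state occupancy).  The analytic expectation of the downstream percent
  power change is therefore $100\,g$, which is what the recovery suite
  tests at $g \in \{0, 0.5, 1, 2\}$.
* **Second channel**: the tenia tecta channel mixes a configurable
  share (default 0.5) of the hippocampal signal into independent
  background noise, so baseline coherence is ≈ 0.25 and light epochs
  add a shared component only when entrainment is present.
* **Artifacts**: with probability 0.1 per trial, a 2000 µV square
  transient of 200 ms lands at a random offset within the trial —
  roughly ten times a clean trial's range, guaranteeing that the range
  rule's ground-truth comparison is meaningful rather than marginal.

What the generator does *not* emulate: spike-field interactions,
asymmetric theta waveforms, movement-related broadband shifts,
volume-conduction geometry, or any biophysical (conductance-based)
dynamics.  Passing recovery tests therefore demonstrates the
correctness of the estimators under the stated statistical model, not
the biological fidelity of the model itself.  Amplitude scales are free
parameters, not calibrated to any particular dataset.

# Current-clamp features

Sweeps follow the standard ladder (500 ms steps from −300 pA, 10 or
50 pA increments).  Features follow fixed definitions:

* **Spike detection**: upward $dV/dt > 20$ mV/ms followed by a peak
  above −10 mV, 1 ms refractory.  The criteria are arguments with
  logged defaults.
* **Threshold**: last negative-to-positive zero crossing of the
  smoothed second difference (Savitzky–Golay, 0.5 ms window, order 3)
  in the 4 ms before the upstroke's maximal $dV/dt$; if no crossing
  exists, the first point exceeding the $dV/dt$ criterion is used and
  flagged.  Raw second differences are noise-dominated at 20 kHz, so a
  local polynomial smoother is applied first; its width trades noise
  rejection against a small early bias (≈ 0.5 mV at the default ramp
  slopes), which stays within the 1 mV recovery tolerance.
* **Half-width**: full width at half maximum, with the half level at
  threshold + amplitude/2 and linear interpolation on both flanks.
  Spike amplitude is referenced threshold-to-peak (threshold is the
  only per-spike reference the definitions provide).
* **Sweep selection**: near-threshold = first step with more than two
  spikes; maximal firing = first step achieving the maximum count.
* **Adaptation ratio** $1 - \mathrm{ISI}_\text{first}/\mathrm{ISI}_\text{last}$
  and **ISI CV** (sample standard deviation / mean, reported ×100) are
  computed on the maximal-firing sweep.
* **Input resistance**: steady-state deflection (mean of the last
  100 ms of the step) versus injected current, through the origin, over
  hyperpolarizing spike-free sweeps.  The protocol for this quantity is
  not standardised, so window and sweep choice are explicit arguments.
* **Persistent (barrage) firing**: any off-phase spike across repeated
  (50% duty cycle, ≥ 300 pA) injections is a positive; a negative
  requires 100 spike-free repeats; anything less is indeterminate.

The synthetic spike template is piecewise — linear approach to
threshold, exponential rise (τ = rise/3), linear repolarisation whose
slope is solved from the requested FWHM, and an exponential
afterhyperpolarisation — so every generated feature is analytically
known.  ISI sequences realise the adaptation target exactly through a
geometric ramp; when a CV target exceeds the ramp-implied CV, an
alternating perturbation of the interior ISIs (first and last held
fixed) is scaled by root finding to hit it.  The recovery suite runs 50
randomised cells and requires: threshold within 1 mV, half-width within
2 sample intervals, adaptation within 0.05, CV within 2 points, input
resistance within 2%.

# Postsynaptic currents

With a high-chloride internal at −60 mV, GABA~A~ responses are inward
(negative) and GABA~B~ responses outward (positive).  Baseline is the
mean of the 50 ms before light onset.  The fast peak is searched 0–50 ms
post-onset and the slow peak 50–400 ms — windows placed around the
typical times to peak (≈ 6 ms and ≈ 134 ms) and exposed as arguments.
Classification uses the ±10 pA criteria exactly (a −9.999 pA deflection
is "none"); a qualifying fast inward response takes precedence.  The
0–63% rise time runs from the last baseline crossing before the peak to
the first crossing of 63% of the peak amplitude.  Amplitudes are meant
to be measured on sweep-averaged traces; validation uses constructed
biexponentials with 0.1 pA noise accordingly.

# Behavior

The discrimination index is
$100\,(t_\text{novel}-t_\text{familiar})/(t_\text{novel}+t_\text{familiar})$
over summed bout durations (time is scored, not bout counts).  Animals
are excluded when the encoding-day |DI| strictly exceeds 20, or when
total investigation in either phase falls below 3 s (object tasks) or
2 s (odor task) — "either phase" is read disjunctively.  The behavioral
generator assigns each bout to the novel object with probability
$(1+\text{preference}/100)/2$ and draws exponential bout durations, so
the expected retrieval DI equals the preference parameter and the
expected encoding DI is zero.  A single session's DI is noisy (sd ≈ 30
at 20 bouts), which is why recovery is asserted on cohort means.

# Validation problem sizes

The suite and the acceptance script size their simulations to keep a
full run in minutes on one core while leaving comfortable Monte-Carlo
margins: entrainment recovery uses 50 sessions per gain level with 40
epochs each; QC recovery 20 sessions; theta-state agreement 8 sessions;
coherence contrasts 6 sessions per condition; feature recovery 50
cells; behavioral recovery 400 sessions per preference level.
Validation sessions schedule epochs 10 s apart rather than the
protocol's default 30 s inter-epoch interval: the analysis windows
(3 s + 3 s around each onset) do not overlap either way, and the
shorter spacing simply packs more independent trials per simulated
second.  The generator's default remains the 30 s protocol spacing.

# Known limitations

* Taper settings used by any particular published analysis are rarely
  reported; exact reproduction of printed percentages from real
  recordings is not attempted anywhere — validation is against ground
  truth and closed forms.
* The entrained component is a pure additive sinusoid; real entrainment
  also reorganises ongoing rhythms (frequency pulling), which the
  generator only mimics through the dominant-frequency shift of the
  additive component.
* `classify_psc` assumes a stable baseline and a single evoked
  response per trace; trains of overlapping responses are out of scope.
* The persistent-firing call follows the fixed 100-repeat rule; it does
  not model the gradual build-up of barrage firing.
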