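---
title: "Models and methods behind ecslice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ecslice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecslice)
```

ecslice quantifies three levels of slice physiology in the
entorhinal-hippocampal system: single-cell current-clamp recordings of
Layer II principal neurons (fan cells of lateral entorhinal cortex,
stellate cells of medial entorhinal cortex), voltage-sensitive dye imaging
(VSDI) of evoked dentate gyrus and MEC network responses, and
cells-within-animals cohort statistics. Because such recordings are rarely
deposited, the package also contains simulators for all three data levels
with exactly known ground truth; every analysis stage is validated by
round-trip recovery against those simulators. This vignette documents the
models, the conventions chosen where published practice leaves latitude,
and what the synthetic data can and cannot establish.

## Single-cell feature extraction

**Input resistance and anomalous rectification.** Steady-state voltage
deflections of subthreshold current steps are fitted by the no-intercept
quadratic $\Delta V = R_{N,0}\,\Delta I + c_{AR}\,\Delta I^2$, where
$R_{N,0}$ (M$\Omega$) is the voltage-independent input resistance and
$c_{AR}$ (mV/pA$^2$) captures anomalous rectification. Steps that elicit
action potentials during the stimulus are excluded; the fit is ordinary
least squares and is checked in the test-suite against the closed-form
normal equations.

**Membrane time constant.** A double exponential is fitted to the onset of
the $-300$ pA response and the *larger* time constant reported. The fit
window spans the first 100 ms from stimulus onset and deliberately runs
*through* the voltage minimum of a sagging response: the double
exponential describes the charge-plus-sag trajectory exactly in the
linear regime, and it is the relaxation segment after the minimum that
makes the slow component statistically identifiable — truncating the fit
at the minimum leaves the slow time constant ill-determined whenever
charging is fast, and under measurement noise such truncated fits
collapse to a bound or to degenerate equal-time-constant solutions.
Fitting is bounded Levenberg–Marquardt (time constants in [0.1, 200] ms)
on the window block-averaged to 2 kHz, started from a grid of
time-constant pairs with amplitudes solved linearly; if no
double-exponential start converges the single exponential is reported
with a downgrade flag.

**Sag and rebound.** The sag ratio is
$(V_{baseline}-V_{ss})/(V_{baseline}-V_{min})$, with $V_{baseline}$ the
mean over the 100 ms before stimulus onset, $V_{min}$ the post-onset
minimum and $V_{ss}$ the mean over the last 200 ms of the step; 1 means no
sag, and stellate cells sit near 0.58. Extrema ($V_{min}$, the rebound
maximum, the post-step AHP minimum) are located on a 1-ms running mean of
the trace: the raw minimum of $n$ noisy samples is biased downward by
roughly $\sigma\sqrt{2\ln n}$, which at 20 kHz sampling would shift sag
ratios by several percent. The rebound is the post-offset
maximum (within 500 ms) minus baseline, and is reported missing when a
rebound spike intervenes. Window lengths are conventions — they are not
standardized in the field — and all of them live in a single
`ephys_config()` object that is serialized into every output.

**Action-potential waveform.** Spikes are detected as local maxima above
$-10$ mV preceded (within 2 ms) by a depolarization rate of at least
20 V/s. The threshold of an AP is the voltage at the maximum of the second
derivative in the 5 ms before the peak; the derivative is taken
analytically on a local cubic (Savitzky–Golay) fit of 0.4 ms width, which
emulates the common "fit-based" threshold estimators without committing to
a parametric spike model. Amplitude is peak minus threshold; half-width is
measured at 50% of that amplitude by linear interpolation between samples,
making it sample-rate independent, as is the per-spike width at 0 mV used
for train analysis. The fAHP is the minimum within 5 ms after the peak and
the DAP the maximum of the following 20 ms minus the fAHP; both are only
measured for MEC cells, and the DAP is reported missing when a doublet
spike falls inside its window. On sharp numerical waveforms the smoothed
threshold estimate can sit a few millivolts above the onset knot of the
generating waveform; the oracle test therefore uses an analytically smooth
waveform, where the estimator localizes the second-derivative maximum to
within one sample.

**Rheobase, trains, f-I.** The rheobase is the amplitude of the first
sweep of the 10-pA series (from 0 pA) with at least one detected spike —
consequently it is quantized to the 10 pA grid. Train features from the
+200/210 pA step are the interspike intervals, the ratio of the first two
ISIs, and the adaptation ratio (first ISI / last ISI, below 1 for adapting
trains). The average firing frequency of a step is the spike count divided
by the 1-s step duration, so silent steps contribute 0 Hz; $f_0$ and
$f_{ss}$ are the reciprocal first and last ISIs. The post-step AHP is the
post-offset minimum minus pre-stimulus baseline, for steps of 50–500 pA.

**Resonance.** The ZAP protocol injects a 15-s sinusoid sweeping linearly
0–20 Hz. The impedance profile is the spectral ratio of voltage to current
smoothed with a 0.5-Hz running mean; the resonance frequency is the
profile maximum inside [0.5, 20] Hz, with the lower band edge excluded as
resonance (the DC-adjacent region is where low-pass cells peak). Traces
containing spikes are rejected as not estimable rather than analyzed. The
chirp amplitude is configurable (default 40 pA) since published protocols
rarely state it.

**Quality control.** Cells are excluded when $V_m > -57$ mV, AP amplitude
$< 75$ mV, or bridge balance $> 22$ M$\Omega$ (strict inequalities), or
when manually flagged as putative interneurons; all violated rules are
enumerated, and the verdict is idempotent and order-independent.

**Liquid junction potential.** The generalized Henderson equation with
limiting equivalent conductivities gives the stationary junction potential
between pipette and bath, with the sign convention (bath minus pipette)
that makes the K-gluconate-internal/ACSF junction positive. Inorganic
mobilities are standard reference values; gluconate, HEPES,
phosphocreatine and nucleotide anions use published estimates of the kind
shipped with junction-potential calculators, and HEPES is taken 35%
ionized at intracellular pH. The shipped example solutions carry
temperature 34 °C because the junction forms in the recording bath, which
is held at 34 °C for such recordings; the function itself defaults to
25 °C when the temperature is unspecified. The computed value for the
standard solutions is near 15.3 mV at 34 °C (14.8 mV at 25 °C); values in
this range are sensitive at the ±1 mV level to the organic-anion mobility
table and the assumed HEPES ionization, which is why junction potentials
are conventionally reported to no better than about a millivolt.

## The model cell

The simulator is a *resonate exponential-integrate-and-fire* neuron — the
cheapest dynamical system that exhibits sag, rebound, subthreshold
resonance, spike-frequency adaptation and stereotyped spike shapes:

$$C\dot v = -g\,(v-E_L) - \textstyle\sum_k g_k w_k - z +
  g\Delta_T e^{(v-V_T)/\Delta_T} + I(t), \qquad
  \tau_k(v)\,\dot w_k = (v-E_L) - w_k,$$

with up to two H-current-like feedback variables $w_k$ and an adaptation
current $z$ that decays with $\tau_z$ and jumps by $b_z$ at each spike.
The relaxation times $\tau_k(v)$ interpolate sigmoidally between a fast
value in deep hyperpolarization and a slow value near rest, mirroring HCN
kinetics; this is what lets one preset show both a fast, deep sag at
$-300$ pA and a ~4.5 Hz resonance around rest. The activation drive
saturates a configurable few millivolts above rest
(`h_deactivation_mV`), mimicking HCN deactivation: without it the
feedback keeps accumulating during depolarizing steps and suppresses the
sustained spike trains the +200 pA protocol is supposed to elicit. When $v$ crosses the spike
threshold a stereotyped waveform (piecewise cubic smoothsteps through
threshold, peak, fAHP, optional DAP, reset) is written into the trace and
integration resumes from the reset voltage. Integration is forward Euler
at 0.05 ms in compiled code; measurement noise (default 0.2 mV SD,
Gaussian, white) is added to the finished trace, so the dynamics
themselves stay deterministic and the deterministic rheobase is exact.

The `phenotype_fan()` and `phenotype_stellate()` presets were calibrated
once, by derivative-free minimax search against the pipeline's own
measurements — averaged over simulations at the default measurement
noise, with a penalty on the across-seed spread of the fitted time
constant so that fit-degenerate parameter corners (which pass a
noise-free calibration but break under noise) are avoided — so that
extraction recovers the canonical population means (fan: $R_{N,0}$ 138 M$\Omega$, $\tau$ 28.9 ms,
sag 0.803, $V_m$ $-69.3$ mV, rheobase 70 pA on the 10-pA grid; stellate:
50.3 M$\Omega$, 13.3 ms, 0.580, $-64.7$ mV, 4.5 Hz resonance, rheobase
120 pA, fAHP $-51.6$ mV, DAP 1.9 mV). Because the calibration equates
*measured* features, the conductances and capacitances are effective
phenomenological values and should not be read as anatomical quantities;
one visible consequence is that the fan preset's impedance profile rises
mildly through the analyzed band, so its (unreported, untargeted)
resonance flag is positive even though real fan cells are at most weakly
resonant.
The spike-threshold parameter is set by bisection so that the emergent
dynamic rheobase — which is lower than the steady-state saddle-node
current whenever the sag conductances are slow — lands on the target
step. Preset variances are conventions: the published tables report
marginal means, not distributions, so between-cell variability in the
synthetic cohorts is chosen at levels a practitioner would call typical
rather than estimated from data.

What passing recovery tests does *not* show: the simulator has white
measurement noise, no electrode artifacts, no slow drift, no seal
degradation, and stereotyped spikes; robustness of the extractors to
those real-data pathologies is not established here, only their
correctness on well-formed traces.

## VSDI quantification

Movies are nominally 100×100 pixels × 512 frames at 1.0 ms/frame with the
first 50 frames as optical baseline and the stimulus after 50 ms; eight
trials are averaged. $\Delta F/F$ is computed per pixel against the
baseline mean, with the sign flipped so depolarization is positive (the
dye dims on depolarization); pixels with non-positive baseline are masked.
Filtering is a 3×3 spatial mean followed by an order-3, 5-frame
Savitzky–Golay temporal filter with proper asymmetric end windows — a
cubic-in-time signal passes through unchanged, which the tests assert.
The exact kernels of vendor analysis software are unpublished, so both
kernels are configurable and recorded in the provenance.

ROI activation is the trapezoidal area under the $\Delta F/F$ trace from
stimulus onset to the end of the recording (window configurable), averaged
over the ROI's voxels; the activated area is the number of pixels whose
post-stimulus *peak* exceeds 0.05% $\Delta F/F$ strictly; the paired-pulse
ratio divides the second-pulse amplitude by the first at a 25-ms
interval, measuring the second pulse against the $\Delta F/F$ level
immediately before it so that the overlapping decay of the first response
cancels (an absolute-peak mode is provided). Whether published pipelines
integrate the filtered or unfiltered trace is unstated; this one
quantifies the filtered movie.

The scene simulator composes isotropic Gaussian blade/CA3 footprints with
a difference-of-exponentials time course, chosen because every quantity
the pipeline measures then has a closed form. For two-pulse scenes the
second-pulse scaling is solved (on the noise-free trace) so that the
*measured* PPR equals the requested one — overlap between responses makes
raw amplitude scaling and measured PPR differ, and the design value is
the quantity tests should recover. The default scene's footprint
amplitudes and widths were set so the activated-pixel count sits at the
scale reported for wild-type slices (~1700 pixels).

## Cohort statistics

The cohort stage fits linear mixed models by REML through `nlme::lme`:
fixed factors genotype, age, sex and setup (plus declared two-way
interactions and, for repeated measures, the within-cell factor and its
genotype interaction), a random intercept per animal — cells from one
animal are not independent — and a selectable covariance structure for
repeated measures: independent, diagonal (heterogeneous variances),
compound symmetry, or unstructured. Structures are compared by
information criterion (AIC by default, BIC optionally) among converged
candidates, with ties broken toward fewer covariance parameters;
non-convergence triggers a recorded downgrade along unstructured →
compound symmetry → diagonal → independent.

Estimated marginal means are computed in this package from the fixed-effect
estimates: the reference grid over all fixed-factor levels is averaged with
equal weights over off-target factors (the SPSS-style EMM analogue), and
contrasts carry the denominator degrees of freedom that the fit assigns to
the target factor's marginal test. Exact numerical agreement with any
particular commercial implementation is not promised — the reference
degrees-of-freedom method is recorded in the output instead. No
multiple-testing correction is applied, matching the analysis convention
this pipeline reproduces; $\alpha = 0.05$.

Simulation-based properties asserted by the suite: in the balanced
zero-variance limit the fixed effects equal OLS to $10^{-6}$; a 0.03
genotype shift in sag ratio over 20+20 animals × 4 cells is covered by the
95% interval in at least 93 of 100 replicates; the null rejection rate
over 500 cohorts stays within binomial error of 5%; covariance selection
recovers the generating structure in the majority of replicates for both
compound-symmetry and strongly heterogeneous diagonal data.

The ΔΔC$_T$ genotyping helper computes
$(C_T^{tg}-C_T^{norm})-(C_T^{tg,ref}-C_T^{norm,ref})$ against a known
homozygous reference and calls genotype by the nearest of relative
quantity 0, ½ and 1 — the thresholds are a convention, with undetermined
targets called negative outright.

## Problem sizes and numerical choices

The test-suite runs 50 simulated cells per phenotype for recovery, 100
cohort replicates for coverage and 500 for the type-I rate, and
80×80–100×100 scenes for imaging recovery; these sizes put Monte-Carlo
error comfortably below the asserted tolerances while keeping the default
suite fast. Integration uses dt = 0.05 ms (refusing coarser steps);
level crossings are interpolated; the exponential spike current is capped
just above the cut voltage to make a missed crossing harmless; ROI and
stripe indices are validated against frame bounds, and stripes that exit
the frame are truncated with a warning rather than an error.

## Known limitations

No proprietary acquisition formats are read (HEKA Patchmaster/Chartmaster,
Brainvision); no voltage-clamp analysis; no image registration; no
automated interneuron classification (the QC flag is manual by design).
The simulators are phenomenological: they are ground-truth generators for
validating analysis code, not biophysical models of entorhinal neurons or
dentate circuitry, and parameter shifts (not pathology mechanisms) are the
only way they represent disease effects.
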