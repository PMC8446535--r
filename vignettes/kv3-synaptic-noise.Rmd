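---
title: "Quantifying Kv3-modulated synaptic noise, synchrony and presynaptic calcium"
author: "kv3noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Kv3-modulated synaptic noise, synchrony and presynaptic calcium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kv3noise)
```

## Scope

Fusiform cells of the dorsal cochlear nucleus sit in a continuous barrage
of spontaneous excitatory and inhibitory synaptic potentials — synaptic
noise — whose amplitude and frequency content shape when the cell fires
and how tightly neighboring units synchronize. Presynaptic Kv3 potassium
channels regulate that noise. `kv3noise` implements the complete analysis
chain such a study needs, together with seeded synthetic-data generators
that emulate each recording modality with known ground truth, so every
stage can be validated quantitatively without access to raw recordings.

The chain has six analytical parts: Morlet-wavelet band decomposition and
wavelet-filtered noise stimulus synthesis; spike and synaptic-event
detection with spike-triggered averaging; the jitter-based synchrony
index (JBSI); a Hodgkin–Huxley point membrane with a Kv3 conductance;
fluorescence puncta analysis; and co-localization plus shared curve
fitting and statistical corrections.

## Wavelet band decomposition

Membrane noise is band-limited by convolution with a Morlet wavelet, a
sine carrier under a Gaussian envelope:

$$MW(t) = a\,\sin(2\pi f t)\,\exp\!\left(-\frac{t^2}{2\sigma^2}\right).$$

The envelope SD is set from the required frequency-domain bandwidth,
defined here as the full width at half maximum of the kernel *power*
spectrum: $\sigma = \sqrt{\ln 2}/(\pi\,\mathrm{FWHM})$, with
FWHM = 0.75 Hz by default at every center frequency. (An
amplitude-spectrum FWHM convention would give a $\sqrt{2}$-wider kernel;
the power-spectrum convention is adopted because it is what
`morlet_fwhm()` measures and tests.) The amplitude $a$ is normalized so
a unit sinusoid at $f$ passes with gain 1, which keeps band amplitudes in
mV.

A single convolution with the odd-symmetric kernel shifts phase by 90
degrees, so `wavelet_filter()` convolves forward and backward; the two
passes cancel the phase and square the magnitude response, leaving unit
gain at $f$ and zero phase everywhere. Edges are reflection-padded and
the kernel half-length is reported as edge-contaminated.

Band amplitude follows the 6-SD convention: recordings are cut into 30 s
epochs and each epoch's peak-to-peak amplitude in a band is six standard
deviations of the filtered signal (`band_amplitude()`); a trailing
partial epoch is dropped.

Noise current stimuli are built by convolving a Morlet kernel with a
discrete-time Ornstein–Uhlenbeck (AR(1)) process
$X_{n+1} = \lambda_1 X_n + \lambda_2 \xi_{n+1}$ and rescaling so the
6-SD amplitude equals the requested peak-to-peak current
(`make_noise_stimulus()`). $\lambda_1$ defaults to 0.8; after the
narrow-band convolution it affects realization statistics only weakly.
Spike–stimulus coherence is implemented as phase locking: the modulus of
the mean unit phase vector of the stimulus analytic signal sampled at
spike times. Its null expectation for $N$ random spikes is
$\sqrt{\pi/4N}$. The original coherence reference is external to the
source study, so only this bounded vector-strength contract is promised.

## Synthetic synaptic noise and the 23/33 Hz spectral centers

`generate_psp_trace()` superimposes Poisson trains of EPSP-like and
IPSP-like difference-of-exponentials kernels on a −65 mV baseline with
white membrane noise. Defaults are the measured spontaneous rates (4.1
and 6.8 Hz). The kernel family is a modeling choice — the source
recordings constrain shapes only through two observations: mean EPSP and
IPSP waveforms whose power spectra are Gaussian-like with centers near
23 and 33 Hz, and band amplitudes that fall with frequency.

A difference of exponentials has a low-pass spectrum, so the 23/33 Hz
centers are only reproducible on waveforms that passed the 2–100 Hz
band-limited recording chain, which is how the study's own traces were
processed before event analysis. `mean_event_waveform()` therefore
band-passes (2–100 Hz, order-2 Butterworth, zero-phase) before averaging
event-aligned snippets, and `psp_spectrum_center()` fits a Gaussian to
the positive-frequency power spectrum. Kernel time constants were chosen
once by grid search against that oracle and frozen: EPSP rise/decay
0.8/3.0 ms (center ≈ 23 Hz), IPSP 0.4/1.0 ms (center ≈ 33 Hz).

Two consequences are worth stating plainly. First, these effective
kernels are band-limited shapes matching the measured spectral centers,
not biophysical membrane kinetics. Second, with these kernels the
*expected* band amplitudes over 3–40 Hz decrease monotonically
(0.071 → 0.059 mV at default settings) but the 3 vs 6 Hz difference is
under 1%, far below the ~15% per-epoch estimator SD, so tests assert the
resolvable content of the inverse amplitude–frequency relation — 3 Hz
clearly above 40 Hz and a negative trend — rather than strict sample
ordering of all five bands. In the real recordings the strong
low-frequency dominance comes largely from slow, non-synaptic membrane
components that this generator deliberately excludes (its events are
kernel convolutions only). The default membrane noise SD is 0.05 mV,
chosen so the synaptic component dominates every analysis band as it
does in the recordings; it is a free parameter of the emulation.

`psp_spectrum_center()` flags degenerate inputs: a spectrum whose
maximum sits at the lowest bins, or a fitted center below two Rayleigh
widths of the waveform window, cannot be distinguished from a DC/step
component and returns `ok = FALSE`.

## Spike detection and reverse correlation

Extracellular field potentials are conditioned with a second-order
elliptic 0.3–3 kHz band-pass applied forward–backward (0.1 dB ripple,
40 dB stopband — unstated in the source and fixed here). The detection
threshold is $Thr = k\,H$ with $H = \mathrm{median}(|fV|)/0.6745$, the
scaled median absolute deviation that estimates the noise SD while
ignoring the spikes themselves; $k = 5$ by default with 4 as the
conventional fallback. Peaks are local extrema above threshold in the
chosen polarity (negative by default for extracellular spikes), thinned
to a 1 ms refractory separation with larger peaks winning — sub-ms
doublets in field recordings are overlap artifacts.

Synaptic potential detection (`detect_psps()`) band-passes at 2–100 Hz,
demeans first (the −65 mV offset would otherwise drive large zero-phase
settling transients), excludes a 0.25 s edge guard, and thresholds each
polarity; thresholds default to $3H$ as a programmatic stand-in for
manual adjustment. Timestamp hygiene for paired recordings removes
target spikes within ±200 µs (closed interval) of any reference spike
(`dedup_timestamps()`), preventing a cell-attached unit from
contaminating the multi-unit trace.

`spike_triggered_average()` averages injected-current segments around
spike times and extracts features from the unfiltered average: the
pre-spike peak, the latency from peak to spike, and the maximum rising
slope of the pre-spike limb.

## The jitter-based synchrony index

For a synchrony span $W_s$ centered on every target spike, $N_c$ counts
reference spikes inside at least one window (half-open intervals decide
boundary ties). Each reference spike then gets a jitter window
$W_j = 2 W_s$, and

$$J = \sum_i \frac{|[\,r_i - W_s,\, r_i + W_s) \cap U\,|}{W_j},
\qquad JBSI = \beta\,\frac{N_c - J}{n}, \quad \beta = 2,$$

where $U$ is the *union* of synchrony windows: $J$ is the expected
number of coincidences if every reference spike were re-drawn uniformly
within its jitter window. Overlap is computed against the union to avoid
double counting when target spikes cluster. Identical trains give
exactly 1 (each jitter window overlaps its own synchrony window by
exactly $W_s$, probability one half), and the curve over spans 1–130 ms
is summarized by its maximum and the span at the maximum (ties to the
smallest span).

One boundary property deserves emphasis: for an evenly spaced train the
index equals 1 only while spans stay below two-thirds of the inter-spike
interval. Beyond that, neighboring synchrony windows enter each jitter
window, and once the span reaches the ISI the windows tile the whole
recording — jittering can no longer reduce coincidences and the index
falls to chance. This is intrinsic to the statistic (it is why empirical
JBSI-versus-span curves have interior maxima), not an implementation
artifact; `jbsi_oracle()`, an independent brute-force enumeration of all
window overlaps, agrees with the fast implementation to 1e−12 on
thousands of fuzzed instances. The index is also not clipped: degenerate
clustered-target geometries can push it below −1, which raises a warning
rather than silent truncation.

`generate_sync_pair()` builds the benchmarking geometry: an evenly
spaced 300-spike, 10 Hz reference and a target with a controlled number
of synchronous spikes (Gaussian jitter truncated to ±10 ms windows) and
asynchronous spikes placed uniformly outside all windows.

## The Kv3 point membrane

The membrane carries canonical Na⁺, delayed-rectifier K⁺ and leak
currents (conductances 120, 36, 0.3 mS/cm², rates shifted so rest is
−65 mV, leak reversal 10.6 mV above rest) plus a Kv3 current
$I_{Kv3} = g_{Kv3} n_{Kv3}^4 (V - E_{Kv3})$ with $E_{Kv3} = -81$ mV and
gate rates

$$\alpha = \frac{0.3\,(-(V - 4.18))}{e^{-(V-4.18)/6.43} - 1}
  \ \mathrm{ms^{-1}}, \qquad
  \beta = 0.011\, e^{(V - V_{rest})/80}\ \mathrm{ms^{-1}}.$$

Rates are per millisecond (per-second rates cannot produce
millisecond-scale action potentials) and conductance in mS/cm². The
$\beta$ exponent is referenced to rest so that $\beta(V_{rest}) = d$,
making the resting $n^4$ decay constant $1/(4d) \approx 22.7$ ms — the
mechanism behind the conductance remaining active for tens of
milliseconds after a spike; an absolute-voltage exponent (about twice
slower) is available behind `kv3_beta_ref = "absolute"`. The gate is
high-voltage activated: steady-state activation is below 0.05 at −65 mV
and above 0.9 at +40 mV, so Kv3 switches on late and fast during the
spike upstroke, deepens and prolongs the after-hyperpolarization, and
leaves the spike upstroke essentially untouched.

Integration is forward Euler, exactly as the update equation is posed,
with dt = 0.01 ms by default (halving dt moves spike peaks by well under
0.1 ms); gates are clamped to [0, 1] and a |V| > 200 mV excursion raises
an integration failure naming the step. The default $g_{Kv3}$ is
35 mS/cm², the top of the 0–35 range studied.

Measured behavior worth recording: with the default conductance the
after-hyperpolarization settles near −80 mV, 15 mV below rest, where
$\beta$ is smaller than at rest; the measured 1/e active duration of the
post-spike conductance is therefore ≈ 27.4 ms rather than the 22.7 ms
rest-potential arithmetic (or the ≈ 20 ms the rest-decay argument
suggests). The duration itself is defined as the time from the post-peak
conductance maximum until it first falls below 1/e of that maximum — a
definition this package supplies, since "active" has no numeric
definition in the source description.

Pulse-train experiments use rectangular 50 Hz, 100-pulse trains whose
per-pulse amplitudes carry ~5% Gaussian variability;
`calibrate_stimulus()` bisects the mean amplitude until the per-pulse
firing probability across training seeds reaches 95% ± 2 points (the
amplitude noise smooths the probability into a monotone function of
amplitude, which the bisection needs; without noise success is a step
function and a bracketing amplitude is returned with a warning). Because
the Kv3 conductance outlasts the 20 ms inter-pulse interval, residual
activation accumulates across the train: raising $g_{Kv3}$ at fixed
drive monotonically increases action potential failures, the central
qualitative prediction.

## Calcium puncta

`generate_calcium_stack()` emulates presynaptic bouton imaging: Gaussian
puncta on a dim background, a stimulus-locked transient (exponential
rise during a 2 s train, exponential decay after) on responding puncta, a
global double-exponential bleaching envelope, and Gaussian noise with
variance proportional to the local mean as a shot-noise surrogate (no
noise model is stated in the source). Default framing is 10 frames/s.

Analysis mirrors the imaging chain. `segment_puncta()` median-filters in
x, y and time (3 × 3 × 3), projects over time, thresholds at a robust SD
multiple and splits touching blobs by watershed on the masked intensity;
components that remain fused (single maximum after smoothing) are
flagged as merged when their intensity-weighted major/minor axis ratio
exceeds 1.15 — single puncta measure 1.0–1.08 on noisy synthetic stacks,
sub-resolution pairs above 1.25. `bleach_correct()` fits the double
exponential to non-evoked frames only and subtracts the decay terms
while keeping the constant offset, so `dff()` — division by the mean raw
pre-stimulation fluorescence — maps a flat trace to exactly 1; a fitted
component with a time constant far beyond the recording is folded into
the offset, and degenerate tau pairs fall back to a single exponential.

`classify_puncta()` offers the two published rules: a one-sided Wilcoxon
rank-sum test of evoked versus baseline frames at α = 0.05 (exact for
small tie-free samples, normal approximation with tie correction
otherwise), and the stricter 4-SD rule (maximum evoked fluorescence above
baseline mean + 4 SD). Window lengths per punctum are configuration
parameters; the source does not state how many frames entered its tests.

`fit_hill()` fits the four-parameter Hill function
$y = y_0 + a x^b/(c^b + x^b)$ to peak fluorescence versus stimulus
intensity and enforces the published acceptance gate r² > 0.85. The
"rising phase" for the linear slope is defined here as the intensity
interval where the fitted curve lies between 20% and 80% of its dynamic
range (the source shows regression lines without numbers).
`ensemble_bouton_correlation()` is the Pearson correlation between
ensemble peak fluorescence and responding-bouton counts across
intensities, with recordings combined by Fisher-z averaging.

## Co-localization

`manders()` uses the pixel-presence definition: the G coefficient is the
percentage of green-positive pixels that are also red-positive, R the
converse; the intensity-weighted original is behind `weighted = TRUE`.
`binarize_objects()` reproduces the binary chain — threshold (Otsu per
channel by default, the deterministic stand-in for an interactive
binarization), hole filling, 3 × 3 median, optional watershed splitting —
and `object_colocalization()` counts first-channel objects sharing at
least one pixel with any second-channel object, times 100 over the
first-channel object count. On synthetic punctate fixtures, toggling the
watershed moves the percentage by under five points, mirroring the
robustness check reported for the original analysis.

## Conductance curves and statistics

Voltage-step currents convert to conductance via a −85 mV theoretical K⁺
reversal and normalize to their maximum; `fit_boltzmann()` fits
$B(V) = a + (b-a)/(1+e^{(V_{50}-V)/c})$ and rejects non-sigmoidal data
(r² < 0.8). `generate_iv_dataset()` produces Boltzmann-true currents
with multiplicative noise; its default half-activation is −11.4 mV and
its slope factor 8 mV, a typical Kv3 activation slope (the source does
not print one). Fisher-z averaging (`fisher_mean_r()`), Holm correction
(`holm_correct()`, with plain Bonferroni reproducing the multiply-by-m
convention) and paired TOST equivalence testing (`tost_equivalence()`,
bounds on the paired mean difference, or on the test mean via
`scale = "mean"`) round out the statistics.

All nonlinear fits run Levenberg–Marquardt least squares directly on
residual functions, with fit quality judged by explicit r² gates.

## Problem sizes, determinism and limitations

Every generator takes an integer seed and is bit-reproducible, restoring
the global RNG state afterwards. Test and validation runs use desk-scale
sizes chosen to make each property resolvable: 10–120 s traces at 1 kHz
for band and event analysis, 10 s at 25 kHz for spike detection, 300 ms
single-spike and 2 s pulse-train simulations at dt = 0.01 ms,
48 × 48 × 50–60 stacks for imaging, 50-replicate Monte-Carlo recovery
studies, and 1000-instance oracle fuzzing.

What passing tests show — and what they do not: truth-scored recovery on
these synthetic inputs demonstrates that each algorithm implements its
stated contract, not that real recordings satisfy the generators'
assumptions. The generators omit slow non-synaptic membrane noise,
spike-frequency adaptation, imaging drift and registration error, and
optics; inputs are assumed registered, and no spike sorting, scalogram
analysis or calcium-to-spike inference is attempted. The Hill and
Boltzmann recovery precision quoted in the tests is what the stated
designs (7 intensity levels; 12 voltage steps) support at 5% noise, a
design property rather than an algorithmic limit.
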