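---
title: "Methods: echogram-based quantification of caged-school responses to noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: echogram-based quantification of caged-school responses to noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echoschool)
```

## The problem

A school of large pelagic fish (the motivating system is ~900 bluefin tuna of
~200 kg in a floating feeding cage, 50 m diameter by 28 m deep) is monitored
by an upward-looking 200 kHz single-beam echosounder mounted at 24 m depth,
with a 25 degree aperture at -3 dB. Acoustic stimuli — pure tones, synthetic
broadband signals, ship and wind-turbine playback, impulsive slaughter-tool
shots — are projected into the cage, and the question is whether and how
strongly the school reacts. `echoschool` implements the observation chain
that turns raw echograms into quantified, statistically testable behavioral
responses, plus a simulator that generates ground-truthed scenes so that
every stage can be validated by parameter recovery rather than by eye.

## Coordinates and containers

The canonical vertical coordinate is **range from the transducer face** (m);
depth below the surface is a derived report (`range_to_depth()`, clamped at
0 m so off-axis surface echoes, whose slant range exceeds the transducer
depth, never yield negative depths). Echograms travel in a plain-text
container (`read_egram()`/`write_egram()`): `# key: value` header lines and
one whitespace-separated row of dB values per ping, printed at 2 decimals —
enough for backscatter data, and bit-exact round trips for values produced
by the renderer. Missing samples use the sentinel -999 dB, ignored by every
metric. Stimulus schedules are CSV with half-open event windows
`[start, start + duration)`; overlapping windows are rejected at load.

## School envelope

Per ping, the school's average range is the center of mass of the
backscatter field over bins at or above a threshold (default -70 dB, not a
printed value; it sits well above the simulated noise floor of -85 dB and
well below fish echo levels):

$$\mathrm{com} = \frac{\sum_i r_i\,10^{v_i/10}}{\sum_i 10^{v_i/10}},
\qquad v_i \ge \mathrm{thr}.$$

Weights live in the **linear power domain**: the center of mass of a
physical intensity field. Whether the original analysis weighted in dB or
linear domain is not documented anywhere we could find; the linear choice is
recorded here once, and the gain-invariance property (adding c dB to data
and threshold leaves com and limits unchanged) is stated and tested for this
choice. School upper/lower limits are the extreme above-threshold bins after
removing above-threshold runs shorter than `min_run_bins = 2` (despeckle);
aggregation over windows is the arithmetic mean of valid per-ping values,
with a per-window valid fraction. Saturated samples are kept but counted; a
window with more than 20% saturated samples warns, reflecting the real
failure mode of a misconfigured digital gain.

## Traces

Echograms are binarized at a threshold, cleaned morphologically, segmented
into 4-connected regions, and filtered by size and mean echo level; the
survivors are fish traces. All morphology uses the 3x3 cross and one
iteration each of: *thickening*, *opening*, *closing*. Thickening is
implemented as a conservative compaction fill — background pixels with at
least two foreground 4-neighbours are set. The textbook (hit-or-miss)
thickening would grow an isolated pixel into a diamond that then survives
opening, defeating the stated purpose of the sequence (isolated noise pixels
must die in the opening); the compaction fill compacts staircase regions
without growing isolated pixels, and solid blocks pass through unchanged.

Trace **length** is the number of distinct pings; trace **tilt** is the OLS
slope of the per-ping maximum-backscatter range on ping index (ties at the
maximum resolve toward the transducer), in m/ping, positive = upward for an
up-looking transducer. Tilt is undefined below 3 pings. We deliberately do
not convert tilt to degrees: the field-reported tilt tables use units that
are not stated, so the package defines its own unit and never claims to
match those numbers. Ping index (not wall time) is the abscissa, so tilt is
per ping whatever the ping rate.

Window summaries count a trace in every window its ping span overlaps.
Assignment by start time or midpoint was tried first and discarded: a school
compressing during a reaction merges into long-lived regions that start
before the event window and would otherwise vanish from it.

## Scene simulator

The simulator is kinematic, not hydrodynamic. Fish orbit the cage axis at
`swim_speed` (default 1 m/s — trace durations in pings depend on it and on
the 0.5 s default ping interval; neither is a published value) with per-fish
orbit radius ~ N(12.5 m, 2.5 m) around the transducer offset (the transducer
sits at the middle of the cage radius, so orbits cross the beam). Per-fish
depth is

$$d_f(t) = D(t) + u_f\,\frac{\mathrm{extent}(t)}{4} + w_f(t),$$

with $u_f$ fixed standard-normal offsets (centered, so the school mean *is*
D(t) by construction), $w_f$ a slow Ornstein-Uhlenbeck jitter (sd 0.3 m,
tau 60 s), truncated to the cage. D(t) carries a 24 h sinusoid of
peak-to-trough `circadian_amplitude` (default 2.8 m, the day/night
difference reported for long-term cage monitoring), shallowest at midday;
day/night is defined by clock phase, not ephemerides.

**Reactions.** A trigger (event id, or source type + minimum level class)
moves the school state toward modified values after `onset_latency`:
mean range by `dive_delta` (the canonical dive magnitude, -3.3 m, is the
difference between the printed pre/post feeding-boat distances 12.2 m and
8.9 m), vertical extent by `contraction_factor` (13/19 matches the reported
contraction from 19 to 13 m), speed by `speed_factor`. The vertical
transition is a linear ramp at `tilt_bias` m/ping when given, otherwise an
exponential with `transition_tau`. The ramp is the model's tilt mechanism:
bounded per-fish vertical oscillation necessarily has zero time-averaged
slope, so a per-fish "wiggle" cannot leave a recoverable signed tilt in the
trace statistics; a coherent school ramp does, and every trace recorded
during the ramp inherits the slope. After the event the state relaxes back
with `recovery_time`. Habituation: the k-th repetition of the same trigger
responds with latency `onset_latency + k * habituation_increment`, and from
`habituation_max` (default 2) repetitions on, not at all — emulating the
respond-at-8-min / respond-at-11-min / no-response sequence reported for
repeated long emissions. During long emissions (>= `long_emission_s`) a
configurable number of fish (default 15, the reported count) reverse their
swimming direction.

**Rendering.** Each fish inside the beam cone (Gaussian one-way pattern,
-3 dB at the half aperture, cut at -15 dB; no sidelobes — only the -3 dB
aperture is documented) contributes at its slant-range bin with level
`ts + G(theta)` plus a sampled-volume normalization `(10 m / r)^2`.
The normalization makes a homogeneous school render range-independent
volume backscattering — without it the beam footprint growing as r^2
over-weights shallow fish and biases the center of mass by meters; the
10 m reference keeps the on-axis level of a single fish at 10 m equal to
its target strength. Per-fish target strength is N(-15, 3) dB, constant per
fish; only relative levels matter downstream. Fish are extended targets:
echo energy spreads over neighbouring bins with a Gaussian profile of full
width `echo_width` (default 1 m — body plus pulse envelope at 0.25 m bins).
Point (single-bin) echoes would be annihilated by the morphological opening
(a 1-px line has no interior under the cross) and are not physical for
200 kg fish. Contributions and a per-bin Gaussian-dB noise floor add in
linear power; values clip at `dynamic_range_max` with a clip count; the
range axis extends to `transducer_depth / cos(theta_cut)` so off-axis
surface echoes are kept. No TVG or propagation-loss modelling: values are
treated as already range-compensated Sv, which is what the analysis
consumes. All randomness flows from one integer seed; simulation and
rendering are deterministic given the config.

## Event tables, composite score, statistics

Per event, envelope and trace summaries are averaged over the event window
and over an equal-length baseline window immediately before it; the change
variables (d_com, d_extent, d_length, d_tilt) feed the composite score: PC1
of the z-scored changes (z-reference: background-class events when at least
3 exist, otherwise all events), sign-fixed so larger = stronger response.
Classes: |score| < 0.5 is B0 (none), < 2.0 is B1 (moderate), else B2
(severe), in baseline-SD units. The source material states the idea of a
PCA-derived linear combination but no formula, variables, or cut points;
these are package definitions, chosen once: 0.5 SD is below any convincing
response, 2 SD is an unambiguous departure.

SPL level classes are half-open bins: background < 120, low [120, 140),
medium [140, 150), high [150, 170), very_high >= 170 dB re 1 uPa; the
165-170 dB region that the published class labels leave ambiguous is
assigned to "high".

The ANOVA layer is authored, not delegated: unbalanced two-way ANOVA with
interaction and **Type III** sums of squares from an explicit sum-to-zero
design matrix (each term's SS = RSS increase when its columns are removed
with all others retained). Empty cells are handled by reducing the design to
its full-rank basis first, so interaction df shrink exactly as in the
published tables (e.g. df = 4 for a 7 x 4 design with missing cells) instead
of erroring. Levene's test uses deviations from group means (the classic
form). Tukey-Kramer pairwise comparisons use the studentized range on the
one-way residual mean square; homogeneous subsets are the maximal runs of
mean-ordered groups containing no significant pair — the presentation used
by standard post hoc tables. No attempt is made to reproduce published F or
p values: the underlying per-event data were never published.

## Acoustics

Hydrophone calibration is `p = V * 10^(-(sensitivity + gain)/20)` uPa. SPL
uses exponential RMS averaging (default time constant 1 s; the averaging
type is documented in the source material, the constant is not). Third-octave
levels use base-10 bands (centers `10^(n/10)`, edges `fc * 10^(+/-1/20)`)
computed by integrating a Hann-windowed periodogram over each band rather
than a 6th-order IIR filter bank: no filter-design library exists in the
supported dependency set, and the spectral route meets every stated check
(tone capture within 0.5 dB, adjacent bands >= 20 dB down, white-noise power
closure within 1 dB). Narrowband spectra are Welch averages (Hann, 50%
overlap); harmonic distortion is `10*log10(sum of harmonic powers /
fundamental power)` over small windows around each harmonic, the metric used
to flag loudspeaker super-harmonics. A minimal WAV reader/writer (PCM16,
float32) is included because no pre-installed package provides one; it is
round-trip tested.

## What the simulator does and does not establish

The generator emulates: circadian depth rhythm, circular schooling through a
fixed beam, stimulus-triggered dive/contraction/speed/tilt responses with
latency, recovery and habituation, direction reversal under long emissions,
beam-pattern and noise-floor rendering with saturation. It does **not**
emulate: orientation-dependent target strength, multiple scattering or
shadowing in dense aggregations, prey/feeding behavior, net avoidance,
multi-frequency response, or propagation loss. A green recovery test
establishes that the analysis chain measures what the model generates at
realistic geometry and noise — not that the model is tuna.

Known quantified limitation: a school whose vertical extent (default 19 m,
the pre-contraction value) spans beyond the observable water column
(transducer at 24 m, school centred near 12 m) is partially unobservable —
the night-time tail sits below the transducer and the day-time tail presses
against the surface. Measured on 48 h runs, this compresses the rendered
circadian amplitude by ~14% regardless of estimator, while a fully
insonified school (extent 10 m) recovers the amplitude within 1%. The
circadian recovery test therefore uses the fully-insonified scenario (the
long-term monitoring campaign it emulates is a different season and school
state from the exposure experiment that fixed the 19 m default), and the
envelope-tracking invariant is tested at the default extent over windows
where the school is observable. Scaled-down scene parameters in tests
(coarser pings for 48 h runs, sparse schools where individual traces must be
resolvable) are runtime and observability choices; the recovered quantities
do not depend on them.

Estimator caveat: the per-ping center of mass is a ratio estimator. With few
fish in the beam (sparse test scenes) its hourly mean carries a ~1 m
shallow-ward sampling bias; at the default 900-fish density the bias is
~0.1 m. Difference-based quantities (dive depth, contraction ratio,
circadian amplitude) cancel most of it, which is why the recovery criteria
are stated as changes.
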