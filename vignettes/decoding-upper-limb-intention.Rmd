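---
title: "Decoding upper-limb motion intention from EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding upper-limb motion intention from EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eegreach)
```

## The decoding problem

A transhumeral amputee retains shoulder motion but has lost the elbow,
forearm and hand. Two everyday actions — lifting the arm and reaching
for an object — begin with nearly identical shoulder trajectories, so
the residual limb alone cannot reveal which distal motion a prosthesis
should produce. `eegreach` resolves the ambiguity in two stages: the
*intention* stage classifies lifting / reaching / rest from scalp EEG,
and the *estimation* stage converts the decoded class plus the residual
shoulder-angle history into elbow-angle and hand-endpoint commands,
using relationships learned from healthy subjects.

Both stages are deliberately simple — linear-phase FIR filters, static
feature classifiers with delay embedding, and small sigmoid networks —
because a prosthesis controller must eventually run causally on modest
hardware.

## Stage one: features and classifiers

All processing starts from the common average reference,
$e_{\mathrm{car},i}(t) = e_i(t) - \tfrac1N\sum_{k=1}^{N} e_k(t)$,
which removes montage-wide noise and renders the channel sum exactly
zero (a property the tests assert sample-wise). Four per-sample feature
families are computed per channel:

| feature | definition | units |
|---|---|---|
| MRCP amplitude | 0.1–2 Hz bandpass of the CAR signal | µV |
| delta power | (0.1–4 Hz bandpass)² | µV² |
| alpha power | (8–12 Hz bandpass)² | µV² |
| running RMS | RMS over a trailing 400 ms window | µV |

The RMS window is causal: the value at $t$ uses the $N_a$ samples
ending at $t$ (200 samples at 500 Hz), with the shorter available
prefix before warm-up. A causal window is the only choice compatible
with eventual real-time control, and it fixes the ambiguity in where
the averaging window sits. By default the RMS is taken on the 0.1–4 Hz
band (the slow-activity range the other amplitude features occupy); a
`prefilter = FALSE` switch exposes the raw-signal RMS.

Filters are Hamming windowed-sinc FIR designs. The tap count is the
smallest odd integer of at least $3 f_s / f_{\mathrm{low}}$, capped at
a third of the recording length, so the transition band scales with the
lower edge: the 0.1 Hz slow-potential filter gets a long kernel, the
alpha filter a short one. Cutoffs sit at the conventional −6 dB points;
offline analysis applies the kernel twice with the group delay
compensated (`zero_phase`), giving squared magnitude response and no
lag, while `causal` mode implements the plain convolution a real-time
system would run. Zero-phase filtering reflect-pads by one kernel
length and trims afterwards, which suppresses the startup transient
that a 0.1 Hz-edge kernel would otherwise smear over tens of seconds.

Two channels per feature feed the classifier. The conventional montage
choices — FC2/C2 for the slow-potential, delta and RMS features, P3/Pz
for alpha — are pinned via the `override` argument of
`select_channels()`; without an override, channels are ranked by a
reproducible discriminability score (absolute class-vs-rest mean
difference over the pooled standard deviation, maximised over the two
movement classes, ties broken alphabetically so the result cannot
depend on input order). The score replaces by-eye selection from
feature plots with something auditable.

Each selected series is delay-embedded with $\Delta t$ = 250 ms and
three taps, so a two-channel feature yields six columns and the
combined set $4 \times 2 \times 3 = 24$. Rows exist only once two full
lags of history are available. Feature columns are z-scored with
statistics of the *training* partition only; the scaler travels with
the fitted model.

**The neural-network classifier** is one hidden layer of sigmoid units
(30; 80 for the combined set) with a sigmoid output rescaled to
$(-1, 1)$, trained by full-batch backpropagation on squared error
against targets +1/0/−1. The step size starts at 0.01 and adapts
deterministically: a step that would raise the loss is retried at half
size, an accepted step grows it by 10%. This keeps the recorded loss
trace non-increasing — a property the tests assert — and makes the
whole trajectory a function of (data, seed). Training stops after at
most 2000 epochs or once the per-epoch improvement stays below 1e-6
for ten consecutive epochs; the patience window matters because an
adaptive step can make individual epochs arbitrarily slow without the
fit being anywhere near converged. Continuous outputs are thresholded
at ±0.5 (the midpoint between adjacent class targets); values exactly
on a threshold tie to rest, the conservative choice for a prosthesis.

**The k-nn classifier** grid-searches $k \in \{1, 3, \dots, 25\}$,
metrics {Euclidean, cityblock, cosine} and two vote rules (plain
majority, and similarity-weighted with $\mathrm{Sim} = 1/(1+d)$),
minimising 5-fold cross-validated misclassification. Folds are
contiguous blocks: feature rows 50 ms apart are strongly correlated,
and interleaved folds would leak that correlation into the loss.
Selection ties prefer smaller $k$, then the earlier metric. Vote ties
go to rest when rest is among the tied classes, else to the smallest
class code — fixed rules, so predictions are reproducible and an
independent brute-force oracle can be checked against them exactly.

The 80/20 train/test split is chronological (first 80% train) for the
same leakage reason: with overlapping lagged windows, a random split
would place near-duplicates of training rows in the test set.

**Gating.** The final output is rest whenever the residual-limb
detector says the shoulder is not moving; otherwise the classifier's
class passes through. The detector median-filters the shoulder angle
(5 samples), takes finite-difference speed, and requires
|speed| > 10°/s sustained for 200 ms. The threshold is far below
movement speed (~45°/s mid-trial) and far above band-limited capture
jitter; the hold window rejects transients, and the median kills
single-sample glitches. Movement labels for training and scoring use
the same detector, from the first to the last flagged sample after
each cue — the labelling rule is therefore a stand-in definition of
"movement onset/offset", stated openly as such.

## Stage two: motion estimation

`build_motion_database()` pools one record per (strided) EEG-rate
sample inside each labelled span — class code, shoulder angle at lags
0/250/500 ms, elbow angle, endpoint (x, y) — plus a 250 ms rest margin
so estimators also see the resting posture. Estimators are
10-hidden-unit sigmoid networks with linear outputs, inputs min-max
scaled to [0, 1] by training statistics, targets standardised
internally (population scale, so duplicating records leaves the
full-batch fit bit-identical) and returned in native units, clipped to
the training range ±10%. Training is leave-one-subject-out: the
excluded subject's records are absent from both the fit and the
scalers, which a test audits by id.

The estimators train with iRprop+ (per-weight sign-based adaptive
steps) rather than the plain adaptive-step descent used for the
intention classifier. The regression surface is stiff — the reaching
elbow dips ~70° within the first 20° of shoulder travel and the rest
of the surface is nearly flat — and plain descent needs roughly five
times the epochs to reach the same held-out error. iRprop+ is still
full-batch backpropagation and still an exact function of (data,
seed).

## What the synthetic generator does and does not emulate

The generator reproduces the statistical structure the pipeline
assumes, with every parameter in `synthetic_config()`:

- **Protocol**: 10 s rest lead; 20 cues (10 per class, random order);
  gaps drawn from {5, 6} s; EEG at 500 Hz, capture at 120 Hz, linearly
  resampled to the EEG clock.
- **EEG**: independent 1/f background on all 16 channels (RMS 1.5 µV);
  an event-locked negative half-cosine on FC2/C2 rising through the
  1.5 s before movement onset and decaying over the movement, peak
  −8 µV (lifting) / −12 µV (reaching) with class-specific lateral
  spread; a 10 Hz alpha rhythm of 10 µV on P3/Pz attenuated to a 0.4
  amplitude factor during movement, with a small class-specific P3/Pz
  asymmetry. The asymmetry is needed for the alpha feature to carry
  *class* information at all — symmetric attenuation would make alpha a
  pure movement detector, and movement is already observable from the
  limb. The signature strengths were fixed once so that gated
  accuracies land in the 60–85% band that separates "decodable" from
  "trivial"; `difficulty` scales all of them, with `difficulty = 0` a
  null world containing no class information.
- **Kinematics**: minimum-jerk shoulder excursion to 90° starting
  0.4 s after the cue, return mirroring outbound; lifting keeps the
  elbow at 175° with the endpoint on the extended-arm arc; reaching
  follows a dip-then-extend elbow template (minimum at 20° of shoulder
  travel) and an endpoint that reaches its plateau within the first 20°
  and stays there, retracing the same curves on the way back. Angle
  noise is Gaussian with σ = 0.5° but band-limited below ~8 Hz:
  white noise at the capture rate would imply physically impossible
  instantaneous velocities and defeat any velocity-threshold detector,
  which is a statement about real capture jitter, not a convenience.

Not emulated: volume-conduction head models, EOG/EMG artifacts,
electrode drift, inter-subject topography differences, or
non-stationary background statistics. Passing tests therefore show the
pipeline is correct and sensitive *under its own assumptions* — they
say nothing about artifact robustness on real recordings, and the
inter-subject transfer result is easier here than in reality because
all synthetic subjects share the same underlying templates.

## Numerical and degenerate-input choices

- Half-open label spans and 0-based sample times avoid fencepost
  ambiguity; a one-sample movement window is exactly one sample long.
- Weight initialisation is uniform in ±1/√(fan-in + 1) from a local
  RNG stream (`with_seed`), so generation and training never perturb
  the caller's RNG state.
- Single-class training labels raise `"degenerate labels"`; a
  single-channel recording has no common average (`"CAR undefined"`);
  a bandpass with its upper edge at or above Nyquist, a window longer
  than the signal, and a signal shorter than three kernel lengths are
  all rejected with specific errors rather than mangled.
- Zero-variance feature columns scale by 1 instead of 0/0.
- Reported accuracies round half-up to one decimal; table aggregation
  uses the population SD (divide by N), matching the convention of
  study summary tables and error bars.

## Problem sizes

The test suite decodes 8-trial sessions (~54 s) for feature-level
checks and one full 20-trial session end to end; the motion tests use
three 8-trial subjects, and the acceptance-level recovery check five
full-protocol subjects with a stride of 10 on the database (50
records/s). The acceptance script runs the five-subject study at the
full 20-trial protocol with 20 classifier decisions per second. These
sizes were chosen as the smallest that leave every statistical
assertion comfortably powered.

## Known limitations

- Accuracy is scored per sample over the chronological test segment;
  per-trial-event scoring would weight long and short movements
  differently and is not implemented.
- The per-subject chance levels of the evaluation module (prior-max
  and permutation) are two defensible conventions; neither is claimed
  to match any particular published chance computation.
- The EDF writer quantises to 16 bits; exact round-trips are only
  guaranteed by the delimited-text session dialect.
- Stage two emits endpoint coordinates; converting them into joint
  commands for a specific prosthesis requires an inverse-kinematic
  model that is out of scope here.
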