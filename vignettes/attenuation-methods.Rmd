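---
title: "Quantifying attenuation of responses to self-generated sounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying attenuation of responses to self-generated sounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfsound)
```

## The problem

When an animal produces a sound with its own movement — here, a head-fixed
mouse pressing a lever that triggers a brief white-noise burst — auditory
cortical responses to that sound are weaker than responses to the
physically identical sound played at random times. This *sensory
attenuation* is thought to be driven by corollary-discharge signals from
motor cortex, and its magnitude is a phenotype of interest in models of
schizophrenia risk. `selfsound` implements the complete spike-train
analysis needed to quantify it from sorted extracellular recordings: event
selection, evoked-response profiling, a modulation index, waveform-based
cell typing, detection of optogenetically evoked responses, and
hierarchical-bootstrap inference — together with a synthetic-session
generator that provides ground truth for every stage.

## Measures and models

**Evoked amplitude.** For each retained sound, the response is the mean
firing rate 10–50 ms after onset minus the rate in the 200 ms before
onset. A unit is *auditory responsive* when, for either sound class, its
trial-averaged amplitude is at least twice the standard deviation of the
trial-averaged rate across the 5 ms bins of the baseline window
(inclusive threshold). A unit with a perfectly silent baseline has an
undefined z-score; by convention it is responsive only if its amplitude
is positive and backed by response-window spikes on at least 25% of
trials. This convention is an artifact of finite recordings and is
flagged in the profile.

**Modulation index.** With mean amplitudes \(S\) (self-generated) and
\(R\) (random),

\[ \mathrm{MI} = \frac{S - R}{S + R}, \]

so \(-1\) means response only to random sounds, \(0\) equal responses.
The index inverts to a percent reduction
\(100\,(1 - (1+\mathrm{MI})/(1-\mathrm{MI}))\): an MI of \(-0.25\)
corresponds to a 40% smaller self-generated response, \(-0.08\) to about
15%. Units with \(S + R = 0\) are dropped from MI summaries; negative
amplitudes (suppression) can push the index outside \([-1, 1]\) and are
retained but flagged.

**Event selection.** Both sound classes are subject to a 1 s refractory
rule — the gap to the immediately preceding sound of *any* type,
measured onset-to-onset against the full physical stimulus sequence,
must be at least 1 s — because adaptation depends on stimulus history,
not on which sounds an analyst later keeps. Random sounds are further
required to match the behavioral state of self-generated ones; the
default rule keeps a random sound only when the immediately preceding
sound was self-generated (alternatives: within a configurable window
before a press, or while the lever is held). A random sound with no
predecessor is excluded, since the predecessor condition cannot be
verified. Experience blocks are defined on the ordinal sequence of self
sounds (first 300, next 300) with a laxer 0.5 s refractory to keep
sessions analyzable; sessions with fewer than 400 self sounds, or
blocks retaining fewer than 20 sounds of a class, are excluded.
Preparatory-activity analyses use presses at least 2 s after the last
sound. The refractory gap is taken onset-to-onset; the 100 ms stimulus
duration makes the offset-to-onset alternative differ by one bin width
and was not adopted.

**Preparatory activity.** Pre-press firing is summarized in 100 ms bins
over the final second before the press, referenced to the rate in the
−1000 to −900 ms bin; the headline statistic is the mean change over the
final 200 ms. The 100 ms bin width matches the reference and summary
windows' arithmetic.

**Cell typing.** From each mean waveform (495 µs before to 1287 µs
after the trough; 33 µs sampling in the generator) two features are
extracted: trough width at half-minimum (baseline-referenced to the
mean of the first five samples, crossings interpolated linearly) and
trough-to-peak time. A two-component full-covariance Gaussian mixture is
fit to all units pooled across genotypes; the narrow component (smaller
mean trough-to-peak) is labeled putative interneuron. Units with
maximum posterior below 0.95 are `unclassified` — equivalently, the
probability of the other class exceeds 0.05. We use `mclust`'s
deterministic model-based agglomerative initialization, which makes
assignments invariant to unit order without explicit seeding; a
degenerate fit is retried with a covariance prior and, failing that,
every unit is returned unclassified.

**Optogenetic mapping.** Light responses are assessed on a PSTH from
−100 to +100 ms around light onset in 5 ms bins, as the rate change
ΔFR of each post-onset bin relative to the mean pre-onset rate. The
null distribution is built from 1000 surrogate PSTHs: each draws as
many 200 ms segments as there were light pulses from the session's
baseline periods (times at least 200 ms from any post-light epoch),
treats the first half of each segment as baseline and the second as
response, and contributes 20 ΔFR values; all 20,000 values are pooled,
which gives p-value resolution below 0.001. A bin's p is the fraction
of null values at least as extreme in the direction of its own ΔFR
sign. Latency is the *end* time of the first bin with positive ΔFR and
p < 0.001 — under this convention a 10 ms cutoff admits exactly the
first two bins. Excitatory (monosynaptic-proxy) labels require latency
≤ 10 ms for terminal stimulation (15 ms for somatic) and at least ten
spikes in the latency bin; inhibitory labels require three consecutive
suppressed bins with p < 0.05 within the first 50 ms and at least 20
baseline spikes. Surrogate segment starts are drawn on the 5 ms grid,
so surrogate binning matches PSTH binning and each segment costs O(1);
segments may overlap one another, as nothing in the procedure requires
disjointness.

**Hierarchical bootstrap.** Comparisons between genotypes resample
animals with replacement, then each drawn animal's units with
replacement (the animal's own count), and take the pooled mean; 1000
replicates per group, paired by index. The p value is the proportion of
replicate pairs whose difference is zero or opposite in sign to the
observed difference — a directional quantity that concentrates on
(0, 0.5] under the null. Calibration on simulated nested nulls shows
the doubled p is close to uniform but mildly *conservative* (KS
distance ≈ 0.09 at nine animals of ten units): the two-level resampling
counts within-animal variance once in the animal-level resampling and
again in the unit-level resampling. This is a property of the procedure
itself, so our calibration tests bound the distance from uniformity and
require that false-positive rates are never inflated, rather than
testing exact uniformity, which any consistent check would eventually
reject.

## The synthetic-session generator

Every downstream stage is validated against sessions produced by
`simulate_cohort()`. Each unit is an inhomogeneous Poisson process built
from non-negative components, sampled independently by superposition:

* a homogeneous baseline with rate drawn from a log-normal
  (default meanlog \( \log 4 \), sdlog 0.6 — median 4 Hz, matching
  typical cortical regular-spiking rates);
* an evoked transient uniform over 10–50 ms after every sound, of
  amplitude 20 Hz (random sounds) scaled by the attenuation factor
  \(a\) for self-generated sounds, and by the adaptation gain
  \(g(\Delta t) = 1 - A e^{-\Delta t/\tau}\) (defaults \(A = 0.5\),
  \(\tau = 0.3\) s) where \(\Delta t\) is the time since the previous
  sound of any type — an exponential-recovery form chosen as the
  simplest law with the right magnitude and time course;
* a linear ramp from zero at 0.6 s before each press to 3 Hz at the
  press, emulating preparatory activity.

Behavior is bout-structured: geometric bout lengths (mean 15 presses),
uniform 2–6 s inter-press intervals, 30–120 s pauses, random sounds
every 5–10 s, two-hour sessions — which yields well over the 250
presses per session used as a training criterion, and several hundred
retained sounds per class. The attenuation factor may be a scalar, a
per-genotype vector (defaults WT 0.60, mutant 0.852, the values whose
analytic MIs are −0.25 and −0.08), or a function of depth, genotype and
sound ordinal, which is how depth-graded and experience-dependent
attenuation are simulated. Waveforms are biphasic Gaussian
trough-plus-peak shapes with class templates (broad 700/300 µs,
narrow 300/150 µs trough-to-peak/half-width, 10% SD, 14% narrow
fraction). Opto sessions deliver 100 ms pulses every 2–3 s for 600 s;
directly excited units exist only below 600 µm, with per-unit latency
drawn from 2–8 ms, 0.4 ms jitter, and 1.5 evoked spikes per pulse;
inhibited units are thinned to 15% of baseline for 40 ms from 10 ms
after onset. The generator's trial-to-trial variability is pure Poisson
noise: real recordings have slow rate drift, bursting, correlated
noise, and sound-level nonstationarities that it does not emulate, so
passing tests demonstrate correctness of the estimators under the
stated model, not robustness to every property of real data.

## Numerical and design choices

* With the ramp on, self-sound baselines (the 200 ms before the press)
  contain the rising ramp, which lowers measured self amplitudes and
  makes the measured MI more negative than \((a-1)/(a+1)\). This is a
  real property of the measurement, not a bug; parameter-recovery
  checks therefore run with the ramp off (isolating the auditory
  pathway), and recover the analytic MI to within ±0.03 over
  \(a \in [0.25, 1.25]\) at the default SNR. Recovery cohorts use nine
  animals per genotype and twenty units per animal — enough for about
  180 responsive units per genotype and two-hour sessions with more
  than 200 retained sounds per class, while keeping a full run in tens
  of seconds.
* PSTH bins are half-open \([lo, hi)\); a spike exactly at an event
  time belongs to the first post-event bin. Depth bins are likewise
  half-open with the deepest edge closed, so a unit at exactly 1100 µm
  counts in the 900–1100 µm bin.
* Ties in the rank-sum classification use the normal approximation
  (`exact = FALSE`); with two trials per class no two-sided rank-sum p
  can fall below 0.05, so such units are `ns` by construction.
* The paired-pulse ratio is the ratio of trial-averaged responses
  (second over first, both baseline-referenced to the window before the
  first sound) rather than the average of per-pair ratios, which is
  unstable when single-trial first responses are near zero; 100 ms
  intervals are excluded from summaries because first responses can
  outlast 100 ms.
* Population summaries of the MI are computed over auditory-responsive
  units only.

## Known limitations

Spike sorting, raw-signal preprocessing, and anatomy are out of scope —
the pipeline starts from sorted spike times and an event log. The
Poisson generator cannot probe robustness to non-Poisson variability.
The surrogate-null classifier's false-positive behavior is guarded by
spike-count thresholds, but very high-rate units with strong slow drift
could still produce spurious inhibitory labels; the no-opsin control
analysis (`generate_opto_session(opsin = FALSE)` through
`opto_map_session()`) is the recommended check on real data.
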