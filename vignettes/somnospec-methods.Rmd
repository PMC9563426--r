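---
title: "somnospec: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{somnospec: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

somnospec analyses rodent polysomnography recorded as multi-channel EEG
(frontal and parietal screw electrodes, left and right) plus a 3-axis
head-mounted accelerometer, over the 12-h lights-on period (zeitgeber time
0–12) when mice do most of their sleeping. The pipeline stages are: Welch
spectral estimation per 1-s epoch, automatic wake/NREM/REM staging,
band-power quantification with outlier exclusion and median normalization,
sleep-architecture metrics, and a gated two-group statistical layer for
genotype comparisons. Because no public recordings accompany the design, a
ground-truthed simulator generates cohorts on which every stage is
validated end to end.

## The vigilance-state model and the simulator

Sleep in rodents alternates among three states. The simulator draws a
semi-Markov chain: the next state comes from a 3×3 zero-diagonal
transition matrix, the dwell time from a state-specific log-normal
distribution truncated to at least 1 s and rounded to whole seconds, and
the final bout is clipped so bouts tile the recording exactly. The chain
starts in wake, since animals are handled into the recording box.

Default dynamics (wild type): dwell means of 30 s (wake), 26 s (NREM)
and 19 s (REM) with a coefficient of variation of 0.7; wake always enters
sleep through NREM; NREM exits split evenly between waking and REM; REM
usually ends in an awakening. These values put the three states near
44%/41%/15% of the lights-on period with a REM share of sleep at the
upper end of what is reported for lights-on mouse sleep, and they sit at
the fragmented end of published bout statistics (mouse bouts scored at
1-s resolution are routinely tens of seconds). A fragmented baseline is
deliberate: state proportions then stabilize quickly within an analysis
window, so per-animal summaries are dominated by physiology rather than
by the luck of a few long bouts. The dwell law is log-normal because
rodent bout durations are strongly right-skewed.

Each EEG channel is a sum of (i) 1/f-shaped background activity
(power ∝ 1/f², amplitude 0.3) plus a broadband noise floor (SD 0.3)
standing in for electrode/amplifier noise, (ii) band-limited Gaussian
oscillations per state and site — NREM delta and spindles, REM theta
(strongest parietally, as volume-conducted hippocampal theta), wake theta
and gamma, and a small beta component in every state so multiplicative
beta effects act on a common nonzero baseline — and (iii) a slowly varying
log-normal gain (AR(1) on the log scale, SD 0.35, one step per second)
emulating the arousal-related power fluctuations of real EEG. Components
are synthesized by Fourier-domain shaping with an order-2 Butterworth
band-pass power profile, per bout, overlap-added with a 0.5-s
raised-cosine cross-fade at every state boundary; the ground-truth label
of a transition second is the state occupying most of it. The
accelerometer is white noise whose per-axis SD switches with state (1.0
wake, 0.08 NREM, 0.04 REM — REM atonia is stiller than NREM).

The gain modulation and noise floor matter beyond cosmetics: they give
band powers the heavy-tailed epoch-to-epoch variability that a
15-interquartile-range outlier rule presumes. Without them, a band that
is active only in a minority state (parietal ripple during REM, say)
protrudes so far above an implausibly tight background that the fence
flags the whole state.

Mutant phenotypes are multiplicative modifiers applied only to mutant
animals: bout durations ×0.5 in every state (more, shorter bouts), the
NREM→REM entry probability ×1.8 (longer total REM and a higher REM share
of sleep), the REM theta component centres shifted −1 Hz, and band
amplitudes scaled per (state, site, band) — by default REM beta ×2 at
both sites, REM frontal delta ×1.5, REM parietal ripple ×0.7, NREM
parietal beta ×1.5, wake parietal delta ×1.5 and wake parietal gamma
×0.67. Effect magnitudes are free parameters of the simulator — the
source phenotypes are reported as violin plots without printed effect
sizes — chosen here to be unmistakable on a single animal's spectrogram
yet small enough that recovery still exercises the statistics.

What the simulator does **not** model: electrode artifacts, circadian
drift, the lights-off period, EMG, spindle/twitch microstructure, or any
within-state spectral nonstationarity beyond the global gain. Passing
recovery tests on these cohorts therefore demonstrates that the pipeline
is correct and calibrated, not that it is robust to every artifact of
real recordings.

## Spectral estimation and band powers

Each 1-s epoch of each EEG channel gets a Welch PSD: 0.5-s segments, 50%
overlap, Hann taper. At the default analysis rate this gives 2-Hz
resolution, so the first usable bin of the delta band (0.5–4 Hz) is the
2-Hz bin; the trailing partial epoch is dropped. Bands follow the rodent
convention used throughout: delta 0.5–4, theta 5–10, spindle 11–19, beta
20–30, gamma 40–100, ripple 130–180 Hz — deliberately non-contiguous,
with power in the gaps unassigned. Band power is the arithmetic mean of
the PSD over bins whose centre falls inside the inclusive bounds (mean
rather than integral; the choice is scale-free after normalization).

Outlier exclusion: per channel and band, quartiles are taken over all
epochs of the recording with the linear-interpolation convention
(`quantile` type 7 — stated because k×IQR fences are sensitive to it),
and an epoch is dropped for a channel when **any** of its band values
lies beyond Q3 + 15·IQR or Q1 − 15·IQR. The rule is applied to band
powers, the quantity subsequently analysed, not to raw spectrogram bins.
Each remaining value is divided by the median of its (channel, band) over
the unflagged epochs of the lights-on period, making the unflagged median
exactly 1 by construction. State summaries average normalized power over
unflagged epochs per state, then average left/right electrodes of a site;
a missing electrode simply reduces the average, and a state with no
epochs yields `NA`, never 0.

The REM theta peak is estimated on a second spectral pass at 1-Hz
resolution (1-s segments) restricted to REM epochs, as the frequency of
the maximum of the state-averaged PSD in 5–10 Hz with parabolic
interpolation around the argmax bin (ties to the lower frequency). The
raw rather than median-normalized spectrum is scanned: dividing by the
per-frequency recording median — the display normalization — imprints the
median's own theta structure (dominated by wake theta) onto the REM
spectrum and can displace the peak by several tenths of a Hz in a
genotype-dependent way.

## Automatic staging

Three features per epoch, each smoothed by a centred 5-epoch running
median: slow-wave activity (median-normalized frontal delta power — the
canonical NREM marker), the theta ratio theta/(delta+theta) from parietal
channels (bounded in [0,1]; defined this way rather than theta/delta so a
threshold on it is stable), and movement (within-epoch accelerometer
variance summed over axes). Which electrodes feed each feature is an
assumption: frontal sites emphasize slow waves, parietal sites carry
hippocampal theta.

Scoring is a deterministic threshold cascade, chosen over mixture-model
clustering for explainability and reproducibility: (1) Otsu's threshold
on log movement separates wake; (2) among still epochs, Otsu on log SWA
marks NREM; (3) the remaining still, low-SWA epochs are REM when their
theta ratio exceeds its Otsu threshold, else quiet wake. Every threshold
is attached to the hypnogram for audit. An Otsu split is accepted only
when the resulting class medians differ by at least 1.5 log units
(movement, SWA) or 0.2 (theta ratio); otherwise the population is treated
as containing a single state and assigned by a physiological fallback
(still epochs with delta-dominant theta ratio are all NREM; a uniformly
theta-dominant remainder is all REM). Without this guard Otsu happily
slices a unimodal cluster in half — the failure mode appears whenever a
short recording lacks a state entirely.

Post-processing enforces a 3-s minimum bout (runs shorter than the
minimum are absorbed into the longer flank, ties to the preceding state;
the recording's first and last runs are exempt) and the rodent convention
that REM is entered only from NREM: REM bouts with no NREM in the
preceding 10 s are relabelled wake. Both are exposed as arguments
(`min_bout_s`, `forbid_wake_rem`). Manual re-scoring is out of scope, but
any externally edited hypnogram CSV can be supplied in place of the
automatic one at every stage.

## Architecture metrics

A bout is a maximal run of identical labels; edge runs count, and no
minimum duration is imposed at this stage (smoothing belongs to the
scorer), so 1-s singletons are counted as bouts. Per state: total
seconds, bout count, mean bout duration, and — for REM and NREM — the
percentage of total sleep time, with TST = REM + NREM seconds as the
denominator. Absent states give zero time and `NA` mean duration; an
all-wake hypnogram gives `NA` percentages rather than 0. Invariants held
exactly: state times sum to the recording duration, and
bouts × mean duration = total time per state.

## The statistical layer

Each metric is compared between genotypes with the gated two-group test:
Shapiro–Wilk normality per group and a median-centred Levene
(Brown–Forsythe) variance check; when all three p-values exceed 0.05, a
two-sided pooled-variance t-test, otherwise a two-sided Mann–Whitney with
mid-rank ties, exact when the combined n ≤ 20 and there are no ties. A
constant group is treated as non-normal. The gate instruments are a
design choice (none are named in the underlying description); the
diagnostics are reported with every comparison so the decision trail is
auditable. A Kruskal–Wallis alternative is available behind the `method`
argument but is not the default for a two-group design. Groups smaller
than 3 are an error — the gate is undefined below that.

Bonferroni families follow the figure-panel structure the results are
read in: one family per architecture metric (across the three states),
one family per state for band powers (6 bands × 2 sites = 12 tests), one
family for the REM theta peaks (2 sites), with p·m clipped at 1.
Sex-ratio balance between genotypes uses Pearson's chi-square on the 2×2
genotype-by-sex table without continuity correction (documented, since
the corrected statistic is the other common convention).

Validation studies (`evaluate_*`): staging recovery pools 10 one-hour
wild-type recordings; architecture-effect recovery runs 20 cohorts of
9 wild types vs 5 mutants (the study cohort shape) on full 12-h
hypnograms, which need no signal synthesis; spectral-effect recovery runs
20 full-pipeline cohorts at 25 min per animal — long enough that every
animal accrues hundreds of REM epochs, short enough that a cohort's
synthesis-to-statistics round trip takes seconds; null calibration uses
100 effect-free cohorts plus 2000 gated-test replicates under normal and
log-normal nulls. Problem sizes are stated here once and used identically
by the test suite and `scripts/acceptance.R`.

## Numerical and design notes

- All randomness flows from one master seed through deterministically
  drawn per-animal, per-stage sub-seeds; identical (config, seed) gives
  byte-identical outputs, including CSVs.
- EDF (16-bit, 1-s records) carries the signals; a JSON sidecar carries
  the role map, lights-on window and animal metadata that EDF labels
  cannot. The physical range written to the header is padded by 0.1%
  before rounding to its 8-character field so extreme samples can never
  overflow the digital range, and the writer re-reads its own header
  representation so scaling is self-consistent. The reader falls back to
  parsing roles from channel labels when no sidecar exists.
- Median normalization interacts with state composition: the (channel,
  band) median is anchored wherever the 50th percentile of that band's
  epoch distribution falls, so a genotype effect on a band in a state
  that dominates that band's median partially cancels in normalized
  units. This is a property of the method, not of the implementation;
  the simulator's default spectra keep each tested band's median
  anchored in a broad, genotype-neutral part of the distribution, which
  is also the regime real recordings occupy.
- Degenerate inputs: constant features stage to a single state with a
  warning rather than an error; a zero band-power median aborts
  normalization naming the offending (channel, band); bands that capture
  no frequency bin, truncated EDFs, unknown hypnogram tokens and
  non-contiguous epoch grids are all named errors.

## Limitations

Staging is validated against the simulator's own ground truth, not
against manual scores of real recordings; accuracy on real data will be
lower and should be spot-checked. The outlier rule and normalization are
exactly as specified for the 12-h lights-on design and are not
circadian-aware. The simulator's genotype effects are stylized
multiplicative contrasts; graded or state-composition-confounded effects
will behave differently through the normalization, as noted above.
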