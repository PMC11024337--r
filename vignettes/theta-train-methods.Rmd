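---
title: "Methods: simulating and analyzing rhythmic TMS-EEG working-memory training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing rhythmic TMS-EEG working-memory training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`thetatrain` is an end-to-end, fully synthetic replica of a class of
experiments that combine rhythmic transcranial magnetic stimulation (rhTMS)
with longitudinal cognitive training under concurrent EEG. The package
exists because raw recordings for such studies are typically unavailable:
every analysis stage therefore ships with a generator that produces data
with exactly the statistical structure the stage assumes, so the whole
chain is testable offline. This vignette documents the models, the
parameter choices and their rationale, the numerical conventions, and what
a passing test does and does not establish.

## The task and the behavioral observer

The simulated task is auditory working-memory manipulation: each 15-s trial
presents a three-tone sequence at 0 ms, a visual reorder cue at 5000 ms,
and a probe sequence at 10000 ms; the subject answers match/mismatch.
*Simple* trials carry the identity cue "123" (pure retention);
*manipulation* trials carry one of the five non-identity permutations. A
session is 3 runs x 42 trials (14 simple + 28 manipulation), i.e. 126
trials; order is a seed-fixed shuffle per run. Two stated-world choices:

* **Match/mismatch ratio** is 50/50 within each trial type (the protocol
  source states this only for a sibling task; it is the natural default
  and is configurable via `match_prop`).
* **Tone acoustics are not synthesized.** Only event times matter to the
  EEG analysis; rendering 250-1000 Hz tones would add nothing testable.

Responses come from an equal-variance Gaussian observer. On a mismatch
(signal) trial the decision variable is $X \sim N(d', 1)$, on a match
trial $X \sim N(0, 1)$, and the observer answers "mismatch" when
$X > d'/2 + c$ with criterion $c = 0$ by default (the analysis chain
computes bias-free $d'$, so an unbiased observer is the matching world).
Sensitivity in session $s$ is $d'_s = \max(0,\; b + \beta (s-1))$ with
per-subject baseline $b$ and learning slope $\beta$. The long-run
estimated $d' = z(H) - z(FA)$ of this observer equals the programmed value,
which the suite verifies at $10^4$ trials.

Cohort defaults (all in `cohort_effects()`): baseline manipulation $d'$
$\sim N(1.7, 0.5)$ and simple-trial $d' \sim N(2.9, 0.5)$ — the scale of
the published group baselines (1.53/1.91 manipulation, 2.61/3.3 simple);
learning slopes $N(0.2, 0.1)$ d'/session for rhTMS and $N(0, 0.1)$ for
sham, an 0.2/session group separation on the order implied by the
published day-5 means (2.4 vs 1.4) over five training sessions. Group
assignment is pair-matched on sorted baselines with randomized within-pair
labels, redrawn until group means differ by at most 0.25 — emulating
"balanced on baseline performance" assignment.

## The EEG generator

Epochs span $[-1000, 12000)$ ms around the first-tone onset (all windows in
the package are half-open, which avoids double-counting boundary samples
between baseline and trial). The generator composes, per trial and
channel:

* **Background**: $1/f$ Gaussian noise, 10 uV SD per channel, synthesized
  in the frequency domain. 10 uV broadband with exponent 1 puts roughly
  10% of the variance in 4-8 Hz, a realistic resting-theta floor.
* **Theta burst** (manipulation trials only): a sinusoid at 5 Hz — the
  stimulation frequency — gated to the manipulation window
  $[5000, 10000)$ ms with 200-ms raised-cosine ramps. Ramps prevent
  spectral splatter at the window edges; the analysis windows are interior
  to the burst, so ramp shape never enters a tested quantity. Amplitude is
  the subject's `theta_gain_uv` ($\sim N(5, 1.5)$ uV) plus, when a pulse
  schedule is present and the subject is in the rhTMS group, an
  entrainment gain ($\sim N(4, 1)$ uV; identically 0 for sham). The burst
  is scaled by a Gaussian spatial profile (sigma 30 mm) peaking on a
  fronto-parietal target set (P7...CP2, F3/F1/Fz), the scalp footprint the
  published topographies show.
* **TMS artifact** (when scheduled): ten pulses per trial at 5 Hz from the
  cue onset (5000, 5200, ..., 6800 ms; 420 pulses per 42-trial block). The
  waveform — one 4-ms biphasic sine cycle with an 8-ms exponential tail at
  2000 uV — is invented: the source does not describe its shape, and only
  its *removal* matters downstream. It is deterministic given the
  schedule, and the noise/phase streams are seeded independently of the
  schedule, so with/without-artifact simulations of the same subject are
  sample-identical outside the artifact support. That pairing is what the
  artifact-fidelity criterion measures against.

The per-session pulse ledger of the source protocol is internally
inconsistent (a 2,160-per-session total vs 3 x 420 per block); the
scheduler follows the per-block arithmetic, as documented in
`?schedule_tms`.

## Preprocessing

Canonical order: detect -> replace -> resample (500 Hz) -> band-pass
(0.3-50 Hz) -> epoch -> average re-reference -> amplitude rejection.
Whether the original chain filtered before or after downsampling is
ambiguous; both orders commute to well under the tested tolerances for
band-limited signals, and the chosen order is configurable by calling the
stages directly.

* **Pulse detection** is either schedule-driven (onsets projected through
  the trial markers, refined +-5 ms to the absolute peak) or data-driven:
  any channel exceeding `threshold_sd` (default 8) robust SDs
  (1.4826 x MAD), flags merged within 20 ms, peak = the cluster's largest
  absolute sample.
* **Replacement** substitutes, per channel, the closed span
  $[peak - 10, peak + 20]$ ms with Gaussian draws matching the mean/SD of
  that channel's $[-35, -15)$ ms reference window. The closed span
  guarantees the raw transient is fully covered. If a reference window
  would overlap the previous pulse's replacement span, the nearest earlier
  clean window of equal length is used and logged (cannot occur at the
  default 200-ms inter-pulse interval). Everything outside the spans is
  bit-identical — a tested invariant.
* **Filtering** is a Hamming windowed-sinc FIR applied forward-backward
  (zero phase, effective response $|H|^2$), transition widths 0.3 Hz low /
  12.5 Hz high. The band-pass kernel is a difference of two unity-DC
  low-pass kernels, so DC gain is exactly zero.
* **Resampling** is FFT spectrum truncation (anti-aliased by
  construction); event onsets are rescaled and rounded.
* **Rejection** drops a trial iff any channel's absolute amplitude
  *strictly exceeds* 250 uV anywhere in the epoch. "Ranges of values
  exceeding +-250 uV" is read as an absolute-amplitude bound, the common
  convention and the stricter reading; a sample at exactly 250 uV is kept
  (boundary convention, tested).
* **ICA** is exposed only as a pass-through hook: component decomposition
  is off-the-shelf elsewhere and has no testable contract on this
  generator, which plants no structured residual artifacts by default.

## Time-frequency analysis

`morlet_tfr()` convolves each trial with complex Morlet wavelets defined by
$f_0/\sigma_f = 7$, i.e. $\sigma_t = 1/(2\pi\sigma_f)$ (222.8 ms at 5 Hz),
and averages *magnitudes* across trials — induced plus evoked power.
Convolution edges are mirror-padded and the first/last $3\sigma_t$ per
frequency are flagged invalid; baseline and analysis windows are interior,
so flags never touch tested quantities. `zscore_baseline()` normalizes per
channel (x frequency) by the mean/SD of the $[-1000, 0)$ ms pre-stimulus
window; zero-SD bins are set to 0 and logged rather than propagating NaN.

`band_envelope()` band-passes 4-8 Hz (zero-phase FIR) and takes the
analytic-signal magnitude per trial, averages over trials, z-scores
against baseline, and averages $[5000, 10000)$ ms into a per-channel
topography. The theta band is fixed at 4-8 Hz, not individualized,
mirroring the fixed 5 Hz stimulation choice. The suite checks that Hilbert
and Morlet window topographies agree in rank order (Spearman rho > 0.9) on
generated data. Power-behavior maps are Pearson correlations across
subjects at every bin (the published statistic is $r$); the correlation
module reports $n$ and leaves degrees-of-freedom notation to the caller,
since the published $r(17)$ with $n = 18$ does not follow the usual
$n - 2$ convention.

## Cluster-based permutation statistics

Point-wise $t$ maps (one-sample/paired via sign flips, independent via
group-label shuffles) are thresholded at the one-tailed $t$ quantile at
`cluster_alpha = 0.05` with the design's df — the threshold convention of
the standard sensor-space implementations; the source never states its
own. Supra-threshold bins are clustered by montage adjacency (channels
neighbors iff within 50 mm; for channel x grid inputs, plus $|\Delta| \le
1$ along each ordered axis), the cluster statistic is the **mass** (sum of
member $t$), and $k$ (cluster size) is reported alongside for
comparability with published cluster sizes. The null is the permutation
distribution of the maximum cluster mass; $p = (1 + \#\{null \ge
obs\})/(1 + n_{perm})$ so $p$ is never 0, and when the number of distinct
permutations is at most `n_perm` the test switches to exact enumeration
(verified bin-for-bin against a brute-force oracle at $2^6$ sign flips).
Family-wise type-I error is measured directly: over 500 null cohorts
(7 vs 7 subjects, 62-channel i.i.d. Gaussian topographies) the rate must
land in $0.05 \pm 0.02$. Null *topographies* rather than null raw EEG are
the right unit here — the criterion targets the test, and full-EEG nulls
at that count would exceed any single-CPU budget.

## Behavioral statistics

$d'$ uses the $1/(2N)$ clamp on hit/false-alarm rates before the probit
transform (log-linear correction available behind a flag); the clamp is
the most common convention and handles the near-ceiling simple trials the
generator produces. The screening metric Hits $-$ FA is deliberately
unclamped. Screening excludes above 0.70 (ceiling) and at or below 0.1
("above chance" is undefined in the source; 0.1 is a documented,
configurable guess). Learning slopes are OLS of per-session $d'$ on the
session index over training sessions 2-6. Mann-Whitney uses
$U = \min(U_x, U_y)$ with exact enumeration for $n_x + n_y \le 20$ without
ties; Wilcoxon uses the positive-rank sum $W$ with exact enumeration for
$n \le 25$ — consistent with the published $W \le 28$ at $n = 7$. Both are
verified against brute-force enumeration on every tested instance with
$n \le 8$.

Effect-size planning: Cohen's $d = (m_1 - m_2)/\sqrt{(s_1^2 + s_2^2)/2}$
gives 0.995 on the published day-5 summaries; the smallest per-group $n$
with noncentral-$t$ power $\ge 0.8$ (two-tailed, $\alpha = 0.05$,
ncp $= d\sqrt{n/2}$, df $= 2n-2$) is **17**, cross-checked against a
$10^5$-rep Monte Carlo within 0.01. The source's "32 total (17 per
group)" is arithmetically inconsistent; the package returns both $n = 17$
and $2n = 34$ and treats the computation as authoritative. Similarly, the
unbiased-observer accuracies at $d' = 0.5$ and $2.5$ are 59.87% and
89.44% — the source rounds these as "roughly 60 and 90%"; note 89.44
rounds to 89, so the published 90 is a rough figure, not arithmetic.

## What the suite establishes, and scaling

The acceptance suite runs every criterion at a size that fits a single
CPU: the effect-recovery criterion simulates 100 cohorts of 7 vs 7
subjects with **3 manipulation trials per subject at 500 Hz** (scaled from
the study's 84 per session at 1000 Hz) with artifact amplitude 0 — the
artifact path has its own paired-fidelity criterion — and requires a
significant rhTMS-vs-sham theta cluster overlapping the planted channels
in at least 80% of seeds. Fewer trials per subject only *lower* power
(noisier topographies), so passing at 3 trials is conservative with
respect to the stated world. The slope Mann-Whitney rejection rate is
estimated over 400 cohorts (a 100-cohort rate has Monte-Carlo SE of about
5 points, which would make a +-5-point comparison uninformative) and must
match, within 5 points, the power simulated from an independent
delta-method model of observer noise on fitted slopes.

A green suite establishes that the implementation recovers what the
generator plants, at the generator's noise levels, and reproduces every
closed-form number the source prints. It does not establish performance on
real recordings: the generator has no eye/muscle artifacts by default, no
inter-channel noise correlation, no drift, stationary 1/f background, a
single fixed-frequency theta source, and no residual TMS artifacts after
replacement — the reasons ICA and visual inspection exist in real chains
and are out of scope here.

## Known limitations

* The generator models entrainment as an *online* effect: the extra theta
  gain applies only while a pulse schedule is present. Lasting
  (post-training) oscillatory enhancement is not built into the world, so
  the post-vs-pre contrasts the pipeline computes test a true null on
  default synthetic cohorts. Persisting effects can be emulated by
  editing a cohort's `theta_gain_uv` between sessions.
* Sensor space only; source imaging (BEM forward models, minimum-norm
  inverse) requires anatomical data and is out of scope. Published
  source-level cluster sizes have no analogue here.
* BrainVision I/O supports the common INT_16 multiplexed little-endian
  dialect only; other dialects are rejected loudly rather than guessed.
* Digitized electrode positions are unavailable; the built-in 62-channel
  10-10 template uses an idealized spherical head (85 mm), adequate for
  distance-based adjacency but not for forward modeling.
* Exact nonparametric null distributions come from base R
  (`pwilcox`/`psignrank`); the package's contribution there is the
  conventions (U/W definitions, tie handling, tails), tested against
  enumeration.
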