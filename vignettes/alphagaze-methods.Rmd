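---
title: "Methods: coregistered EEG/eye-tracking analysis of internal attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coregistered EEG/eye-tracking analysis of internal attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When cognition turns inward — mental arithmetic, imagery, memory search —
the brain partially decouples from the sensory environment. Two
neurophysiological signatures of this *internally directed cognition* (IDC)
are well documented: EEG alpha-band activity (8.5–12.5 Hz) increases over
posterior cortex, consistent with inhibition of task-irrelevant visual
processing, and oculomotor behavior changes (fewer microsaccades, larger
pupil, longer fixations — "perceptual decoupling"). Coregistered
EEG + eye-tracking makes it possible to study both channels simultaneously
and, crucially, to remove ocular artifacts from the EEG using the eye
tracker's event stream rather than blind statistical correction.

`alphagaze` implements that analysis pipeline end to end:

1. **Task analysis** — task-related alpha power (TRP) and twelve oculometric
   parameters per trial, validity filtering, and repeated-measures ANOVAs
   over ATTENTION (internal/external), TASK, HEMISPHERE and AREA.
2. **Rest covariation** — the central novel computation: a 120 s rest
   period is cut into 120 one-second segments; per subject, log alpha power
   per region is correlated with each eye parameter over artifact-free
   segments, and correlations are pooled across subjects via Fisher's z.
3. **A synthetic-data generator** that produces coupled EEG + binocular
   eye-tracking recordings with known ground truth, so every stage is
   testable without any external data.

## Signal model of the generator

All coupling runs through two latent processes shared by brain and eye:

* a two-state attention process \(s(t)\in\{\text{internal},
  \text{external}\}\) — a Markov chain with mean dwell time 12 s during
  rest, clamped to the condition label during task activation phases;
* a continuous arousal latent \(g(t)\), an Ornstein–Uhlenbeck process with
  mean-reversion \(\theta = 0.5\,\mathrm{s}^{-1}\) and unit stationary
  variance.

Per channel \(c\) in region \(r\), the EEG is

\[ x_c(t) = A_r\,m_r(t)\,\max\{0.05,\; 1 + \kappa g(t) + \kappa_\perp
\eta_c(t)\}\, \sin(2\pi f_\alpha t + \phi_c) + n_{1/f}(t) + n_w(t), \]

with \(f_\alpha = 10.5\) Hz, baseline amplitudes \(A_r\) increasing from
anteriofrontal (4 µV) to occipital (10 µV), and
\(m_r(t)\) the state/task factor: 1 at rest and reference (times
\(1 + g_r\) when the rest state is internal), and
\(d\,(1 + g_r\,\mathbb{1}[\text{internal}])\) during activation with
desynchronization factor \(d = 0.75\) and attention gains \(g_r\) rising
posteriorly (AF 0.02 … O 0.22). \(\eta_c\) is a channel-specific OU
nuisance; \(\kappa = 0.25\) and \(\kappa_\perp = 0.45\) set how much alpha
amplitude variance is shared with the pupil. Background noise is pink
(\(1/f\), fixed exponent 1) plus white, both specified as power spectral
densities (0.3 µV²/Hz at 10 Hz; 0.2 µV²/Hz) so that in-band
signal-to-noise is invariant to the simulation rate — per-sample noise SDs
scale as \(\sqrt{\text{rate}}\).

The pupil shares the same latents,
\(p(t) = p_0 + \beta g(t) + \beta_\perp \xi(t) + \Delta_s
\mathbb{1}[s=\text{internal}] + \Delta_{SG} + \varepsilon(t)\), with
\(\beta = 50\), \(\beta_\perp = 110\), internal-state offset 120 a.u., a
sentence-task offset of 60 a.u., and white measurement noise (SD 30 a.u.
per sample). Gaze is fixational OU drift (SD 0.1°, τ = 2 s) plus injected
saccadic events: microsaccade amplitudes lognormal (median 0.3°, σ = 0.4
log units), macrosaccades jumping between fixation targets scattered with
SD 1.2°, both moved along a raised-cosine position profile whose duration
follows the main sequence (peak velocity \(= 100\,a^{0.7}\) deg/s, durations
clamped to 6–80 ms). Microsaccade and saccade rates are state dependent
(internal 1.0/s vs external 1.8/s; 0.08 vs 0.25/s), blinks are binocular
Poisson events (0.15/s, lognormal durations around 120 ms) during which
gaze and pupil drop out (`NA`). Vergence varies through an OU fixation
depth around the screen plane (SD 30 mm, τ = 5 s). Where the study design
fixes a value (trial structure, rates, rest length, masking latency), the
generator uses it; the remaining parameters above were chosen once as
values a practitioner would call realistic for a darkened-cabin fixation
task, and are not tuned thereafter.

What the generator does *not* emulate: stimulus-locked ERPs and phase
locking, the pupil light reflex (constant luminance is assumed), smooth
pursuit, post-saccadic oscillations, EEG nonstationarities other than the
latent processes, and clock drift between the two recording systems
(bundles are assumed perfectly synchronized; the hardware verification
step that justifies this is out of scope). Passing recovery tests
therefore demonstrates correctness of the *pipeline computations* under
realistic statistical structure, not robustness to every artifact of real
recordings.

## EEG conditioning and alpha power

Preprocessing order is fixed: 50 Hz notch (zero-phase 2nd-order
Butterworth band-stop), anti-aliased downsampling to 100 Hz (zero-phase
6th-order Butterworth low-pass at 0.8× the target Nyquist, then
decimation), then re-referencing to the mastoid average when mastoid
channels are present (synthetic recordings are generated already
referenced and say so in their metadata).

Ocular artifacts are removed, not corrected: the validity mask invalidates
each blink from **350 ms before onset to 200 ms after offset** (the window
over which blink-locked averages show alpha-power distortion — see
`blink_locked_power()`), each saccade ±20 ms, plus any manual artifact
intervals. Those windows are treated as exact constants.

Instantaneous alpha power comes from complex demodulation: multiply by
\(e^{-2\pi i f_0 t}\) at \(f_0 = 10.5\) Hz, low-pass the product, and take
\(2\,|z|^2\), so a pure in-band sine of amplitude \(A\) has mean power
\(A^2/2\) — its mean square. The demodulation low-pass is a zero-phase
4th-order Butterworth at 2.0 Hz (half the 4 Hz band); the reference
implementation the field uses ships an unpublished filter, so equivalence
is instead bounded by testing against an FFT band-pass oracle (within 3%
on stationary tones). The first and last 0.5 s of each power series are
flagged `NA` against filter edge effects. Power means require at least 10
valid samples (0.1 s at 100 Hz) — a variance guard for windows truncated
by blinks — and return "missing", never an error.

TRP for electrode \(i\) is
\(\log(1 + \overline{POW}_{i,\text{act}}) - \log(1 +
\overline{POW}_{i,\text{ref}})\), natural log; negative values are
task-related desynchronization. The log base only rescales TRP and cancels
from every F statistic, so the choice is recorded in metadata rather than
exposed as an option. The reference window discards the first and last
500 ms of the 5 s fixation period; the activation window runs from 1.5 s
after stimulus onset (1 s after the conditional mask change) to the end of
the 20 s presentation — 18.5 s.

## Oculometrics

Twelve parameters per analysis window: pupil diameter (binocular average,
±3 SD outlier removal, z-scored within subject — rest and task periods
scoped separately), vergence angle (ray-intersection geometry from
binocular gaze, eyes ±30 mm from the midline, screen plane at 705 mm;
the published formula this reconstructs is cited but not reproduced in the
source literature, so the geometry here is a from-first-principles
reconstruction), their variances, micro/saccade counts and amplitude
means, blink count/duration, and fixation count/duration.

Saccadic events are detected at the native 1000 Hz with the classic
velocity-threshold algorithm: 5-point moving-window velocity, per-axis
robust SD via \(\sqrt{\langle v^2\rangle_{med} - \langle
v\rangle_{med}^2}\) (which concentrates on 0.6745 σ for Gaussian noise —
the conventional behavior of this estimator), elliptic threshold at
λ = 4 robust SDs, minimum duration 6 ms, binocular combination by temporal
overlap with union extent and amplitude averaging. Events below 1° of
visual angle (strictly) are microsaccades. Detection cannot run at 100 Hz
— 6 ms is sub-sample there — which is why only the continuous series (PD,
vergence) are block-downsampled (10-sample means, `NA` when more than half
a block is missing). Counts are raw per-window counts by event *onset*
(deterministic and order-preserving for 1 s segments); "saccade count"
excludes microsaccades, which are reported separately.

## Validity filtering and ANOVAs

A trial is analyzed iff the response was correct, the reference window
keeps *more than* 500 ms artifact-free data (strict) and the activation
window keeps at least 1/3 (inclusive — the "= 3/9" gloss of the
participant-level rule forces inclusivity there, and the trial level
mirrors it). A participant is retained iff every task × condition cell has
≥ 3 valid trials and ≥ 18 of 36 responses were correct.

`rm_anova()` is the classical univariate within-subject decomposition:
replicates are collapsed to subject × cell means; each effect is tested
against its own subject × effect interaction; partial eta squared is
\(SS_e/(SS_e + SS_{err})\). No sphericity correction is applied by default
(plain degrees of freedom are the reporting convention here);
Greenhouse–Geisser adjusted p values are available behind `gg = TRUE`.
Zero error SS yields an infinite F with an explicit `degenerate` flag.
Eye-parameter attention tests use the Bonferroni critical alpha
0.05/12 ≈ 0.00417.

## Rest covariation

Subjects enter if ≥ 66% of the 120 s rest period is artifact-free
(inclusive). Per 1 s segment: log(1 + mean alpha power) per electrode over
mask-valid samples (missing below 10 of 100 samples — a segment containing
one fully extended blink window still retains ~250 ms of EEG, and such
segments must stay, because blink counts are among the correlates),
aggregated across both hemispheres per region; means/variances of the
conditioned eye series; onset counts for discrete events. Continuous
columns are z-scored within subject over non-missing segments; counts stay
raw frequencies. Per-subject Pearson correlations run over segments where
both variables are present, requiring ≥ 30 of 120 complete pairs (the
source convention states no minimum; 30 bounds the standard error of one
subject's r). Segments are used when partially artifact-free rather than
requiring fully clean seconds; this floor-based reading is recorded in the
output attributes.

Across subjects, correlations are pooled as \(\tanh(\overline{\text{atanh}\,
r})\); the difference from zero is a one-sample t test on the Fisher z
values with matching t-quantile CIs, at the Bonferroni level 0.05/40 for
the 5-region × 8-parameter matrix. The exact CI construction is not
specified in the source literature; the one-sample-t convention is the
declared choice here.

## Numerical choices and degenerate inputs

* Time is seconds from recording start; intervals are half-open
  \([on, off)\); a sample belongs to an interval iff \(on \le t < off\) —
  this removes every fencepost ambiguity, and masks/intervals are exact
  inverses at sample resolution.
* Missing data are explicit `NA` end to end; every mean runs over
  non-`NA` ∧ mask-valid samples; "not enough data" is a missing value, not
  an error. Zero-variance conditioning scopes and < 2 complete subjects
  *are* errors (degenerate subject / design).
* Gaps interior to a series are bridged by linear interpolation before
  filtering and re-flagged `NA` afterwards, so filters never propagate
  `NA` and never hallucinate data into the output.
* `|r| = 1` is clamped to \(1 - 10^{-12}\) before the Fisher transform,
  with a warning.
* Zero-phase filtering runs in compiled code with odd-reflection padding;
  the R-level contract is identical to the conventional
  forward–backward Butterworth cascade (verified against `signal::filtfilt`
  to ~1e-12).

## Problem sizes used in validation

The validation suite and the acceptance script regenerate everything from
seeds. Full-rate (1000 Hz) simulation is used where the sampling rate is
itself under test (detector validation: 50 × 120 s runs). The
multi-subject studies run at reduced rates (EEG 200 Hz, eye 500 Hz) and
modest counts (40 subjects for covariation recovery, 15 × 8 for the null
calibration, and 5 replicates of a 20-subject study for direction
recovery — the study size is kept at 20 subjects because it determines the
power of the within-subject tests, while the replicate count only sets the
Monte-Carlo resolution of the recovery rate; the script uses slightly
smaller sizes again) — these are the package's
chosen problem sizes; because noise is PSD-referenced, in-band statistics
do not depend on the rate, and effect sizes, noise levels and thresholds
are never scaled.

The covariation recovery test calibrates the generator (β = 35,
internal-state pupil offset 80) so that the independent long-run coupling
oracle (`theoretical_coupling()`: 1 s binning of the noiseless amplitude
and pupil over ≥ 2 simulated hours, then first-order analytic attenuation
by the known measurement-noise variances) sits near r ≈ 0.25 posteriorly,
and requires the full pipeline's Fisher-pooled mean r to land within
±0.07 of the oracle.

## Known limitations

* The vergence computation reconstructs the ray-intersection geometry from
  first principles; absolute vergence values depend on the configurable
  pixel pitch, which screen metadata must supply (0.294 mm/px default).
* The RM-ANOVA is the classical univariate decomposition; no multivariate
  or mixed-model alternatives, and sphericity correction is opt-in.
* Blink detection in synthetic data equates blinks with binocular pupil
  dropout ≥ 20 ms; real-data adapters should trust the tracker's blink
  events instead.
* The attention gain can shrink linearly across the activation phase via a
  config hook (`time_varying_gain`), but it is off by default; no other
  within-trial nonstationarity is modeled.
* Raw vendor formats (EDF, ASC) are not parsed; the bundle directory of
  TSV/JSON files is the interchange format.
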