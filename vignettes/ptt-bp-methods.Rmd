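---
title: "Pulse-transit-time blood pressure estimation: model, pipeline and simulator design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulse-transit-time blood pressure estimation: model, pipeline and simulator design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pttbp)
```

## The measurement model

The arterial pulse wave travels faster in stiffer (higher-pressure)
arteries. The pulse transit time (PTT) between a proximal fiducial — the
aortic-valve-opening (AO) peak of the chest seismocardiogram (SCG) — and a
distal one — the diastolic foot of the wrist photoplethysmogram (PPG) —
is therefore an inverse correlate of blood pressure, and the conventional
two-parameter calibration model is

$$\mathrm{BP} = \frac{K_1}{\mathrm{PTT}} + K_2,$$

fit per participant and per pressure component (DBP, MAP, SBP) by ordinary
least squares of the reference pressure on $\mathrm{PTT}^{-1}$. $K_1$
(mm Hg·s) absorbs the participant's baseline vascular stiffness — stiffer
arteries mean shorter transit times at the same pressure, hence a smaller
slope — and $K_2$ (mm Hg) the correlated baseline offset. We report $K_1$
in mm Hg·s, the unit dictated by dimensional analysis of the model
(reports of the same quantity sometimes print "mm Hg/s"; the numbers are
directly comparable).

Using the SCG AO point rather than the ECG R wave as the proximal
reference removes the pre-ejection period (PEP) — the electromechanical
delay between depolarization and aortic valve opening — from the timing
path. The pulse arrival time PAT = PEP + PTT is also reported for every
beat, and the quality gate operates on it.

## Pipeline stages and their parameters

`run_participant()` executes the stages below in order; every tunable sits
in `run_config()`.

**Alignment.** Wearable and reference systems record independently, so the
streams are aligned by the lag maximizing the cross-correlation of the two
ECGs' R-peak impulse trains (computed by tabulating pairwise peak-sample
differences, with ±1-sample triangular smoothing to absorb detector
jitter). The search half-window `max_lag_s` (default 0.4 s) must exceed
any plausible acquisition offset but stay below one R-R interval: a
perfectly regular rhythm repeats every beat, so lags one beat apart are
genuinely indistinguishable, and a wider window would trigger the
ambiguity error (two lags within 1 % of the maximum) on low-variability
recordings. The lagging group is shifted and both are truncated to common
support, so alignment is idempotent.

**Filtering.** Delay-compensated Hamming windowed-sinc FIR band-passes:
ECG 10–40 Hz (isolates the R wave from baseline sway), SCG 1–40 Hz,
PPG 1–8 Hz, and a 50 ms centered moving average (shrinking windows at the
edges) for the arterial pressure. Order is `min(4·fs/f_lo, 2000)`, i.e.
2000 taps at the 1 Hz edges; the group delay (order/2) is removed so
fiducial timing is unbiased, and the taps are re-centered to a mathematically
exact DC null (the windowed design alone leaves about −54 dB at 0 Hz).

**R-peak detection.** Local maxima above half the rolling 2 s maximum
(computed block-wise), refractory period 250 ms (supports up to 240 bpm).
The detector is deliberately simple; 1 ms resolution at 1 kHz is
sufficient because beats are R-gated, not R-timed.

**Segmentation and ensembling.** Beats span half-open R-R intervals.
Windows of `width = 10` beats advance by `hop = 5` (50 % overlap) and are
averaged over the common shortest-member length; windows never cross task
boundaries, and beats starting within `guard_s = 1` s of a task edge are
excluded — the FIR impulse response spans one second either side, so the
guard keeps filter transients caused by between-task pressure steps out of
the averages. Trailing beats that do not fill a window are dropped.

**SNR and selection.** Window SNR is
$10\log_{10}(P_{\mathrm{signal}}/P_{\mathrm{noise}})$ with
$P_{\mathrm{signal}}$ the mean power of the averaged beat and
$P_{\mathrm{noise}}$ the mean power of member residuals about it, capped
at +60 dB (identical members). This is the package's own scoring rule —
a self-contained, swappable strategy (`snr_fun`) standing where a
proprietary noise-detection algorithm would sit in a device pipeline. The
PPG beat per task is chosen physiologically: candidates with the top 10 %
of systolic upstrokes (pool size $\lceil 0.1M \rceil$, minimum 1), then the
pool member with maximum SNR, ties to the earlier window. Its window-paired
SCG ensemble is used for AO; the reference-pressure beat is simply the
maximum-SNR window. With fewer than ten windows per task the pool has a
single member and SNR never weighs in — a known property of the rule worth
remembering with short tasks.

**Gating.** A task is kept only if the selected SCG, PPG and ABP SNRs all
strictly exceed their thresholds and the PPG foot, as a PAT, lies in
`foot_range_s` (default 0.10–0.50 s). Default thresholds are
participant-specific: the 25th percentile of that participant's window
SNRs per channel, minus 10⁻⁶ dB — the epsilon matters because on clean
recordings every window saturates at the 60 dB cap and a threshold exactly
at the percentile would reject everything under the strict inequality.
Absolute thresholds can be configured instead (they are what makes
drop-rates monotone in noise level; relative thresholds adapt by design).
Dropped tasks carry machine-readable reasons
(`scg_snr`, `ppg_snr`, `abp_snr`, `foot_range`, `no_ao`, `too_few_beats`).

**Fiducials.** The PPG foot is the intersection of the tangent at the
maximum of the centered first difference on the upstroke with the
horizontal through the preceding local minimum, solved by exact line
algebra (sub-sample). AO is the earliest local maximum of the SCG ensemble
inside `pep_range_s` (default 0.03–0.15 s) and before the foot, with
topographic prominence at least 10 % of the beat's peak-to-peak amplitude
and three-point parabolic sub-sample refinement. `ao_mode = "consistent"`
additionally prefers, per task, the candidate closest to the participant's
median AO latency — the automated analogue of an annotator consistently
choosing the same morphological peak. At least `min_tasks = 4` gated tasks
are required to calibrate; otherwise the participant is flagged
uncalibratable.

**Evaluation.** Agreement reports MAD, RMSE, Pearson correlation
(undefined and flagged for constant margins), Bland-Altman bias with
1.96·SD limits (both half- and full width, since published "95 % CI"
figures are of ambiguous convention), and a device grade with configurable
MAD thresholds (A ≤ 5, B ≤ 6, C ≤ 7 mm Hg) anchored to the wearable
cuffless-device standard. Group comparisons stratify the coefficients by
obesity (BMI ≥ 30), sex, race (black vs other) or age and route to the
Mann-Whitney U test after a KS normality check per group (the groupings
are unpaired; the wavelength comparison is paired and uses the Wilcoxon
signed-rank test). Published conventions place age 40 in both the younger
(≤ 40) and older (≥ 40) groups; here 40 joins the older group. Exact
enumeration p-values are used for tie-free samples up to n = 12, the
normal approximation with tie and continuity corrections otherwise. The
two-sample t test for cohort demographic tables uses the pooled-variance
form computed from group means/SDs/sizes, which is identical to the
raw-data test. No multiple-testing correction is applied, matching the
analysis convention this package follows.

## What the simulator emulates — and how it stays honest

`simulate_session()` builds the seven channels from per-beat templates
with *known* fiducials, so the generator doubles as an oracle for the
pipeline. Key design choices:

- **One transit time, three pressure laws.** A single per-task PTT must be
  consistent with all three component models, so a `bp_law()` is
  parameterized by per-component $(K_1, K_2)$ plus per-task PTT (optionally
  derived from MAP targets); the pressure triples follow from the shared
  PTT. Component-ordered coefficients guarantee DBP ≤ MAP ≤ SBP at every
  transit time.
- **Task schedule.** The default mirrors the measurement segments of a
  perturbation protocol: sitting/standing baselines, rest, recoveries from
  mental arithmetic and cold pressor, and an early/late split of exercise
  recovery. Measurements exist only in these segments because the device
  cannot record during the perturbations. Default MAP targets span
  26 mm Hg, the dynamic range calibration needs; PEP defaults to 60 ms,
  constant within a session.
- **In-band templates.** The measurement filters would distort any
  waveform with energy outside their bands, biasing the "true" fiducials.
  The PPG beat is therefore synthesized from heart-rate harmonics 2–6
  (wrapped-Gaussian coefficients, width 0.13 cycles): with no energy at DC
  or at the fundamental, the 1–8 Hz band-pass transmits it essentially
  unchanged, and the second harmonic contributes a physiological
  secondary (dicrotic-like) wave in diastole. The template is
  time-registered so that its intersecting-tangent foot — located
  analytically from the Fourier form — falls exactly at the nominal
  arrival time, making the ground truth a property of the waveform itself
  rather than a label. The SCG burst is a Gaussian-enveloped 20 Hz
  oscillation (envelope SD 20 ms) whose spectrum sits inside 1–40 Hz and
  whose central peak is exactly the AO marker. The ABP beat is piecewise
  (raised-cosine upstroke, systolic plateau, raised-cosine fall) with the
  plateau length solved per beat so that minimum, maximum and time average
  equal the task's DBP/SBP/MAP exactly; plateaus longer than the 50 ms
  smoothing window keep those values exact after filtering. With these
  choices the zero-noise pipeline recovers feet to ~0.02 ms and
  coefficients to ~0.05 %, so the acceptance margins (2 ms, 1 %) measure
  the pipeline, not simulator artifacts.
- **Noise.** Additive white noise per channel, Poisson-timed band-limited
  motion bursts (amplitude 10× the channel SD, duration 0.5–2 s), R-R
  jitter from a heart-rate SD, and PPG amplitude scales
  (IR 1.0 > red 0.7 > green 0.4) emulating the downstream effect of
  melanin and body composition on optical SNR — the mechanism (LED current
  scaling, skin absorption) is out of scope, only its SNR consequence is
  modelled. "Zero noise" sets all of these to zero *including* the R-R
  jitter: noiseless beats are then exact copies, which is the condition
  under which exact recovery is a meaningful invariant. Beat onsets are
  snapped to the 1 kHz grid for the same reason.
- **Cohorts.** `simulate_cohort()` draws per-participant diastolic
  coefficients and demographics from group specifications; MAP/SBP laws
  are derived with fixed component ratios so group contrasts live in the
  diastolic coefficients. With `waveforms = FALSE` only coefficients and
  demographics are sampled — the right tool for operating-characteristic
  studies of the statistics (200-cohort type-I error, power), where
  waveform-level recovery error (≤ 1 %, established separately) is
  negligible against the 0.3 mm Hg·s between-participant SD and full
  waveform synthesis would add hours of compute without information.

## Problem sizes used by the tests

The test-suite and acceptance computations use a compact schedule (the
same seven tasks at 20–60 s each) rather than the full 2-minute-baseline
protocol: at 70 bpm a 20 s task already yields ≥ 3 ensemble windows, which
is sufficient for every property under test, and the full-length schedule
is exercised once to confirm identical behaviour. Recovery checks use 20
participants (coefficients, pressures) and 100 random laws (fiducials);
noise robustness uses 60 s tasks where the selection rule has more windows
to choose from.

## Known limitations

The generator reproduces the *statistical structure* the analysis relies
on, not cardiovascular physiology: no Windkessel dynamics, no respiratory
modulation beyond what the band-passes remove, no wave-reflection
interference in the PPG (the reason systolic-peak PTT is avoided in
practice), stylized beat morphology, and abrupt between-task pressure
steps (handled by the transition guard) where real pressure drifts
smoothly. Passing the acceptance suite therefore demonstrates that the
pipeline implements the method correctly and robustly — not that the
method achieves any particular accuracy on human subjects. Real-data
concerns that remain out of scope: inter-participant PEP variability
(PAT-only devices conflate it with PTT), calibration drift over time, and
population-level calibration transfer.
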