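---
title: "Methods: detecting fatigue-induced inattention from ECG and GSR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting fatigue-induced inattention from ECG and GSR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Physically fatigued workers lose the ability to sustain attention, and on
construction sites inattention is a leading precursor of injuries.
`distractr` implements a wearable-sensor pipeline for detecting this
state from two peripheral signals that are practical to record on a job
site: a single-channel electrocardiogram (ECG) and skin conductance
(galvanic skin response, GSR). Each subject is observed in two sessions
of a 5-minute vigilance (continuous-performance) task — once rested
("focused") and once after exhausting physical work ("distracted") — and
a classifier is trained to tell the two states apart from 14 heart rate
variability (HRV) features and 7 electrodermal features.

Because recordings of this kind are rarely shareable, the package ships a
synthetic cohort generator with a ground-truth channel. Every processing
stage is tested against planted truth rather than against irreproducible
recordings.

## HRV extraction

**Filtering.** The band-pass is a zero-phase frequency-domain filter:
the FFT of the mirror-padded, demeaned signal is multiplied by a
raised-cosine band mask. This was chosen over a Butterworth `filtfilt`
because no IIR filtering infrastructure is available in the supported
dependency set, and because the contract — exact zero phase, unit
in-band gain, >20 dB stop-band rejection — is easier to guarantee
spectrally. Pan-Tompkins R detection uses the classic chain (5-15 Hz
band-pass, five-point symmetric derivative, squaring, 150 ms
moving-window integration, adaptive dual thresholds with a 200 ms
refractory period and search-back at half threshold), with each accepted
peak refined to the band-passed waveform maximum. On the default
synthetic cohort (20 dB SNR, 250 Hz) sensitivity and positive
predictivity are above 0.99.

**Artifact correction.** Intervals deviating more than 30% from the
local 11-beat median are flagged and replaced by cubic-spline
interpolation. The 30% level is a package default (the reference
tooling's correction level is not public); it is a config argument.

**Spectral analysis.** The RR tachogram is unevenly sampled, so power
spectra use the Lomb-Scargle periodogram on a 0-0.4 Hz grid with 0.002 Hz
steps. Normalization is variance-preserving: the spectrum is scaled so
that its trapezoidal integral over the grid equals the sample variance of
the intervals. A pure oscillation of amplitude $A$ then contributes
$A^2/2$ ms$^2$ to its band, which is the property the tests assert. Band
edges are VLF 0-0.04, LF 0.04-0.15, HF 0.15-0.4 Hz; `nLF` is
$100\,LF/(LF+HF)$ and `nHF` is defined as $100 - nLF$ so the pair sums
to 100 exactly. No detrending is applied by default (`detrend =
"linear"` is available); the reference tool's smoothness-prior setting
is unknown, and the synthetic generator produces stationary tachograms.

**Nonlinear features.** Entropies use embedding dimension $m = 2$ and
tolerance $r = 0.2\,\mathrm{SD}$ of the analysed series, frozen once per
series before both measures (the source protocol does not state them;
these are the field's customary defaults). Approximate entropy includes
self-matches. Sample entropy follows the convention fixed by its worked
example: $B$ counts matching pairs among all $N-m+1$ length-$m$
templates and $A$ among the $N-m$ length-$(m+1)$ templates. This
convention carries a finite-sample bias for perfectly regular series
(a constant series would score $-\ln\frac{N-m-1}{N-m+1} > 0$), so the
fully-degenerate case — every template pair matching at both lengths —
is defined as 0, which restores the intuitive "constant series has zero
entropy" behaviour. Both entropies are verified bit-for-bit against a
naive $O(N^2)$ template-counting oracle.

**Poincare geometry.** The successive-difference convention is chosen so
that $SD1 = RMSSD/\sqrt{2}$ holds as an exact identity: RMSSD is the
uncentred root mean square of successive differences, $SD1$ is defined
from it, and $SD2 = \sqrt{2\,SDRR^2 - SD1^2}$ (with the sample-SD, $n-1$,
convention for SDRR). A centred definition of SD1 would break the
identity whenever the mean successive difference is nonzero. The ratio
is reported as SD1/SD2, matching how the source study tabulates it; the
reciprocal is also returned.

## Electrodermal decomposition

Skin conductance is modelled as tonic level + phasic response train +
noise, with each sudomotor impulse shaped by the Bateman kernel
$b(t) = e^{-t/\tau_1} - e^{-t/\tau_2}$ ($\tau_1 = 3.75$ s decay,
$\tau_2 = 1$ s rise — standard continuous-decomposition initialisation;
the kernel is peak-normalised so driver amplitudes stay in µS).

Decomposition is two-stage with a joint refinement:

1. **Tonic initialisation.** 10th percentile of the (0.5 s smoothed)
   signal per 10 s segment, a rolling minimum over ±1 neighbouring
   segment (so that SCR decay tails, which outlast one segment, cannot
   inflate the baseline), cubic-spline interpolated.
2. **Driver initialisation.** The tonic-subtracted residual is
   deconvolved against the kernel by projected FISTA under a
   nonnegativity constraint (relative objective tolerance $10^{-8}$).
3. **Joint refinement.** Tonic (represented on a 20 s-knot natural cubic
   spline basis) and driver are re-fitted together as one constrained
   least-squares problem, warm-started at the two-stage solution. This
   removes the reconstruction error that a fixed baseline leaves behind
   in SCR-dense recordings while keeping the attribution of variance
   close to the two-stage split.

SCRs are scored by segmenting contiguous supra-floor driver bursts
(gaps under 1 s merged), reconstructing each burst's conductance
deflection through the kernel, and keeping events whose reconstructed
amplitude reaches the 0.01 µS threshold inside the response window —
i.e. the threshold is applied to reconstructed conductance, not to the
raw driver. Latency is measured from the window start (first stimulus)
to the first event onset; sessions without any SCR report a missing
Latency, which the feature-matrix stage imputes with the window length
(300 s, "no response within the window"). `ISCR` is defined as
`SCR * window_length` so the two features satisfy their documented
identity exactly.

## Paired statistics

Per feature, the decision procedure is: compute paired differences
(distracted − focused); screen for outliers beyond 1.5 IQR of the
difference quartiles (type-7 quantiles); Shapiro-Wilk on the
differences; paired t-test if the normality p ≥ α and no outlier is
present, Wilcoxon signed-rank otherwise. Descriptives mirror the branch
(mean ± SD vs median (P25, P75)). The outlier rule is this package's
concretisation of the protocol's unspecified "no outlier" condition; the
conservative choice routes outlier-bearing samples to the rank test.

The Wilcoxon p-value is exact for up to 25 nonzero differences
(sign-assignment enumeration via convolution over doubled average
ranks, so ties are handled), and a continuity- and tie-corrected normal
approximation above; the z statistic is always reported because the
feature-elimination stage ranks by |t| or |z|. The composite
procedure's measured type-I error on null normal data is ≈ 0.055 at
α = 0.05 — slightly above nominal because routing by a data-dependent
gate perturbs the conditional level of each branch; this is a property
of the published procedure itself, not an implementation artifact. No
multiple-testing correction is applied by default (matching per-feature
reporting); a Holm option exists.

## Classification protocol

Rows are sessions (2 per subject, 30 subjects at study scale), labels
`distracted` = positive. Evaluation is leave-one-subject-out: both
sessions of one subject form the test fold, z-score normalisation is
fitted on the training fold only, and grid search maximises LOSO
accuracy (ties resolve to the first grid point). Four families are
supported with the grids of the source protocol (`C` in $2^{-5..15}$,
$\gamma$ in $2^{-15..3}$, $k$ in 1..15, forest depth in {∞, 3, 5, 10}):

* **RBF-SVM** — implemented natively by solving the soft-margin dual QP
  with `quadprog` (no SVM package is available in the supported stack);
  the decision value is the score.
* **KNN** — native; even-$k$ ties are broken by the nearest neighbour's
  label, and the ROC score is the positive-neighbour fraction.
* **LDA** — `MASS::lda`; the positive-class posterior is the score.
* **Random forest** — native bagged CART with Gini splits and
  $\lfloor\sqrt{p}\rfloor$ features per node, 500 trees by default,
  seeded; the vote fraction is the score.

Feature elimination ranks all features once on the full matrix by
absolute paired statistic and evaluates nested suffixes of the ranking
from the full set down to one feature, re-running the grid search each
time. Ranking on the full matrix leaks label information across folds —
this mirrors the literal protocol; `rank_per_fold = TRUE` in `loso_cv()`
is the leakage-safe variant that recomputes the ranking inside every
training fold.

## The synthetic world

The generator states one fixed world, calibrated to the focused-condition
summary statistics of the study population, and injects the reported
effect directions when a session is distracted:

* RR tachogram: interval $n$ is
  $\mu + a_{LF}\sin(2\pi\,0.10\,t_n) + a_{HF}\sin(2\pi\,0.25\,t_n+\phi)
  + \varepsilon_n$. The 0.10 Hz term stands for blood-pressure
  (Mayer-wave) oscillations, 0.25 Hz for respiratory sinus arrhythmia;
  both sit inside the standard LF/HF bands. Per-subject
  hyperdistributions: $\mu \sim N(884, 25)$ ms, noise SD
  $\sim N(8, 2)$ ms, $a_{LF} \sim N(15, 4)$, $a_{HF} \sim N(20, 5)$ ms
  (truncated at physiological floors). Distracted sessions add 10 ms to
  the mean, 2 ms to the noise SD, scale $a_{LF}$ by 1.6 and total power
  by 1.15 — signs and sizes follow the published condition summaries
  (higher mean RR, SDRR, LF and TP when fatigued); every sign is a
  config field because the source itself is internally inconsistent
  about the LF/HF direction.
* ECG: a fixed QRS-like template (Gaussian R wave with symmetric
  negative flanking lobes, ~100 ms support) at each R instant snapped to
  the sample grid (250 Hz default), plus 0.3 Hz baseline wander, 50 Hz
  powerline, and white noise at 20 dB SNR.
* GSR (10 Hz): tonic drift around a $N(1.2, 0.4)$ µS level, SCRs at a
  Poisson rate of ~13/min with lognormal amplitudes (median ≈ 0.04 µS),
  measurement noise SD 0.002 µS (a realistic wearable noise floor,
  chosen a priori). Distracted sessions delay the first SCR by 2.5 s,
  lower tonic by 0.05 µS and the rate by 3/min — all small, mirroring
  the mostly non-significant electrodermal contrasts reported.
* Behaviour: 150 stimuli, 20% targets; hit probability ≈ 0.95 (−0.12
  when distracted), lognormal reaction times (×1.15 when distracted),
  concentration ratings 4-5 focused vs 1-2 distracted.

One master seed expands into per-session seeds through a documented
counter scheme (`session_seed()`), so cohorts are reproducible even if
sessions are generated independently.

**What a green test does and does not establish.** The generator's
tachogram is sinusoid-plus-noise (an integral-pulse-frequency-modulation
model was rejected for testability), its ECG morphology is a schematic
template, and its SCRs are exactly Bateman-shaped — so detection and
decomposition are evaluated under the model family they assume. Passing
tests establish correctness of the algorithms and the pipeline's
plumbing, and that the configured effect directions are recoverable
end to end; they do not certify performance on real recordings with
motion artifacts, ectopic beats, respiration-coupled variability or
non-Bateman sudomotor responses, and the headline accuracies of the
original study are expressly not reproduction targets.

## Numerical choices and degenerate inputs

* FISTA tolerances: relative objective change $10^{-8}$, checked every
  10 iterations; 150 warm-start + 300 joint-refinement iterations.
* Lomb grid: 0.002 Hz steps (below half the 1/300 Hz resolution of a
  5-min record); the f = 0 ordinate is defined as 0 on the mean-removed
  tachogram.
* Grid-search and elimination ties resolve deterministically (first
  grid point, original column order).
* Zero-variance inputs raise typed errors (`distractr_degenerate_input`)
  rather than NaN: Shapiro-Wilk, paired tests on identical conditions,
  Poincare ratio of a constant train (constant up to $10^{-8}$ relative
  round-off).
* HF = 0 reports LF/HF = Inf with a warning; undefined sample entropy
  (no template matches) returns NaN with a warning, and classifier
  input assembly refuses matrices with missing values other than the
  documented Latency imputation.

## Known limitations

* The Bateman time constants are fixed, not optimised per recording.
* The tonic/phasic split in SCR-dense stretches is partially
  unidentifiable; the joint refinement resolves it in favour of small
  reconstruction error near the two-stage attribution.
* Trough-to-peak SCR scoring, EDF input, multi-lead ECG and arrhythmia
  handling are out of scope.
* With 30 subjects, LOSO accuracies move in steps of 1/60; differences
  smaller than ~3 percentage points between configurations are not
  meaningful at this scale.
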