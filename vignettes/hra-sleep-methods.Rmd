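---
title: "Methods: RR-interval descriptors, labeling rules, and clustered models for sleep staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RR-interval descriptors, labeling rules, and clustered models for sleep staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and numerical conventions behind
`hrasleep`: what each descriptor measures, how segments acquire stage and
transition labels, how the clustered one-versus-all models are fit and
selected, what the synthetic cohort generator emulates, and where the open
design choices were and why they were resolved the way they were.

## The problem

Polysomnography assigns each moment of sleep to one of five stages — wake
(W), three non-REM stages of increasing depth (N1, N2, N3), and REM (R) —
using EEG, EOG and EMG channels. The RR-interval series (time between
successive heartbeats, in ms) is far cheaper to record and is shaped by the
autonomic shifts that accompany those stages: deep NREM is
vagally dominated (slow, regular, high-frequency-rich heart rate), REM and
wake show relatively higher low-frequency power and variability. `hrasleep`
quantifies how much stage information the RR series alone carries: it
computes windowed descriptors, attaches stage labels from an expert
hypnogram, and asks a clustered regression model to separate each stage (or
stage transition) from everything else.

## Windowing and labels

Recordings are cut into consecutive 5-minute windows, `[k*300, (k+1)*300)`
seconds; a beat belongs to the window containing its onset and a trailing
partial window is dropped. Half-open windows make the partition unambiguous;
nothing is counted twice.

Each window receives per-stage occupancy fractions — the share of the window
covered by each stage — rounded half-up to one decimal. All labeling rules
operate on this rounded 0.1 grid:

* **Certain stage**: fraction ≥ 0.7. The threshold is inclusive, so a
  segment with 0.70 of one stage is certain while 0.69 is not, and at most
  one stage can be certain per segment.
* **Transition S → E**, per segment `t`, marked when either rule fires:
  * *Rule A*: both stages present (`f_S[t] > 0`, `f_E[t] > 0`), the ending
    stage still small (`f_E[t] ≤ 0.6`) and not receding
    (`f_E[t] ≥ f_E[t-1]`, with the pre-recording value taken as 0).
  * *Rule B*: the change sits on a window boundary — the segment is free of
    E (`f_E[t] = 0`) but contains S, and the next segment has
    `0 < f_E[t+1] ≤ 0.6`.

  Only seven transition types are labeled (N1–N2, N2–N3, N2–R, N3–N2, N3–R,
  R–N2, W–N1); other combinations are left unlabeled. Note that the two
  rules are not mutually exclusive: when a stage change falls near a
  boundary, rule B can mark the last pure-S segment and rule A the mixed
  segment that follows. Both markings are retained — the rules are applied
  literally, and any further filtering is left to the modeling layer. A
  segment may also carry a certain-stage label and a transition label
  simultaneously; nothing forbids it and the models treat the responses
  independently (one-versus-all).

## Descriptors

All descriptors are computed per window from normal-to-normal (sinus)
intervals only. Beats flagged as artifacts (either by the input annotations
or automatically, for intervals outside 200–3000 ms) split the series, so no
successive-beat pair, Poincaré pair or run ever bridges an edited beat. The
alternative policy — dropping artifact beats and concatenating — is exposed
in `mask_artifacts()` for users who prefer it; how edited beats inside a
window should be treated is genuinely underdetermined, so both policies are
first-class.

**Time domain.** SDNN is the standard deviation of the NN intervals (sample
divisor by default; configurable, as conventions differ). pNN30 is the
percentage of successive differences strictly exceeding 30 ms in absolute
value — the same construction as the classical pNN50 at a lower threshold.

**Poincaré geometry.** The Poincaré plot scatters `(x_i, x_{i+1})`. Each
point has a signed distance from the identity line,
`d_i = (x_{i+1} - x_i)/√2`, and a signed position along the identity line
about the plot centroid, `s_i = (x_i + x_{i+1} - 2x̄)/√2`. SD1 and SD2 are
the root mean squares of `d` and `s` — second moments about the identity
line and centroid, *not* re-centred standard deviations. This convention is
deliberate: it is the one under which the asymmetry partitions below are
exact algebraic identities rather than approximations, and it preserves the
rotation identity `SD1² + SD2² = mean((x_i - x̄)² + (x_{i+1} - x̄)²)`.

**Heart rate asymmetry (variance based).** A deceleration is an RR
lengthening (`d_i > 0`), an acceleration a shortening. The variance
decompositions

* `SD1d² = mean over pairs of d_i² restricted to d_i > 0`, `SD1a²`
  analogously for `d_i < 0`, so `SD1² = SD1d² + SD1a²`;
* `SD2d²` and `SD2a²` split `Σ s_i²` by the sign of `d_i`, with points on
  the identity line (`d_i = 0`) contributing half to each side, so
  `SD2² = SD2d² + SD2a²`;
* `SDNNd² = (SD1d² + SD2d²)/2` and likewise `SDNNa²`, so
  `SDNNd² + SDNNa² = (SD1² + SD2²)/2`

hold to machine precision for every input; the test suite asserts them at
1e-9 relative tolerance on a thousand random series. The half-split of
neutral points is the tie-break that makes the second and third partitions
close exactly.

**Heart rate asymmetry (microstructure).** A run is a maximal block of
consecutive same-sign successive differences; its length is the number of
differences. DRi/ARi count deceleration/acceleration runs of length i
(DR4/AR4 enter the models), DRMAX/ARMAX are the longest runs in the window.
The Shannon entropy of the run-type/length distribution (relative
frequencies over all runs, neutral runs included in the total by default —
configurable, since conventions vary) splits into a deceleration component
HDR, an acceleration component HAR, and a neutral remainder; `0·log 0 := 0`
and the logarithm is base 2. Every deceleration/acceleration quantity is
exactly mirrored by time reversal: reversing a series swaps SD1d↔SD1a,
DRi↔ARi, DRMAX↔ARMAX, HDR↔HAR, pNN30dec↔pNN30acc. The suite asserts this
bit-for-bit.

**Spectral.** The tachogram (interval value at its onset time) is resampled
to an even 4 Hz grid by cubic splines, mean-removed, and a Welch-averaged
periodogram is computed (Hann-tapered 120-s windows, 50% overlap, one-sided
density normalised so its integral equals the variance). LF power integrates
0.04–0.15 Hz, HF power 0.15–0.40 Hz, half-open at the top edge so 0.15 Hz is
counted once; LF/HF is their ratio, reported missing (not infinite) when HF
power is zero. The spectral estimator is the least standardized step of any
HRV pipeline — different estimators shift absolute LF/HF values — so a
Lomb–Scargle alternative operating directly on the uneven samples is
provided, and the tests only pin down estimator-independent behaviour
(single-tone band dominance, Parseval, scaling).

**Sample entropy.** SampEn(m, r) = `−ln(A/B)`, with B the number of
m-template pairs within Chebyshev tolerance r and A the same for
m+1-templates, self-matches excluded, template starts ranging over
`1..n−m` for both counts (so a constant series gives exactly 0). Defaults
`m = 2`, `r = 0.2·SD` of the window — the field-standard convention, used
because the appropriate values are situation-dependent and the absolute
SampEn level depends on them. The implementation vectorises over template
offsets; it is tested for exact equality against a literal double-loop
oracle up to n = 500.

## Clustered one-versus-all models

Segments within a subject are correlated, so each binary response (5 certain
stages, 7 transitions) is modeled marginally with generalized estimating
equations: logistic link, subjects as clusters, a working correlation
R(α), and robust (sandwich) covariance. The solver is Fisher scoring on the
estimating equations with moment re-estimation of α from Pearson residuals
at each step; exchangeable and AR(1) structures use the closed-form inverse
of R(α), and independence reduces to ordinary logistic regression (the
suite checks equality with `glm` to 1e-6 on singleton clusters).
Exchangeable is the default structure: GEE coefficient estimates are
consistent under misspecification, and exchangeability is the natural first
choice for segments nested in subjects; AR(1) is available for users who
expect serial decay across adjacent segments.

Covariates with zero variance are excluded (coefficient `NA`), and exactly
collinear columns are dropped by QR rank detection — relevant here because
the full descriptor vocabulary is rank-deficient by construction
(`pNN30 = pNN30dec + pNN30acc`), so a full-vocabulary model silently loses
one of the three, just as `glm` would alias it.

**Backward selection.** From the full model, the covariate whose removal
most lowers the criterion is dropped, until no removal improves it. "AIC"
for GEE is ambiguous; the default criterion is the AIC of the binomial
quasi-likelihood at the GEE estimates (`−2·QL + 2p`), and Pan's QIC
(`−2·QL + 2·trace(Ω̂_I V̂_R)`) is available as the statistically
conventional alternative. The accepted-step criterion sequence is
non-increasing by construction and is asserted in tests.

**Split.** Subjects — never segments — are assigned to training or test.
Subjects are grouped into strata of similar certain-stage composition
(k-medoids via `cluster::pam` on per-subject label-share vectors, 4 strata
by default) and ~70% of each stratum is randomly assigned to training. With
31 subjects the achieved segment-level training share lands near 0.71 on
average. Each stratum keeps at least one subject on each side when it has
two or more.

**Evaluation.** Hard labels use `prob ≥ threshold` (default 0.5; ties
positive). Confusion-matrix metrics (accuracy, precision, recall, F1)
report `NA` for undefined ratios rather than conventional zeros, and AUC is
the Mann–Whitney rank estimator with half-credit for ties (exactly the
all-pairs count). Report tables round half-up to two decimals; raw values
are retained. When a response's held-out slice is too sparse to evaluate
(few positives), the pipeline falls back to evaluating on the training
subjects and flags the result `on_training_set = TRUE` — sparse transition
types make this fallback unavoidable in small cohorts.

## The synthetic cohort generator

Real overnight PSG cohorts cannot be bundled, so the generator produces
stage-conditioned RR series with *known* structure — enough structure for
every pipeline stage to be testable end-to-end, and no more:

* **Hypnogram**: a first-order Markov chain on 30-s epochs with
  `P = p·I + (1−p)·π`, where π is the target occupancy law. This
  construction has π as its exact stationary distribution for any
  persistence p (default 0.88, giving mean bouts of roughly 4–6 minutes),
  so occupancy is controlled without tuning. Default targets
  (W 0.29, N1 0.12, N2 0.27, N3 0.14, R 0.18) describe a sleep-clinic
  population with abundant wake: N2 sits near one quarter of the recording
  and REM under a fifth. The price of exact stationarity is that the
  *transition mix* is not faithful to sleep architecture (e.g. direct W→N3
  jumps are possible); only the seven labeled transition types are modeled
  downstream, so this mainly thins the transition labels rather than
  corrupting them.
* **RR series**: per beat, mean RR of the active stage plus an AR(1)-white
  noise mixture (total scale `sd_scale`, white share `complexity_noise` —
  the SampEn dial), two sinusoidal oscillators at 0.10 and 0.25 Hz (the
  LF/HF dial), and a deceleration-event process: with probability
  `asym_skew` per beat, an abrupt lengthening followed by a geometric
  recovery ramp (factor 0.72/beat). The events reproduce the asymmetry
  signature of real heart rate — decelerations contributing more to
  short-term variance, accelerations forming longer and more numerous runs.
  Two fixed oscillators are the minimum structure that makes LF/HF
  stage-discriminative; this is a testability choice, not cardiorespiratory
  modeling.
* **Cohort**: subjects draw a normal shift of all stage means
  (`mean_rr_sd`, default 40 ms) and lognormal multipliers on
  noise/oscillator amplitudes (`amp_cv`, default 0.20). These random
  effects induce the within-subject correlation that the working
  correlation absorbs; setting them to zero yields α ≈ 0.

What passing tests on synthetic cohorts do **not** show: robustness to
ectopy and artifact patterns of real ECG, respiratory-frequency drift,
apnea-related oscillations, circadian trends, or the label noise of human
scoring. Synthetic recovery results bound what the pipeline can do under
its own assumptions, nothing more.

## Problem sizes and determinism

Tests run on reduced cohorts (typically 8 subjects × 2 h, 20 seeds for the
recovery suite) — large enough for the configured effects to be detected
with margin, small enough to keep the suite quick. All randomness flows
from explicit integer seeds: cohort generation derives per-subject streams
from a master seed, and the split takes its own seed, so any run is
reproducible to the byte.

## Known limitations

* Absolute LF/HF and SampEn levels are estimator- and parameter-dependent;
  cross-study comparison of raw coefficients is not meaningful.
* The exchangeable moment estimate of α is noisy on small cohorts and can
  go slightly negative under weak clustering; it is clamped to the valid
  range and should be read as a nuisance parameter, not an estimand.
* Backward selection inherits the usual caveats of stepwise procedures;
  selected-model p-values are exploratory.
* Rule A and rule B can both mark the same physical transition in adjacent
  segments; consumers wanting exclusive marks must post-process.
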