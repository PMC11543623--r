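---
title: "Quantifying hyperarousal in sleep EEG: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hyperarousal in sleep EEG: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`somnarch` implements an analysis pipeline for polysomnography (PSG) EEG
aimed at the neurophysiology of chronic insomnia: the hypothesis that
insomnia involves *hyperarousal*, a persistently elevated cortical arousal
state visible in the sleep EEG as excess high-frequency (beta/alpha) power,
persistent wakefulness, and wake-like spectral profiles during the night.
The package quantifies these signatures and estimates how a treatment shifts
them in a randomized multi-site trial design. This vignette documents the
models, the tunable parameters, the synthetic-data generator that makes the
pipeline testable end-to-end, and the design decisions taken where the
methodology left genuine freedom.

## The feature families

### Sleep-wake transition probabilities

A hypnogram — the sequence of scored 30-second epochs labelled W, N1, N2,
N3, REM between lights-off and lights-on — is treated as a realization of a
first-order Markov chain. `transition_counts()` tabulates all consecutive
epoch pairs (self-transitions included) into a 5×5 count matrix; with $n$
epochs it holds exactly $n-1$ counts. `transition_probabilities()`
row-normalises occupied rows; a stage never occupied as a from-stage yields
a missing row, not zeros. Probabilities are per-recording; cohort summaries
average per-recording probabilities rather than pooling counts, because the
recording is the modelling unit of the statistical layer. Epochs outside the
lights-off/lights-on span are excluded, and a pair straddling an unscored
epoch would be dropped.

### Multitaper spectral features

Band powers are estimated by multitaper spectral density estimation on
2-second windows with 1-second overlap. The four canonical bands are delta
0.5–4 Hz, theta 4–8 Hz, alpha 8–12 Hz and beta 12–30 Hz (half-open
intervals, so adjacent bands never double-count a frequency bin). The
DPSS (Slepian) tapers are computed from the symmetric tridiagonal
eigenproblem; defaults are time–bandwidth product NW = 2 with K = 3 tapers.
The window/overlap scheme is fixed by the method; the taper count is not,
and is exposed in `multitaper_bandpowers()` — a reproducibility caveat worth
stating, since different NW/K choices change the bias/variance trade-off of
every band power.

The aggregation order is: absolute band powers of the 2-s windows are
averaged to each 30-second epoch; *relative* power (each band divided by the
four-band total) is computed per epoch; epoch fractions are averaged across
all epochs of a stage and across the central channels (C3, C4); the stage
mean is then natural-log transformed to reduce skew. Windows overlapping any
artifact-flagged 3-second segment are discarded; an epoch with no surviving
window is missing, and a stage absent from the hypnogram is reported
missing, never zero.

Artifact masking uses the root-mean-square amplitude of contiguous
3-second segments anchored at lights-off: a segment is rejected when its
RMS is ≤ 1 µV (flat/disconnected) or ≥ 250 µV (movement/sweat), thresholds
chosen to sit well outside the physiological 10–100 µV range. Before any of
this, recordings are high-pass filtered at 0.5 Hz to normalise acquisition
differences; the realization is a zero-phase forward–backward 4th-order
Butterworth, chosen so filtering cannot shift spindle peak times.

### Spindles and slow oscillations

Spindle analysis runs on one channel at a time: the signal is resampled to
128 Hz, low-pass filtered at 35 Hz, and N2 epochs whose delta power exceeds
2.5× the mean over a 15-epoch sliding window are rejected (the window
shrinks symmetrically at the edges). Detection convolves a complex Morlet
wavelet centred at 13.5 Hz (7 cycles — the cycle count is not fixed by the
method and is configurable), squares the magnitude, and smooths over 0.1 s.
Events require at least 0.3 s above 4.5× the all-N2 mean of this smoothed
power, are extended up to 0.5 s per side while power stays above 2× the
mean, merged when separated by less than 0.5 s, and rejected when longer
than 3 s. The flank (2×) rule is interpreted on the same smoothed
wavelet-power scale as the core rule. Each event's observed frequency is
the dominant 11–15 Hz component of the low-passed signal over its span
(zero-padded periodogram with parabolic peak interpolation), classing it
fast (≥ 13 Hz) or slow (11–<13 Hz).

Slow oscillations are intervals between consecutive positive-to-negative
zero crossings of the 4.5 Hz low-passed signal, 0.8–2 s long, inside N2.
Because they are delimited by *consecutive* crossings they can never
overlap. A spindle whose power peak falls inside an SO gets a coupling
phase: $360°\,(t_{peak}-t_{start})/(t_{end}-t_{start})$.

Per channel, four features summarise a recording: density (spindles per
minute of N2), dispersion (variance of per-epoch counts divided by their
mean; *population* variance by default, configurable to sample variance —
the convention is not fixed by the method), and the circular mean SO phase
for fast and slow spindles separately (the phase summary statistic is
likewise an open choice; the circular mean is the natural one for angles).

### The wake EEG similarity index (WESI)

WESI places every artifact-free 3-second segment on a 0 (sleep-like) to 1
(wake-like) continuum. Features are the four relative band powers,
logit-transformed ($\log(x/(1-x))$, clipped to $[10^{-6}, 1-10^{-6}]$) and
z-scored with statistics estimated *from the training split only*. Training
labels all sleep-stage segments 0 and within-night wake segments 1, splits
segments 80/20 into training and test sets, and reports held-out AUC and
accuracy. The classifier family here is maximum-likelihood logistic
regression on the 4 features: with four well-conditioned features and large
segment counts it is the minimal model producing calibrated 0–1 scores, and
it makes determinism and serialization trivial. The split is by segment,
with the caveat that segments of one recording are correlated; a
by-recording split is the stricter alternative when leakage matters.
Scoring refuses feature tables whose normalization statistics do not
fingerprint-match the model's, so scores can never silently mix
normalizations.

Stage-level WESI is the mean of *logit-transformed* segment scores; the
linear-scale summary is the inverse logit of that mean (deliberately not
the arithmetic mean of raw scores). Model estimates and confidence
intervals are mapped back to the 0–1 scale by the delta method with a
central finite-difference derivative (step $10^{-5}$); a parametric
bootstrap validator (default 10 000 draws) is provided and agrees with the
finite-difference interval to within 0.001 at cohort-scale standard errors.

## The statistical layer

Every feature is analysed with a null/main pair of linear mixed models,
fitted by maximum likelihood (not REML — the likelihood-ratio test between
the pair is only valid under ML; estimates and CIs are reported from the
same ML fits for internal consistency):

```
null:  value ~ age * sex * month * night * study + (1 | subject) + (1 | site)
main:  null fixed effects + month * night * treatment
```

with age centred at 50 years, sex coded +1 (female) / −1 (male), month a
categorical factor (0 = baseline, 1, 3), night a factor (1, 2), study the
trial identifier, and treatment a categorical factor with placebo reference
(categorical, because per-dose contrasts are the quantities of interest; a
numeric dose coding would impose linearity in dose). A factor observed at a
single level is dropped from the fixed structure. A singular random-effect
fit falls back to dropping the site intercept, with a warning.

Treatment effects are reported as placebo-corrected changes from baseline:
$(\bar{y}_{a,m} - \bar{y}_{a,0}) - (\bar{y}_{p,m} - \bar{y}_{p,0})$, built
as a linear combination of fixed effects evaluated at age 50, the sex
midpoint, averaged over nights and studies, with delta-method (Wald) 95%
intervals. Significance uses a dual criterion: the LRT between main and
null must survive Benjamini–Hochberg FDR correction across features within
the family (spectral, spindle, WESI, transitions), *and* the specific
contrast must have p < .05.

Transition counts are sparse: many recordings lack a given transition
entirely. Per transition, prevalence (fraction of recordings with a nonzero
count) selects the model: below 1.5% the transition is not modelled; from
1.5% to 98.5% a two-stage hurdle model; above 98.5% an ordinary generalized
mixed model. Both hurdle stages are logistic-link generalized mixed models
with the shared covariates: the zero stage models the zero/nonzero
indicator; the nonzero stage models counts as successes out of the
recording's $n_{epochs}-1$ transition opportunities — a binomial
construction adopted because the nonzero-stage outcome distribution is
otherwise underdetermined by "logistic link"; it is an interpretation, and
is documented as such. The hurdle fixed structure uses additive covariates
with month × treatment terms rather than the linear layer's full factorial:
binomial stages on sparse counts do not support 50+ fixed effects. Count
stages carry an observation-level random intercept: transition counts from
a Markov chain are overdispersed relative to a conditional binomial (the
from-stage occupancy varies across recordings), and without it Wald tests
on null cells reject far above the nominal rate.

One interpretive caveat the pipeline makes explicit: count models and
probability difference-in-differences answer different questions. Raising
the wake-to-N1 *probability* raises N1 occupancy, and with it the
*count* of N1-to-N2 transitions, even when the conditional N1-to-N2
probability is untouched. Reports therefore annotate significance
direction by the count-model coefficient, and show the probability
difference-in-differences separately.

## The synthetic cohort generator

No public PSG trial data accompany this problem, so the generator is a
first-class module: every downstream stage is tested against cohorts whose
ground truth is known exactly.

**Signal tier.** EEG is synthesized per stage as a sum of four band-limited
filtered Gaussian noise components scaled so the band variance fractions
equal the stage profile and total RMS matches the profile amplitude —
analytically controllable spectra, which is the point. N2 receives
Hann-windowed 13.5 Hz bursts (Poisson counts at the profile spindle rate,
default 2/min, 50 µV peak — mid-range for visually scored spindles) and N2/N3
receive 0.8–1.2 Hz negative-first sine cycles (so their delimiting
zero-crossings mimic SO timing). Stage profiles default to the canonical
ordering of stage spectra (alpha-dominant wake through delta-dominant N3)
with RMS amplitudes 30–70 µV, inside the physiological range so clean
signal survives artifact rejection. Artifacts are inserted as flat
(< 1 µV) or high-amplitude 3-s segments at known positions. What this tier
does *not* emulate: K-complexes, eye movements, ECG contamination, spindle
chirp, circadian/ultradian structure, or realistic waveform morphology —
passing signal-tier tests shows the estimators recover controlled spectra
and events, not that they are robust to every real-world artifact.

**Feature tier.** For statistical testing, features are generated directly
on the analysis scale (percentage points of relative power; logit WESI):
value = grand mean + visit drift + night offset + subject intercept + site
intercept + injected placebo-corrected delta + residual noise. Injecting on
the analysis scale is deliberate: recovery can then be checked against an
exact known truth. Default variance components (e.g. wake relative delta:
subject SD 5, site SD 1, residual SD 3 percentage points) are sized to the
between-subject and night-to-night variability plausible for stage-averaged
spectral fractions in a large insomnia cohort; within-subject correlation
across visits and site variance magnitudes are not pinned down by any
published table, so they are configurable defaults, documented rather than
inferred. Two nights of a visit share the subject intercept and differ by a
small fixed night offset. The default trial shape is 586/584/296 subjects
(placebo/25 mg/50 mg), two studies (the 50 mg arm in study 1 only), 50
sites, visits at months 0, 1, 3, two nights per visit.

**Transition tier.** Hypnograms are drawn from arm×visit-specific Markov
matrices: a plausible insomnia baseline matrix (strong W and N2
self-transition, W occupancy ≈ 30%) perturbed by injected cell deltas.
Perturbations must keep every row stochastic, so the non-significant cells
of a perturbed row absorb the remainder. The Markov engine is vectorised
over recordings, which keeps cohort-scale simulation (thousands of nights ×
960 epochs) in plain R.

## Numerical choices and degenerate inputs

* Indices are 0-based with half-open intervals everywhere (epoch $k$ spans
  $[30k, 30(k+1))$ seconds from lights-off); the 3-s segment grid is
  anchored at lights-off and tiles each epoch exactly (10 per epoch).
* Logit clipping bound $\varepsilon = 10^{-6}$ for relative powers and
  scores at {0, 1}; clipping is logged, not fatal. A zero-total-power
  window is excluded and logged.
* A training split with a zero-variance feature, or a single class, is an
  error, not a silent degenerate fit.
* All-zero or all-nonzero counts handed to the hurdle fit raise an error
  pointing at the prevalence rule that should have routed them elsewhere.
* Every stochastic function takes an explicit seed; derived child seeds are
  computed in double precision and reduced below $2^{31}-1$.

## Problem sizes used by the test suite

The suite exercises recovery at the cohort shapes above: transition
recovery with 300 subjects/arm and 960-epoch nights over 20 replicates;
spectral and WESI recovery with 586 + 296 subjects over 20 replicates;
null calibration over 200 replicates at 100 subjects/arm (a reduced cohort,
chosen so 400 mixed-model fits remain desk-scale); signal-tier round trips
on 5–10-minute pure-stage segments. Under these null conditions the LRT
rejects at the nominal 5% rate and the Wald intervals cover at ~96%; the
dual criterion, being a conjunction, flags strictly less often than the LRT
gate alone.

## Limitations

Single-night aggregate features ignore within-night dynamics (when during
the night a treatment changes the EEG is invisible here). The WESI
stand-in is trained on synthetic or user-supplied staged data, not on any
large clinical corpus, so its absolute scores are not comparable across
differently-trained models — only within one. The hurdle nonzero-stage
binomial construction is one defensible reading of an underdetermined
specification. And the generator's realism bounds what green tests prove:
they certify correct recovery of known structure, not performance on
arbitrary clinical recordings.
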