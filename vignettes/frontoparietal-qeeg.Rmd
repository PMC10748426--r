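---
title: "Quantitative EEG coma prognosis with a limited frontoparietal montage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative EEG coma prognosis with a limited frontoparietal montage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpqeeg)
```

## The problem

Early prognosis of comatose patients in intensive care guides clinical
decision-making, and continuous resting-state EEG is the natural bedside
monitor for it. Full 10--20 montages are labor-intensive; because the
frontoparietal network is consistently implicated in recovery of
consciousness, a reduced montage of four electrodes -- F3, F4, P3, P4
referenced to Cz -- retains the spatial information most relevant to coma
outcome while staying practical in the ICU.

`fpqeeg` implements the complete analysis for this setting: preprocessing of
the four-channel recordings, extraction of 48 quantitative features across
the temporal, frequency and connectivity (spatial) domains, and the
statistical chain that turns a patient-by-feature table into cross-validated
logistic prognostic models of unfavorable 60-day outcome (Glasgow Outcome
Scale 1--2 versus 3--5). A synthetic cohort generator reproduces the
statistical contrasts the analysis assumes, so every stage is testable
without patient data.

## Preprocessing

Recordings (EDF or delimited text plus a sidecar config; microvolts; 250 Hz
is the montage's standard rate) are cut into contiguous non-overlapping
2-minute epochs starting at the first sample; a trailing partial window is
discarded so every epoch feeds the feature estimators with the same length.
Each epoch is then:

1. **baseline-calibrated** -- per-channel mean removal. This is the minimal,
   idempotent reading of "baseline calibration"; no detrending beyond the
   mean is applied, and the 0.1 Hz high-pass edge of the next step removes
   any residual drift.
2. **bandpass filtered** -- 0.1--40 Hz Butterworth, order 4, applied forward
   and backward so the pass is zero-phase and the effective attenuation is
   twice the single-pass order. Finite windows are padded by odd reflection
   over one filter-settling length (three periods of the slowest passband
   component) to suppress edge transients; the first and last seconds of an
   epoch still carry slightly larger numerical transients than the interior,
   which is inherent to zero-phase filtering of finite windows.
3. **artifact-rejected** -- an epoch is discarded iff any channel contains a
   sample with |amplitude| above 200 uV, the only dimensionally coherent
   reading of a point-wise density threshold; movement and electrode pops
   are the target. The QC log records every decision with the offending
   channel and sample. Rejection runs after filtering, following the listed
   preprocessing order; with a zero-phase filter the decision is in practice
   insensitive to this choice.

A subject whose epochs are all rejected yields no feature vector and is
reported as a fatal QC failure rather than silently imputed.

## The 48 features

All features are computed per epoch, collapsed across the four channels by
the median (connectivity metrics are inherently pairwise and skip this
step), and averaged over the retained epochs, so one row per patient enters
the statistics. Missing epoch values (e.g. Hjorth parameters of a flat
channel) are excluded from the average and counted.

**Temporal (8).** Burst suppression ratio (BSR): the fraction of the epoch
whose amplitude envelope -- absolute value smoothed over 100 ms -- stays at
or below 5 uV for at least 0.5 s. The run-length requirement stops the zero
crossings of ordinary oscillations from counting as suppression; both knobs
are configurable. RMS: the population standard deviation, the quantitative
analogue of the ACNS "voltage" descriptor. Hjorth activity (variance),
mobility and complexity, with the derivative taken as the first difference
times the sampling rate so a sinusoid of frequency $f$ has mobility
$2\pi f$ rad/s. Kurtosis (non-excess, normal = 3) and skewness as
standardized population moments. Shannon entropy of the amplitude histogram
(64 equal-width bins over the epoch's range, natural log; the bin count is a
configuration knob because the entropy scale depends on it).

**Frequency (16).** A Welch spectrum (4-s Hann segments, 50% overlap,
density-normalised so the spectral integral matches the variance) yields
band powers for delta (0.5--4 Hz), theta (4--8), alpha (8--13) and beta
(13--30). Total power is defined as the sum of the four band powers so the
four `/total` ratios sum to one; the six between-band ratios and
$\beta/\alpha$ complete the ratio set. `f_m` is the frequency of the
spectral maximum in 0.5--30 Hz and `f_h` the 95% spectral edge of the same
band. "Upper cutoff frequency" has no unique definition; the 95% spectral
edge is the conventional choice and the edge fraction is configurable. We
report both `f_m` and `f_h` in Hz; reference median values near 0.5 and 0.85
suggest a normalized-frequency convention elsewhere, which is why these two
features are documented prominently but treated like any other feature by
the statistics.

**Connectivity (24).** For each of the six channel pairs: Pearson
correlation; mutual information $H(x)+H(y)-H(x,y)$ from amplitude histograms
(same binning policy as the entropy feature; negative estimates from
histogram bias are clipped to zero); and two phase metrics from the analytic
signal of the broadband-filtered channels -- the phase locking value
$\mathrm{PLV} = |\langle e^{i\varphi_{xy}(t)}\rangle|$ and the phase-lag
index $\mathrm{PLI} = |\langle \mathrm{sign}\,\varphi_{xy}(t)\rangle|$,
where $\varphi_{xy}$ is the phase difference. PLI ignores consistent
zero-lag coupling (volume conduction through the common Cz reference), which
is exactly why it is the connectivity feature of interest with so few
electrodes. Phases are computed once on the broadband (0.1--40 Hz) epoch,
not per rhythm, because a single value per pair is reported; the modulus in
both definitions is the standard convention.

## Statistical pipeline

`run_prognosis()` chains the stages; each is exported separately.

* **Group comparison** (`compare_groups`): per feature, Shapiro--Wilk
  normality in each outcome group and Levene's test (classic, mean-centred,
  matching the defaults of mainstream clinical statistics software) gate the
  choice between a pooled two-sided t-test with mean ± SD summaries and a
  two-sided Mann--Whitney U with median (IQR) summaries. The U test is
  reported as the tie-corrected standardized z, signed so that the favorable
  group ranking higher is positive -- the scale on which such tables print
  signed values like −3.992. Benjamini--Hochberg correction is applied
  across all 48 features via `stats::p.adjust`.
* **Partial-correlation pruning**: spectral band powers scale with overall
  voltage, so their group differences can be RMS in disguise. Every
  BH-significant feature except RMS is partially correlated with the ordinal
  60-day GOS controlling for RMS; the rank-based (Spearman-flavoured)
  partial correlation is the default because GOS is ordinal, with the raw
  Pearson flavour behind a flag. Features that lose significance are pruned
  as voltage surrogates.
* **MCA** (`mca_discriminate`): survivors are median-split (parameter-free
  and reproducible) and analysed together with the outcome by
  indicator-matrix correspondence analysis. Discrimination measures are
  correlation ratios of the object scores across each variable's categories,
  so a variable perfectly aligned with the outcome scores 1 on the
  separating dimension; the sign of dimension 1 is fixed so the unfavorable
  category sits on the positive side.
* **Logistic models**: single-feature fits report odds ratios with Wald 95%
  CIs; complete separation is flagged and the CI reported unbounded rather
  than as a numeric artifact. The multiple model is built by forward
  selection with backward pruning driven by likelihood-ratio tests at
  p-enter 0.05 / p-remove 0.10 (conventional stepwise defaults), ties broken
  by smaller p then input order so the procedure is deterministic.
* **Cross-validation** (`cv_prognosis`): patients are dealt into K = 3 folds
  stratified jointly on outcome x etiology -- cells largest first, members
  dealt across folds re-ranked by current size each cycle, so fold sizes and
  per-cell counts both differ by at most one, reproducibly from a seed.
  Held-out predictions at cutoff 0.5 (unfavorable = positive) give per-fold
  sensitivity, specificity, PPV, NPV and false-positive rate with Wilson
  score intervals; the pooled out-of-fold predictions give the merged ROC
  and a rank-formulation AUC with a DeLong interval. Wilson, Wald and DeLong
  are used because 95% CIs of proportions, odds ratios and AUCs are
  conventionally reported with these methods; each table labels its method.

## The synthetic cohort generator

`gen_cohort()` emulates the *statistical structure* of a comatose ICU
cohort, not biophysical EEG: there is no forward head model and no 1/f
background calibrated to real recordings. Each patient's four channels are
sums of band-filtered Gaussian noise with configurable delta/theta/alpha/
beta variance weights; configured channel pairs share a narrowband (2--6 Hz)
source injected with a constant phase lag plus slow phase jitter, which
makes the phase-lag index controllable per pair; a common burst-suppression
gate with exponential segment durations (mean burst 3 s) sets the suppressed
fraction; independent sensor noise (1 uV) completes the signal, which is
saturated at ±135 uV so generated physiology always passes the amplitude QC
rule even after filter ringing (artifacts appear only when explicitly
injected).

The outcome classes differ in the directions the analysis expects:
the unfavorable class has a higher suppressed fraction (0.45 vs 0.12), lower
burst amplitude (14 vs 30 uV), a beta-shifted alpha/beta balance
(beta/alpha weight ratio 2 vs 0.5) and weaker, noisier F3--P4 coupling
(strength 0.25 at jitter 1.2 vs 0.8 at 0.25), with lognormal within-class
variability on every parameter. The GOS template is 39/20/10/7/5 for GOS
1..5 (81 patients, 22 favorable), etiology marginals follow the reference
cohort per class, and every per-patient seed derives from the master seed,
so cohorts are fully reproducible.

These defaults were chosen once to reproduce the direction and significance
pattern of the group contrasts, not any particular table of medians --
patient EEG depends on recording conditions a simulator cannot know. The
resulting contrasts are *cleaner* than clinical data (standardized
differences well above 0.8, near-perfect cross-validated AUCs), so passing
the end-to-end tests demonstrates that the pipeline recovers planted
structure of the expected kind, not that it would achieve any particular
performance on real patients.

## Numerical choices and problem sizes

Degenerate inputs are reported as missing, never coerced to zero: Hjorth
mobility of a constant channel, correlations of a flat feature, ratios of a
zero-power spectrum. Negative MI estimates are clipped at zero. The
test-suite problem sizes are chosen to keep a full run on one CPU within
minutes while leaving the estimators in their asymptotic regime: oracle
fixtures use 12-s epochs at 100 Hz, Monte-Carlo checks use 30 000 samples,
and the end-to-end recovery uses 20 replicates of an 81-patient cohort with
one 2-minute recording per patient -- enough for one epoch per subject,
which is the minimum the aggregation path accepts. The default recording
duration for the generator itself is 30 minutes, the montage's standard
monitoring duration.

## Known limitations

* Re-referencing and montage transformation are out of scope; data are
  assumed recorded against Cz. So are ocular/muscle artifact decomposition
  and epileptiform-pattern detection.
* The entropy and MI scales depend on the histogram bin count (64 per axis
  by default); comparisons are internally consistent but not directly
  comparable to estimators with other binning policies.
* The subgroup path (strokes, TBI) only re-runs the group comparison on a
  subset; no subgroup-specific model fitting with performance claims is
  attempted at subgroup sample sizes.
* EDF support covers the standard 16-bit format with a shared sampling rate
  across signals, which is what four-channel ICU exports look like.
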