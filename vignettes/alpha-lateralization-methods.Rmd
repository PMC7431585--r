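---
title: "Methods: alpha lateralization in a retro-cue working-memory task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alpha lateralization in a retro-cue working-memory task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphalat)
```

## The scientific question and the measurement

When a cue arrives *after* stimuli have left the world, attention must be
re-oriented inside working memory. Posterior alpha-band (8–13 Hz) EEG
oscillations index where covert spatial attention points: alpha power tends
to drop over the hemisphere contralateral to an attended location and to
rise contralateral to an ignored one. In the auditory retro-cue task this
package models, listeners hold one lateral and one central sound in memory;
a spoken retro-cue then marks the lateral item as still relevant
(*target-lateral*, tokens `li`/`re`), marks the central item as relevant so
the lateral one becomes a distractor (*distractor-lateral*, `mi`), or keeps
both relevant (*neutral*, `bei`).

The core quantity is the **Alpha Lateralization Index** over a posterior
electrode cluster (PO7/8, P7/8, P5/6, PO3/4), computed relative to the side
of the lateralized memory item:

$$\mathrm{ALI} = \frac{P_\text{ipsi} - P_\text{contra}}
                      {P_\text{ipsi} + P_\text{contra}}$$

Positive values mean a contralateral power *decrease* (the lateral item is
being prioritized); negative values mean a contralateral *increase* (it is
being suppressed). Raw, non-baseline-corrected power enters the ratio:
baseline normalization would cancel out of numerator and denominator
inconsistently across time and is deliberately absent. Trial-mean power is
computed *before* the ratio (per hemisphere, per condition); averaging
per-trial indices instead is a different estimator, noisier at low power,
and is not what this pipeline does.

## Pipeline and parameters that matter

1. **Epochs** span −1000…7500 ms around pre-cue onset at 500 Hz (4250
   samples). Event timing is fixed by the task: the retro-cue starts at
   3000 ms, so windows quoted "post retro-cue" are shifted by +3000 ms.
2. **Time–frequency decomposition** (`build_wavelet_family()`,
   `morlet_power()`): 52 center frequencies, log-spaced from 4 to 30 Hz.
   The cycle count rises linearly *in frequency* from 3 cycles at 4 Hz to
   11.25 at 30 Hz; the linear-through-both-endpoints rule is adopted
   because common toolbox conventions ("increase by a factor per step") do
   not reproduce both printed endpoints simultaneously. Wavelets are
   Gaussian-windowed complex exponentials, σ\_t = cycles/(2πf), truncated
   at ±3σ and unit-energy normalized; power is therefore in µV² up to a
   family-constant factor, which cancels in the ALI and in within-frequency
   contrasts. Output is sampled on 200 evenly spaced time points over
   −582…7080 ms — a span that keeps every sample clear of the epoch edges
   by at least the widest wavelet's half-support. Implementation note: the
   convolution is evaluated only at the output grid points by one batched
   matrix product over all wavelets; this is numerically identical to full
   convolution at those points.
3. **ALI maps** (`subject_ali()`): electrodes are assigned ipsi/contra per
   trial relative to the pre-cued side (which carries the target in
   target-lateral and neutral trials and the distractor in
   distractor-lateral trials), averaged over the four-channel cluster per
   hemisphere, then over trials. Band/window means use closed intervals
   ([8, 13] Hz, [700, 1300] ms post cue). ALI at zero total power is
   defined as 0; over a pink-noise floor that point is unreachable.
4. **Cluster-based permutation test** (`cluster_test()`): pointwise paired
   t-tests (two-tailed, df = n−1) over the 52 × 200 grid; supra-threshold
   points (p < 0.05) form 4-connected clusters — no diagonal adjacency, the
   conservative common choice — and clusters are restricted to uniform
   t-sign, since a physically coherent effect does not reverse direction
   inside one cluster (configurable via `same_sign`). The null is built by
   independently keeping/swapping each subject's condition pair
   (probability ½), which preserves the paired design and equals
   sign-flipping the difference maps; full reshuffling across subjects
   would break pairing. Per iteration the maximum cluster size (0 if none)
   is recorded; the cutoff is the empirical 95th percentile (smallest value
   at or above the percentile rank, ties included) and only clusters
   *strictly larger* than the cutoff are significant. Zero-variance grid
   points get p = 1 with a warning.
5. **Follow-up and behavioral statistics** (`ali_followup()`,
   `behavioral_analysis()`): the five window-mean comparisons (2 paired,
   3 one-sample) form one FDR family. Behavioral analysis 1 contrasts
   selective vs. neutral cues on RT and accuracy with non-cued-probe trials
   excluded (they cannot occur under a neutral cue); analysis 2 contrasts
   probe types within selective trials (rm-ANOVA for RT, Friedman for
   accuracy) with pairwise post-hocs. Paired contrasts go parametric only
   when the difference scores pass a Lilliefors gate (Monte-Carlo null
   table, 10,000 seeded simulations per sample size, cached, so the gate is
   deterministic). Error trials are late (beyond 200–2100 ms from probe
   onset: 1500 ms response window plus the 600 ms probe), premature, or
   missing responses; RT means use correct trials only.

### The FDR convention (adjusted p-values above 1)

The correction applied by the reference analysis chain reports adjusted
p-values that can exceed 1. A plain Benjamini-Hochberg step-up can never do
that — the largest p-value receives factor m/m = 1 — so `fdr_adjust()`
implements both variants explicitly: `"bh"` (factor m/i) and `"by"`
(Benjamini–Yekutieli, factor m·c(m)/i with c(m) = Σ 1/i, valid under
arbitrary dependence), both with step-up monotonicity and **no cap at 1**.
Feeding the five published follow-up t statistics (df = 19) through the
`"by"` variant reproduces the published adjusted values (0.016, 0.297,
0.039, 0.016, 0.317), as does the three-test post-hoc family containing
p = 0.871 → p_adj = 0.871·11/6 = 1.60 and the two-test family containing
p = 0.481 → 0.721. The analysis functions therefore default to `"by"`; the
generic `fdr_bh()` keeps the textbook BH behavior.

### Effect sizes and Bayes factors

Hedges g (paired) standardizes the mean difference by the SD of the
difference scores, g1 (one-sample) by the sample SD, both with the
small-sample correction J = 1 − 3/(4·df − 1). The alternative paired
standardizer (mean of the two condition SDs) is available behind
`method = "average"` since effect-size toolboxes differ here. Bayes factors
are JZS: a Cauchy prior (scale √2/2, configurable) on the standardized
effect, computed as the prior-averaged noncentral-t likelihood of the
observed t over the central-t likelihood by adaptive quadrature; the test
suite checks agreement with an independent quadrature of the
inverse-chi-square mixture representation to four significant digits.

### Repeated-measures ANOVA details

The one-way rm-ANOVA computes F with (k−1, (k−1)(n−1)) df and partial eta
squared. Mauchly's W is computed on the covariance of orthonormalized
within-subject contrasts with the standard chi-square approximation;
when it rejects at 0.05 the Greenhouse-Geisser ε̂ (trace form of the
contrast covariance) multiplies both df. For k = 2, ε = 1 and sphericity
holds trivially. The implementation is cross-checked in the tests against
`stats::anova.mlm`/`stats::mauchly.test` on random data.

## What the synthetic generator emulates — and what it does not

`generate_design()` reproduces the design *exactly*, not stochastically:
four retro-cue tokens at 25% each (hence 50% target-lateral), cued probes
at 50% overall and within every token, non-cued and new probes at 25%
overall, blocks of 100 trials, and the structural constraint that neutral
trials never carry a non-cued probe. Because non-cued probes exist only in
the three selective tokens, their total (n/4) is spread over those tokens
by largest remainder — exactly 25% overall at the full 800 trials (67, 67,
66), at the cost of per-token counts differing by one.

`simulate_eeg()` superimposes, on a 1/f pink-noise floor (exponent 1, RMS
5 µV — a realistic broadband background for scalp EEG), a 10 Hz oscillation
at the eight cluster electrodes (baseline amplitude 10 µV, random phase per
trial). Inside the 700–1300 ms post-cue window the two hemispheres' alpha
amplitudes become √(1 ± ALI) of baseline — ipsilateral up, contralateral
down — so the oscillation's power ratio is exactly (1−ALI)/(1+ALI) and its
ALI equals the injected value (+0.2 target-lateral, −0.2
distractor-lateral, 0 neutral by default). Amplitude transitions use 100 ms
raised-cosine ramps to avoid spectral splatter that would artificially
enlarge cluster extent. An optional, default-off bilateral post-cue
suppression mimics the non-lateralized alpha decrease without touching the
ALI. Two caveats follow. First, the *estimated* ALI is attenuated toward
zero relative to the injected value because the pink-noise floor adds
equally to both hemispheres' measured power (with the default amplitudes,
a window-mean of ≈0.16 for an injected 0.2; the noiseless configuration
recovers the closed-form value, which is how the tests verify the
algebra). Second, the generator makes no attempt at ERPs, eye movements,
inter-channel correlation structure, or auditory acoustics — so passing
tests certify the *analysis machinery* (sign conventions, calibration,
error control, recovery), not realism of any particular scalp topography.

`simulate_behavior()` draws log-normal RTs (median 900 ms, σ_log 0.25)
with additive shifts: selective cues faster by `rt_benefit_ms` (60 ms),
non-cued probes slower than new by `interference_ms` (40 ms), cued probes
faster by `cued_advantage_ms` (50 ms); accuracy is Bernoulli (0.9 base,
−0.08 for non-cued probes) with a 2% lapse rate. The reference study
reports only test statistics, not mean RTs, so these magnitudes are chosen
as typical for auditory retro-cue tasks and are free parameters, not
calibrations.

## Numerical choices and degenerate inputs

* Epoch containers store float32 by default (float64 available); channels
  are canonicalized alphabetically on write and addressed by label only.
* The permutation engine draws sign matrices row by row, so extending
  `n_perm` under the same seed reproduces the shorter run as a prefix.
* Zero-variance t-map points: t set to 0, p to 1, with a warning.
* `compute_ali(0, 0)` is 0 by definition; rejection operations never alter
  retained samples and are idempotent on their own output.
* Trial rejection removes at most 5% of remaining trials per iteration
  (worst offenders first; absolute-limit violations outrank z-scores) and
  errors out rather than looping past a 100-iteration cap.
* Downsampling accepts only integer rate ratios (resampling dialects are
  out of scope) and uses a zero-phase Chebyshev-I low-pass with 0.01 dB
  ripple at 0.8 of the new Nyquist, keeping DC and in-band amplitudes flat
  to well under 1%.

## Problem sizes used by the shipped checks

The test suite and acceptance script exercise the full-scale configuration
where it is cheap (52 × 200 grid, 1000 permutations, 800-trial design) and
reduced-but-structurally-identical sizes where whole studies are simulated
repeatedly: the recovery check runs two replicate studies of 20 subjects ×
64 trials with a 26-step family on 100 time points and 500 permutations;
the error-rate studies use 200 null datasets of 20 subjects on a 20 × 30
grid with 500 permutations; behavioral calibration uses 200 replications
of 20 subjects × 48 trials. These sizes are the package's choice of desk
scale: they keep every check's Monte-Carlo error small relative to the
asserted bounds while remaining routine to rerun.

## Known limitations

* The preprocessing module covers the automatable core (kurtosis channel
  screening, average re-reference, iterative SD trial rejection,
  downsampling); FIR filter design, ICA-based ocular correction, dipole
  screening and channel interpolation are out of scope, so real recordings
  must arrive band-limited and ocular-clean.
* No spatial (electrode) dimension enters the cluster test — power is
  averaged over the fixed posterior cluster first — and no cluster-mass or
  TFCE statistics are provided.
* The Wilcoxon exact path applies to untied differences (n ≤ 25); ties
  fall back to the tie-corrected normal approximation at any n.
* Whether the reference chain's pointwise tests were two-tailed and its
  clusters sign-pure is not documented; both choices default to the
  conservative reading here and are configurable.
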