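---
title: "Methods: phase-referenced power, decoding and dimensionality in prpdecode"
author: "prpdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-referenced power, decoding and dimensionality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis in one paragraph

During odor sampling, the olfactory-bulb LFP carries a slow theta
rhythm (6--14 Hz) on which faster beta (15--30 Hz) and high-gamma
(65--95 Hz) bursts ride at preferred theta phases. `prpdecode`
quantifies that phase-amplitude coupling (PAC), asks how much odorant
information a downstream reader could extract if it sampled fast-band
power only at a fixed theta phase (phase-referenced power, PRP), and
tracks how decoding, decision timing and the effective dimensionality
of the multi-electrode signal change as an animal learns a go/no-go
odor discrimination.

## Phase-amplitude coupling

Signals are band-passed with a zero-phase Butterworth filter of
prototype order 20 (40 poles). A direct polynomial realization of that
filter is numerically meaningless in double precision, so the design is
analytic -- closed-form prototype poles, algebraic bandpass
transformation, bilinear mapping -- and the filter is applied as a
cascade of 20 biquad sections, each individually stable. The Hilbert
transform gives the theta phase (cosine convention: 0 degrees at the
waveform maximum; the convention is not standardized in the literature,
so peak-phase values are only comparable within a convention) and the
fast-band amplitude envelope. Mean envelope is collected in 51 phase
bins, normalized to a distribution $p$, and coupling strength is the
modulation index

$$MI = \frac{\ln N - H(p)}{\ln N}, \qquad H(p) = -\sum_j p_j \ln p_j,$$

the Kullback--Leibler distance to uniform rescaled to $[0, 1]$. The
peak (trough) phase is the bin center of the maximum (minimum) of $p$.
Per-trial PAC uses the odor-aligned 0--2.5 s window. Session reference
phases for PRP are computed per electrode from the pooled rewarded
(S+) trials only, and held fixed for both odorants and stages. Because
trial windows are cut from the continuously filtered recording, no
per-window filter transients arise; the standalone `pacChain()` on a
finite signal keeps its (small, deterministic) edge effects, which is
the honest noise floor of the estimator. Two theta variants are
provided (6--14 Hz default, 2--14 Hz wide) because the literature uses
both.

Across-trial variability of the coupling phase is summarized as the
circular variance $1 - R$ of the per-trial peak phases ($R$ = mean
resultant length). Whether "peak angle variance" should instead be the
linear variance of unwrapped angles is ambiguous in the field; the
circular form is the default and a `linear_deg2` option exists.

## Phase-referenced power

Fast-band power is estimated with a complex Morlet transform (7 cycles
by default; the value trades temporal against spectral resolution and
is uncritical between 5 and 10) on a 1 Hz grid of center frequencies
spanning the band. The per-frequency magnitudes are combined with
Parseval-style weights so the estimator integrates power spectral
density over the band: a sinusoid of amplitude $a$ at the band center
reads $10\log_{10}(a^2/2)$ dB re 1 uV^2 regardless of the wavelet
width. The dB reference (1 uV^2) is a package convention; group
*differences*, which carry the scientific content, do not depend on it.

PRP samples the instantaneous band power at each upward crossing of the
electrode's reference phase (peak or trough), one sample per theta
cycle, and averages the samples into a trial-aligned 0.1 s grid
spanning -1.5 to 4 s around odor onset. At ~8 theta cycles per second
roughly half the 0.1 s bins catch no crossing; those are filled by
linear interpolation between neighboring bins (edge bins carried from
the nearest value). Sampling the instantaneous value at the crossing
(rather than a small window around it) is a deliberate choice; with
0.1 s bins downstream the difference is negligible.

## Behavior

A trial is a "go" when the animal licks in each of four consecutive
0.5 s blocks; the response area starts 0.5 s after odor onset by
default (configurable -- the exact anchoring is not standardized).
Go on S+ is a Hit, no-go a Miss; go on S- a False Alarm, no-go a
Correct Rejection. Performance is percent correct in a trailing
20-trial window stepped by one trial; at or below 65% the animal is
naive, at or above 80% proficient, in between intermediate (excluded
from group analyses). Time zero of every trial is the diversion of the
final valve towards the animal; a configurable offset exists for the
66--133 ms valve-to-nose delay but defaults to 0.

## Decoding

Per 0.1 s bin, a two-class linear discriminant (pooled within-class
covariance, empirical priors) is trained on the per-electrode PRP of
all trials but one and classifies the held-out trial; this is repeated
over trials (leave-one-out cross-validation). With 16 electrodes and
tens of trials the pooled covariance can be near-singular, so a ridge
of $10^{-6}\,\mathrm{tr}(S)/M$ is added to the diagonal -- far below
the data scale, it only guarantees solvability. The chance control is
a permutation null: the identical LOOCV run on a permuted label vector
(20 permutations by default), scored against the permuted labels. The
choice matters: leave-one-out with true labels carries a
class-imbalance anti-correlation (holding out a trial of one class
leaves that class under-represented in training) that biases a truly
informationless decoder a few percent *below* 50%; the permutation
null inherits exactly the same bias, so null data and control are
exchangeable, whereas a hybrid control trained on shuffled labels but
scored against true labels loses the bias and flags null data as
"significantly below chance".
The shuffle band reported per bin is the permutation mean with a
95% normal-theory prediction interval, i.e. the interval in which a
single chance-level accuracy is expected to fall; with 20 permutations
a raw percentile band would be dominated by the sample extremes.
Per-outcome accuracy groups the same held-out predictions by Hit /
Miss / CR / FA; the decoder itself is always trained on all trials
regardless of outcome. Decoding quality over the odor window is
summarized by the normalized area under the accuracy curve,
$\mathrm{mean}(\max(acc - 50, 0))/50 \in [0, 1]$; accuracy below
chance is clipped rather than rewarded, since the normalization
anchors 50% at zero. A complementary per-bin PCA (classes pooled)
reports the PC1 group means; axis signs are aligned between
neighboring bins and fixed globally so the S+ odor-window mean is
non-negative.

## Decision times

For licks, each trial is scored 0/1 per 0.1 s bin (licks are not
counted) and a two-sided Wilcoxon rank-sum test compares S+ and S-
trials per bin. For the decoder, the per-trial held-out *predicted
identity* (1 = called S+) is compared between S+ and S- trials: a
correctness score cannot separate the groups (a symmetric decoder is
equally correct on both), whereas the predicted identity diverges
exactly when decoding beats chance. The rank-sum test uses midranks
throughout, exhaustive enumeration when both groups have fewer than 10
observations, and the tie-corrected normal approximation with
continuity correction otherwise. The decision time is the earliest bin
at or after odor onset whose p-value is below 0.05 and stays below
0.05 through the end of odor delivery (2.5 s); transient pre-odor dips
therefore never count. The 2.5 s horizon is a package choice -- some
horizon is needed for "stays below" to be decidable.

## Dimensionality

For each time bin, the covariance across trials of the $M$-channel PRP
vector is decomposed and summarized by the participation ratio

$$\dim = \frac{(\sum_i \lambda_i)^2}{\sum_i \lambda_i^2},$$

which is $M$ for equal eigenvalues and $m$ when $m$ equal eigenvalues
dominate. Negative eigenvalues from finite-precision decompositions are
floored at zero. Curves are computed per (odorant x stage) group by
default -- learning stages are analyzed separately and pooling odorants
is available by flag -- and normalized to the mean over the pre-trial
window (-1 to 0 s; "pre-trial" is not otherwise pinned down).
Cross-animal pooling concatenates electrodes and truncates each
odorant's trials to the minimum count across sessions (first $n$ in
session order), so every pooled pseudo-trial is complete.

Estimating a participation ratio from a sample covariance is biased:
finite trial counts spread equal eigenvalues (pushing the estimate
down) while per-bin sampling noise adds an isotropic component
(pushing it up toward $M$). When a single summary of the latent
trial-to-trial dimensionality is wanted, the covariance of the
*baseline-window mean* PRP is the better-conditioned estimator, since
averaging ~10 bins suppresses the isotropic part; the per-bin curve
remains the object of interest for time-resolved questions.

## The synthetic-data generator

`simulateSession()` realizes exactly the structure the analysis
assumes, so every stage can be validated against known ground truth:

* a theta carrier shared across electrodes, frequency jittered per
  trial (sd 0.3 Hz around 8 Hz);
* beta (22 Hz carrier) and high-gamma (80 Hz carrier) bursts, one per
  theta cycle, gaussian in phase with FWHM of half a cycle. Coupling
  strength is configured on the MI scale and converted to a burst
  modulation depth by numerically inverting the analytic 51-bin
  distribution of the envelope $1 + d\,g(\phi)$ (`miToDepth()`);
* per-trial coupling phase drawn from a von Mises distribution; the
  concentration parameterizes peak-angle variance smoothly;
* outside the odor epoch both odorants share identical baseline
  coupling (MI 0.01), so nothing about the upcoming odorant is readable
  before odor onset. The baseline coupling phase is nearly stable
  across trials (von Mises concentration 30): because the phase draw is
  shared by all electrodes, per-trial baseline phase wander would add a
  rank-one component to the trial-to-trial PRP covariance and the
  pre-odor dimensionality would read latent-count-plus-one instead of
  the configured latent count -- the mixing structure, not phase
  wander, is meant to control dimensionality;
* odor-epoch amplitude gains per odorant (proficient profile: +6 dB
  for S+, -6 dB for S-; naive: 0/0);
* trial-to-trial latent structure: a small number of latent factors
  (default 3) act on the per-electrode burst log-amplitudes through an
  orthonormal mixing matrix, which makes the pre-odor PRP covariance
  exactly rank-3 with equal eigenvalues in the noiseless limit. The
  mixing is applied in the log-amplitude domain rather than to the raw
  traces: raw-signal mixing with a generic matrix neither keeps the
  nonzero eigenvalues equal (so the true participation ratio would not
  equal the latent count) nor guarantees positive envelopes. The
  proficient profile collapses the factors to one shared factor during
  the odor epoch, reproducing the learning-related dimensionality drop;
* white sensor noise (-10 dB re the burst amplitude);
* licks at 7 Hz with a random raster phase per trial (a fixed raster
  would concentrate lick probability in comb-like time bins), from
  0.1 s after odor onset; on correct rejections S- licking stops at a
  configurable divergence latency (0.25 s in the proficient profile,
  1.5 s naive). Outcomes are *not* assigned: they emerge from the lick
  trains through `classifyOutcome()`, with configured hit/false-alarm
  probabilities (0.95/0.10 proficient, 0.90/0.80 naive) realized in
  expectation, and the performance time course and stage labels follow
  from the behavioral scoring.

Sessions default to 16 electrodes, 100 trials (blocks of 20 with
10 S+/10 S- in random order), 7 s trial spacing and a 1 kHz sampling
rate -- one tenth of the hardware rate of typical acquisition systems
but more than five times the highest analyzed frequency, which keeps a
full session around 100 MB and the full pipeline in CPU-minutes. A
separate two-oscillation generator (`simulatePacSignal()`, 20 s at
20 kHz) reproduces the classical PAC validation signal: an 8 Hz cosine
plus a 40 Hz cosine whose bursts have FWHM (1/8 Hz)/2 and sit either at
180 degrees of every theta cycle (coupled), at an independently uniform
random phase each cycle (the matched no-PAC control; its small nonzero
MI is pure finite-sampling noise and is the right yardstick for "no
coupling" through a real estimator chain), or nowhere (constant
amplitude). The coupled condition keeps a constant 40 Hz component of
amplitude 0.58 relative to the bursts; that ratio is the one free
parameter of the construction and was fixed, once, by numerically
matching the chain's modulation index to the conventional
clearly-coupled strength of 0.01.

What the generator does **not** emulate: respiration coupling and
sniff-locked dynamics, 1/f background spectra, electrode drift and
artifacts, inter-trial dependence (satiety, motivation), spike-band
content, and odorant chemistry. Passing tests therefore demonstrate
that the estimators recover the statistical structure they assume --
not that real recordings satisfy those assumptions.

## Numerical choices and degenerate inputs

* Filtering pads by odd reflection (3 low-corner cycles); transients of
  the order-20 theta filter decay over ~1 s, which matters only for
  standalone short signals, not for windows cut from a session.
* FFT lengths are forced to 2-3-5-smooth values (mixed-radix FFTs
  degrade badly on lengths with large prime factors).
* Band power is floored at 1e-12 uV^2 before the dB conversion.
* A phase bin with zero samples aborts the PAC distribution with a
  request for longer input; an all-zero carrier aborts phase
  extraction; an all-zero eigenvalue spectrum aborts the participation
  ratio; a class with fewer than two trials aborts the LDA.
* Exact discriminant ties are broken by a seeded coin flip.
* Bootstrap CIs are percentile CIs of the mean (1000 resamples); the
  sample is sorted first so the interval is exactly invariant to input
  ordering. Coverage of the percentile bootstrap is slightly below
  nominal for small samples; tests calibrate it at n = 100.
* The Anderson--Darling normality gate treats samples that are too
  small for the test (n < 8) or degenerate as non-normal, routing them
  to the rank-sum branch.
* All stochastic stages draw from one root seed through fixed stream
  offsets; reruns with the same config are byte-identical.

## Problem sizes

The test suite exercises the full chain on a 6-electrode, 40-trial
session plus two 16-electrode, 100-trial sessions (proficient and
matched null) for the end-to-end parameter-recovery checks; property
suites use thousands of small randomized cases. These sizes put every
estimator in the regime where its sampling error is well below the
tolerances being asserted while keeping the whole suite in the
tens-of-minutes range on one CPU.

## Known limitations

* The dB scale of PRP depends on the 1 uV^2 reference and the Morlet
  calibration; only within-package comparisons are meaningful.
* The shuffle band with 20 permutations has appreciable width
  uncertainty; raising `nShuffles` sharpens it at linear cost.
* Pooled-session trial truncation ("first n per odorant") follows
  session order and is not randomized.
* Decision times are quantized to the 0.1 s analysis grid.
* The naive/proficient thresholds create a selection coupling between
  behavior and neural grouping; the generator reproduces this (stages
  emerge from simulated behavior) but real intermediate-stage dynamics
  are simply excluded.
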