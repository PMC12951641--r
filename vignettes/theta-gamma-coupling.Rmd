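---
title: "Quantifying theta-gamma coupling and latent working-memory structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying theta-gamma coupling and latent working-memory structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetagamma)
```

## The scientific problem

Working memory is thought to rely on a nested oscillatory code: slow theta
rhythms (4–8 Hz) provide a temporal scaffold whose phase organises bursts of
fast gamma activity (40–80 Hz). The strength of this phase-amplitude
cross-frequency coupling (CFC), and the direction in which it spreads across
the scalp, differ between merely *maintaining* information and actively
*manipulating* it. This package implements the full analysis chain needed to
study that distinction — coupling quantification, permutation validation,
directed coupling networks with family-wise corrected statistics, and a
latent-variable comparison of one- versus two-factor accounts of individual
differences — together with a synthetic-data module that generates EEG-like
recordings and behavioural tables with *known* ground truth, so every stage
can be verified end to end.

## The modulation index

For a chosen channel, the continuous signal is band-pass filtered into a low
(phase) band and a high (amplitude) band, and the analytic signal yields the
instantaneous phase $\varphi(t)$ and envelope $A(t)$. The phase axis
$[-\pi, \pi)$ is cut into $N = 18$ equal bins; the mean envelope per bin,
normalised to a distribution $P(j)$, is compared against the uniform
distribution $U$ with a normalised Kullback–Leibler divergence:

$$\mathrm{MI} \;=\; \frac{D_{KL}(P, U)}{\log N}
  \;=\; \frac{\log N - H(P)}{\log N},
  \qquad H(P) = -\sum_{j=1}^{N} P(j)\log P(j).$$

MI is 0 exactly when the envelope is flat across phase (no coupling) and 1
when all amplitude concentrates in one bin. It is invariant to rescaling the
amplitude, since $P$ is normalised. Natural logarithms are used throughout;
the $\log N$ normalisation makes the base immaterial. Empty phase bins
contribute zero entropy (the $p\log p \to 0$ limit) and raise a warning,
because they signal too few samples for a stable estimate.

Analysis windows run from 500 ms after the response prompt (excluding early
sensory processing) to the second button press (after which the final
response is considered predetermined); windowed samples are concatenated
across trials. Filtering is always applied to the *continuous* recording
before windowing — filtering concatenated segments would manufacture phase
jumps at the joins. The band-pass filter is a zero-phase (forward–backward)
Hamming-window FIR with transition width 25% of the lower band edge; samples
within one filter length of the recording boundary are flagged for
exclusion.

## What the synthetic generator emulates

`generate_recording()` plants coupling with the standard amplitude-modulation
construction: the source channel carries a slow oscillation
$\cos\theta(t)$, and the target channel a fast carrier whose envelope is
$(1 + \chi\cos(\theta(t) - \phi_0))/2$. The depth $\chi \in [0,1]$ is the
ground truth every recovery test works against: $\chi = 0$ gives a flat
envelope and MI at the estimator's noise floor; MI grows continuously with
$\chi$. Gaussian white background noise (SD 1, in units of the unit-amplitude
carrier) is added to every channel; white noise keeps the analytic
expectations simple, and a slow/carrier amplitude of 1 against it gives the
moderate single-trial signal-to-noise typical of scalp EEG. Trial annotations
follow the task timeline (three 1-s sample images with 1.5-s gaps, a 1-s
prompt, three clicks with lognormal latencies), and `generate_behavior()`
draws per-participant ability scores from a bivariate standard normal with
correlation `inter_factor_r`, mapping them to trial RTs through per-partition
loadings plus trial noise.

What the generator deliberately does *not* emulate: 1/f background spectra
(available optionally via the noise SD but not default), volume conduction
between electrodes, ocular or muscle artifacts, non-stationary coupling, or
biophysically realistic sources. Passing recovery tests therefore shows the
*estimators* are correct and calibrated under clean conditions; it does not
certify robustness to the artifact structure of real recordings, which the
original preprocessing pipeline (out of scope here) is responsible for
removing.

## Comodulogram and its permutation null

MI is recomputed over a grid of narrow bands — phase bands of 1 Hz from 3 to
10 Hz, amplitude bands of 10 Hz from 30 to 80 Hz. For a group of
participants, the null reference shuffles each participant's 35 cell values
uniformly across the matrix (1000 permutations by default), re-averages, and
takes the mean + 3 SD of the permuted values as a single global threshold;
cells whose observed group-average MI exceed it form the significance mask.

A calibration caveat that users should know: the MI estimator's small-sample
bias is not homogeneous over the grid. Low phase-frequency bands contain
fewer slow cycles per window, so their bin means are noisier and their
entropy deficit — hence their MI bias — is systematically larger (roughly an
order of magnitude between the 3–4 Hz and 9–10 Hz rows at typical window
lengths). Cells are therefore not perfectly exchangeable, and the
uniform-shuffle null flags a small percentage of low-phase-frequency cells
even without any coupling (about 2–3% of cells per recording in our null
simulations, at both short and full-session data lengths — the effect is
scale-invariant because bias and sampling noise both shrink as $1/n$).
Because the systematic part does not shrink with cohort size while the
threshold does, group masks over many participants inflate this further. In
practice the mask is a descriptive aid for locating the coupling cluster —
which it does reliably, see the acceptance suite — not an exact
false-positive-rate guarantee.

## Time-binned indicators and the motor control

For latent-variable analyses, each participant's concatenated series is
split into three contiguous equal-length segments; within a segment MI is
computed per full 5-second bin (a window length that stabilises MI), a
trailing partial bin is discarded, and the bin MIs are averaged into one
indicator per segment. Contiguous thirds of the concatenated series were
chosen over trial-block thirds — the concatenated series is the object MI is
defined on, and thirds of it keep the per-segment sample counts exactly
balanced.

To check that coupling estimates are not driven by click-locked motor
activity, samples within ±200 ms of each click are masked, MI is computed
separately on the motor and complementary non-motor samples (the two masks
partition the window), and the per-participant differences go into a paired
t-test. One calibration nuance: the motor subset is necessarily smaller than
its complement, so its MI carries a slightly larger small-sample bias, and
the paired test can pick up a trace of that systematic difference. As with
the comodulogram null, the effect is scale-invariant in data length, so on
stationary synthetic coupling with no motor modulation the per-cohort
non-significance rate sits near 85–95% rather than exactly at the nominal
95%.

## Time-frequency visualisation

The descriptive companion to MI is a phase-aligned average time-frequency
map: 1-second epochs tiled across the analysis windows are transformed with
a generalized Morse wavelet (symmetry $\gamma = 3$, time-bandwidth
$P^2 = 60$, so $\beta = 20$; 12 voices per octave over 2–90 Hz — the wavelet
family's frequency sampling is a free choice and 12 voices is the common
default), then each epoch's map is circularly shifted in time by
$-(\varphi/2\pi)/f_{low}$ seconds, where $\varphi$ is the theta phase at the
epoch midpoint (the reference sample is a free choice; the midpoint is
symmetric), so the slow cycle lands at a common position. Sub-sample shifts
round to the nearest sample. Under planted coupling the averaged map shows
the gamma band waxing and waning at a fixed position of the theta cycle; the
`tfr_modulation_depth()` summary (peak-to-trough over mean of the gamma-band
time course) quantifies this.

## Directed networks

Cross-electrode coupling MI(A→B) takes phase from electrode A and amplitude
from B. For each of the $\binom{32}{2} = 496$ unordered pairs the
directionality contrast $\Delta\mathrm{MI} = \mathrm{MI}(A{\to}B) -
\mathrm{MI}(B{\to}A)$ is computed per participant, tested against zero with
a two-sided one-sample t-test across the cohort (the test family is the
natural companion of the paired t-tests used elsewhere in the chain), and
Holm–Bonferroni corrected over all pairs. The step-down Holm procedure is
implemented from its definition — sorted p-values against
$\alpha/(m - k + 1)$ with running-maximum monotonicity — and cross-checked
against `stats::p.adjust` in the tests. Significant pairs become directed
edges oriented by the sign of the mean contrast and weighted by its absolute
value (the contrast, not raw MI, is the quantity the statistics run on, so
it is also the natural edge weight). Task comparisons use paired t-tests per
pair on the directionality values, again Holm-corrected, plus the
"exclusive" edge sets — edges significant in exactly one task's network.

## Confirmatory factor models

Behavioural indicators are median RTs per partition: trials of each
working-memory task are split by trial order into four partitions of 10, and
span-type tasks by set size (3–7, five indicators). Participant exclusion
removes those below 80% accuracy in *both* working-memory tasks, then those
whose mean RT sits more than 4 SD from the group mean. RTs enter the models
untransformed.

The one- versus two-factor comparison is fitted by maximum likelihood on the
sample covariance matrix, minimising
$F = \log|\Sigma(\theta)| + \mathrm{tr}(S\Sigma^{-1}(\theta)) - \log|S| - p$
with $\Sigma = \Lambda\Phi\Lambda' + \Psi$. Identification fixes factor
variances to 1 with all loadings free; that convention is what yields df 19
(two factors, 17 free parameters) and df 20 (one factor) on eight
indicators, and df is asserted as $p(p+1)/2 - {}$#free on every fit. The
model chi-square is $(n-1)F$ at the optimum, and nested models are compared
by the chi-square difference on the df difference.

Numerical choices: L-BFGS-B with the *analytic* gradient of $F$
($\nabla F = \mathrm{tr}[\Omega\, d\Sigma]$ with
$\Omega = \Sigma^{-1}(\Sigma - S)\Sigma^{-1}$) — the closed form is cheap,
exact, and markedly more reliable than finite differences at simulation
scale; three deterministic starts (scaled loading vectors) guard against
local minima; uniquenesses are bounded below at a small positive multiple of
the largest indicator variance, and a fit ending on that bound is flagged as
a Heywood case. Inter-factor correlations are bounded at exactly ±1: the
implied covariance stays positive definite through the uniquenesses, and an
open bound (e.g. ±0.999) would place the one-factor model just *outside* the
two-factor parameter space, occasionally producing spurious negative
chi-square differences. For the same reason the two-factor fit always
includes the one-factor solution (with correlation 1) among its starts, so
the nested model can never appear to fit better than the model containing
it.

With the factor correlation on the boundary under a unitary truth, the
difference test's null distribution is the usual half-and-half mixture of a
point mass and $\chi^2_1$, so its empirical size at $\alpha = 0.05$ sits
near 0.02–0.03 rather than 0.05 — conservative, as expected for a boundary
test, and within the calibration band the acceptance suite checks.

## Problem sizes used in the test suite

The simulations behind the test and acceptance suites use cohorts and
recording lengths chosen to make every property measurable with comfortable
margins: single-channel recordings of 130 s (9 trials) for the
coupling-depth sweep, full 40-trial sessions (~580 s) for comodulogram
localization and null coverage, 20-participant cohorts on an 8-channel
sub-montage for directed-edge recovery, 500 matrix-level null cohorts for
family-wise error, 100–500 replicates of n = 200 behavioural cohorts for
factor-structure power and calibration, and 20 cohorts of 8 participants for
the motor-window control. Family-wise error calibration is run at the
MI-matrix level (i.i.d. null matrices) because the property under test is
the one-sample-t + Holm stage, whose input contract is per-participant MI
matrices.

## Known limitations

* The comodulogram permutation null is descriptive, not exactly calibrated
  (see above); per-cell time-shift surrogates would calibrate exactly but
  are a different procedure from the matrix permutation implemented here.
* Individual-level band selection is out of scope; bands are fixed at the
  canonical theta/gamma ranges.
* Alternative coupling estimators (mean vector length, GLM-based PAC) are
  not provided.
* The EFA, fit indices beyond chi-square/df, and multi-construct structural
  models are outside this package's scope; only the nested one- versus
  two-factor comparison is implemented.
* File interchange uses the raw-matrix + JSON sidecar format and TSV tables;
  EDF is not read or written.
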