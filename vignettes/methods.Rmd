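---
title: "Models and methods behind vsvta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vsvta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`vsvta` analyses paired recordings from the ventral striatum (olfactory
tubercle) and the ventral tegmental area of mice learning an odor-guided
go/no-go reversal task, together with a passive paradigm in which one of two
odors is paired with optogenetically evoked phasic dopamine. This vignette
explains the models and statistics the package implements, the choices made
where the methods left freedom, and what the synthetic-data module does and
does not emulate.

## The reinforcement-learning model family

Instrumental licking is modelled by Q-learning with a hybrid Rescorla-Wagner
rule gated by a Pearce-Hall associability. For the visited state $s$ (the
presented odor) and chosen action $a$ (lick / restrain),

$$Q_{s,a}(t+1) = Q_{s,a}(t) + \kappa\,\alpha(t)\,\delta(t), \qquad
  \delta(t) = r(t) - Q_{s,a}(t),$$
$$\alpha(t+1) = (1-\eta)\,\alpha(t) + \eta\,|\delta(t)| .$$

The associability $\alpha$ tracks recent unsigned prediction errors and acts
as a feedback-dependent learning rate: surprising outcomes accelerate
subsequent updating. Three four-parameter generalisations are implemented
(`qph_kappa`: action-specific $\kappa_1,\kappa_2$; `qph_eta`:
action-specific $\eta_1,\eta_2$; `qph_f`: a forgetting term that decays the
unchosen action's value, $Q_{s,a'} \leftarrow Q_{s,a'} - \kappa_F \alpha_F
Q_{s,a'}$ with $\alpha_F(t+1) = (1-\eta)\alpha_F(t) + \eta\,Q_{s,a'}(t)$).
Setting $\kappa_F = 0$ recovers the plain hybrid model, which is the nested
null of the likelihood-ratio test in `compare_qph_models()`. Actions are
selected by a softmax with inverse temperature $\beta$; initial values are
$Q_{s,a}(1)=0.5$ and $\alpha(1)=0$. The trial-wise stimulus value used
downstream is $V_{CS+}(t) = \max_a Q_{cs+,a}(t)$, where the CS+ state
follows the contingency across the mid-session reversal.

**Fitting.** `qph_fit()` maximises the action log-likelihood with bounded
L-BFGS-B from `n_starts` random initial points (rates uniform on their
$[0,1]$ bounds, $\beta$ log-uniform on $[0.1, 50]$ because uniform draws on
the full $[0,500]$ range almost surely start in the saturated-softmax
plateau). The default of 256 starts is far beyond what the four-dimensional
bounded problem needs — the best log-likelihood plateaus after a few dozen
starts — and the start stream is nested, so enlarging `n_starts` can only
improve the optimum. BIC uses $n$ = number of trials.

**What is and is not identifiable.** Because $\kappa$ and $\alpha$ enter the
update only as a product, the likelihood has a ridge along which a larger
$\kappa$ trades off against a smaller (or boundary) $\eta$: profiling $\eta$
on a typical 400-trial synthetic session changes the log-likelihood by less
than two units across most of $[0,1]$. The inverse temperature $\beta$ and
the overall learning speed are well identified; $\eta$ alone is estimated
with heavy tails (median absolute error around 0.2 under the reference
recovery study in `tests/testthat/test-acceptance.R`). Users interpreting
$\hat\eta$ on single sessions should inspect the profile likelihood. The
same flatness makes the boundary LRT for $\kappa_F$ conservative when the
behavioral signal is weak; its type-I rate approaches the nominal level only
in regimes with fast, reliable learning, which is why the calibration study
uses a strong-signal null agent ($\kappa_L = 0.6$, $\eta = 0.6$,
$\beta = 8$).

**Model-selection study regimes.** `default_agents()` fixes one generating
agent per family. They were chosen (by piloting behavioral separability)
so that each family's distinctive mechanism is actually expressed in
choice data; with mild parameters the three families are nearly
observationally equivalent and a selection exercise would be
uninformative. The forgetting agent uses $\kappa_F = 0.25$; the
associability-asymmetry agent uses $\eta_1 = 0.05$, $\eta_2 = 0.9$ (slow
attention decay after licks, fast after withheld licks).

## Task and spike-train synthesis

`simulate_task_session()` draws a pseudorandom two-odor sequence (never more
than three identical stimuli in a row), samples actions from the agent's
softmax policy, rewards the third lick on CS+ trials, and reverses the
contingency at the first trial after 80% correct over the trailing 50 trials
of the current phase. The session runs to `n_trials_max` and is flagged
`complete` only if the criterion is reached again after the reversal,
mirroring the inclusion rule for recorded sessions. Rewards are binary; the
physical drop size and Pavlovian impulsive licks are deliberately not
modelled, since only binary feedback enters the update rules and the model
family covers only the instrumental component.

Spike trains come from inhomogeneous Poisson processes
(`simulate_unit()`): a baseline rate, an optional slow sinusoidal drift, a
boxcar odor-response kernel per odor, a multiplicative coupling of kernel
amplitude to $V_{CS+}(t)$, and rectification at zero. Assembly pairs
(`simulate_assembly_pair()`) add, for each source spike with probability
`efficacy`, one induced target spike at `lag_s` plus Gaussian jitter
(`precision_s`); efficacy may vary by trial, which is how value-tracking
assemblies are built. `simulate_voltage()` embeds a biphasic waveform
template into multichannel Gaussian noise, optionally with a large
common-mode artifact; its `snr` is defined on the detector's working signal
(band-pass filtered peak over filtered-noise MAD) so that a stated SNR maps
directly onto detection behavior. `simulate_laser_block()` adds
pulse-locked spikes for the tagging test.

What the generators do **not** emulate: sniff-locked spike timing, bursting
and refractory structure, electrode drift, overlapping spike waveforms, and
correlations between behavioral state and firing beyond what the value
coupling induces. Passing tests on these data therefore validate the
statistical machinery, not the biology of any particular recording.

## Spike detection and sniff analysis

`detect_spikes()` follows the fixed chain: per-sample median subtraction
across channels (only applied with at least four channels; it removes
common-mode signals exactly), 4th-order Butterworth band-pass 300-5000 Hz
applied forward-backward, threshold at 7.5 times the *raw* median absolute
deviation of the filtered trace (no 1.4826 normal-consistency factor —
the multiple refers to the raw MAD), 1-ms height-based pruning (ties break
to the earlier sample), cross-channel merging within a tetrode to the
highest peak, and waveform extraction at -10..+21 samples. Negative-going
peaks are detected by default (extracellular convention); polarity is
configurable. The MAD threshold is computed per channel on the whole trace.
One caveat the synthetic fixtures exposed: subtracting the median of only a
handful of channels perturbs the noise tails and inflates the false-positive
rate of a fixed-MAD threshold; with 16 or more channels, as in the recording
arrays this chain is meant for, the effect is negligible.

`sniff_frequency_change()` band-passes the pressure trace at 1-50 Hz,
anchors inhalation onsets at negative-going zero crossings (configurable;
the cycle anchor is a convention), converts the duration of the two full
cycles before and after each odor onset into frequencies, and drops (and
counts) trials with fewer than two cycles on either side.

## Unit classification

Ventral-striatal units are labelled by fixed firing-statistics rules
(passive paradigm: SPN below 5 Hz baseline with a stability gate of <10%
start-to-end drift and <=20% intermittent block fluctuation; task paradigm:
SPN < 2 Hz, fast-spiking > 12 Hz, the 2-12 Hz band resolved by ISI
regularity into cholinergic, pausing SPN, or fast-spiking). VTA units are
characterised by a sliding-window auROC (200-ms bins, 50-ms steps, control
distribution tiled from the 2 s before trial onset) and, if responsive by a
Friedman test across bins with trials as blocks, clustered with L1 distance
and average linkage into three types; the cluster with the strongest phasic
US/CS+ excitation is labelled type I (putative dopaminergic). The Friedman
layout (trials x all bins, response and baseline together) is one of several
defensible operationalisations; it is calibrated near the nominal level on
Poisson nulls. Optogenetic tagging compares the 0-20 ms spike/pulse
cross-correlogram (1-ms bins) against 10,000 control CCGs with every pulse
independently jittered in +/-30 ms; a unit is tagged when two consecutive
test bins exceed the 95th percentile of the pooled control-bin distribution.
The pooled ("global") distribution and the one-sided criterion keep the
false-positive rate below ~5-7% across baseline rates.

## Population-vector analyses

Spike counts are averaged within non-overlapping groups of three trials and
concatenated unit-wise across sessions in trial-group order (progressive
matching); the sensitivity of any result to this arbitrary cross-session
pairing can be probed with 300 random per-session permutations. Sessions
are truncated to the common minimum number of groups, dropping early 'pre'
groups and late 'post' groups. Two distances are used throughout:
$d^{cos}(x,y) = 1 - x\cdot y/(\|x\|\|y\|)$ and the length-normalised
Euclidean distance $\|x-y\|/l$. They answer different questions: the cosine
metric sees only direction (it is invariant to any uniform gain, including
population-wide excitability fluctuations), while the Euclidean metric also
sees coherent rate changes. A potentiation that multiplies a subset of
units by a common factor moves the Euclidean deviation linearly but the
cosine deviation only through the induced rotation, which is why the
plasticity checks read the Euclidean deviation and the cross-odor
separation with the cosine.

Analysis presets follow the two paradigms (behavioral: 0.4-s bins, baseline
-1.8..-0.6 s, 12 tested bins, response window 0.6-1.8 s; passive: 0.25-s
bins, baseline -1.75..-0.75 s, 7 tested bins, response window 0.5-1.25 s).
Decoding uses PCA fitted jointly on all four odor-by-phase groups (so both
phases share one space) followed by QDA with leave-one-out cross-validation;
dimensions where the QDA parameter count $2(D(D-1)/2+2D+1)-1$ reaches the
number of points are refused, which with 30 trial-groups per phase and odor
admits $D = 3..6$. Singular class covariances fall back to a
ridge-regularised Gaussian classifier (logged). Trajectory visualisation
delay-embeds the trial-averaged trajectories ($m=3$, delay 1 bin) and
reduces them with factor analysis fitted jointly across groups, falling
back to principal components when the factor model is infeasible; response
maps use classical MDS. Both are for plotting only.

## Assembly detection

The pairwise detector scans a fixed set of temporal resolutions
$\Delta \in \{10, 15, 30, 50, 80, 120, 250, 350, 500, 600\}$ ms with
per-resolution maximal lags $\{20,20,20,20,20,10,7,5,5,5\}$ bins; at the
finest resolution the smallest representable non-zero lag is one bin =
10 ms. For binned counts $a, b$ the per-lag coincidence count is
$C(l) = \sum_k \min(a_k, b_{k+l})$, and the test statistic contrasts it
with the count at a reference offset two bins away,
$T(l) = C(l) - C(l-2)$: genuine coordination at the tested resolution
produces an excess at its lag only, whereas slow co-modulation of both
rates inflates both terms equally. Significance comes from surrogates in
which every spike of the second train is jittered uniformly within
$\pm 2\Delta$ — a window of $4\Delta$ destroys coordination at the tested
scale while preserving slower non-stationarities, so the null is robust to
the rate drifts typical of learning sessions. The summation window is fixed
so every lag sums the same number of terms, per-lag p-values are computed
against the pooled surrogate distribution of all lags, Bonferroni-corrected
across lags within a pair and scale, and Benjamini-Hochberg-corrected
across pairs and scales. Each significant pair keeps only its
smallest-p-value resolution; an optional second pruning pass restricted to
the sharp scales ($\Delta \le 250$ ms) prevents patterns present at both a
sharp and a broad scale from being absorbed by the broad one. This
construction is a statistically self-contained reimplementation of the
published pairwise assembly-detection idea (coincidence counting at
multiple resolutions with a reference-lag contrast and non-stationarity
correction), not a line-for-line port of any existing code base. Under
independence the surrogate scheme is exchangeable, so detection is
conservative by construction; measured false-detection rates on strongly
co-modulated nulls are well below the nominal level.

Assembly activity in a trial window is the summed joint-pattern count
$\sum_k \min(a_k, b_{k+l})$ over bins starting in the window (default
0-0.7 s after CS onset); learning dynamics compare the first and last 12
CS+ (and CS-) trials per phase with a paired Wilcoxon test.

## Value regression

`value_regression()` fits $\log \mu_t = \beta_0 + \beta V_{CS+}(t)$ by
Poisson maximum likelihood, standardises
$\bar\beta = \beta\,\sigma(V)/\sigma(\hat\mu)$ (fitted means are used for
$\sigma(\mu)$, a deterministic choice), and transforms
$\beta^* = e^{\bar\beta} - 1$ so that positive values indicate positive
activity-value coupling. The baseline-subtraction control repeats the fit
on response-minus-baseline counts; negative differences break the Poisson
likelihood, in which case a Gaussian identity-link fit is used (flagged),
with the standardisation applied identically. Headline tables report only
coefficients whose raw $\beta$ is significant; the pooling helper offers BH
correction as an option, uncorrected being the reporting convention.

## Synthetic plasticity cohort

`simulate_passive_cohort()` is the test bed for the population analyses:
8 sessions of 12 units (8 excitatory with strongly overlapping odor tuning,
non-preferred/preferred amplitude ratio 0.85-1; 2 inhibitory; 2
unresponsive), 90 presentations per odor in each of the pre/pairing/post
phases, baselines 1.5-4 Hz, and a per-unit log-normal response-gain
fluctuation (SD 0.6) shared across a trial's bins. The sizing is
deliberate: 90 trials give 30 trial-groups per phase, the minimum that
admits QDA dimensions up to 6 under the parameter-count guard; the high
tuning overlap and supra-Poisson gain noise hold single-trial decoding in
the 0.7-0.9 range seen in sparse striatal ensembles rather than at ceiling,
so that a decoding *improvement* is measurable. The plasticity injection
multiplies the paired odor's kernel on the units excitatory to it by 1.3
from the pairing phase onward; the control cohort is identical with gain 1.

## Numerical conventions

Ties in spike-detection peak height break to the earlier sample; the best
assembly lag breaks ties by smaller p, then larger statistic, then smaller
absolute lag. Cosine distances involving a zero-norm vector are undefined
and excluded with a message. All generators take a mandatory seed and are
bit-reproducible. Problem sizes in the acceptance studies (for example 30-50
recovery seeds, 200-400 calibration seeds, 15-25 coupled recordings of
10-20 min) were chosen as the smallest sizes at which the Monte-Carlo error
of each reported rate is comfortably below the margin being tested.

## Known limitations

Only pairwise assemblies are considered; higher-order patterns are out of
scope. The Pearce-Hall associability is a single global trace rather than
one per stimulus. The Friedman-test layout for auROC responsiveness and the
surrogate construction of the assembly null are explicit conventions, and
alternative defensible choices exist for both. $\eta$ is weakly identified
from single sessions (see above). The sniff module computes frequency
changes only; it does not model respiration-locked spiking.
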