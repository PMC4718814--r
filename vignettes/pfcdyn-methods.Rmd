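---
title: "Single-trial decision dynamics from field potentials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-trial decision dynamics from field potentials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfcdyn)
```

# The problem

During value-guided choice, prefrontal single units transition from encoding
the difference in value between the available actions to encoding the
selected action, while the simultaneously recorded local field potential
(LFP) carries an evoked response whose *amplitude* tracks overall value and
whose *latency* tracks the chosen option's value. pfcdyn implements the
analysis chain that turns these observations into a single-trial account of
decision dynamics:

1. extract a per-trial amplitude index and a per-trial latency index from
   stacked evoked waveforms by PCA;
2. relate those indices, and the task's decision variables, to unit firing
   with sliding-window OLS and the coefficient of partial determination
   (CPD), with noise-component, shuffle and orthogonalisation controls;
3. test population effects non-parametrically (sign-flip permutations,
   empirical multiple-comparison thresholds, circular--linear phase
   coupling);
4. reproduce the whole phenotype mechanistically with a spiking
   winner-take-all attractor network analysed by the same pipeline.

Because no public recordings accompany this line of work, the package ships
a seeded generator whose outputs have the statistical structure every
downstream stage assumes. All pipeline tests run against that generator and
against closed-form oracles.

# The task and trial model

`sim_trials()` draws, per trial, a reward level and a cost level (each 1--4)
for the left and right option; option value is reward minus cost (range
−3..3). Half of the trials pay the cost as physical effort, half as delay to
reward, randomly interleaved; both options on a trial share the type.
Choices follow a softmax on the left-minus-right value difference,
`P(L) = logistic((v_L − v_R)/T)` with temperature `T` (default 1; `T → 0`
is an argmax). An *error trial* is a choice of the strictly lower-valued
option; ties are never errors. Derived columns (chosen/unchosen value, error
flag) are always populated, and every generator draws its randomness from
streams derived deterministically from one master seed, so a single integer
pins down a full multi-stage dataset.

# The evoked-response generator

`sim_lfp()` renders trial $i$ on electrode $e$ as

$$x_{ie}(t) = (1 + a_{ie})\, g(t - \tau_{ie}) + \varepsilon_{ie}(t),$$

where $g$ is a template waveform (difference of two gamma-shaped bumps: a
fast early deflection and a larger, slower late wave of opposite sign; the
shape is configurable and nothing downstream may depend on it). The
amplitude latent follows the z-scored value sum,
$a = \alpha\, z(v_L + v_R) + \mathcal N(0, \sigma_a)$, and the latency
latent is pushed *earlier* by chosen value and by errors,

$$\tau = -\beta_v\, z(v_{chosen}) - \beta_e\, \mathbf 1[error]
  + s_{region} + l_{electrode},$$

with region-shared and electrode-local Gaussian terms. Latency is applied by
resampling $g$ on a shifted grid with boundary-value padding (no
wrap-around); shifts beyond `max_latency_ms` abort generation rather than
silently truncating the waveform.

Defaults (`erp_model()`): $\alpha = 0.15$ per z-unit of value sum,
$\sigma_a = 0.1$; $\beta_v = 10$ ms per z-unit of chosen value,
$\beta_e = 15$ ms; $\sigma_{shared} = 15$ ms, $\sigma_{local} = 5$ ms;
additive white noise SD 0.1 against a unit-peak template. The literature
states no physical effect sizes for the value--latency link, so these are
free parameters chosen once to give the high single-trial signal-to-noise
visible in raw recordings of this preparation (single-trial waveforms
recognisable by eye; PCA recovers the latents at $|r| \gtrsim 0.8$). The
ground-truth latents are always emitted in a side table; recovery tests read
them from there and never re-derive them.

What the generator does *not* emulate: 1/f background spectra, oscillatory
phase resetting, eye-movement and motor artifacts, electrode drift,
inter-areal conduction delays. Passing tests therefore demonstrate that the
pipeline recovers the targeted structure when it is present, not that real
recordings contain it.

`sim_meg_subjects()` produces the human-style variant: one virtual electrode
per subject, the whole subject multiplied by a random recorded sign
(emulating the sign ambiguity of source reconstruction), and reaction times
`rt = base − slope · v_chosen + k·τ + noise`, truncated positive, so RT is
fast for high-valued choices and slow on late-waveform trials.

## Spike generator

`sim_spikes()` draws inhomogeneous Poisson rasters whose rate combines a
baseline with three unit-peak Gaussian kernels: an early kernel carrying
$z(v_L - v_R)$, a late kernel carrying the chosen side (±1), and a mid-trial
kernel carrying chosen value and/or the latency latent. Each unit draws one
selectivity sign applied to both its early and late kernels, so early
value-difference selectivity predicts late choice selectivity across units.
The `mediation` parameter routes the mid-trial chosen-value drive through
the latent: at 0 the drive is $z(v_{chosen})$ directly, at 1 it is
$-z(\tau)$ (which correlates with chosen value through the generative
$\beta_v$), with convex mixtures between. Rates are rectified at zero and
sampled in 1 ms bins.

# Stacked-trial PCA

Single-trial waveforms from all electrodes and sessions are stacked into a
matrix $X$ with one row per trial per electrode
(`[nRecordedElectrodes·nTrials] × nTimepoints`, analysis window −200 to
+1000 ms at 100 Hz by default, half-open sample grid). Stacking is what
makes the decomposition comparable across electrodes and sessions: the
temporal components $V$ of $X = U S V^\top$ form one shared basis, and the
rows of $U$ are single-trial weights with a common interpretation.

*Artifact exclusion.* Within-trial variability is indexed by
$\sqrt{\mathrm{SD}_t(x)}$ per row; rows strictly more than 2.32 SDs above
the mean index (the Gaussian 99th percentile truncated to two decimals) are
excluded. With zero index spread nothing is excluded (strict inequality).
Only this automated rule is implemented; there is no analogue of visual
electrode curation.

*Demeaning.* The per-timepoint mean over all retained rows (the grand
evoked response) is removed before the SVD, so components capture
cross-trial variability in waveform shape. Whether demeaning should be
global or per-electrode is genuinely open; global is the default (it matches
the rationale of stacking), per-electrode is available via
`demean = "electrode"`.

*Sign conventions.* The sign of each singular vector is arbitrary, so
anchored components are flipped to fixed signs at fixed times (component 1
positive at +190 ms, component 2 negative at +530 ms by default); anchor
times snap to the nearest sample and snaps are recorded. A component with a
zero singular value cannot be anchored and raises an error.

The reconstruction identity $U S V^\top + \text{mean}$ reproduces the
retained demeaned rows to at least 1e−8 relative error (tested), explained
variance fractions are non-increasing and sum to ≤ 1, and
`reconstruct_erp()` exposes the interpretive sweep: adding multiples of the
amplitude component scales the late wave without moving it (within one
sample, by the half-amplitude crossing criterion), adding multiples of the
latency component moves it monotonically in time.

## Which component is the latency component?

In transient evoked data the latency component is typically the *second*
component and its shape approximates the temporal derivative of the mean
ERP — a latency shift is, to first order, derivative admixture. In
ramp-to-attractor dynamics (the network model's summed activity) the
latency variance dominates and lives in the *first* component, whose shape
is a broad hump rather than the mean's derivative; there, shape similarity
to the derivative actively misidentifies the component (it selects a
low-variance sharpness component whose weights carry no timing
information). No single shape statistic we evaluated (derivative
similarity, template cross-correlation lags, temporal centre of mass,
per-trial normalised half-max crossings) identifies the right component in
both regimes.

`latency_component()` therefore offers two LFP-intrinsic criteria:

* `method = "derivative"` (default): maximum absolute correlation of the
  component's shape with the smoothed (80 ms) derivative of the mean ERP
  over 200--1000 ms. Scale-robust; appropriate for transient evoked
  waveforms, where amplitude variance would contaminate crossing times.
* `method = "crossing"`: per-row latency is the first time the smoothed
  waveform crosses half the level of the mean's late extremum (relative to
  the pre-onset baseline), and the latency component is the candidate whose
  weights best correlate with those crossing times. Appropriate for
  sustained ramps, where single-trial amplitude variation is negligible so
  the level-crossing is a pure timing measure. `model_lfp_analysis()` uses
  this method.

Neither criterion consults behaviour, so downstream relations between
latency weights and reaction/decision times remain genuine findings.
`latency_weights()` returns the component's scores oriented so that a
larger weight means an *earlier* waveform, which fixes the interpretation
of regression signs across datasets.

For human-style data, `align_subject_signs()` resolves the per-subject sign
ambiguity by iteratively flipping any subject whose evoked response
correlates negatively with the signed grand mean of the others; the global
sign is resolved by majority (+1), with ties keeping subject 1 positive.
The procedure is order-invariant at its fixed point and errors with
diagnostics if it fails to converge.

# Regression framework

`bin_rates()` estimates firing rates in 200 ms boxcars stepped at a
configurable interval (10 ms default; coarser steps are used in the heavier
property tests). The decision model regresses each bin's rate, across
trials, on five regressors: an effort-trial constant, a delay-trial
constant, the left-minus-right action value, the chosen action (±1) and the
chosen value. Value regressors are z-scored per session by default — the
original five-regressor model's scaling is unstated, z-scoring makes
coefficients comparable across electrodes and matches Z-scored reporting;
raw levels are available via `zscore_values = FALSE`. Standard errors are
classical OLS. Degenerate single-type sessions drop the empty constant with
a warning; rank-deficient designs error, naming the collinear columns.

For a factor $X_i$,

$$\mathrm{CPD}(X_i) = \frac{SSE(X_{\sim i}) - SSE(X)}{SSE(X_{\sim i})},$$

which is nonnegative for nested OLS fits and equals the squared partial
correlation for single-column factors (tested identity). Tiny negative
values from floating-point cancellation are clamped to zero; a perfectly
fitting reduced model yields a flagged `NaN`. Every CPD can be compared to
its analytic chance level `p_factor/(n − p_total)` via `chance_cpd()`.

`lfp_value_regression()` applies per-timepoint OLS of voltage on chosen and
unchosen value, aggregating Z-scored coefficients across electrodes; the
informative comparison is that value coefficients peak where the evoked
response is *ramping* (`erp_derivative()`: centred differences smoothed
with an 80 ms boxcar), not at its peaks. `pc_weight_regression()` regresses
single-trial weights on intercept, chosen value, unchosen value and the
error indicator, optionally appending reaction time residualised against
those three (`orthogonalize()`), so the RT coefficient measures RT variance
beyond task variables.

One caveat the generator makes visible: when amplitude and latency latents
coexist, the top two components mix slightly (the template and its
derivative are not orthogonal, and the $a\,\tau\,g'$ cross-term is second
order), so latency weights can inherit a small value-sum (amplitude)
leakage — e.g. a negative unchosen-value coefficient alongside the genuine
positive chosen-value effect. Tests assert only the generative signs.

# Coupling analyses

`augmented_unit_model()` adds single-trial PC weights — by design from a
*different*, simultaneously recorded electrode of the same region (nearest
electrode by ID; deterministic) — to the task design, and reports the
joint CPD of the PC terms per bin. The full task-covariate set of the
original 19-regressor model is not published, so the package implements a
named, user-extensible registry (`task_design(set = "full19")`) whose
default is the reduced 6-term decision model plus 14 documented,
mutually non-collinear task covariates (previous-trial terms, reward
composition, trial-type interactions; `choice × unchosen value` is
deliberately absent because with `choice` and `choice × chosen value` it
would span the value difference exactly). Every headline analysis must
reproduce under `set = "reduced6"`, and tests enforce agreement between the
two on synthetic data.

`cpd_reduction()` quantifies how much of each decision variable's CPD the
top components explain away, against a control model containing two noise
components (indices 101/102 when the decomposition retains that many, else
the last two retained, with a warning) to absorb the generic effect of
adding regressors. The reduction is bounded above by the control-model CPD
(tested). `shuffled_pc_control()` provides the complementary control:
weights permuted within chosen-value strata keep their value correlation
but lose trial-specific coupling; singleton strata stay in place. The
shuffle control is the sharp instrument for *mediation* questions — the
noise-PC contrast includes the mechanical reduction that any
value-correlated coregressor produces, which the shuffle preserves and
thereby cancels; the package's mediation property suite uses it for exactly
that reason.

`local_vs_distal()` orthogonalises local weights against distal ones, runs
the reduction, performs the reverse analysis and subtracts: positive values
mean local dynamics explain away more task variance than distal dynamics.
The statistic is exactly antisymmetric under swapping the sources (tested).
`cross_region_model()` implements the six-term effort/delay competition
design (two type constants plus each source's weights gated to each trial
type) and reports per-source effort-minus-delay CPD differences.
`median_split()` is deterministic: stable sort, ties to the lower half,
sizes ⌈n/2⌉/⌊n/2⌋ (124 units split 62/62).
`pc_weight_cross_correlation()` summarises shared dynamics as within- vs
between-region correlations of trial-aligned weights.

# Permutation inference

`signflip_test()` builds the null by randomly sign-flipping each unit's
whole effect timecourse (effects are defined relative to a 500 ms
pre-choice baseline by the caller) and averaging; one-sided p-values are
`(#{perm ≥ obs} + 1)/(n_perm + 1)`, floored at `1/(n_perm + 1)`, with
10,000 permutations by default. `empirical_threshold()` estimates
multiple-comparison-corrected Z criteria over a time window by refitting
with whole rows of the design permuted (preserving regressor covariance)
and taking tail quantiles of the max/min Z; the published thresholds
(Z > 2.99, Z < −3.05) are data-dependent outputs of this procedure, not
constants of the package. `circ_linear_corr()` uses the two-harmonic
construction, equal to $\sqrt{R^2}$ from regressing the linear variable on
$\cos\theta$ and $\sin\theta$ (tested algebraic identity); the source work
cites but does not state a formula, and the harmonic form is the standard
reading. It is non-negative, rotation-invariant, and `NaN`-flagged for
zero-variance inputs.

# The attractor network

`network_config()` fixes the structure: 2000 leaky integrate-and-fire cells
(1600 excitatory, 400 inhibitory), two selective pools of fraction
$f = 0.15$ (240 cells each) plus 1120 non-selective cells; all-to-all
connectivity with within-pool weight $w_+ = 1.7$, cross-pool and
non-selective→selective weight

$$w_- = 1 - \frac{f\,(w_+ - 1)}{1 - f} = 0.8765\ (4\ \mathrm{d.p.}),$$

and all other weights 1. The neuron and synapse constants are not restated
in the source work (it defers to its cited decision-network model with
identical parameters), so the package ships that model line's standard
conductance-based set as an editable configuration: AMPA (rise-free, 2 ms
decay), NMDA (2 ms rise, 100 ms decay, α = 0.5 /ms, Mg block
$1/(1+e^{-0.062V}/3.57)$), GABA (5 ms), membrane constants 0.5 nF/25 nS
(E) and 0.2 nF/20 nS (I), threshold −50 mV, reset −55 mV, refractory
2/1 ms. Tests assert behavioural contracts only (spontaneous activity below
the readout threshold, winner-take-all separation, psychometric and
chronometric regularities), never specific voltages.

Each cell receives 2.4 kHz background Poisson drive through external AMPA
synapses. During the 2500 ms stimulus period (after 500 ms of
initialisation) the selective pools additionally receive Poisson input
whose per-trial means $\mu_A, \mu_B$ are independent uniform draws on
20--60 Hz and whose instantaneous rate is resampled every 50 ms from
$\mathcal N(\mu, 10)$, rectified at zero (truncation is rare at these
means; rectification is used and documented). Integration is Euler with
`dt` = 0.02 ms by default and 0.1 ms as the documented fast mode used by
the test suite; the all-to-all, pool-uniform weights let the recurrent
drive be computed exactly from pool-summed gating, so a step is O(N). The
inner loop is compiled (Rcpp) and draws all randomness from R's RNG, so
trials are bit-reproducible under a seed. Divergent voltages abort with the
offending `dt` named.

The choice readout fires when a pool's 50 ms sliding rate first exceeds
25 Hz while leading the other pool by at least 15 Hz, evaluated at every
sample; the simulation always runs the full 3 s — the readout only labels
the trial and its decision time. The LFP proxy is the summed firing rate of
all cells. `model_regression()` uses decided trials only (undecided counts
are reported) and the printed value normalisation: value difference
$(\mu_A - \mu_B)/80$, chosen value $\mu_{chosen}/80$, with a chose-A
indicator. `model_lfp_analysis()` stacks the LFP proxies, decomposes them
with the same machinery, identifies the latency-like component with the
crossing criterion (see above; it is the *first* component here), and
reports its weight regressions plus the chosen-value CPD reduction in
A-pool firing against the noise-component control.

# Problem sizes and numerical choices

The property suites run at sizes chosen to make the targeted effects
unambiguous while keeping the whole suite comfortably interactive: PCA
recovery on 500 trials × 4 electrodes; mediation on 50 synthetic units at
routed fractions {0, 50, 100}% of a 500-trial session; cross-region
recovery on 40 units × 400 trials; sign-flip calibration over 500 null
repeats at 1,000 permutations; network behaviour on 160 random-input trials
plus 200 symmetric-input trials at the 0.1 ms fast mode (about 1.4 s per
simulated 3 s trial on one core). The quartile-trend checks are
operationalised as a positive correlation of quartile index with accuracy
and a negative one with median decision time, plus top-vs-bottom quartile
inequalities.

Other conventions: time grids are half-open (`[t0, t1)`), so 1.5 s at
100 Hz is exactly 150 samples; all generator randomness derives from one
master seed via labelled streams; median splits and electrode pairings are
deterministic; permutation p-values never reach zero.

# Limitations

The generator's latents are Gaussian and enter linearly; real LFP latency
effects may be state-dependent and non-additive. The CPD framework is OLS
on binned rates — by design, matching the analysis being implemented — not
a point-process likelihood. Cross-regional CPD differences quantify
explained variance, not directed influence; no causal claim is encoded in
any test. The network is a single-area, two-option model with the cited
parameter set; no parameter fitting to data is attempted.
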