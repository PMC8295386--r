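---
title: "Methods: reaction-time decomposition and energy-landscape brain states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reaction-time decomposition and energy-landscape brain states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradstate)
```

## The scientific question

In a gradual-onset continuous performance task (gradCPT), city and mountain
scenes cross-fade every 800 or 1300 ms; participants press to city (go) and
withhold to mountain (no-go). Sustained-attention research summarizes the
resulting reaction times (RTs) by their mean and variance, but RT
distributions are positively skewed: a large variance can come either from
pervasive trial-to-trial instability around the central tendency, or from an
occasional long tail of very slow responses. The exGaussian decomposition
separates the two. Independently, network-level fMRI activity during the
same task can be summarized by a small number of recurring *brain states*
obtained from a pairwise maximum-entropy model and its energy landscape.
`gradstate` implements both analyses and their junction: which RT component
differs between brain states.

## The exGaussian model

An exGaussian random variable is the sum of a Normal(μ, σ²) and an
independent Exponential(τ):

* μ — central tendency of the Gaussian core ("strategy factor"),
* σ — spread of the Gaussian core ("variance factor"),
* τ — mean of the exponential tail ("long-tail factor"),

with mean RT = μ + τ and RT variance = σ² + τ². The density is evaluated in
the log domain,

$$\log f(x) = -\log\tau + \frac{\sigma^2}{2\tau^2} - \frac{x-\mu}{\tau}
  + \log\Phi\!\left(\frac{x-\mu}{\sigma} - \frac{\sigma}{\tau}\right),$$

because the naive closed form overflows when τ is small relative to σ.

### Estimation choices

`fit_exgauss()` maximizes the likelihood over (μ, log σ, log τ) with
L-BFGS-B, started from moment matching (τ₀ = sd·(skew/2)^{1/3}, σ₀² =
max(var − τ₀², ε), μ₀ = mean − τ₀). The log parameterization keeps σ, τ > 0
without constraints. Fits require at least 10 correct-commission RTs
(`min_trials`); three parameters cannot be identified from fewer, and small
pools must fail loudly (a classed condition) rather than return a silently
degenerate fit. A Gaussian comparator (mean and MLE standard deviation) is
recorded with every fit.

### Negative skew

The exGaussian can only represent a *right* tail. Samples with negative
bias-corrected Fisher–Pearson skewness (threshold exactly 0) are handled by
policy: `"flip"` fits the sign-reversed sample and maps the location back
(μ := −μ_fit, σ and τ kept as fitted), `"exclude"` marks the unit. State
comparisons use `"exclude"` so the long-tail factor remains unambiguously a
slow tail. In split-half analyses each half is flipped independently; a unit
whose halves straddle the flip decision simply contributes a noisier pair.

### Simulation-based goodness of fit

`goodness_r2()` compares the empirical histogram against a large sample
simulated from the fitted distribution: Freedman–Diaconis bin width computed
on the empirical sample, one shared bin grid covering both samples,
densities (not counts) compared by R² = 1 − SS_res/SS_tot. The binning rule
must be pinned for reproducibility since R² depends on it; densities make
the statistic insensitive to the simulated sample being larger (default
`sim_n = max(10 n, 10000)`). At mild skew the difference between the
exGaussian and Gaussian R² is smaller than the Monte-Carlo noise of the
statistic itself; the comparison is informative in clearly skewed regimes
(τ/σ around 1 or larger).

## The pairwise maximum-entropy model

Network activity is standardized per run, averaged into N = 8 canonical
networks (DMN, Limbic, FPN_A, FPN_B, DAN, SN, SMN, Visual), and binarized
at each network's time mean (ties inactive). The maximum-entropy
distribution over binary patterns matching the empirical activation rates
⟨σᵢ⟩ and co-activations ⟨σᵢσⱼ⟩ is the Boltzmann/Ising law

$$P(V_k) \propto e^{-E(V_k)}, \qquad
E(V_k) = -\sum_i h_i \sigma_i(V_k)
         - \tfrac12 \sum_{i \ne j} J_{ij}\,\sigma_i(V_k)\,\sigma_j(V_k).$$

We use the convention in which **lower energy means higher probability**;
the landscape's minima are then the dominant states, which is the only
self-consistent reading of an energy-landscape analysis.

`fit_mem()` runs moment-matching gradient ascent — h ← h + η(⟨σ⟩_emp −
⟨σ⟩_model), J likewise — with model moments computed by exhaustive
enumeration of all 2^N patterns (N ≤ 16). The base step is η = 0.2 with
backtracking: a step that would lower the log-likelihood is halved, which
makes likelihood monotonicity unconditional rather than dependent on a
stability threshold. Convergence is declared when the largest absolute
moment mismatch drops below 10⁻⁵ (cap 10⁵ iterations). Units observed
always-on/off put the empirical moment on the boundary where the MLE
diverges; such moments are clamped into [ε, 1−ε] with ε = 1/(2T), with a
warning.

The fit is verified by `fit_quality()`: the Pearson correlation between
each pattern's empirical appearance probability (time average of its 1-of-K
indicator) and the model probability.

### Energy landscape and brain states

A pattern is a **local minimum** when its energy is strictly below all N
Hamming-1 neighbors (ties disqualify — a deterministic rule for a
measure-zero case). Every pattern is assigned to a minimum by steepest
descent on the enumerated landscape, moving to the lowest-energy neighbor;
ties among equally lowest neighbors break to the lowest pattern code.
Minima are named by template: State1 when a strict majority of
{FPN_A, DMN, Limbic} is active and a strict majority of the complementary
five networks inactive; State2 for the reverse; anything else "other".

Binarization thresholds and the group model are computed on the series
concatenated across runs and participants, then per-volume labels are
mapped back per run. Per-volume states are aligned to behavior by shifting
labels backwards by round(lag/tr) volumes (hemodynamic lag, default 5 s;
exact halves round down — e.g. TR 2 s gives a 2-volume shift, TR 1.08 s a
5-volume shift). The rounding rule is surfaced in the `state_series`
object because different choices shift pools by one volume.

## Press-to-trial assignment

RT is measured from the start of a cross-fade, so RT = ISI means the
current image was fully coherent. Presses inside a trial's *unambiguous
window* — from 70% coherence of the current scene to 40% coherence of the
next, i.e. [0.7·ISI, 1.4·ISI] after onset, both endpoints included so the
canonical 90%-coherence example is unambiguous — belong to that trial.
Remaining presses are arbitrated iteratively:

1. a trial keeps the fastest of its in-window presses; surplus presses
   (multiple presses) become ambiguous between that trial and the neighbor
   on their side of full coherence;
2. an ambiguous press goes to the single adjacent trial lacking a response;
   when both lack one it goes to the *closest* trial — distance measured to
   the moment of full coherence (onset + ISI), ties to the earlier trial —
   unless one neighbor is a no-go trial, which keeps the benefit of the
   doubt (if both are no-go the press is dropped);
3. pass 2 repeats to a fixed point (an assignment can free a neighbor),
   capped at one sweep per press.

City trials with/without an assigned press are correct commissions /
omission errors; mountain trials with/without are commission errors /
correct omissions. Runs containing a ≥ 30 s interval with no response
("tune-outs", boundary inclusive) can be flagged for exclusion.

The three-pass arbitration is greedy. On dense random toy instances it can
fall short of the brute-force maximum of correct responses, almost always
because the single-empty-neighbor rule assigns an ambiguous press to an
empty *no-go* trial where the optimum would drop the press. The test suite
compares against an exhaustive oracle on small instances and logs every
shortfall rather than silently correcting the documented behavior.

## The synthetic-data generator

Because the original behavioral and imaging cohorts are not downloadable,
every stage is validated against a generator with recorded ground truth:

* **Trial streams** — 10%/90% mountain/city mixes, scene identities drawn
  from 10 photographs per category with immediate repeats rejected, onsets
  on the ISI grid.
* **Network dynamics** — a lazy single-flip Metropolis chain (hold
  probability 1/2, which removes the parity periodicity a pure
  always-accept chain exhibits at zero energy) whose stationary law is the
  planted model's Boltzmann distribution; `dwell_control` steps between
  recorded volumes interpolates between persistent, slowly mixing dynamics
  and independent draws, both limits testable. The chain starts from an
  exact Boltzmann draw so every volume is marginally stationary. The
  continuous signal is ±1 (active/inactive) plus unit-variance Gaussian
  noise: at that signal-to-noise ratio mean-thresholding recovers ~84% of
  entries and basin mapping ~94% of state labels, leaving realistic label
  noise in the pipeline.
* **Planted two-state model** — a Hopfield-style one-pattern construction:
  spin couplings (J₀/N)·ξξᵀ with ξ = +1 on the State1 networks, mapped to
  the 0/1 convention. Its only two minima are the State1 template and its
  complement. J₀ = 1.6 gives two clear minima with comparable basin mass
  and multi-volume dwell times at the default `dwell_control`.
* **Behavior** — per trial, the generating state is the label of the
  volume covering the onset advanced by the *same* integer lag shift the
  pipeline later removes, so round-trips are exact. City trials press with
  probability 1 − omission_rate(state) at an RT drawn from the state's
  exGaussian; mountains press with probability commission_rate(state).
  Deviant presses (rate `ambiguous_press_rate`) are slow realizations: the
  exGaussian tail beyond the window edge is exponential(τ) by memorylessness,
  truncated to the ambiguous gap. An earlier uniform placement was found to
  inject artificially fast re-assigned RTs — a mechanism the task does not
  produce — and was replaced. Multiple presses (rate `multipress_rate`) are
  rapid double-taps 50–150 ms after the first press. Anticipatory early
  presses are not modelled as a class (`anticipation_fraction = 0` by
  default).
* **Population** — participant-level (μ, σ, τ) with Gaussian μ and
  lognormal σ, τ (moment-matched, so they stay positive); error rates are
  logistic transforms of latent scores whose planted Spearman correlations
  with the parameters are set through the Gaussian-copula identity
  ρ = 2 sin(πρ_s/6).

What the generator does **not** emulate: voxel-level fMRI, head motion,
physiological noise structure (confound regression is supported but the
synthetic networks are generated post-cleaning), time-on-task drifts,
probe-triggered task interruptions, and anticipatory presses. Passing tests
therefore demonstrate the pipeline's correctness and statistical behavior
under the stated generative assumptions, not robustness to those real-data
features.

## Default study conditions

The default configuration mirrors a three-run fMRI session: 16
participants × 3 runs × 600 trials at ISI 0.8 s, TR 2 s, 5 s lag,
population means (0.80, 0.08, 0.05) s, State2/State1 σ ratio 1.5 with μ and
τ equal, omission rates 3%/6% and commission rates 25%/35% (suboptimal
state less accurate), 1% deviant and 1% double-tap presses (combined well
under the task's ~5% ambiguity ceiling). Replicate experiments in the test
suite use 25 participants × 300 trials per run; oracle comparisons use
2–8 networks and ≤ 8-trial toys where exhaustive enumeration is exact.

## Statistics

State comparisons fit an exGaussian per state per participant (exclude
policy; both pools need ≥ 10 correct commissions) and run two-tailed paired
t-tests per parameter across participants, with exclusions applied jointly
so the paired design stays balanced. Effect sizes are Hedges' g with the
pooled-SD standardizer and small-sample correction J(df) = 1 − 3/(4df − 1):
the paired-difference standardizer (d_z) would not match the magnitude of
published effect sizes in this literature, which are far below t/√n. No
multiple-comparison correction is applied across the three parameters;
replication across independent synthetic datasets plays that role, matching
field practice. Rank correlations use average ranks and the t
approximation for p-values; multiple regression reports raw and
standardized coefficients (the latter defined only up to the z-scoring of
predictors and outcome, which is stated in the output). Split-half
reliability applies the Spearman–Brown step-up 2r/(1+r).

Under the null (equal state parameters) the σ comparison rejects at the
nominal 5% level (measured 2–8% over 400 simulated experiments), and its
power increases with the planted σ ratio; with the default planted ratio
1.5 the pipeline detects the σ difference in ≥ 90% of replicate
experiments while μ and τ stay at the nominal false-positive level — the
qualitative headline the method is designed to expose.

## Known limitations

* The press-assignment arbitration is the documented greedy procedure, not
  a global optimizer (shortfalls are logged by the tests).
* Exhaustive enumeration bounds the model at N ≤ 16 networks; N = 8 is the
  intended scale.
* The negative-skew exclusion couples with misassignment artifacts: pools
  contaminated by re-assigned fast RTs are more often excluded, which can
  bias who enters the comparison (observed exclusion rates of 15–40% at
  small pools, comparable to published exclusion rates for this analysis).
* The simulation-based R² is itself a Monte-Carlo quantity; comparisons
  built on it are only meaningful when the distributions differ by more
  than its noise floor.
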