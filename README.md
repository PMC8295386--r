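# gradstate

Tools for asking *what kind of reaction-time variability* distinguishes
brain states during sustained attention.

## The problem

In the gradual-onset continuous performance task (gradCPT), scenes
cross-fade every 800/1300 ms; participants press to city scenes and
withhold to mountains. Reaction-time (RT) variability indexes attentional
state, but RT distributions are positively skewed, so a large variance can
mean two different things: pervasive instability of the response process,
or an occasional long tail of very slow responses. The exGaussian
decomposition — RT = Normal(μ, σ²) + Exponential(τ), with mean RT = μ + τ
and RT variance = σ² + τ² — separates a strategy factor (μ), a variance
factor (σ) and a long-tail factor (τ).

On the imaging side, binarized activity of N = 8 canonical brain networks
is modelled by a pairwise maximum-entropy (Ising) distribution,

    E(V) = − Σᵢ hᵢ σᵢ(V) − ½ Σ_{i≠j} J_ij σᵢ(V) σⱼ(V),   P(V) ∝ exp(−E(V)),

whose energy landscape over all 2^N activity patterns is enumerated
exhaustively: local minima (patterns below all Hamming-1 neighbors) define
brain states, steepest descent assigns every pattern to a basin, and the
per-volume state series is aligned to behavior by a hemodynamic-lag shift.
Pooling correct-commission RTs by brain state and fitting the exGaussian
per state per participant then answers the headline question: which RT
factor differs between the dominant states.

The package implements the full pipeline for researchers in computational
neuroscience / sustained attention: gradCPT press-to-trial assignment with
the task's coherence convention, exGaussian MLE with negative-skew
handling and simulation-based fit comparison, MEM fitting by exhaustive
moment-matching gradient ascent, energy-landscape state extraction,
state-wise statistics (paired t, Hedges' g, Spearman correlations,
multiple regression, split-half reliability), and a synthetic-data module
that co-simulates behavior and network dynamics from a planted two-state
Ising model so every stage is testable with recorded ground truth.

## Worked example

Fit an exGaussian to simulated correct-commission RTs:

```r
library(gradstate)
set.seed(7)
rts <- rexgauss(2000, mu = 0.80, sigma = 0.08, tau = 0.05)
fit_exgauss(rts)
#> exGaussian fit (n = 2000)
#>   mu = 0.7920  sigma = 0.0733  tau = 0.0584
#>   logLik = 1932.26 (Gaussian 1898.86)  skewness = 0.47
```

The three numbers are the strategy, variance and long-tail factors in
seconds; the exGaussian log-likelihood exceeds the Gaussian comparator's,
as expected for positively skewed data (skewness 0.47).

Run the end-to-end pipeline on a simulated cohort (12 participants, 2 runs
of 400 trials, planted State2/State1 σ ratio 1.5 with equal μ and τ):

```r
report <- run_pipeline(list(seed = 42, n_participants = 12, n_runs = 2,
                            n_trials_per_run = 400))
report
#> gradstate pipeline report
#>   MEM fit: r(empirical, model pattern probabilities) = 0.9683; 3689 iterations, moment mismatch 1.0e-05
#>   2 local minima:
#>  code  label energy basin_probability         active_networks
#>     7 State1  -4.08             0.528        DMN+Limbic+FPN_A
#>   248 State2  -3.98             0.472 FPN_B+DAN+SN+SMN+Visual
#>   exGaussian parameters by state:
#>  parameter  mean_a  mean_b       t df p_value hedges_g
#>         mu 0.78622 0.77906  0.8299  5 0.44440   0.1056
#>      sigma 0.09617 0.11982 -3.2429  5 0.02287  -1.1883
#>        tau 0.05883 0.06558 -0.5488  5 0.60677  -0.2538
#>   included 6 participants, excluded 6
```

Reading the report: the fitted maximum-entropy model reproduces the
empirical pattern frequencies (r = 0.97), its landscape has exactly two
minima matching the canonical templates (State1 = DMN+Limbic+FPN_A active;
State2 = the complementary five networks), and across participants only σ
differs significantly between states (mean 0.096 s in State1 vs 0.120 s in
State2, p = 0.023), while μ and τ do not — the planted ground truth.
Participants are excluded when a state pool has fewer than 10 correct
commissions or negative skewness (the exGaussian's tail must point right);
`report$comparison$exclusions` itemizes the reasons.

Key entry points: `gen_trial_stream()` / `gen_network_series()` /
`gen_behavior()` / `gen_population()` (synthetic data),
`assign_presses()` / `error_counts()` / `exclude_tuneouts()` (behavior),
`fit_exgauss()` / `fit_with_skew_policy()` / `goodness_r2()` /
`split_half_reliability()` (RT modelling), `fit_mem()` /
`energy_landscape()` / `state_series()` / `label_named_states()` (brain
states), `pool_rts()` / `compare_states()` / `correlate_params()` /
`regress_errors()` / `mind_wandering_correlation()` (statistics),
`simulate_dataset()` / `run_pipeline()` (orchestration). A thin
command-line wrapper for the simulate/run stages lives in
`inst/scripts/gradstate.R`. See the methods vignette
(`vignettes/gradstate-methods.Rmd`) for the model details and design
decisions.

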