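# beatbayes

Bayesian observer modeling of systematic errors in rhythm perception.

When people judge whether the final beat of an isochronic rhythm came
too early or too late, their errors are systematic: with short
inter-beat intervals the last beat tends to be heard as *early*, with
long intervals as *late*, and the errors shrink as the rhythm supplies
more beats. `beatbayes` is for psychophysicists and computational
neuroscientists who want to simulate, fit and analyze this class of
two-alternative forced-choice (2AFC) timing experiments with an
ideal-observer model.

## The model

A stimulus has `N` beats at spacing Δ, the last interval deviated to
Δ(1+ρ). Each beat elicits one internal spike at a causal Gamma lag
(shape *n*, time constant τ_I; mode (n−1)τ_I). The observer MAP-estimates
the first-beat time and interval from the first N−1 spikes under a
lognormal interval prior (scale τ_Δ, shape σ; mean τ_Δ·exp(σ²/2)),
extrapolates the last beat, and predicts the last spike by minimizing an
expected loss — Dirac (posterior mode), quadratic (mean), absolute
(median) or a margin loss — always shifted earlier by a
better-early-than-late constant τ_E. It answers "late" when the
predicted last spike precedes the actual one. Observer parameters are
fitted to per-condition response counts by coordinate-descent
minimization of Pearson χ² on a common-random-number Monte-Carlo
objective, with df = conditions − parameters − 1. Companion modules
supply the group statistics of such studies (exact binomial tests,
Cohen's *h*, Kendall trend tests, population prevalence, cross-subject
medians) and a synthetic-cohort generator with a ground-truth manifest.

## Worked example

```r
library(beatbayes)
params <- standard_observer_params()  # the standard fitted observer
params
#> Bayesian beat-timing observer
#>   impulse response: Gamma(shape n = 1, tau_I = 0.075 s)
#>   interval prior:   lognormal(tau_Delta = 1.4 s, sigma = 1.1), mean 2.564 s
#>   loss:             absolute (tau_E = 0.015 s)

rbind(simulate_condition(params, 3, 0.15, 0.05, n_mc = 1000, seed = 7),
      simulate_condition(params, 3, 1.20, 0.05, n_mc = 1000, seed = 7))
#>   n_beats delta_s  rho trials n_late n_early n_correct p_correct p_late
#> 1       3    0.15 0.05   1000    437     563       437     0.437  0.437
#> 2       3    1.20 0.05   1000    608     392       608     0.608  0.608
```

With a late-deviated final beat (ρ = +0.05) the observer is *below*
chance at the short interval (p_correct = 0.437): the prior, whose mean
(≈2.6 s) far exceeds 0.15 s, inflates the interval estimate, so the
predicted last spike lands late and the observer answers "early" too
often. At Δ = 1.2 s the bias reverses (p_correct = 0.608). The same
signature appears in the zero-deviation late-minus-early excess:

```r
surf <- simulate_design(params, build_design("canonical"),
                        n_mc = 1000, seed = 7)
aggregate(excess_late ~ delta_s, bias_table(surf), sum)
#>   delta_s excess_late
#> 1    0.15        -638
#> 2    0.30        -556
#> 3    0.60         274
#> 4    1.20         350
```

Fitting, cohort generation and the group statistics follow the same
pattern; see `?coordinate_descent_fit`, `?generate_cohort`,
`?run_stats` and the vignette `vignettes/beat-timing-model.Rmd`. A thin
command-line wrapper with `simulate`/`fit`/`synth`/`stats` subcommands
is installed at `system.file("cli", "beatbayes.R", package = "beatbayes")`.

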