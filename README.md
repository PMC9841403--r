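# geopriors

Prior diagnostics for discrete-geographic phylodynamic inference, without
BEAST.

## The problem

Discrete-geographic phylodynamic models describe how a pathogen lineage
moves among a finite set of areas as it evolves down a time-calibrated
phylogeny. The dispersal process is a continuous-time Markov chain: with
*k* areas it is specified by a *k* × *k* instantaneous-rate matrix **Q**,
whose off-diagonal element *q*<sub>*ij*</sub> is the rate of dispersal from
area *i* to area *j*, together with an average dispersal rate *μ* that
scales the whole matrix (here normalized so that
−Σ<sub>*i*</sub> π<sub>*i*</sub> *q*<sub>*ii*</sub> = *μ*, making *μ* the
expected number of dispersal events per unit tree time). An asymmetric
model has *k*(*k* − 1) pairwise rate parameters — 20 at *k* = 5, 90 at
*k* = 10, 380 at *k* = 20 — all estimated from a single observation per
sample: the area it was collected in. With so many parameters and so
little data, posterior estimates can be driven largely by the priors.

`geopriors` is a self-contained R toolkit for detecting and navigating
that prior sensitivity at desk scale:

- **Bayesian inference** of (*μ*, relative rates) by Metropolis–Hastings
  MCMC over a fixed tree or a posterior sample of trees (sequential
  inference), with an exact Felsenstein-pruning likelihood for the
  geographic character.
- **Robust-Bayesian prior sweeps**: the same analysis under a panel of
  priors, with HPD-overlap comparison (`run_robust_bayes`).
- **Data cloning**: powered posteriors prior × likelihood^β for
  β ∈ {0, 1, 5, 20, …}; as β grows the posterior collapses onto the
  maximum-likelihood estimate, and the speed of that collapse measures how
  much work the prior is doing (`run_data_cloning`, `grid_mle`).
- **Induced event-count priors**: what a prior on *μ* implies about the
  observable number of dispersal events — e.g. a pathogen sampled in 10
  areas must have dispersed at least 9 times
  (`induced_event_count_prior`).
- **Model adequacy** by posterior-predictive simulation with pluggable
  summary statistics (Fitch parsimony score, tipwise multinomial)
  (`posterior_predictive_pvalue`).
- **Model comparison** by stepping-stone and path-sampling marginal
  likelihoods over a Beta(0.3, 1)-spaced power-posterior ladder, and Bayes
  factors (`run_power_posterior`, `stepping_stone_lnML`, `bayes_factor`).
- **Stochastic mapping** of full dispersal histories (uniformization) and
  posterior counts of dispersal events between each pair of areas
  (`sample_full_mapping`, `posterior_event_counts`).
- **Seeded synthetic fixtures** (coalescent trees + simulated tip areas)
  so every analysis runs with no external data (`make_scenario`).

Prior families for *μ*: the CTMC-rate reference prior
(∝ *μ*<sup>−1/2</sup>e<sup>−*μT*</sup>, *T* = tree length), exponential,
gamma, a hierarchical exponential (Exp(*λ*) with a Gamma hyperprior on
*λ*, sampled by a conjugate Gibbs move), and fixed point masses.

## Worked example

Simulate a 30-tip, 3-area dataset with true *μ* = 0.5, fit it under the
hierarchical exponential prior (relative rates fixed for a 1-D
illustration), and summarize:

```r
library(geopriors)

sc  <- make_scenario(n_tips = 30, k = 3, mu = 0.5, seed = 11)
fit <- geo_fit(sc$tree, sc$tips,
               priors = list(
                 mu = prior_spec("hierarchical_exponential", "mu"),
                 rel_rates = prior_spec("fixed", "rel_rates", value = 1)),
               n_iterations = 20000, thin = 20, seed = 1)
summary(fit)
#> Posterior summary (beta =1; 95% HPD)
#>      parameter      mean variance  hpd_lower hpd_upper    ess
#>    lnPosterior -15.58400 1.294300 -17.951000 -14.40000 889.26
#>   lnLikelihood -13.47200 0.561080 -15.014000 -12.92700 883.35
#>             mu   0.79857 0.273180   0.119150   1.84440 808.73
#>   hyper_lambda   0.28427 0.055918   0.003145   0.75532 860.25
#> MH acceptance rate: 0.79
```

The 95% HPD for *μ*, [0.119, 1.844], covers the simulating value 0.5. How
many dispersal events does that imply? One stochastic mapping per
posterior draw gives the posterior of the event count:

```r
pec <- posterior_event_counts(fit$trace, fit$tree_set, sc$tips,
                              n_draws = 200, seed = 2)
pec$total_summary
#>   mean hpd_lower hpd_upper
#> 1 6.23         3        13
parsimony_statistic(sc$tree, sc$tips)   # the hard lower bound
#> [1] 3
```

And is the fitted model adequate for these data? Posterior-predictive
simulation with the parsimony statistic:

```r
posterior_predictive_pvalue(fit$trace, fit$tree_set, sc$tips,
                            n_draws = 200, seed = 3)
#> Posterior-predictive check
#>   observed statistic : 3
#>   predictive mean    : 4.085  ( 200 draws )
#>   p (upper tail)     : 0.6525
#>   p (two-sided)      : 0.695
```

The observed statistic sits comfortably inside the predictive
distribution: no evidence of misfit. Prior-sensitivity instruments work
the same way — see `run_data_cloning()` and `run_robust_bayes()`, and the
methods vignette (`vignettes/prior-diagnostics.Rmd`) for the full account
of the model, the samplers and the design choices.

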