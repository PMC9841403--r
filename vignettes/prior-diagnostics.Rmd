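---
title: "Prior diagnostics for discrete-geographic phylodynamic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior diagnostics for discrete-geographic phylodynamic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geopriors)
```

## The model

A pathogen lineage moves among $k$ discrete areas as a homogeneous
continuous-time Markov chain evolving along a fixed, rooted, binary,
time-calibrated phylogeny. The chain is specified by a $k \times k$
instantaneous-rate matrix $Q$ whose off-diagonal entry $q_{ij}$ is the
rate of dispersal from area $i$ to area $j$, built from nonnegative
pairwise *relative* rates $r_{ij}$ (one per ordered pair, or one per
unordered pair under a symmetric model) and an *average dispersal rate*
$\mu > 0$. The data are minimal: one categorical observation per tip, the
area in which the sample was collected. An asymmetric model therefore has
$k(k-1)$ relative-rate parameters (20 at $k=5$, 90 at $k=10$, 380 at
$k=20$) informed by a single character — which is exactly why prior
choice matters so much in this model class, and why this package exists.

**Normalization.** Relative rates are rescaled so that
$-\sum_i \pi_i q_{ii} = \mu$ exactly, with $\pi$ the root frequencies
(`build_rate_matrix`). Under this convention $\mu$ is the expected number
of dispersal events per unit tree time, so the induced mean number of
events on a tree of length $T$ is $\mu T$ whenever $\pi$ is stationary
for $Q$ (e.g. uniform frequencies with exchangeable rates). Because the
normalization absorbs the overall scale of the relative rates, their
absolute magnitude is not identifiable — only their ratios are. The
sampler deliberately leaves them unconstrained positive and relies on the
normalization; users reading rate traces should interpret ratios, not
levels.

**Root frequencies** default to uniform $1/k$ and are configurable; the
likelihood conditions on them rather than estimating them.

**Likelihood.** The probability of the observed tip areas is computed by
Felsenstein pruning with per-node rescaling against underflow
(`tree_log_likelihood`). Transition matrices $P(t) = e^{Qt}$ come from a
dense eigendecomposition of the *unit-rate* generator $\hat{Q}$ (where
$Q = \mu \hat{Q}$), so rescaling $\mu$ — the most frequent MCMC move —
reuses the eigenvectors and costs only a diagonal rescale. A
scaling-and-squaring Taylor fallback covers defective or ill-conditioned
generators; row sums of every $P(t)$ are verified to 1e-10 in tests. An
exhaustive-summation oracle (`brute_force_log_likelihood`, refusing more
than 5 internal nodes) provides the independent check that the pruning
pass is exact.

## Priors on the dispersal rate

Four families are supported for $\mu$ (`prior_spec`):

| family | density | default hyperparameters |
|---|---|---|
| `ctmc_reference` | $\propto \mu^{-1/2} e^{-\mu T}$, i.e. Gamma(1/2, rate $T$) | $T$ = tree length |
| `exponential` | Exp(rate) | rate 1 |
| `gamma` | Gamma(shape, rate) | shape 1, rate 1 |
| `hierarchical_exponential` | $\mu \mid \lambda \sim$ Exp($\lambda$), $\lambda \sim$ Gamma(0.5, $0.5\,\bar{T}$) | $\bar{T}$ = mean tree length |

The reference prior's exact functional form is a package convention: the
Gamma(1/2, $T$) shape is the standard reference prior for an overall CTMC
rate on a tree of length $T$ and is what this package means by
"CTMC-rate reference prior" throughout. Likewise the hierarchical
family's hyperprior (shape 0.5, rate $0.5\bar{T}$) is a documented
default chosen to be weakly informative on the scale of events-per-tree;
both are configurable. The hierarchical marginal on $\mu$ is the Lomax
distribution $f(\mu) = a b^a/(b+\mu)^{a+1}$ (shape $a = 0.5$,
scale $b = 0.5\bar{T}$), which has closed-form density, CDF and quantiles
— used by the prior-recovery tests. Relative rates default to iid
Exponential(mean 1).

## The sampler

`geo_fit` / `run_chain` run a Metropolis–Hastings chain targeting
$\text{prior} \times \text{likelihood}^\beta$:

- multiplicative scale moves $x' = x\,e^{\delta(u - 1/2)}$ (Hastings log
  ratio $\log x'/x$) on $\mu$ and on each free relative rate, with
  tuning window $\delta = 2$ by default;
- a conjugate Gibbs draw for the hierarchical hyper-rate,
  $\lambda \mid \mu \sim$ Gamma($a+1$, $b+\mu$);
- an up-down operator rescaling $(\mu, \lambda) \to (m\mu, \lambda/m)$
  (unit Jacobian, symmetric on the log scale), which traverses the
  strongly correlated $(\mu, \lambda)$ ridge that single-parameter moves
  cross only slowly — without it, prior-only chains for the heavy-tailed
  hierarchical marginal decorrelate far too slowly;
- a uniform tree-index jump every `tree_jump_period` iterations (default
  1) when a posterior sample of trees is supplied, accepted with the full
  posterior ratio. The package assumes sequential inference: trees are
  estimated elsewhere and supplied fixed; redrawing the tree every
  iteration is the package's documented choice.

There is no adaptive tuning: chains are exactly reproducible from the
seed, and replicate analyses are simply chains with distinct seeds.
Burnin is never discarded inside the sampler — summaries
(`summarize_trace`, default 10%) do that explicitly. ESS uses the
initial-positive-sequence rule; HPD intervals are the narrowest interval
containing $\lceil p N \rceil$ sorted samples.

$\beta$ has three uses, all through the same target: $\beta = 0$ samples
the joint prior (the prior-recovery diagnostics), integer $\beta > 1$ is
data cloning (powering the log likelihood is *exactly* the likelihood of
$\beta$ literal copies of a single character — kept as a test, not
assumed), and $\beta \in (0,1)$ gives the power-posterior rungs for
marginal likelihoods.

## The diagnostics

**Robust Bayes** (`run_robust_bayes`) re-runs the identical analysis
under a panel of priors. Sensitivity is flagged when the Jaccard overlap
(intersection/union length) of the 95% HPD intervals of $\mu$ across a
prior pair drops below 0.35 — a package convention for a comparison the
source methodology leaves qualitative; the full summary table is always
returned so users can apply their own judgment.

**Data cloning** (`run_data_cloning`) runs cells at
$\beta \in \{0, 1, 5, 20\}$ by default. The reference point is a 1-D grid
MLE of $\mu$ with relative rates fixed (`grid_mle`: log-spaced grid
refined to relative width 1e-4, cross-checked in tests against Brent
optimization). Two regimes are worth distinguishing. Under a *diffuse*
prior the posterior variance is likelihood-dominated and shrinks roughly
as $1/\beta$, so variance decreases monotonically in $\beta$ and
$\beta \cdot \text{Var}$ is roughly constant. Under a prior *more
concentrated than the likelihood* (the reference prior on a typical
50-tip tree, say) the $\beta = 1$ variance is prior-dominated and can be
*smaller* than at $\beta = 5$; what diagnoses the informative prior there
is the posterior mean marching across clone numbers toward the MLE. Both
regimes are exercised in the test suite.

**Induced event-count priors** (`induced_event_count_prior`) translate a
prior on rates into a prior on an observable: each draw samples a model
from the prior, simulates an unconditioned history over the tree, and
counts events. Data occupying $m$ areas require at least $m-1$ events, so
the report includes the induced mass below that floor — a direct check of
whether a prior is biologically absurd before any MCMC is run.

**Model adequacy** (`posterior_predictive_pvalue`) simulates replicate
datasets from posterior draws and compares a summary statistic with its
observed value; $p$ is the upper tail with the midpoint tie rule
($p = (\#\{s > s_{obs}\} + \tfrac12 \#\{s = s_{obs}\})/n$, two-sided
$2\min(p, 1-p)$). Ties matter because the default parsimony statistic is
integer-valued. The two default statistics — the Fitch parsimony score
(tree-aware; counts forced dispersal events) and the tipwise multinomial
log likelihood (tree-free; measures spread of samples over areas) — are
package choices for this model class, and the statistic argument accepts
any `function(tree, tips)`.

**Marginal likelihoods** (`run_power_posterior`,
`stepping_stone_lnML`, `path_sampling_lnML`) use a
$\beta_j = (j/K)^{1/0.3}$ ladder ($K = 32$ stones by default),
stepping-stone with log-sum-exp stabilization, and trapezoidal path
sampling; `bayes_factor` reports $\ln BF$ with the $2\ln BF$ convention
as an attribute. Both estimators are validated against a 10,000-point
quadrature of the 1-D toy marginal.

**Stochastic mapping** (`sample_full_mapping`) draws internal-node areas
from their exact joint conditional (root from the conditional root
distribution, then preorder conditional draws), then fills each branch
with an endpoint-conditioned path by uniformization: dominating rate
$\Lambda = \max_i |q_{ii}|$ (no inflation factor), a Poisson number of
candidate jumps conditioned on the endpoints via the truncated series
$P(N = n \mid a, b) \propto \text{Pois}(n; \Lambda t)\,[R^n]_{ab}$
(truncated where the Poisson tail is below 1e-12), uniform
order-statistic jump times, and removal of virtual self-jumps.
Uniformization was chosen over rejection sampling because it never stalls
on short branches with unequal endpoints. One mapping is drawn per
posterior draw (`posterior_event_counts`), and counts are reported per
ordered pair; the mapping total can never fall below the Fitch score,
which is asserted for every sample in the tests.

## The synthetic fixtures, and what the tests do (and do not) show

`make_scenario` generates a neutral-coalescent tree (via `ape::rcoal`,
waiting-time rate $\binom{j}{2}/N_e$) and simulates tip areas forward
under the true model; defaults are 50 tips, $k = 3$, $\mu = 0.5$ —
sized so a full analysis cycle runs in minutes on one CPU while leaving
genuine uncertainty in the data. `make_tree_posterior_stub` emulates a
posterior tree sample by lognormal branch-length jitter with fixed
topology. The `one_tip_per_area` option builds the minimal-information
design (each of $n$ tips in its own area), whose parsimony score is
$n - 1$ by construction — with 10 areas, 9 dispersal events.

These fixtures deliberately idealize: ultrametric trees, a correctly
specified homogeneous CTMC, no topology uncertainty (jitter moves lengths
only), no serial sampling, no rate variation across branches or time.
Passing tests therefore demonstrate that the estimators are *correct
under the model*, not that the model describes any particular empirical
outbreak; the prior-sensitivity phenomena the package diagnoses are, if
anything, stronger on real data where $k$ is larger and the character is
just as single.

## Numerical choices and problem sizes

- Eigendecomposition is accepted only if it reconstructs $Q$ to 1e-9
  (relative); otherwise scaling-and-squaring is used. $P(t)$ entries are
  clipped into $[0, 1]$.
- The pruning pass rescales a node's partial only when its maximum drops
  below 1e-140, adding the log factor to a running total.
- `grid_mle` declares a likelihood flat (with a warning) when the grid's
  log-likelihood range is below 1e-10 — single-area data on a zero-length
  tree, for instance.
- Degenerate inputs: zero-length branches give $P(0) = I$ exactly, so
  polytomy resolutions (inserted zero-length edges, left-to-right) leave
  the likelihood unchanged — asserted in tests; constant traces get ESS
  $= N$ with a warning and zero-width HPDs.
- Test problem sizes were fixed once at desk scale: prior-recovery chains
  use 100,000 iterations thinned to 5,000 samples; the quadrature
  comparison uses 32 stones with 5,000 retained samples per rung on an
  8-tip, 2-area toy; posterior-predictive calibration uses 50 replicate
  15-tip fits; mapping identities use 20,000 simulations on a 4-tip tree;
  parameter recovery uses 20 replicate 50-tip, 3-area fits. The cloning
  acceptance cell uses the diffuse Exponential(0.2) prior for the reasons
  in the data-cloning section above.

## Known limitations

- No joint tree-and-geography inference, and no BSSVS-style rate
  indicators: the model is the dense (a)symmetric CTMC.
- Relative-rate inference with all $k(k-1)$ rates free mixes slowly on
  single-character data (as it must — the data carry almost no
  information about individual rates); the diagnostics here are designed
  around $\mu$, which is where prior sensitivity bites first.
- Event counting is sampling-based (one stochastic map per draw), not
  expectation-based; dwelling times are not reported.
- The trace reader accepts BEAST-style logs for summarization, but the
  package neither reads nor writes BEAST XML.
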