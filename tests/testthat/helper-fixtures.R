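# Shared fixture builders for the suite; everything generated in code.

# Small 3-tip tree with 2 areas, split tips.
tiny_fixture <- function() {
  tree <- parse_newick("((A:0.4,B:0.6):0.5,C:1.0);")
  tips <- tip_areas(c(A = "east", B = "west", C = "east"))
  list(tree = tree, tips = tips, alphabet = attr(tips, "alphabet"))
}

# Random small instance for oracle comparisons: n tips, k areas, random
# rates and branch lengths. Deterministic under seed.
random_small_instance <- function(n_tips, k, seed) {
  set.seed(seed)
  tree <- ape::rcoal(n_tips)
  tree$edge.length <- stats::runif(length(tree$edge.length), 0.05, 1.5)
  al <- geo_alphabet(paste0("s", seq_len(k)))
  rr <- stats::runif(k * (k - 1), 0.2, 2)
  fr <- stats::runif(k, 0.5, 2); fr <- fr / sum(fr)
  model <- dispersal_model(al, mu = stats::runif(1, 0.2, 2),
                           rel_rates = rr, root_freqs = fr)
  states <- sample(al$areas, n_tips, replace = TRUE)
  tips <- tip_areas(stats::setNames(states, tree$tip.label), alphabet = al)
  list(tree = tree, tips = tips, model = model)
}

# 1-D inference setup: relative rates fixed so mu is the only free
# parameter; used by cloning / marginal-likelihood checks.
fixed_rate_priors <- function(mu_prior = prior_spec("exponential", "mu",
                                                    rate = 1)) {
  list(mu = mu_prior, rel_rates = prior_spec("fixed", "rel_rates", value = 1))
}

# Grid/quadrature log marginal likelihood for the 1-D toy:
# integral of exp(loglik(mu)) * prior(mu) d mu on a fine grid.
quadrature_lnML <- function(tree, tips, mu_prior, mu_max = 40,
                            n_grid = 10000L) {
  al <- attr(tips, "alphabet")
  model1 <- dispersal_model(al, mu = 1)
  ctx <- lik_context(tree, tips, model1)
  qe <- geopriors:::.q_eigen(build_rate_matrix(model1))
  mus <- seq(1e-7, mu_max, length.out = n_grid)
  ll <- vapply(mus, function(m) geopriors:::.prune_loglik(ctx, qe, m),
               numeric(1))
  lp <- log_prior_density(mu_prior, mus, tree_length = tree_length(tree))
  h <- mus[2] - mus[1]
  m <- max(ll + lp)
  log(sum(exp(ll + lp - m)) * h) + m
}
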