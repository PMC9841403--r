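test_that("robust-Bayes sweep: identical priors give overlapping posteriors", {
  sc <- make_scenario(n_tips = 20, k = 2, mu = 0.5, seed = 4)
  cfg <- mcmc_config(n_iterations = 3000, thin = 5, seed = 10)
  pri <- fixed_rate_priors()
  rb <- run_robust_bayes(list(a = pri, b = pri), sc$tree, sc$tips, cfg)
  expect_gt(rb$min_overlap, 0.5)
  expect_false(rb$prior_sensitive)
  expect_error(run_robust_bayes(list(a = pri), sc$tree, sc$tips, cfg),
               "at least 2")
})

test_that("no-data sweep reproduces each prior's analytic mean", {
  fx <- tiny_fixture()
  T <- tree_length(fx$tree)
  cfg <- mcmc_config(n_iterations = 20000, thin = 4, seed = 2, beta = 0)
  configs <- list(
    exp2 = fixed_rate_priors(prior_spec("exponential", "mu", rate = 2)),
    gam = fixed_rate_priors(prior_spec("gamma", "mu", shape = 2, rate = 4)),
    ctmc = fixed_rate_priors(prior_spec("ctmc_reference", "mu")))
  rb <- run_robust_bayes(configs, fx$tree, fx$tips, cfg)
  for (nm in names(configs)) {
    row <- rb$summary[rb$summary$prior == nm, ]
    truth <- prior_mean(configs[[nm]]$mu, tree_length = T)
    mc_se <- sqrt(row$variance / row$ess)
    expect_lt(abs(row$mean - truth), 3 * mc_se)
  }
})

test_that("grid MLE agrees with an independent optimizer and flags flatness", {
  sc <- make_scenario(n_tips = 30, k = 2, mu = 0.5, seed = 6)
  g <- grid_mle(sc$tree, sc$tips)
  expect_false(g$flat)
  # independent route: golden-section/Brent optimizer on the same surface
  al <- attr(sc$tips, "alphabet")
  m1 <- dispersal_model(al, mu = 1)
  ctx <- lik_context(sc$tree, sc$tips, m1)
  qe <- geopriors:::.q_eigen(build_rate_matrix(m1))
  opt <- stats::optimize(function(m) geopriors:::.prune_loglik(ctx, qe, m),
                         c(1e-4, 50), maximum = TRUE)
  expect_lt(abs(g$mu_hat - opt$maximum) / opt$maximum, 1e-3)

  # single-tip-information degenerate data: all tips one area -> flat-ish
  # likelihood rises toward mu = 0; monomorphic data cannot bound mu above
  tree1 <- parse_newick("(A:1,B:1);")
  tp_same <- tip_areas(c(A = "x", B = "x"), geo_alphabet(c("x", "y")))
  g2 <- grid_mle(tree1, tp_same, mu_range = c(1e-4, 1))
  expect_true(g2$mu_hat <= 2e-4)  # boundary: no dispersal signal
})

test_that("grid MLE warns when the likelihood carries no information", {
  # a zero-length tree: the likelihood is constant in mu
  tree0 <- parse_newick("(A:0,B:0);")
  tp <- tip_areas(c(A = "x", B = "x"), geo_alphabet(c("x", "y")))
  expect_warning(g <- grid_mle(tree0, tp), "flat")
  expect_true(g$flat)
})

test_that("data cloning converges toward the grid MLE as beta grows", {
  sc <- make_scenario(n_tips = 30, k = 2, mu = 0.5, seed = 12)
  mle <- grid_mle(sc$tree, sc$tips)$mu_hat
  pri <- fixed_rate_priors(prior_spec("exponential", "mu", rate = 0.2))
  cfg <- mcmc_config(n_iterations = 4000, thin = 5, seed = 1)
  dc <- run_data_cloning(c(1, 5, 20), pri, sc$tree, sc$tips, cfg)
  s <- dc$summary
  m1 <- s$mean[s$beta == 1]; m20 <- s$mean[s$beta == 20]
  expect_lt(abs(m20 - mle), abs(m1 - mle))
  expect_lt(s$variance[s$beta == 5], s$variance[s$beta == 1])
  expect_lt(s$variance[s$beta == 20], s$variance[s$beta == 5])
  expect_error(run_data_cloning(c(0, 5), pri, sc$tree, sc$tips, cfg),
               "include 1")
  expect_error(run_data_cloning(c(5, 1), pri, sc$tree, sc$tips, cfg),
               "sorted")
})

test_that("powered chain equals a chain on literal data copies", {
  sc <- make_scenario(n_tips = 15, k = 2, mu = 0.5, seed = 14)
  pri <- fixed_rate_priors()
  cfg3 <- mcmc_config(n_iterations = 6000, thin = 5, seed = 4, beta = 3)
  tr_pow <- run_chain(pri, sc$tree, sc$tips, cfg3)
  # literal three copies of the character, beta = 1
  tips3 <- list(sc$tips, sc$tips, sc$tips)
  al <- attr(sc$tips, "alphabet")
  ctx1 <- lik_context(sc$tree, sc$tips, dispersal_model(al, mu = 1))
  ctx3 <- lik_context(sc$tree, tips3, dispersal_model(al, mu = 1))
  qe <- geopriors:::.q_eigen(build_rate_matrix(dispersal_model(al, mu = 1)))
  # same target: 3 * l(mu) == l_3copies(mu) for all mu
  for (m in c(0.1, 0.5, 2))
    expect_equal(3 * geopriors:::.prune_loglik(ctx1, qe, m),
                 geopriors:::.prune_loglik(ctx3, qe, m), tolerance = 1e-10)
  # and the powered posterior mean matches an independent grid posterior
  grid <- seq(1e-4, 8, length.out = 3000)
  w <- vapply(grid, function(m)
    exp(3 * geopriors:::.prune_loglik(ctx1, qe, m)), numeric(1)) *
    exp(log_prior_density(pri$mu, grid))
  mu_grid <- sum(grid * w) / sum(w)
  mu_chain <- mean(tr_pow$mu[-seq_len(200)])
  ess <- suppressWarnings(effective_sample_size(tr_pow$mu[-seq_len(200)]))
  mc_se <- sd(tr_pow$mu[-seq_len(200)]) / sqrt(ess)
  expect_lt(abs(mu_chain - mu_grid), 4 * mc_se)
})

test_that("beta * variance stays roughly constant at large beta", {
  sc <- make_scenario(n_tips = 30, k = 2, mu = 0.5, seed = 12)
  pri <- fixed_rate_priors()
  cfg <- mcmc_config(n_iterations = 5000, thin = 5, seed = 7)
  dc <- run_data_cloning(c(1, 5, 20), pri, sc$tree, sc$tips, cfg)
  s <- dc$summary
  bv5 <- s$beta_x_variance[s$beta == 5]
  bv20 <- s$beta_x_variance[s$beta == 20]
  expect_lt(abs(bv20 - bv5) / bv5, 0.5)
})

test_that("induced event-count prior has mean mu*T and reports the floor", {
  # fixed mu, symmetric rates, uniform (stationary) root frequencies:
  # events arrive at rate mu per unit tree time
  tree <- simulate_coalescent_tree(8, seed = 44)
  al <- geo_alphabet(c("a", "b", "c"))
  pri <- list(mu = prior_spec("fixed", "mu", value = 1.5),
              rel_rates = prior_spec("fixed", "rel_rates", value = 1))
  out <- induced_event_count_prior(pri, tree, al, n_sims = 20000, seed = 2,
                                   symmetric = TRUE, m_areas = 3)
  expected <- 1.5 * tree_length(tree)
  se <- sd(out$counts) / sqrt(length(out$counts))
  expect_lt(abs(out$mean - expected), 3 * se)
  expect_equal(out$floor, 2L)
  expect_true(out$frac_below_floor >= 0 && out$frac_below_floor <= 1)

  # tiny mu concentrates all mass at zero events
  pri0 <- list(mu = prior_spec("fixed", "mu", value = 1e-8),
               rel_rates = prior_spec("fixed", "rel_rates", value = 1))
  out0 <- induced_event_count_prior(pri0, tree, al, n_sims = 200, seed = 3,
                                    symmetric = TRUE)
  expect_true(all(out0$counts == 0))
})
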