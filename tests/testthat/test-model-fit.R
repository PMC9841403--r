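test_that("tip-data simulation is seeded and matches CTMC marginals", {
  tree <- parse_newick("(A:0.8,B:1.3);")
  al <- geo_alphabet(c("x", "y"))
  m <- dispersal_model(al, mu = 0.9, root_freqs = c(0.35, 0.65))
  # determinism
  expect_identical(unclass(simulate_tip_data(tree, m, seed = 5)),
                   unclass(simulate_tip_data(tree, m, seed = 5)))
  # tiny mu: all tips share the root area
  m0 <- dispersal_model(al, mu = 1e-9)
  mono <- replicate(20, length(unique(unclass(
    simulate_tip_data(tree, m0)))))
  expect_true(all(mono == 1))
  # marginal tip frequencies match pi %*% P(t_tip)
  q <- build_rate_matrix(m)
  pA <- as.numeric(m$root_freqs %*% transition_probabilities(q, 0.8))
  set.seed(6)
  simA <- replicate(20000, unclass(simulate_tip_data(tree, m))[["A"]])
  fA <- mean(simA == "x")
  se <- sqrt(pA[1] * (1 - pA[1]) / 20000)
  expect_lt(abs(fA - pA[1]), 3 * se)
})

test_that("Fitch parsimony counts forced changes", {
  al <- geo_alphabet(c("p", "q"))
  tree <- parse_newick("((A:1,B:1):1,C:1);")
  expect_equal(parsimony_statistic(
    tree, tip_areas(c(A = "p", B = "p", C = "p"), al)), 0L)
  expect_equal(parsimony_statistic(
    tree, tip_areas(c(A = "p", B = "q", C = "p"), al)), 1L)
  # 10 tips in 10 distinct areas on any binary tree -> 9
  for (s in 1:5) {
    sc <- make_scenario(n_tips = 10, k = 10, seed = s,
                        one_tip_per_area = TRUE)
    expect_equal(parsimony_statistic(sc$tree, sc$tips), 9L)
  }
  # cross-check against an independent implementation on random instances
  skip_if_not_installed("phangorn")
  for (s in 1:20) {
    inst <- random_small_instance(sample(4:12, 1), sample(2:4, 1),
                                  seed = 500 + s)
    states <- as.character(unclass(inst$tips))
    pd <- phangorn::phyDat(matrix(states, ncol = 1,
                                  dimnames = list(names(inst$tips), NULL)),
                           type = "USER", levels = inst$model$alphabet$areas)
    expect_equal(parsimony_statistic(inst$tree, inst$tips),
                 as.integer(phangorn::parsimony(inst$tree, pd)))
  }
})

test_that("tipwise multinomial statistic has its closed form", {
  al <- geo_alphabet(c("u", "v"))
  expect_equal(tipwise_multinomial_statistic(
    tip_areas(c(a = "u", b = "u", c = "u"), al)), 0)
  x <- tip_areas(c(a = "u", b = "u", c = "u", d = "v"), al)
  expect_equal(tipwise_multinomial_statistic(x),
               3 * log(0.75) + 1 * log(0.25), tolerance = 1e-12)
  # permutation invariance in area labels
  y <- tip_areas(c(a = "v", b = "v", c = "v", d = "u"), al)
  expect_equal(tipwise_multinomial_statistic(x),
               tipwise_multinomial_statistic(y))
})

test_that("posterior-predictive p-values follow the midpoint tie rule", {
  sc <- make_scenario(n_tips = 12, k = 2, mu = 0.5, seed = 21)
  fit <- geo_fit(sc$tree, sc$tips, priors = fixed_rate_priors(),
                 n_iterations = 1500, thin = 5, seed = 2)
  # constant statistic -> two-sided p = 1
  const_stat <- function(tree, tips) 1
  p <- posterior_predictive_pvalue(fit$trace, fit$tree_set, sc$tips,
                                   statistic = const_stat, n_draws = 50,
                                   seed = 3)
  expect_equal(p$p_upper, 0.5)
  expect_equal(p$p_two_sided, 1)
  expect_error(posterior_predictive_pvalue(fit$trace, fit$tree_set,
                                           sc$tips, n_draws = 1e6),
               "exceeds")
  # real statistic returns sane structure
  pp <- posterior_predictive_pvalue(fit$trace, fit$tree_set, sc$tips,
                                    n_draws = 60, seed = 4)
  expect_length(pp$simulated, 60)
  expect_true(pp$p_two_sided >= 0 && pp$p_two_sided <= 1)
})

test_that("an adequate model is not flagged while a pathological prior is", {
  sc <- make_scenario(n_tips = 25, k = 3, mu = 0.5, seed = 30)
  # adequate: fit under a sensible prior; observed statistic inside the
  # central predictive interval
  fit <- geo_fit(sc$tree, sc$tips, priors = fixed_rate_priors(),
                 n_iterations = 2500, thin = 5, seed = 3)
  pp <- posterior_predictive_pvalue(fit$trace, fit$tree_set, sc$tips,
                                    n_draws = 150, seed = 5)
  q <- stats::quantile(pp$simulated, c(0.025, 0.975))
  expect_true(pp$observed >= q[1] && pp$observed <= q[2])
  # inadequate: a prior concentrated far above the truth forces far too
  # many dispersal events in the predictive datasets
  bad <- fixed_rate_priors(prior_spec("fixed", "mu", value = 100))
  fit_bad <- geo_fit(sc$tree, sc$tips, priors = bad,
                     n_iterations = 1500, thin = 5, seed = 4)
  pp_bad <- posterior_predictive_pvalue(fit_bad$trace, fit_bad$tree_set,
                                        sc$tips, n_draws = 150, seed = 6)
  qb <- stats::quantile(pp_bad$simulated, c(0.025, 0.975))
  expect_false(pp_bad$observed >= qb[1] && pp_bad$observed <= qb[2])
})

test_that("beta schedules are Beta(alpha,1) quantiles", {
  b <- beta_schedule(4, alpha = 0.3)
  expect_equal(b[1], 0)
  expect_equal(b[5], 1)
  expect_equal(b[3], 0.5^(1 / 0.3), tolerance = 1e-12)
  for (K in c(2, 8, 32))
    expect_true(!is.unsorted(beta_schedule(K), strictly = TRUE))
  expect_error(beta_schedule(1), ">= 2")
})

test_that("marginal-likelihood estimators handle degenerate ladders exactly", {
  # constant likelihood c across rungs: both estimators return c
  ladder <- structure(list(betas = beta_schedule(8),
                           loglik = rep(list(rep(-12.5, 200)), 9)),
                      class = "pp_ladder")
  expect_equal(stepping_stone_lnML(ladder), -12.5, tolerance = 1e-12)
  expect_equal(path_sampling_lnML(ladder), -12.5, tolerance = 1e-12)
  # translation identity
  ladder2 <- ladder
  ladder2$loglik <- lapply(ladder$loglik, function(x) x + 7)
  expect_equal(stepping_stone_lnML(ladder2),
               stepping_stone_lnML(ladder) + 7, tolerance = 1e-12)
  bad <- ladder
  bad$loglik <- bad$loglik[-3]
  expect_error(stepping_stone_lnML(bad), "missing")
  expect_error(path_sampling_lnML(bad), "missing")
})

test_that("stepping-stone and path sampling recover a quadrature truth", {
  # 1-D toy: rates fixed, exponential prior on mu, small 2-area dataset
  sc <- make_scenario(n_tips = 8, k = 2, mu = 0.8, seed = 41)
  mu_prior <- prior_spec("exponential", "mu", rate = 1)
  truth <- quadrature_lnML(sc$tree, sc$tips, mu_prior)
  ladder <- run_power_posterior(fixed_rate_priors(mu_prior), sc$tree,
                                sc$tips, betas = beta_schedule(16),
                                n_iterations = 2500, thin = 1, seed = 11)
  ss <- stepping_stone_lnML(ladder)
  ps <- path_sampling_lnML(ladder)
  expect_lt(abs(ss - truth), 0.15)
  expect_lt(abs(ps - ss), 0.2)
})

test_that("Bayes factors are antisymmetric differences of lnML", {
  expect_equal(as.numeric(bayes_factor(-10, -10)), 0)
  b12 <- bayes_factor(-8.2, -11.7)
  b21 <- bayes_factor(-11.7, -8.2)
  expect_equal(as.numeric(b12), -as.numeric(b21))
  expect_equal(attr(b12, "twice_ln_bf"), 2 * as.numeric(b12))
  expect_error(bayes_factor(-Inf, 0), "finite")
})
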