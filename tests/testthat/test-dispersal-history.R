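test_that("node-state sampling matches the exact conditional distribution", {
  # zero-length tree, all tips one area: every node gets that area
  tree0 <- parse_newick("((A:0,B:0):0,C:0);")
  al <- geo_alphabet(c("x", "y"))
  tp0 <- tip_areas(c(A = "x", B = "x", C = "x"), al)
  ctx0 <- lik_context(tree0, tp0, dispersal_model(al, mu = 1))
  st <- sample_node_states(ctx0, seed = 1)
  expect_true(all(st == 1L))

  # determinism under seed
  fx <- tiny_fixture()
  ctx <- lik_context(fx$tree, fx$tips,
                     dispersal_model(fx$alphabet, mu = 0.7))
  expect_identical(sample_node_states(ctx, seed = 9),
                   sample_node_states(ctx, seed = 9))

  # empirical root-state frequencies vs brute-force conditional
  # distribution: P(root = s | tips) computed by explicit enumeration
  m <- dispersal_model(fx$alphabet, mu = 0.9, rel_rates = c(1.3, 0.7),
                       root_freqs = c(0.45, 0.55))
  ctx <- lik_context(fx$tree, fx$tips, m)
  tree <- ctx$tree
  k <- 2
  Pl <- lapply(seq_len(nrow(tree$edge)), function(e)
    transition_probabilities(build_rate_matrix(m), tree$edge.length[e]))
  root <- ctx$ntip + 1L
  internal <- root:(ctx$ntip + ctx$nnode)
  grid <- as.matrix(expand.grid(rep(list(1:k), length(internal))))
  joint <- numeric(k)
  for (g in seq_len(nrow(grid))) {
    assign <- grid[g, ]
    state_of <- function(node) {
      if (node <= ctx$ntip) ctx$tip_states[node, 1]
      else assign[match(node, internal)]
    }
    p <- m$root_freqs[assign[1]]
    for (e in seq_len(nrow(tree$edge)))
      p <- p * Pl[[e]][state_of(tree$edge[e, 1]), state_of(tree$edge[e, 2])]
    joint[assign[1]] <- joint[assign[1]] + p
  }
  cond <- joint / sum(joint)
  set.seed(17)
  draws <- replicate(20000, sample_node_states(ctx)[root])
  f1 <- mean(draws == 1)
  se <- sqrt(cond[1] * (1 - cond[1]) / 20000)
  expect_lt(abs(f1 - cond[1]), 3 * se)
})

test_that("endpoint-conditioned paths obey their endpoints", {
  al <- geo_alphabet(c("x", "y"))
  q <- build_rate_matrix(dispersal_model(al, mu = 1, symmetric = TRUE))
  # zero-length same-endpoint branch: no events
  expect_equal(nrow(endpoint_conditioned_history(q, 0, 1, 1)), 0L)
  expect_error(endpoint_conditioned_history(q, 0, 1, 2), "impossible")
  # a != b: at least one event, path chains from a to b
  set.seed(23)
  for (i in 1:200) {
    ev <- endpoint_conditioned_history(q, 0.8, 1, 2)
    expect_gte(nrow(ev), 1L)
    expect_equal(unname(ev[1, "from"]), 1)
    expect_equal(unname(ev[nrow(ev), "to"]), 2)
    if (nrow(ev) > 1) {
      expect_true(all(diff(ev[, "time"]) > 0))
      expect_true(all(ev[-1, "from"] == ev[-nrow(ev), "to"]))
    }
    expect_true(all(ev[, "time"] > 0 & ev[, "time"] < 0.8))
  }
  # short same-endpoint branch: empty path with probability -> 1
  n_ev <- replicate(500, nrow(endpoint_conditioned_history(q, 1e-4, 1, 1)))
  expect_gt(mean(n_ev == 0), 0.99)
})

test_that("conditioned event counts match a truncated-series oracle", {
  # 2-state symmetric unit-rate chain, t = 1, endpoints unequal. The
  # oracle computes E[N | a != b] from the uniformization series
  # P(N = n, end = b) = dpois(n, t) R^n[a, b] truncated far in the tail,
  # independently of the sampler.
  al <- geo_alphabet(c("x", "y"))
  q <- build_rate_matrix(dispersal_model(al, mu = 1, symmetric = TRUE))
  t <- 1
  R <- diag(2) + q / max(-diag(q))
  Rn <- diag(2)
  num <- 0; den <- 0
  for (n in 0:60) {
    term <- stats::dpois(n, max(-diag(q)) * t) * Rn[1, 2]
    num <- num + n * term
    den <- den + term
    Rn <- Rn %*% R
  }
  oracle_mean <- num / den
  set.seed(29)
  counts <- replicate(50000, nrow(endpoint_conditioned_history(q, t, 1, 2)))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - oracle_mean), 3 * se)
})

test_that("full mappings respect the data and the parsimony floor", {
  sc <- make_scenario(n_tips = 12, k = 3, mu = 0.8, seed = 51)
  ctx <- lik_context(sc$tree, sc$tips, sc$model)
  pars <- parsimony_statistic(sc$tree, sc$tips)
  al <- sc$model$alphabet
  for (s in 1:30) {
    h <- sample_full_mapping(ctx, seed = s)
    cm <- count_events_by_pair(h)
    expect_gte(attr(cm, "total"), pars)
    # tips keep their observed areas
    obs <- geopriors:::.bind_tips(h$tree, sc$tips)
    expect_identical(h$node_state[seq_along(obs)], obs)
    # per-branch endpoint consistency
    for (e in seq_len(nrow(h$tree$edge))) {
      ev <- h$events[[e]]
      a <- h$node_state[h$tree$edge[e, 1]]
      b <- h$node_state[h$tree$edge[e, 2]]
      if (nrow(ev) == 0) expect_equal(a, b)
      else {
        expect_equal(unname(ev[1, "from"]), a)
        expect_equal(unname(ev[nrow(ev), "to"]), b)
      }
    }
  }
})

test_that("event counting by pair matches hand-built histories", {
  hist <- list(events = list(
    cbind(time = c(0.1, 0.5), from = c(1, 2), to = c(2, 1)),
    cbind(time = 0.2, from = 1, to = 2)), k = 2)
  cm <- count_events_by_pair(hist, k = 2)
  expect_equal(unclass(cm)[1, 2], 2L)
  expect_equal(unclass(cm)[2, 1], 1L)
  expect_equal(attr(cm, "total"), 3L)
  expect_true(all(diag(unclass(cm)) == 0L))
  # empty history -> zero matrix
  cm0 <- count_events_by_pair(list(events = list(), k = 3), k = 3)
  expect_equal(attr(cm0, "total"), 0L)
})

test_that("unconditional mapping means recover mu * T", {
  # resample tips forward, then map conditional on them; averaging over
  # both reproduces the unconditional event rate
  tree <- simulate_coalescent_tree(5, seed = 61)
  al <- geo_alphabet(c("x", "y"))
  model <- dispersal_model(al, mu = 1.2, symmetric = TRUE)
  T <- tree_length(tree)
  set.seed(62)
  n_sim <- 4000
  totals <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    tp <- simulate_tip_data(tree, model)
    ctx <- lik_context(tree, tp, model)
    totals[i] <- attr(count_events_by_pair(sample_full_mapping(ctx)),
                      "total")
  }
  se <- sd(totals) / sqrt(n_sim)
  expect_lt(abs(mean(totals) - 1.2 * T), 3 * se)
})

test_that("posterior event counts summarize per pair and total", {
  sc <- make_scenario(n_tips = 12, k = 2, mu = 0.6, seed = 71)
  fit <- geo_fit(sc$tree, sc$tips, priors = fixed_rate_priors(),
                 n_iterations = 1500, thin = 5, seed = 2)
  pec <- posterior_event_counts(fit$trace, fit$tree_set, sc$tips,
                                n_draws = 80, seed = 3)
  pars <- parsimony_statistic(sc$tree, sc$tips)
  expect_true(all(pec$totals >= pars))
  expect_gte(pec$total_summary$mean, pars)
  expect_equal(nrow(pec$pair_summary), 2L)
  expect_equal(sum(pec$mean_matrix), pec$total_summary$mean,
               tolerance = 1e-10)

  # no dispersal signal + low-mu prior: posterior mean near zero
  al <- geo_alphabet(c("x", "y"))
  tp_same <- tip_areas(stats::setNames(rep("x", 12), sc$tree$tip.label), al)
  fit0 <- geo_fit(sc$tree, tp_same,
                  priors = fixed_rate_priors(
                    prior_spec("exponential", "mu", rate = 50)),
                  n_iterations = 1500, thin = 5, seed = 3)
  pec0 <- posterior_event_counts(fit0$trace, fit0$tree_set, tp_same,
                                 n_draws = 80, seed = 4)
  expect_lt(pec0$total_summary$mean, 1)
})
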