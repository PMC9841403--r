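## Absolute fit (posterior-predictive simulation) and relative fit
## (power-posterior marginal likelihoods, Bayes factors).

# Forward-simulate the dispersal CTMC down the tree (Gillespie per branch).
# Returns integer tip states, the per-branch event lists and node states.
.forward_simulate <- function(tree, model) {
  q <- build_rate_matrix(model)
  k <- nrow(q)
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  # preorder: reverse postorder edge order visits parents before children
  edge_order <- rev(seq_len(nrow(po$edge)))
  node_state <- integer(ntip + po$Nnode)
  root <- ntip + 1L
  node_state[root] <- sample.int(k, 1L, prob = model$root_freqs)
  events <- vector("list", nrow(po$edge))
  leave_rate <- -diag(q)
  for (e in edge_order) {
    a <- po$edge[e, 1]; b <- po$edge[e, 2]
    s <- node_state[a]
    t_rem <- po$edge.length[e]
    tpos <- 0
    ev <- list()
    while (TRUE) {
      if (leave_rate[s] <= 0) break
      w <- stats::rexp(1, rate = leave_rate[s])
      if (w >= t_rem) break
      tpos <- tpos + w
      t_rem <- t_rem - w
      probs <- q[s, ]; probs[s] <- 0
      s_new <- sample.int(k, 1L, prob = probs)
      ev[[length(ev) + 1L]] <- c(time = tpos, from = s, to = s_new)
      s <- s_new
    }
    events[[e]] <- ev
    node_state[b] <- s
  }
  list(tree = po, node_state = node_state, events = events, k = k,
       ntip = ntip)
}

#' Simulate tip areas under a dispersal model
#'
#' Draws the root area from the model's root frequencies and evolves the
#' CTMC along every branch by explicit event simulation; the areas reached
#' at the tips form the simulated dataset.
#'
#' @param tree a \code{phylo} time tree.
#' @param model a \code{dispersal_model}.
#' @param seed optional integer; if given the simulation is reproducible.
#' @return a \code{tip_areas} object over the model's alphabet.
#' @export
simulate_tip_data <- function(tree, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sim <- .forward_simulate(tree, model)
  areas <- model$alphabet$areas[sim$node_state[seq_len(sim$ntip)]]
  tip_areas(stats::setNames(areas, sim$tree$tip.label),
            alphabet = model$alphabet)
}

#' Fitch small-parsimony score of the geographic character
#'
#' Minimum number of area changes on the tree consistent with the observed
#' tip areas: a postorder intersection/union pass followed by counting the
#' forced changes (each empty intersection adds one).
#'
#' @param tree a \code{phylo} (resolved to binary internally if needed).
#' @param tips a \code{tip_areas}.
#' @return integer parsimony score.
#' @export
parsimony_statistic <- function(tree, tips) {
  tree <- .validate_timetree(tree)
  if (!inherits(tips, "tip_areas")) tips <- tip_areas(tips)
  al <- attr(tips, "alphabet")
  st <- .bind_tips(tree, tips)
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(po$tip.label)
  sets <- vector("list", ntip + po$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- st[i]
  score <- 0L
  e <- 1L
  edges <- po$edge
  n_edge <- nrow(edges)
  while (e <= n_edge) {
    p <- edges[e, 1]
    # children of p are consecutive in postorder edge order
    kids <- integer(0)
    while (e <= n_edge && edges[e, 1] == p) {
      kids <- c(kids, edges[e, 2]); e <- e + 1L
    }
    s <- sets[[kids[1]]]
    for (ch in kids[-1]) {
      inter <- intersect(s, sets[[ch]])
      if (length(inter)) s <- inter
      else { s <- union(s, sets[[ch]]); score <- score + 1L }
    }
    sets[[p]] <- s
  }
  score
}

#' Tipwise multinomial summary statistic
#'
#' The multinomial log likelihood of the tip-area counts at their maximum:
#' \eqn{\sum_a n_a \log(n_a / n)} over areas with \eqn{n_a > 0}. A purely
#' tip-frequency statistic (tree-free), sensitive to how evenly samples are
#' spread over areas.
#'
#' @param tips a \code{tip_areas}.
#' @return numeric (<= 0; 0 when all tips share one area).
#' @export
tipwise_multinomial_statistic <- function(tips) {
  if (!inherits(tips, "tip_areas")) tips <- tip_areas(tips)
  n <- length(tips)
  cnt <- table(as.character(unclass(tips)))
  sum(cnt * log(cnt / n))
}

#' Posterior-predictive p-value for a summary statistic
#'
#' For each of \code{n_draws} rows sampled from the posterior trace, rebuild
#' the model (and pick the recorded tree), simulate a replicate dataset, and
#' compute the statistic. The upper-tail p-value uses the midpoint tie rule
#' \eqn{p = (\#(sim > obs) + 0.5\,\#(sim = obs)) / n}; the two-sided value
#' \eqn{2 \min(p, 1-p)} is reported alongside.
#'
#' @param trace a trace data frame from \code{\link{run_chain}} /
#'   \code{\link{geo_fit}}.
#' @param tree_set the \code{tree_set} the trace was run on.
#' @param tips observed \code{tip_areas}.
#' @param statistic function \code{(tree, tips) -> numeric}; the defaults
#'   are \code{\link{parsimony_statistic}} and (ignoring its tree argument)
#'   \code{\link{tipwise_multinomial_statistic}}.
#' @param n_draws posterior draws to use (<= rows of trace).
#' @param seed integer seed.
#' @param symmetric,root_freqs model settings matching the fit.
#' @return list of class \code{"pps_result"}: \code{observed},
#'   \code{simulated}, \code{p_upper}, \code{p_two_sided}.
#' @export
posterior_predictive_pvalue <- function(trace, tree_set, tips,
                                        statistic = parsimony_statistic,
                                        n_draws = 100L, seed = 1L,
                                        symmetric = FALSE,
                                        root_freqs = NULL) {
  if (n_draws > nrow(trace))
    stop("n_draws (", n_draws, ") exceeds trace length (", nrow(trace), ")")
  if (inherits(tree_set, "phylo")) tree_set <- tree_set(tree_set)
  set.seed(seed)
  al <- attr(tips, "alphabet")
  rows <- sample.int(nrow(trace), n_draws)
  obs <- statistic(tree_set[[1]], tips)
  sim <- vapply(rows, function(i) {
    model <- .model_from_trace_row(trace, i, al, symmetric, root_freqs)
    ti <- if ("tree_index" %in% names(trace)) as.integer(trace$tree_index[i])
          else 1L
    rep_tips <- simulate_tip_data(tree_set[[ti]], model)
    statistic(tree_set[[ti]], rep_tips)
  }, numeric(1))
  p_up <- (sum(sim > obs) + 0.5 * sum(sim == obs)) / n_draws
  structure(list(observed = obs, simulated = sim, p_upper = p_up,
                 p_two_sided = 2 * min(p_up, 1 - p_up)),
            class = "pps_result")
}

#' @export
print.pps_result <- function(x, ...) {
  cat("Posterior-predictive check\n")
  cat("  observed statistic :", format(x$observed, digits = 5), "\n")
  cat("  predictive mean    :", format(mean(x$simulated), digits = 5),
      " (", length(x$simulated), "draws )\n")
  cat("  p (upper tail)     :", format(x$p_upper, digits = 4), "\n")
  cat("  p (two-sided)      :", format(x$p_two_sided, digits = 4), "\n")
  invisible(x)
}

#' Power-posterior beta schedule
#'
#' Quantiles of a Beta(alpha, 1) distribution:
#' \eqn{\beta_j = (j/K)^{1/\alpha}} for \eqn{j = 0, \dots, K}. The default
#' \code{alpha = 0.3} concentrates rungs near \eqn{\beta = 0}, where the
#' integrand of the marginal-likelihood identity changes fastest.
#'
#' @param K number of stones (>= 2); the schedule has K + 1 values.
#' @param alpha spacing parameter (> 0).
#' @return strictly increasing numeric vector from 0 to 1.
#' @export
beta_schedule <- function(K, alpha = 0.3) {
  if (K < 2) stop("K must be >= 2")
  (0:K / K)^(1 / alpha)
}

#' Run a ladder of power-posterior chains
#'
#' One chain per beta in \code{betas}, all sharing data, priors and chain
#' controls; per-rung log-likelihood samples feed
#' \code{\link{stepping_stone_lnML}} and \code{\link{path_sampling_lnML}}.
#'
#' @param priors,tree_set,tips,symmetric,root_freqs as
#'   \code{\link{run_chain}}.
#' @param betas increasing beta values ending at 1 (first may be 0).
#' @param n_iterations,thin,seed chain controls; rung j uses seed
#'   \code{seed + j}.
#' @param burnin_fraction per-rung burnin discarded before storing.
#' @return object of class \code{"pp_ladder"}: list with \code{betas} and
#'   \code{loglik} (list of per-rung log-likelihood sample vectors).
#' @export
run_power_posterior <- function(priors, tree_set, tips, betas,
                                n_iterations = 2000L, thin = 1L, seed = 1L,
                                burnin_fraction = 0.1, symmetric = FALSE,
                                root_freqs = NULL) {
  if (is.unsorted(betas, strictly = TRUE))
    stop("betas must be strictly increasing")
  if (utils::tail(betas, 1) != 1) stop("last beta must be 1")
  ll <- vector("list", length(betas))
  for (j in seq_along(betas)) {
    tr <- run_chain(priors, tree_set, tips,
                    mcmc_config(n_iterations = n_iterations, thin = thin,
                                seed = seed + j, beta = betas[j]),
                    symmetric = symmetric, root_freqs = root_freqs)
    drop <- floor(burnin_fraction * nrow(tr))
    v <- tr$lnLikelihood
    if (drop > 0) v <- v[-seq_len(drop)]
    ll[[j]] <- v
  }
  structure(list(betas = betas, loglik = ll), class = "pp_ladder")
}

#' Stepping-stone marginal-likelihood estimator
#'
#' \deqn{\ln \hat{Z} = \sum_j \ln \frac{1}{n}\sum_i
#'   e^{(\beta_{j+1}-\beta_j)(\ell_i - \ell^{max})}
#'   + (\beta_{j+1}-\beta_j)\,\ell^{max}}
#' summed over adjacent rungs, using the samples of the lower rung of each
#' pair and a log-sum-exp stabilization.
#'
#' @param ladder a \code{pp_ladder} (betas spanning up to 1 and per-rung
#'   log-likelihood samples).
#' @return numeric log marginal likelihood.
#' @export
stepping_stone_lnML <- function(ladder) {
  betas <- ladder$betas
  ll <- ladder$loglik
  if (length(ll) != length(betas)) stop("ladder is missing rungs")
  total <- 0
  for (j in seq_len(length(betas) - 1L)) {
    d <- betas[j + 1L] - betas[j]
    l <- ll[[j]]
    lmax <- max(l)
    total <- total + log(mean(exp(d * (l - lmax)))) + d * lmax
  }
  total
}

#' Path-sampling (thermodynamic integration) marginal-likelihood estimator
#'
#' Trapezoidal integral of the per-rung mean log likelihood over beta.
#'
#' @inheritParams stepping_stone_lnML
#' @return numeric log marginal likelihood.
#' @export
path_sampling_lnML <- function(ladder) {
  betas <- ladder$betas
  ll <- ladder$loglik
  if (length(ll) != length(betas)) stop("ladder is missing rungs")
  m <- vapply(ll, mean, numeric(1))
  sum(diff(betas) * (utils::head(m, -1) + utils::tail(m, -1)) / 2)
}

#' Log Bayes factor between two models
#'
#' \code{lnML_1 - lnML_2}; the \code{2 ln BF} convention used in reporting
#' tables is returned as an attribute.
#'
#' @param lnML_1,lnML_2 log marginal likelihoods (finite).
#' @return numeric log Bayes factor with attribute \code{twice_ln_bf}.
#' @export
bayes_factor <- function(lnML_1, lnML_2) {
  if (!is.finite(lnML_1) || !is.finite(lnML_2))
    stop("log marginal likelihoods must be finite")
  structure(lnML_1 - lnML_2, twice_ln_bf = 2 * (lnML_1 - lnML_2))
}
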