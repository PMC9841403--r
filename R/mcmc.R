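#' MCMC configuration
#'
#' Chain controls for the Metropolis-Hastings sampler. The target is
#' prior x likelihood^beta: beta = 1 is the ordinary posterior, beta = 0 the
#' joint prior, integer beta > 1 a data-cloning posterior, beta in (0,1) a
#' power-posterior rung.
#'
#' @param n_iterations number of MCMC iterations (> 0).
#' @param thin record every \code{thin}-th iteration (>= 1).
#' @param seed integer RNG seed; identical seeds give identical traces.
#' @param beta power on the likelihood, >= 0.
#' @param proposal_weights named nonnegative weights over the move types
#'   \code{mu}, \code{rel_rates}, \code{hyper}; blocks under fixed priors are
#'   dropped automatically.
#' @param tree_jump_period propose a uniform tree-index jump every this many
#'   iterations (>= 1); irrelevant for a single tree.
#' @param tuning multiplicative scale-move tuning parameter (window width on
#'   the log scale).
#' @return object of class \code{"mcmc_config"}.
#' @export
mcmc_config <- function(n_iterations = 10000L, thin = 10L, seed = 1L,
                        beta = 1,
                        proposal_weights = c(mu = 1, rel_rates = 1, hyper = 1),
                        tree_jump_period = 1L, tuning = 2) {
  if (n_iterations <= 0) stop("n_iterations must be > 0")
  if (thin < 1) stop("thin must be >= 1")
  if (beta < 0) stop("beta must be >= 0")
  if (tree_jump_period < 1) stop("tree_jump_period must be >= 1")
  if (all(proposal_weights <= 0)) stop("proposal weights must not all be zero")
  structure(list(n_iterations = as.integer(n_iterations),
                 thin = as.integer(thin), seed = as.integer(seed),
                 beta = beta, proposal_weights = proposal_weights,
                 tree_jump_period = as.integer(tree_jump_period),
                 tuning = tuning),
            class = "mcmc_config")
}

#' Multiplicative scale proposal
#'
#' Proposes \code{value * m} with \code{m = exp(tuning * (u - 0.5))},
#' \code{u ~ U(0,1)}. The Hastings log ratio of this move is \code{log m}.
#'
#' @param value current (positive) value.
#' @param tuning window width (> 0); 0 degenerates to no move.
#' @param u optional uniform deviate (drawn internally if missing).
#' @return list with \code{value} (proposal) and \code{log_hastings}.
#' @export
scale_proposal <- function(value, tuning, u = stats::runif(1)) {
  m <- exp(tuning * (u - 0.5))
  list(value = value * m, log_hastings = log(m))
}

# Joint log prior of a state under the prior set (beta-independent part of
# the target). Hierarchical: Exp(mu | lambda) * Gamma(lambda).
.state_log_prior <- function(state, priors, tlen_mean) {
  lp <- 0
  mu_spec <- priors$mu
  if (mu_spec$family == "hierarchical_exponential") {
    a <- mu_spec$hyperparams$hyper_shape
    b <- .hyper_rate(mu_spec, tlen_mean)
    lp <- lp + stats::dexp(state$mu, rate = state$hyper_lambda, log = TRUE) +
      stats::dgamma(state$hyper_lambda, shape = a, rate = b, log = TRUE)
  } else if (mu_spec$family != "fixed") {
    lp <- lp + log_prior_density(mu_spec, state$mu, tree_length = tlen_mean)
  }
  rr <- priors$rel_rates
  if (!is.null(rr) && rr$family != "fixed")
    lp <- lp + sum(log_prior_density(rr, state$rel_rates,
                                     tree_length = tlen_mean))
  lp
}

# Per-tree likelihood contexts with a shared unit-mu eigen cache keyed on
# the relative rates: Q(mu, r) = mu * Qhat(r), so only rate moves trigger a
# re-decomposition.
.make_engine <- function(tree_list, tips, alphabet, symmetric, root_freqs) {
  k <- alphabet$k
  if (is.null(root_freqs)) root_freqs <- rep(1 / k, k)
  ctxs <- lapply(tree_list, function(tr) {
    q0 <- diag(k); diag(q0) <- 0; diag(q0) <- -rowSums(q0)  # placeholder
    ctx <- lik_context(tr, tips, q0, root_freqs)
    ctx
  })
  qhat_eigen <- NULL
  list(
    set_rates = function(rel_rates) {
      model <- dispersal_model(alphabet, mu = 1, rel_rates = rel_rates,
                               symmetric = symmetric,
                               root_freqs = root_freqs)
      qhat_eigen <<- .q_eigen(build_rate_matrix(model))
    },
    loglik = function(mu, tree_index) {
      .prune_loglik(ctxs[[tree_index]], qe = qhat_eigen, mu = mu)
    },
    n_trees = length(ctxs))
}

#' Run a Metropolis-Hastings chain targeting prior x likelihood^beta
#'
#' The sampler updates the average dispersal rate \code{mu}, each free
#' relative rate, the hierarchical hyper-rate (when present), and the tree
#' index (uniform jump over the tree set, a symmetric move accepted with the
#' full posterior ratio). All positive parameters use multiplicative scale
#' moves. With \code{beta = 0} the data never enter and the chain samples
#' the joint prior.
#'
#' @param priors named list of \code{prior_spec} (\code{mu}, optionally
#'   \code{rel_rates}).
#' @param tree_set a \code{tree_set} (or a single \code{phylo}).
#' @param tips a \code{tip_areas}.
#' @param config an \code{mcmc_config}.
#' @param symmetric logical dispersal-model symmetry.
#' @param root_freqs optional root frequencies (default uniform).
#' @param init optional initial state (as from \code{sample_from_prior}).
#' @return A trace data frame (class \code{"geo_trace"}): columns
#'   \code{state}, \code{lnPosterior}, \code{lnLikelihood}, \code{mu}, one
#'   column per relative rate, \code{hyper_lambda} (hierarchical only) and
#'   \code{tree_index}; attributes \code{beta}, \code{accept_rate}.
#' @export
run_chain <- function(priors, tree_set, tips, config,
                      symmetric = FALSE, root_freqs = NULL, init = NULL) {
  if (inherits(tree_set, "phylo")) tree_set <- tree_set(tree_set)
  stopifnot(inherits(config, "mcmc_config"))
  alphabet <- attr(tips, "alphabet")
  tlens <- vapply(tree_set, tree_length, numeric(1))
  tlen_mean <- mean(tlens)
  set.seed(config$seed)

  hier <- priors$mu$family == "hierarchical_exponential"
  mu_fixed <- priors$mu$family == "fixed"
  rr_spec <- priors$rel_rates
  rr_fixed <- is.null(rr_spec) || rr_spec$family == "fixed"
  np <- count_free_rate_parameters(alphabet$k, symmetric)

  state <- if (is.null(init))
    sample_from_prior(priors, alphabet, tree_length = tlen_mean,
                      symmetric = symmetric)
  else init
  if (hier && is.na(state$hyper_lambda)) state$hyper_lambda <- 1
  state$tree_index <- 1L

  engine <- .make_engine(unclass(tree_set), tips, alphabet, symmetric,
                         root_freqs)
  engine$set_rates(state$rel_rates)
  beta <- config$beta
  cur_ll <- if (beta > 0) engine$loglik(state$mu, state$tree_index) else
    engine$loglik(state$mu, state$tree_index)  # recorded even at beta = 0
  cur_lp <- .state_log_prior(state, priors, tlen_mean)

  # move menu (weight -> multiplicity in the draw pool)
  w <- config$proposal_weights
  wv <- function(nm) if (nm %in% names(w)) w[[nm]] else 1
  moves <- character(0)
  if (!mu_fixed) moves <- c(moves, rep("mu", max(1L, round(10 * wv("mu")))))
  if (!rr_fixed)
    moves <- c(moves, rep("rel_rates", max(1L, round(10 * wv("rel_rates")))))
  if (hier) {
    moves <- c(moves, rep("hyper", max(1L, round(10 * wv("hyper")))))
    # up-down operator: rescale (mu, lambda) inversely to traverse their
    # correlated ridge; unit Jacobian, symmetric on the log scale
    if (!mu_fixed) moves <- c(moves, rep("updown", max(1L, round(10 * wv("hyper")))))
  }
  n_out <- config$n_iterations %/% config$thin
  rr_names <- if (np > 0) rate_param_names(alphabet, symmetric) else character(0)
  cols <- c("state", "lnPosterior", "lnLikelihood", "mu", rr_names,
            if (hier) "hyper_lambda", "tree_index")
  out <- matrix(NA_real_, n_out, length(cols),
                dimnames = list(NULL, cols))
  n_prop <- 0L; n_acc <- 0L
  row <- 0L
  multi_tree <- engine$n_trees > 1L

  for (it in seq_len(config$n_iterations)) {
    if (length(moves)) {
      mv <- moves[sample.int(length(moves), 1L)]
      n_prop <- n_prop + 1L
      if (mv == "mu") {
        pr <- scale_proposal(state$mu, config$tuning)
        new_state <- state; new_state$mu <- pr$value
        new_ll <- if (beta > 0) engine$loglik(pr$value, state$tree_index)
                  else cur_ll
        new_lp <- .state_log_prior(new_state, priors, tlen_mean)
        logr <- (new_lp + beta * new_ll) - (cur_lp + beta * cur_ll) +
          pr$log_hastings
        if (is.finite(logr) && log(stats::runif(1)) < logr) {
          state <- new_state
          if (beta > 0) cur_ll <- new_ll
          cur_lp <- new_lp
          n_acc <- n_acc + 1L
        }
      } else if (mv == "rel_rates") {
        j <- sample.int(np, 1L)
        pr <- scale_proposal(state$rel_rates[j], config$tuning)
        new_state <- state; new_state$rel_rates[j] <- pr$value
        if (beta > 0) {
          engine$set_rates(new_state$rel_rates)
          new_ll <- engine$loglik(state$mu, state$tree_index)
        } else new_ll <- cur_ll
        new_lp <- .state_log_prior(new_state, priors, tlen_mean)
        logr <- (new_lp + beta * new_ll) - (cur_lp + beta * cur_ll) +
          pr$log_hastings
        if (is.finite(logr) && log(stats::runif(1)) < logr) {
          state <- new_state
          if (beta > 0) cur_ll <- new_ll
          cur_lp <- new_lp
          n_acc <- n_acc + 1L
        } else if (beta > 0) {
          engine$set_rates(state$rel_rates)  # restore cache
        }
      } else if (mv == "updown") {
        m <- exp(config$tuning * (stats::runif(1) - 0.5))
        new_state <- state
        new_state$mu <- state$mu * m
        new_state$hyper_lambda <- state$hyper_lambda / m
        new_ll <- if (beta > 0) engine$loglik(new_state$mu, state$tree_index)
                  else cur_ll
        new_lp <- .state_log_prior(new_state, priors, tlen_mean)
        logr <- (new_lp + beta * new_ll) - (cur_lp + beta * cur_ll)
        if (is.finite(logr) && log(stats::runif(1)) < logr) {
          state <- new_state
          if (beta > 0) cur_ll <- new_ll
          cur_lp <- new_lp
          n_acc <- n_acc + 1L
        }
      } else if (mv == "hyper") {
        # conjugate Gibbs draw: lambda | mu ~ Gamma(a + 1, b + mu)
        a <- priors$mu$hyperparams$hyper_shape
        b <- .hyper_rate(priors$mu, tlen_mean)
        state$hyper_lambda <- stats::rgamma(1, shape = a + 1,
                                            rate = b + state$mu)
        cur_lp <- .state_log_prior(state, priors, tlen_mean)
        n_acc <- n_acc + 1L
      }
    }
    if (multi_tree && it %% config$tree_jump_period == 0L) {
      prop_idx <- tree_jump_proposal(state$tree_index, engine$n_trees)
      new_ll <- engine$loglik(state$mu, prop_idx$index)
      logr <- beta * (new_ll - cur_ll)
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        state$tree_index <- prop_idx$index
        cur_ll <- new_ll
      }
    }
    if (it %% config$thin == 0L) {
      row <- row + 1L
      if (beta == 0) {
        if (!rr_fixed) engine$set_rates(state$rel_rates)
        cur_ll_rec <- engine$loglik(state$mu, state$tree_index)
      } else cur_ll_rec <- cur_ll
      out[row, ] <- c(it, cur_lp + beta * cur_ll_rec, cur_ll_rec, state$mu,
                      state$rel_rates, if (hier) state$hyper_lambda,
                      state$tree_index)
    }
  }
  if (n_prop > 0L && n_acc == 0L)
    warning("zero accepted proposals: the chain never moved")
  df <- as.data.frame(out)
  attr(df, "beta") <- beta
  attr(df, "accept_rate") <- if (n_prop > 0) n_acc / n_prop else NA_real_
  class(df) <- c("geo_trace", "data.frame")
  df
}

#' Uniform tree-jump proposal
#'
#' Draws a tree index uniformly over the tree set; the move is symmetric so
#' the Hastings log ratio is 0. Acceptance (in \code{\link{run_chain}}) uses
#' the full posterior ratio, i.e. the likelihood on the proposed tree.
#'
#' @param current current tree index (1-based).
#' @param n_trees number of trees in the set.
#' @return list with \code{index} and \code{log_hastings} (always 0).
#' @export
tree_jump_proposal <- function(current, n_trees) {
  list(index = sample.int(n_trees, 1L), log_hastings = 0)
}

#' Effective sample size of an MCMC series
#'
#' \code{ESS = N / (1 + 2 sum rho_t)} with empirical autocorrelations summed
#' until the first nonpositive consecutive pair (initial positive sequence
#' rule). A constant series returns N with a warning.
#'
#' @param x numeric series, length >= 10.
#' @return numeric ESS.
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 10L) stop("series too short for an ESS estimate (need >= 10)")
  v <- stats::var(x)
  if (v == 0 || !is.finite(v)) {
    warning("degenerate (constant) series: ESS defined as N")
    return(n)
  }
  ac <- stats::acf(x, lag.max = min(n - 2L, 10L * floor(sqrt(n))),
                   plot = FALSE)$acf[-1]
  s <- 0
  t <- 1L
  while (t <= length(ac)) {
    pair <- ac[t] + if (t + 1L <= length(ac)) ac[t + 1L] else 0
    if (pair <= 0) break
    s <- s + ac[t] + if (t + 1L <= length(ac)) ac[t + 1L] else 0
    t <- t + 2L
  }
  max(1, n / (1 + 2 * s))
}

#' Highest posterior density interval
#'
#' The narrowest interval containing \code{ceiling(prob * N)} of the sorted
#' samples.
#'
#' @param x numeric samples.
#' @param prob interval mass, default 0.95.
#' @return numeric length-2 vector \code{c(lower, upper)}.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  xs <- sort(x)
  n <- length(xs)
  m <- min(n, ceiling(prob * n))
  if (m == n) return(c(xs[1], xs[n]))
  starts <- seq_len(n - m + 1L)
  widths <- xs[starts + m - 1L] - xs[starts]
  i <- which.min(widths)
  c(xs[i], xs[i + m - 1L])
}

#' Summarize an MCMC trace
#'
#' Per-parameter posterior mean, variance, HPD interval and effective sample
#' size; burnin is discarded here (never silently inside the sampler).
#'
#' @param trace a trace data frame (from \code{\link{run_chain}} or
#'   \code{\link{read_trace}}).
#' @param prob HPD mass (default 0.95).
#' @param burnin_fraction fraction of initial rows to discard.
#' @return data frame with one row per parameter column.
#' @export
summarize_trace <- function(trace, prob = 0.95, burnin_fraction = 0) {
  stopifnot(nrow(trace) > 0)
  drop <- floor(burnin_fraction * nrow(trace))
  if (drop > 0) trace <- trace[-seq_len(drop), , drop = FALSE]
  pcols <- setdiff(names(trace), c("state", "tree_index"))
  res <- lapply(pcols, function(nm) {
    x <- trace[[nm]]
    h <- hpd_interval(x, prob)
    ess <- if (stats::var(x) == 0) length(x)
           else suppressWarnings(effective_sample_size(x))
    data.frame(parameter = nm, mean = mean(x), variance = stats::var(x),
               hpd_lower = h[1], hpd_upper = h[2], ess = ess,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
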