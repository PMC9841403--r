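## Prior-diagnosis instruments: robust-Bayesian prior sweeps, data cloning,
## the grid MLE reference point, and the induced prior on the number of
## dispersal events.

#' Robust-Bayesian prior sweep
#'
#' Runs the same inference (same data, same chain controls) under each of
#' several candidate priors and compares the resulting marginal posteriors.
#' If the posteriors for a parameter barely move across priors the estimate
#' is robust; if they track their priors, it is prior sensitive. The
#' sensitivity flag compares the 95% HPD intervals of \code{mu} across prior
#' pairs by Jaccard overlap (intersection length / union length) against
#' \code{overlap_threshold}.
#'
#' @param prior_configs named list of prior sets (each a named list of
#'   \code{prior_spec}); at least 2.
#' @param tree_set,tips shared data.
#' @param config shared \code{mcmc_config}; replicate r uses seed
#'   \code{config$seed + 1000 * (r - 1)}.
#' @param replicates chains per prior configuration (>= 1), to expose MCMC
#'   noise the way paired replicate analyses do.
#' @param overlap_threshold flag sensitivity when the minimum pairwise HPD
#'   overlap falls below this (default 0.35).
#' @param parameter trace column compared across priors (default "mu").
#' @param symmetric,root_freqs model settings.
#' @param ess_floor flag any chain whose parameter ESS falls below this.
#' @return list of class \code{"robust_bayes"}: \code{traces} (nested list
#'   prior -> replicate), \code{summary} (per prior x replicate), pairwise
#'   \code{overlap} matrix, \code{prior_sensitive} flag, \code{flags}.
#' @export
run_robust_bayes <- function(prior_configs, tree_set, tips, config,
                             replicates = 1L, overlap_threshold = 0.35,
                             parameter = "mu", symmetric = FALSE,
                             root_freqs = NULL, ess_floor = 50) {
  if (length(prior_configs) < 2L)
    stop("robust-Bayes sweep needs at least 2 prior configurations")
  if (is.null(names(prior_configs)))
    names(prior_configs) <- paste0("prior", seq_along(prior_configs))
  traces <- list()
  rows <- list()
  flags <- character(0)
  for (nm in names(prior_configs)) {
    traces[[nm]] <- list()
    for (r in seq_len(replicates)) {
      cfg <- config
      cfg$seed <- config$seed + 1000L * (r - 1L)
      tr <- run_chain(prior_configs[[nm]], tree_set, tips, cfg,
                      symmetric = symmetric, root_freqs = root_freqs)
      traces[[nm]][[r]] <- tr
      s <- summarize_trace(tr, burnin_fraction = 0.1)
      s <- s[s$parameter == parameter, , drop = FALSE]
      s$prior <- nm; s$replicate <- r
      rows[[length(rows) + 1L]] <- s
      if (s$ess < ess_floor)
        flags <- c(flags, sprintf("%s replicate %d: ESS %.1f below floor %g",
                                  nm, r, s$ess, ess_floor))
    }
  }
  summ <- do.call(rbind, rows)
  # pairwise HPD overlap between priors (first replicate of each)
  npr <- length(prior_configs)
  ov <- matrix(1, npr, npr,
               dimnames = list(names(prior_configs), names(prior_configs)))
  for (i in seq_len(npr)) for (j in seq_len(npr)) if (j > i) {
    hi <- summ[summ$prior == names(prior_configs)[i] & summ$replicate == 1, ]
    hj <- summ[summ$prior == names(prior_configs)[j] & summ$replicate == 1, ]
    ov[i, j] <- ov[j, i] <- interval_overlap(
      c(hi$hpd_lower, hi$hpd_upper), c(hj$hpd_lower, hj$hpd_upper))
  }
  min_ov <- min(ov)
  structure(list(traces = traces, summary = summ, overlap = ov,
                 min_overlap = min_ov,
                 prior_sensitive = min_ov < overlap_threshold,
                 flags = flags, parameter = parameter),
            class = "robust_bayes")
}

#' @export
print.robust_bayes <- function(x, ...) {
  cat("Robust-Bayesian prior sweep on '", x$parameter, "'\n", sep = "")
  tb <- x$summary[, c("prior", "replicate", "mean", "hpd_lower",
                      "hpd_upper", "ess")]
  tb[3:6] <- lapply(tb[3:6], signif, 4)
  print(tb, row.names = FALSE)
  cat("minimum pairwise HPD overlap:", signif(x$min_overlap, 3), "->",
      if (x$prior_sensitive) "PRIOR SENSITIVE" else "robust", "\n")
  if (length(x$flags)) cat("flags:\n ", paste(x$flags, collapse = "\n  "),
                           "\n")
  invisible(x)
}

#' Jaccard overlap of two intervals
#' @param i1,i2 numeric length-2 intervals.
#' @return intersection length / union length (1 for two identical points).
#' @export
interval_overlap <- function(i1, i2) {
  lo <- max(i1[1], i2[1]); hi <- min(i1[2], i2[2])
  inter <- max(0, hi - lo)
  uni <- max(i1[2], i2[2]) - min(i1[1], i2[1])
  if (uni == 0) return(1)
  inter / uni
}

#' Data-cloning analysis
#'
#' Runs one chain per clone count beta (the number of copies of the
#' dataset), all under the same prior. beta = 0 targets the prior, beta = 1
#' the ordinary posterior; as beta grows the posterior concentrates on the
#' maximum-likelihood estimate, and the speed of that concentration measures
#' how much the prior (rather than the data) is driving the posterior.
#' Cloning is implemented by powering the log likelihood, which for this
#' model is exactly the likelihood of beta literal copies of the character.
#'
#' @param clone_counts distinct sorted integers >= 0; must include 1.
#' @param priors prior set (shared across cells).
#' @param tree_set,tips data.
#' @param config base \code{mcmc_config}; the cell at beta b, replicate r
#'   runs with seed \code{config$seed + 97 * r + b}.
#' @param replicates chains per clone count.
#' @param symmetric,root_freqs model settings.
#' @return list of class \code{"data_cloning"}: \code{traces} (per beta,
#'   per replicate), \code{summary} data frame with per-cell posterior mean,
#'   variance and \code{beta * variance} for \code{mu}.
#' @export
run_data_cloning <- function(clone_counts = c(0, 1, 5, 20), priors,
                             tree_set, tips, config, replicates = 1L,
                             symmetric = FALSE, root_freqs = NULL) {
  clone_counts <- as.numeric(clone_counts)
  if (is.unsorted(clone_counts, strictly = TRUE))
    stop("clone counts must be distinct and sorted")
  if (!1 %in% clone_counts)
    stop("clone counts must include 1 (the plain posterior)")
  traces <- list()
  rows <- list()
  for (b in clone_counts) {
    key <- as.character(b)
    traces[[key]] <- list()
    for (r in seq_len(replicates)) {
      cfg <- config
      cfg$beta <- b
      cfg$seed <- as.integer(config$seed + 97L * r + round(b))
      tr <- run_chain(priors, tree_set, tips, cfg, symmetric = symmetric,
                      root_freqs = root_freqs)
      traces[[key]][[r]] <- tr
      mu <- tr$mu[-seq_len(floor(0.1 * nrow(tr)))]
      rows[[length(rows) + 1L]] <-
        data.frame(beta = b, replicate = r, mean = mean(mu),
                   variance = stats::var(mu),
                   beta_x_variance = b * stats::var(mu),
                   ess = suppressWarnings(effective_sample_size(mu)))
    }
  }
  structure(list(traces = traces, summary = do.call(rbind, rows),
                 clone_counts = clone_counts),
            class = "data_cloning")
}

#' @export
print.data_cloning <- function(x, ...) {
  cat("Data-cloning analysis over beta in {",
      paste(x$clone_counts, collapse = ", "), "}\n")
  tb <- x$summary
  tb[3:6] <- lapply(tb[3:6], signif, 4)
  print(tb, row.names = FALSE)
  invisible(x)
}

#' Grid maximum-likelihood estimate of the average dispersal rate
#'
#' One-dimensional MLE of \code{mu} with the relative rates held fixed:
#' coarse log-spaced grid search refined until the bracketing interval has
#' relative width below \code{rel_width}. The independent reference point
#' that data-cloning posteriors converge to.
#'
#' @param tree a \code{phylo} (or \code{tree_set}; first tree used).
#' @param tips a \code{tip_areas}.
#' @param rel_rates fixed relative rates (default all 1).
#' @param symmetric,root_freqs model settings.
#' @param mu_range initial search range.
#' @param rel_width refinement stop: relative width of the final bracket.
#' @return list: \code{mu_hat}, \code{loglik}, \code{flat} (TRUE when the
#'   likelihood is numerically flat in \code{mu}, with a warning).
#' @export
grid_mle <- function(tree, tips, rel_rates = NULL, symmetric = FALSE,
                     root_freqs = NULL, mu_range = c(1e-4, 100),
                     rel_width = 1e-4) {
  if (inherits(tree, "tree_set")) tree <- tree[[1]]
  al <- attr(tips, "alphabet")
  model1 <- dispersal_model(al, mu = 1, rel_rates = rel_rates,
                            symmetric = symmetric, root_freqs = root_freqs)
  qe <- .q_eigen(build_rate_matrix(model1))
  ctx <- lik_context(tree, tips, build_rate_matrix(model1),
                     model1$root_freqs)
  ll <- function(mu) .prune_loglik(ctx, qe = qe, mu = mu)
  lo <- mu_range[1]; hi <- mu_range[2]
  best <- NA_real_
  repeat {
    grid <- exp(seq(log(lo), log(hi), length.out = 40L))
    vals <- vapply(grid, ll, numeric(1))
    i <- which.max(vals)
    if (max(vals) - min(vals) < 1e-10) {
      warning("flat likelihood in mu: no information; reporting ",
              "range boundary state")
      return(list(mu_hat = grid[i], loglik = vals[i], flat = TRUE))
    }
    lo2 <- grid[max(1L, i - 1L)]; hi2 <- grid[min(length(grid), i + 1L)]
    best <- grid[i]
    if ((hi2 - lo2) / best < rel_width) break
    lo <- lo2; hi <- hi2
  }
  list(mu_hat = best, loglik = ll(best), flat = FALSE)
}

#' Induced prior on the number of dispersal events
#'
#' What a prior on the dispersal-rate parameters implies about an observable
#' quantity: the total number of dispersal events on the tree. Each draw
#' samples a model from the prior, simulates an unconditioned CTMC history
#' over the whole tree, and counts events. A dataset occupying m areas must
#' have experienced at least m - 1 events, so the fraction of induced prior
#' mass below that floor is reported when \code{m_areas} is given.
#'
#' @param priors named list of \code{prior_spec}.
#' @param tree a \code{phylo}.
#' @param alphabet a \code{geo_alphabet}.
#' @param n_sims number of prior draws (>= 1).
#' @param seed integer seed.
#' @param symmetric,root_freqs model settings.
#' @param m_areas optional number of observed areas for the event floor
#'   m - 1.
#' @return list: \code{counts} (integer vector), \code{mean},
#'   \code{quantiles} (2.5/25/50/75/97.5%), \code{floor},
#'   \code{frac_below_floor} (NA without \code{m_areas}).
#' @export
induced_event_count_prior <- function(priors, tree, alphabet,
                                      n_sims = 1000L, seed = 1L,
                                      symmetric = FALSE, root_freqs = NULL,
                                      m_areas = NULL) {
  stopifnot(n_sims >= 1)
  set.seed(seed)
  T <- tree_length(tree)
  counts <- integer(n_sims)
  for (s in seq_len(n_sims)) {
    st <- sample_from_prior(priors, alphabet, tree_length = T,
                            symmetric = symmetric)
    model <- dispersal_model(alphabet, mu = st$mu, rel_rates = st$rel_rates,
                             symmetric = symmetric, root_freqs = root_freqs)
    sim <- .forward_simulate(tree, model)
    counts[s] <- sum(vapply(sim$events, length, integer(1)))
  }
  floor_events <- if (!is.null(m_areas)) m_areas - 1L else NA_integer_
  list(counts = counts, mean = mean(counts),
       quantiles = stats::quantile(counts, c(0.025, 0.25, 0.5, 0.75, 0.975)),
       floor = floor_events,
       frac_below_floor = if (is.na(floor_events)) NA_real_
                          else mean(counts < floor_events))
}
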