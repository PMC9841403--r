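#' Fit a discrete-geographic dispersal model by MCMC
#'
#' The package's central fitting function: Bayesian inference of the
#' dispersal CTMC (average rate \code{mu}, pairwise relative rates, and the
#' hierarchical hyper-rate when that prior is chosen) conditional on a fixed
#' time tree or a posterior sample of trees (sequential inference). The
#' target distribution is prior x likelihood^beta, so the same function runs
#' ordinary posteriors (\code{beta = 1}), prior-only chains
#' (\code{beta = 0}), data-cloning posteriors (integer \code{beta > 1}) and
#' power-posterior rungs (\code{beta} in (0,1)).
#'
#' @param tree a \code{phylo}, \code{tree_set}, or Newick string.
#' @param tips a \code{tip_areas} mapping (or named character vector).
#' @param priors named list of \code{\link{prior_spec}}; default
#'   \code{\link{default_priors}()}.
#' @param beta power on the likelihood (>= 0), default 1.
#' @param n_iterations,thin,seed chain controls (see
#'   \code{\link{mcmc_config}}).
#' @param symmetric share dispersal rates across unordered area pairs?
#' @param root_freqs optional root-area frequencies (default uniform).
#' @param ... further arguments passed to \code{\link{mcmc_config}}.
#' @return An object of class \code{"geo_fit"}: list with the \code{trace}
#'   (a \code{geo_trace} data frame), the bound \code{tree_set},
#'   \code{tips}, \code{priors}, \code{config} and model settings. Methods:
#'   \code{print}, \code{summary}, \code{coef}, \code{plot},
#'   \code{simulate}.
#' @examples
#' sc <- make_scenario(n_tips = 12, k = 2, mu = 0.5, seed = 1)
#' fit <- geo_fit(sc$tree, sc$tips,
#'                priors = list(mu = prior_spec("exponential", "mu", rate = 1),
#'                              rel_rates = prior_spec("fixed", "rel_rates",
#'                                                     value = 1)),
#'                n_iterations = 2000, thin = 10, seed = 1)
#' summary(fit)
#' @export
geo_fit <- function(tree, tips, priors = default_priors(), beta = 1,
                    n_iterations = 10000L, thin = 10L, seed = 1L,
                    symmetric = FALSE, root_freqs = NULL, ...) {
  if (is.character(tree) && length(tree) == 1L) tree <- parse_newick(tree)
  if (inherits(tree, "phylo")) tree <- tree_set(tree)
  if (!inherits(tips, "tip_areas")) tips <- tip_areas(tips)
  config <- mcmc_config(n_iterations = n_iterations, thin = thin,
                        seed = seed, beta = beta, ...)
  trace <- run_chain(priors, tree, tips, config,
                     symmetric = symmetric, root_freqs = root_freqs)
  structure(list(trace = trace, tree_set = tree, tips = tips,
                 priors = priors, config = config, symmetric = symmetric,
                 root_freqs = root_freqs, beta = beta),
            class = "geo_fit")
}

#' @export
print.geo_fit <- function(x, ...) {
  al <- attr(x$tips, "alphabet")
  cat("Discrete-geographic dispersal fit (MCMC)\n")
  cat("  tips      :", length(x$tips), "in", al$k, "areas\n")
  cat("  trees     :", length(x$tree_set), "\n")
  cat("  beta      :", x$beta, "\n")
  cat("  iterations:", x$config$n_iterations, "(thin", x$config$thin, ")\n")
  cat("  prior(mu) :", x$priors$mu$family, "\n")
  cat("  posterior mean mu:",
      format(mean(x$trace$mu[-seq_len(nrow(x$trace) %/% 10)]), digits = 4),
      "\n")
  invisible(x)
}

#' @param object a \code{geo_fit}.
#' @param prob HPD interval mass.
#' @param burnin_fraction fraction of the trace discarded before summarizing.
#' @rdname geo_fit
#' @export
summary.geo_fit <- function(object, prob = 0.95, burnin_fraction = 0.1, ...) {
  s <- summarize_trace(object$trace, prob = prob,
                       burnin_fraction = burnin_fraction)
  structure(list(table = s, prob = prob, beta = object$beta,
                 accept_rate = attr(object$trace, "accept_rate")),
            class = "summary.geo_fit")
}

#' @export
print.summary.geo_fit <- function(x, ...) {
  cat("Posterior summary (beta =", x$beta, "; ",
      format(100 * x$prob), "% HPD)\n", sep = "")
  tb <- x$table
  tb[-1] <- lapply(tb[-1], function(v) signif(v, 5))
  print(tb, row.names = FALSE)
  if (!is.na(x$accept_rate))
    cat("MH acceptance rate:", format(x$accept_rate, digits = 3), "\n")
  invisible(x)
}

#' @rdname geo_fit
#' @export
coef.geo_fit <- function(object, burnin_fraction = 0.1, ...) {
  s <- summarize_trace(object$trace, burnin_fraction = burnin_fraction)
  keep <- !(s$parameter %in% c("lnPosterior", "lnLikelihood"))
  stats::setNames(s$mean[keep], s$parameter[keep])
}

#' @param x a \code{geo_fit} object.
#' @param y ignored.
#' @param parameter trace column to display (default \code{"mu"}).
#' @rdname geo_fit
#' @export
plot.geo_fit <- function(x, y, parameter = "mu", ...) {
  v <- x$trace[[parameter]]
  if (is.null(v)) stop("no such trace column: ", parameter)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$trace$state, v, type = "l", xlab = "iteration",
                 ylab = parameter, main = "trace", ...)
  graphics::plot(stats::density(v), main = "marginal density",
                 xlab = parameter)
  invisible(x)
}

#' Posterior-predictive simulation from a fitted model
#'
#' Draws parameter values (and a tree) from the posterior trace and
#' simulates replicate tip-area datasets under the dispersal CTMC.
#'
#' @param object a \code{geo_fit}.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param burnin_fraction fraction of the trace discarded before drawing.
#' @param ... unused.
#' @return list of \code{tip_areas} objects, one per draw.
#' @export
simulate.geo_fit <- function(object, nsim = 1, seed = NULL,
                             burnin_fraction = 0.1, ...) {
  if (!is.null(seed)) set.seed(seed)
  trace <- object$trace
  drop <- floor(burnin_fraction * nrow(trace))
  if (drop > 0) trace <- trace[-seq_len(drop), , drop = FALSE]
  al <- attr(object$tips, "alphabet")
  rows <- sample.int(nrow(trace), nsim, replace = nsim > nrow(trace))
  lapply(rows, function(i) {
    model <- .model_from_trace_row(trace, i, al, object$symmetric,
                                   object$root_freqs)
    tr <- object$tree_set[[as.integer(trace$tree_index[i])]]
    simulate_tip_data(tr, model)
  })
}

# Rebuild a dispersal_model from one trace row.
.model_from_trace_row <- function(trace, i, alphabet, symmetric, root_freqs) {
  rn <- rate_param_names(alphabet, symmetric)
  rr <- if (length(rn) && all(rn %in% names(trace)))
    as.numeric(trace[i, rn]) else NULL
  dispersal_model(alphabet, mu = trace$mu[i], rel_rates = rr,
                  symmetric = symmetric, root_freqs = root_freqs)
}
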