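#' Area alphabet for a discrete-geographic model
#'
#' An ordered set of distinct area labels. The alphabet fixes the dimension
#' \code{k} of the dispersal rate matrix and the index <-> label mapping used
#' everywhere else in the package.
#'
#' @param areas character vector of distinct area labels (length >= 2).
#' @return An object of class \code{"geo_alphabet"} with elements
#'   \code{areas} and \code{k}.
#' @examples
#' geo_alphabet(c("Asia", "Europe", "Africa"))
#' @export
geo_alphabet <- function(areas) {
  areas <- as.character(areas)
  if (length(areas) < 2L)
    stop("invalid alphabet: need at least 2 areas, got ", length(areas))
  if (anyDuplicated(areas))
    stop("invalid alphabet: duplicated area labels: ",
         paste(unique(areas[duplicated(areas)]), collapse = ", "))
  structure(list(areas = areas, k = length(areas)), class = "geo_alphabet")
}

#' @export
print.geo_alphabet <- function(x, ...) {
  cat("Geographic alphabet:", x$k, "areas\n ",
      paste(x$areas, collapse = ", "), "\n")
  invisible(x)
}

#' Number of free pairwise dispersal-rate parameters
#'
#' Under an asymmetric model every ordered pair of areas has its own rate,
#' giving k(k-1) parameters; a symmetric model shares rates across each
#' unordered pair, giving k(k-1)/2.
#'
#' @param k integer number of areas (>= 2).
#' @param symmetric logical; share rates across unordered pairs?
#' @return integer parameter count.
#' @examples
#' count_free_rate_parameters(5, symmetric = FALSE)  # 20
#' count_free_rate_parameters(10, symmetric = FALSE) # 90
#' @export
count_free_rate_parameters <- function(k, symmetric = FALSE) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L)
    stop("invalid alphabet: k must be an integer >= 2")
  if (symmetric) (k * (k - 1L)) %/% 2L else k * (k - 1L)
}

#' Names of the pairwise relative-rate parameters, in storage order
#'
#' @param alphabet a \code{geo_alphabet}.
#' @param symmetric logical.
#' @return character vector, e.g. \code{"r_A_B"}; unordered pairs are listed
#'   upper-triangle row-wise for symmetric models, ordered pairs row-wise
#'   (skipping the diagonal) otherwise.
#' @export
rate_param_names <- function(alphabet, symmetric = FALSE) {
  a <- alphabet$areas
  k <- alphabet$k
  out <- character(0)
  for (i in seq_len(k)) {
    js <- if (symmetric) seq_len(k)[seq_len(k) > i] else seq_len(k)[-i]
    for (j in js) out <- c(out, paste("r", a[i], a[j], sep = "_"))
  }
  out
}

#' Discrete-geographic dispersal model
#'
#' Bundles the area alphabet, the pairwise relative dispersal rates, the
#' average dispersal rate \code{mu} (expected dispersal events per unit tree
#' time under the normalization convention, see \code{\link{build_rate_matrix}}),
#' and the root-area frequencies.
#'
#' @param alphabet a \code{geo_alphabet} (or character vector of area labels).
#' @param mu average dispersal rate, > 0.
#' @param rel_rates nonnegative relative rates, one per unordered pair if
#'   \code{symmetric} else one per ordered pair (see
#'   \code{\link{rate_param_names}} for the order). Defaults to all 1 (equal
#'   rates).
#' @param symmetric logical; default \code{FALSE}.
#' @param root_freqs probability vector of length k; defaults to uniform.
#' @return An object of class \code{"dispersal_model"}.
#' @export
dispersal_model <- function(alphabet, mu = 1, rel_rates = NULL,
                            symmetric = FALSE, root_freqs = NULL) {
  if (!inherits(alphabet, "geo_alphabet")) alphabet <- geo_alphabet(alphabet)
  k <- alphabet$k
  np <- count_free_rate_parameters(k, symmetric)
  if (is.null(rel_rates)) rel_rates <- rep(1, np)
  if (length(rel_rates) != np)
    stop("rel_rates must have length ", np, " (k = ", k,
         if (symmetric) ", symmetric)" else ", asymmetric)")
  if (any(rel_rates < 0)) stop("rel_rates must be nonnegative")
  if (is.null(root_freqs)) root_freqs <- rep(1 / k, k)
  if (length(root_freqs) != k) stop("root_freqs must have length k")
  if (any(root_freqs < 0) || abs(sum(root_freqs) - 1) > 1e-12)
    stop("root_freqs must be a probability vector summing to 1")
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0) stop("mu must be > 0")
  structure(list(alphabet = alphabet, symmetric = symmetric,
                 rel_rates = as.numeric(rel_rates), mu = as.numeric(mu),
                 root_freqs = as.numeric(root_freqs)),
            class = "dispersal_model")
}

#' @export
print.dispersal_model <- function(x, ...) {
  cat("Discrete-geographic dispersal model\n")
  cat("  areas     :", x$alphabet$k, "(",
      paste(x$alphabet$areas, collapse = ", "), ")\n")
  cat("  symmetric :", x$symmetric, "\n")
  cat("  mu        :", format(x$mu), "\n")
  cat("  rel rates :", paste(format(x$rel_rates, digits = 3), collapse = " "),
      "\n")
  invisible(x)
}

# k x k matrix of relative rates (off-diagonal), mirrored if symmetric.
.rel_rate_matrix <- function(model) {
  k <- model$alphabet$k
  R <- matrix(0, k, k)
  idx <- 1L
  if (model$symmetric) {
    for (i in seq_len(k)) for (j in seq_len(k)) if (j > i) {
      R[i, j] <- R[j, i] <- model$rel_rates[idx]; idx <- idx + 1L
    }
  } else {
    for (i in seq_len(k)) for (j in seq_len(k)) if (j != i) {
      R[i, j] <- model$rel_rates[idx]; idx <- idx + 1L
    }
  }
  R
}

#' Build the instantaneous-rate matrix Q of a dispersal model
#'
#' Off-diagonal entries are proportional to the pairwise relative rates;
#' diagonals are set so each row sums to zero. The matrix is rescaled so that
#' the expected number of dispersal events per unit time at the root
#' frequencies equals \code{mu} exactly: \eqn{-\sum_i \pi_i q_{ii} = \mu}.
#' This makes \code{mu} directly interpretable as the average dispersal rate,
#' and the induced mean number of events on a tree of total length T is
#' \code{mu * T} when the state distribution stays at \code{root_freqs}.
#'
#' @param model a \code{dispersal_model}.
#' @return A k x k numeric matrix with \code{dimnames} set to the area labels.
#' @export
build_rate_matrix <- function(model) {
  R <- .rel_rate_matrix(model)
  if (all(R == 0))
    stop("degenerate rate matrix: all relative rates are zero")
  pi0 <- model$root_freqs
  leave <- rowSums(R)
  scale <- model$mu / sum(pi0 * leave)
  Q <- R * scale
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(model$alphabet$areas, model$alphabet$areas)
  Q
}

## ---------------------------------------------------------------------------
## Prior specifications
## ---------------------------------------------------------------------------

.prior_families <- c("ctmc_reference", "exponential",
                     "hierarchical_exponential", "gamma", "fixed")
.prior_targets <- c("mu", "rel_rates", "hyper")

#' Prior specification for a dispersal-model parameter block
#'
#' Supported families:
#' \describe{
#'   \item{ctmc_reference}{density proportional to \eqn{\mu^{-1/2} e^{-\mu T}}
#'     with T the tree length, i.e. Gamma(1/2, rate = T); the conventional
#'     default reference prior for an overall CTMC rate on a time tree.
#'     Requires a tree-length context at evaluation time.}
#'   \item{exponential}{Exp(\code{rate}).}
#'   \item{hierarchical_exponential}{\eqn{\mu | \lambda \sim} Exp(\eqn{\lambda}),
#'     \eqn{\lambda \sim} Gamma(shape 0.5, rate 0.5 T); the hyper-rate
#'     \eqn{\lambda} is sampled in the MCMC. The marginal on \eqn{\mu} is
#'     Lomax(shape 0.5, scale 0.5 T).}
#'   \item{gamma}{Gamma(\code{shape}, \code{rate}).}
#'   \item{fixed}{point mass at \code{value}; the block is never updated.}
#' }
#'
#' @param family one of \code{"ctmc_reference"}, \code{"exponential"},
#'   \code{"hierarchical_exponential"}, \code{"gamma"}, \code{"fixed"}.
#' @param target parameter block the prior governs: \code{"mu"},
#'   \code{"rel_rates"} or \code{"hyper"}.
#' @param ... named hyperparameters (\code{rate}, \code{shape},
#'   \code{hyper_shape}, \code{hyper_rate}, \code{value} as the family needs).
#' @return object of class \code{"prior_spec"}.
#' @examples
#' prior_spec("exponential", "mu", rate = 1)
#' prior_spec("ctmc_reference", "mu")
#' @export
prior_spec <- function(family, target = "mu", ...) {
  family <- match.arg(family, .prior_families)
  target <- match.arg(target, .prior_targets)
  hp <- list(...)
  if (length(hp) == 1L && is.list(hp[[1]]) && is.null(names(hp)[1]))
    hp <- hp[[1]]
  defaults <- switch(family,
    exponential = list(rate = 1),
    gamma = list(shape = 1, rate = 1),
    hierarchical_exponential = list(hyper_shape = 0.5, hyper_rate = NULL),
    ctmc_reference = list(),
    fixed = list(value = 1))
  for (nm in names(defaults))
    if (is.null(hp[[nm]])) hp[[nm]] <- defaults[[nm]]
  for (nm in c("rate", "shape", "hyper_shape", "hyper_rate"))
    if (!is.null(hp[[nm]]) && hp[[nm]] <= 0)
      stop("hyperparameter ", nm, " must be > 0")
  if (family == "fixed" && (!is.numeric(hp$value)))
    stop("fixed prior needs a numeric 'value'")
  structure(list(family = family, target = target, hyperparams = hp),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  hp <- x$hyperparams
  hp <- hp[!vapply(hp, is.null, logical(1))]
  cat("Prior on ", x$target, ": ", x$family,
      if (length(hp)) paste0("(", paste(names(hp), unlist(hp), sep = "=",
                                        collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Default prior set
#'
#' The package default: a ctmc_reference prior on \code{mu} and iid
#' Exponential(mean 1) priors on the relative rates.
#'
#' @return named list of \code{prior_spec} objects (names are the targets).
#' @export
default_priors <- function() {
  list(mu = prior_spec("ctmc_reference", "mu"),
       rel_rates = prior_spec("exponential", "rel_rates", rate = 1))
}

# rate of the Gamma hyperprior on lambda; defaults to 0.5 * tree length
.hyper_rate <- function(spec, tree_length) {
  hr <- spec$hyperparams$hyper_rate
  if (is.null(hr)) {
    if (is.null(tree_length) || !is.finite(tree_length) || tree_length <= 0)
      stop("hierarchical_exponential prior requires a tree-length context ",
           "(or an explicit hyper_rate)")
    hr <- 0.5 * tree_length
  }
  hr
}

#' Log prior density
#'
#' Evaluates the log density of a \code{prior_spec} at \code{value}. Values
#' outside the support return \code{-Inf} (never an error). For the
#' hierarchical exponential family this is the closed-form Lomax marginal of
#' \code{mu} with the hyper-rate integrated out; the conditional
#' Exp(\code{lambda}) density used inside the MCMC is available by passing
#' \code{lambda}.
#'
#' @param spec a \code{prior_spec}.
#' @param value numeric vector of evaluation points.
#' @param tree_length total tree length T; required by \code{ctmc_reference}
#'   and by the default hierarchical hyper-rate.
#' @param lambda optional hyper-rate: evaluate the conditional
#'   Exp(\code{lambda}) density instead of the marginal (hierarchical family
#'   only).
#' @return numeric vector of log densities.
#' @export
log_prior_density <- function(spec, value, tree_length = NULL, lambda = NULL) {
  stopifnot(inherits(spec, "prior_spec"))
  hp <- spec$hyperparams
  out <- switch(spec$family,
    exponential = stats::dexp(value, rate = hp$rate, log = TRUE),
    gamma = stats::dgamma(value, shape = hp$shape, rate = hp$rate, log = TRUE),
    ctmc_reference = {
      if (is.null(tree_length) || !is.finite(tree_length) || tree_length <= 0)
        stop("ctmc_reference prior requires tree_length > 0")
      stats::dgamma(value, shape = 0.5, rate = tree_length, log = TRUE)
    },
    hierarchical_exponential = {
      if (!is.null(lambda)) {
        stats::dexp(value, rate = lambda, log = TRUE)
      } else {
        a <- hp$hyper_shape
        b <- .hyper_rate(spec, tree_length)
        # Lomax marginal: f(x) = a b^a / (b + x)^(a+1)
        ifelse(value >= 0,
               log(a) + a * log(b) - (a + 1) * log(b + value), -Inf)
      }
    },
    fixed = ifelse(value == hp$value, 0, -Inf))
  out[is.nan(out)] <- -Inf
  out
}

#' Marginal prior CDF (analytic), where closed form exists
#'
#' Used by prior-recovery diagnostics: for each supported family returns the
#' cumulative distribution function of the (marginal) prior.
#'
#' @inheritParams log_prior_density
#' @return a function of one numeric vector argument.
#' @export
prior_cdf <- function(spec, tree_length = NULL) {
  hp <- spec$hyperparams
  switch(spec$family,
    exponential = function(x) stats::pexp(x, rate = hp$rate),
    gamma = function(x) stats::pgamma(x, shape = hp$shape, rate = hp$rate),
    ctmc_reference = {
      if (is.null(tree_length) || tree_length <= 0)
        stop("ctmc_reference prior requires tree_length > 0")
      function(x) stats::pgamma(x, shape = 0.5, rate = tree_length)
    },
    hierarchical_exponential = {
      a <- hp$hyper_shape
      b <- .hyper_rate(spec, tree_length)
      function(x) ifelse(x < 0, 0, 1 - (b / (b + x))^a)
    },
    fixed = function(x) as.numeric(x >= hp$value))
}

#' Mean of the (marginal) prior, where finite and closed form
#' @inheritParams log_prior_density
#' @return numeric scalar (possibly \code{Inf}).
#' @export
prior_mean <- function(spec, tree_length = NULL) {
  hp <- spec$hyperparams
  switch(spec$family,
    exponential = 1 / hp$rate,
    gamma = hp$shape / hp$rate,
    ctmc_reference = 0.5 / tree_length,
    hierarchical_exponential = {
      a <- hp$hyper_shape
      b <- .hyper_rate(spec, tree_length)
      if (a <= 1) Inf else b / (a - 1)
    },
    fixed = hp$value)
}

#' Draw a joint model state from a set of priors
#'
#' One independent joint draw of (mu, relative rates, hyper-rate) from the
#' given prior specifications. All supported families admit direct sampling.
#'
#' @param priors named list of \code{prior_spec}, names in
#'   \code{c("mu", "rel_rates", "hyper")}; \code{rel_rates} optional.
#' @param alphabet a \code{geo_alphabet}.
#' @param tree_length total tree length (context for ctmc_reference /
#'   hierarchical defaults).
#' @param symmetric logical, rate-parameter count convention.
#' @param seed optional integer; if given, \code{set.seed(seed)} first so the
#'   draw is reproducible.
#' @return list with elements \code{mu}, \code{rel_rates},
#'   \code{hyper_lambda} (NA unless hierarchical), \code{tree_index} (1).
#' @export
sample_from_prior <- function(priors, alphabet, tree_length = NULL,
                              symmetric = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw1 <- function(spec) {
    hp <- spec$hyperparams
    switch(spec$family,
      exponential = stats::rexp(1, rate = hp$rate),
      gamma = stats::rgamma(1, shape = hp$shape, rate = hp$rate),
      ctmc_reference = {
        if (is.null(tree_length) || tree_length <= 0)
          stop("ctmc_reference prior requires tree_length > 0")
        stats::rgamma(1, shape = 0.5, rate = tree_length)
      },
      fixed = hp$value,
      stop("no direct sampler for family ", spec$family))
  }
  lambda <- NA_real_
  mu_spec <- priors$mu
  if (is.null(mu_spec)) stop("priors must include a spec for 'mu'")
  if (mu_spec$family == "hierarchical_exponential") {
    a <- mu_spec$hyperparams$hyper_shape
    b <- .hyper_rate(mu_spec, tree_length)
    lambda <- stats::rgamma(1, shape = a, rate = b)
    mu <- stats::rexp(1, rate = lambda)
  } else {
    mu <- draw1(mu_spec)
  }
  np <- count_free_rate_parameters(alphabet$k, symmetric)
  rr_spec <- priors$rel_rates
  rel_rates <- if (is.null(rr_spec)) {
    rep(1, np)
  } else if (rr_spec$family == "fixed") {
    v <- rr_spec$hyperparams$value
    if (length(v) == 1L) rep(v, np) else v
  } else {
    vapply(seq_len(np), function(i) draw1(rr_spec), numeric(1))
  }
  list(mu = mu, rel_rates = rel_rates, hyper_lambda = lambda, tree_index = 1L)
}
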