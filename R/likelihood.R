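## Exact CTMC likelihood of the geographic character on a fixed time tree
## (Felsenstein pruning), with an eigendecomposition cache so that rescaling
## the whole matrix (Q = mu * Qhat) reuses the eigenvectors.

# Eigen "factory" for a generator matrix: P(s) = Re(V exp(d s) V^-1).
# Falls back to scaling-and-squaring when V is ill-conditioned.
.q_eigen <- function(q) {
  k <- nrow(q)
  eg <- tryCatch(eigen(q), error = function(e) NULL)
  ok <- FALSE
  V <- Vi <- d <- NULL
  if (!is.null(eg)) {
    V <- eg$vectors
    d <- eg$values
    Vi <- tryCatch(solve(V), error = function(e) NULL)
    if (!is.null(Vi)) {
      # condition check: reconstruct Q and compare
      ok <- max(abs(Re(V %*% (d * Vi)) - q)) < 1e-9 * max(1, max(abs(q)))
    }
  }
  list(q = q, k = k, ok = ok, V = V, d = d, Vi = Vi)
}

# Matrix exponential by scaling and squaring with a Taylor core; only used
# as the fallback path for defective/ill-conditioned generators.
.expm_ss <- function(A) {
  nrm <- max(rowSums(abs(A)))
  r <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  As <- A / 2^r
  k <- nrow(A)
  P <- diag(k)
  term <- diag(k)
  for (i in 1:20) {
    term <- term %*% As / i
    P <- P + term
    if (max(abs(term)) < 1e-18) break
  }
  for (i in seq_len(r)) P <- P %*% P
  P
}

# Transition matrix from a cached eigendecomposition, time s (already
# includes any mu scaling). Entries clipped to [0, 1].
.p_from_eigen <- function(qe, s) {
  P <- if (qe$ok) Re(qe$V %*% (exp(qe$d * s) * qe$Vi))
       else .expm_ss(qe$q * s)
  P[P < 0] <- 0
  P[P > 1] <- 1
  P
}

#' Transition-probability matrix of a dispersal CTMC
#'
#' Computes \eqn{P(t) = e^{Qt}} by dense eigendecomposition (with a
#' scaling-and-squaring fallback for defective matrices). Rows sum to one
#' within 1e-10 and entries are clipped into [0, 1].
#'
#' @param q a k x k instantaneous-rate matrix (rows summing to zero).
#' @param t elapsed time, >= 0.
#' @return k x k probability matrix.
#' @export
transition_probabilities <- function(q, t) {
  if (t < 0) stop("time t must be >= 0")
  if (t == 0) return(diag(nrow(q)))
  qe <- .q_eigen(q)
  P <- .p_from_eigen(qe, t)
  P / rowSums(P)
}

#' Likelihood context: tree, bound tip states, rate matrix, root frequencies
#'
#' Precomputes the postorder traversal and the tip-state indicators so
#' repeated likelihood evaluations (as in MCMC) are cheap. The character data
#' may be a single tip-area mapping or a list of mappings (independent
#' characters whose log likelihoods add); the standard dataset is one
#' character, the area each sample was collected in.
#'
#' @param tree an \code{ape::phylo} time tree.
#' @param tips a \code{tip_areas} object (or list of them).
#' @param q a rate matrix (as from \code{\link{build_rate_matrix}}), or a
#'   \code{dispersal_model}.
#' @param root_freqs root-state probability vector; defaults to uniform (or
#'   to the model's frequencies when \code{q} is a model).
#' @return object of class \code{"lik_context"}.
#' @export
lik_context <- function(tree, tips, q, root_freqs = NULL) {
  if (inherits(q, "dispersal_model")) {
    if (is.null(root_freqs)) root_freqs <- q$root_freqs
    q <- build_rate_matrix(q)
  }
  k <- nrow(q)
  if (is.null(root_freqs)) root_freqs <- rep(1 / k, k)
  tips_list <- if (inherits(tips, "tip_areas")) list(tips) else tips
  nch <- length(tips_list)
  ntip <- length(tree$tip.label)
  states <- vapply(tips_list, function(tp) {
    al <- attr(tp, "alphabet")
    if (al$k != k) stop("alphabet size (", al$k,
                        ") does not match rate-matrix dimension (", k, ")")
    .bind_tips(tree, tp)
  }, integer(ntip))
  states <- matrix(states, nrow = ntip)
  po <- ape::reorder.phylo(tree, "postorder")
  structure(list(tree = po, k = k, ntip = ntip, nnode = po$Nnode,
                 nchar = nch, tip_states = states, q = q,
                 root_freqs = root_freqs, qe = .q_eigen(q)),
            class = "lik_context")
}

# Core pruning pass. qe: eigen cache of the *scaled* generator (or of the
# unit-mean generator, with mu supplied to rescale branch times).
.prune_loglik <- function(ctx, qe = ctx$qe, mu = 1) {
  tree <- ctx$tree
  k <- ctx$k
  nch <- ctx$nchar
  ntot <- ctx$ntip + ctx$nnode
  partial <- vector("list", ntot)
  for (i in seq_len(ctx$ntip)) {
    m <- matrix(0, k, nch)
    m[cbind(ctx$tip_states[i, ], seq_len(nch))] <- 1
    partial[[i]] <- m
  }
  logscale <- 0
  parents <- tree$edge[, 1]
  children <- tree$edge[, 2]
  elen <- tree$edge.length
  for (e in seq_along(parents)) {
    p <- parents[e]; ch <- children[e]
    P <- .p_from_eigen(qe, mu * elen[e])
    contrib <- P %*% partial[[ch]]
    if (is.null(partial[[p]])) partial[[p]] <- contrib
    else partial[[p]] <- partial[[p]] * contrib
    partial[[ch]] <- NA  # free
    # rescale once the node's partial could underflow
    mx <- max(partial[[p]])
    if (mx < 1e-140) {
      partial[[p]] <- partial[[p]] / mx
      logscale <- logscale + log(mx)
    }
  }
  root <- ctx$ntip + 1L
  site_l <- colSums(ctx$root_freqs * partial[[root]])
  sum(log(site_l)) + logscale
}

#' Log likelihood of the geographic character(s) on the tree
#'
#' Felsenstein pruning over the fixed time tree: the exact log probability of
#' the observed tip areas under the dispersal CTMC, with per-node rescaling
#' against underflow.
#'
#' @param ctx a \code{\link{lik_context}}.
#' @return finite numeric log likelihood.
#' @export
tree_log_likelihood <- function(ctx) {
  stopifnot(inherits(ctx, "lik_context"))
  .prune_loglik(ctx)
}

#' Powered log likelihood
#'
#' \code{beta * tree_log_likelihood(ctx)}: the log of the likelihood raised
#' to the power beta. Integer beta equals the likelihood of beta literal
#' copies of the dataset (data cloning); beta = 0 gives the prior-only
#' target; beta in (0, 1) gives the power-posterior rungs used for marginal
#' likelihoods.
#'
#' @param ctx a \code{\link{lik_context}}.
#' @param beta power on the likelihood, >= 0.
#' @return numeric.
#' @export
powered_log_likelihood <- function(ctx, beta) {
  if (beta < 0) stop("beta must be >= 0")
  if (beta == 0) return(0)
  beta * tree_log_likelihood(ctx)
}

#' Exhaustive-summation likelihood oracle (small trees only)
#'
#' Sums the joint probability over every assignment of states to internal
#' nodes explicitly. Exponential in the number of internal nodes, so it
#' refuses trees with more than 5 of them; intended purely as an independent
#' check of the pruning likelihood.
#'
#' @param ctx a \code{\link{lik_context}} with at most 5 internal nodes.
#' @return numeric log likelihood.
#' @export
brute_force_log_likelihood <- function(ctx) {
  stopifnot(inherits(ctx, "lik_context"))
  if (ctx$nnode > 5L)
    stop("brute-force oracle refuses trees with more than 5 internal nodes")
  tree <- ctx$tree
  k <- ctx$k
  # transition matrix per edge
  Pl <- lapply(seq_len(nrow(tree$edge)),
               function(e) .p_from_eigen(ctx$qe, tree$edge.length[e]))
  root <- ctx$ntip + 1L
  internal <- root:(ctx$ntip + ctx$nnode)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  total_ll <- 0
  for (s in seq_len(ctx$nchar)) {
    state_of <- function(node, assign) {
      if (node <= ctx$ntip) ctx$tip_states[node, s]
      else assign[match(node, internal)]
    }
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      assign <- grid[g, ]
      p <- ctx$root_freqs[assign[1]]
      for (e in seq_len(nrow(tree$edge))) {
        a <- state_of(tree$edge[e, 1], assign)
        b <- state_of(tree$edge[e, 2], assign)
        p <- p * Pl[[e]][a, b]
      }
      tot <- tot + p
    }
    total_ll <- total_ll + log(tot)
  }
  total_ll
}
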