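## Stochastic mapping of dispersal histories conditional on tip areas:
## exact joint sampling of node states from the pruning partials, then
## endpoint-conditioned CTMC paths on every branch by uniformization.

#' Sample internal-node areas from their joint conditional distribution
#'
#' Computes the pruning partials, draws the root area from its posterior
#' distribution given the tips, then walks the tree in preorder drawing each
#' node's area conditional on its parent's.
#'
#' @param ctx a \code{\link{lik_context}} (single character).
#' @param seed optional integer seed.
#' @return integer vector of area indices for all nodes (tips then internal,
#'   ape numbering); tip entries equal the observed states.
#' @export
sample_node_states <- function(ctx, seed = NULL) {
  stopifnot(inherits(ctx, "lik_context"))
  if (!is.null(seed)) set.seed(seed)
  tree <- ctx$tree
  k <- ctx$k
  ntot <- ctx$ntip + ctx$nnode
  # partials, kept for every node
  partial <- vector("list", ntot)
  for (i in seq_len(ctx$ntip)) {
    v <- numeric(k)
    v[ctx$tip_states[i, 1]] <- 1
    partial[[i]] <- v
  }
  edges <- tree$edge
  elen <- tree$edge.length
  Pl <- lapply(seq_len(nrow(edges)),
               function(e) .p_from_eigen(ctx$qe, elen[e]))
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1]; ch <- edges[e, 2]
    contrib <- as.numeric(Pl[[e]] %*% partial[[ch]])
    partial[[p]] <- if (is.null(partial[[p]])) contrib
                    else partial[[p]] * contrib
    # joint sampling only needs relative partials per node
    partial[[p]] <- partial[[p]] / max(partial[[p]])
  }
  root <- ctx$ntip + 1L
  state <- integer(ntot)
  state[seq_len(ctx$ntip)] <- ctx$tip_states[, 1]
  w <- ctx$root_freqs * partial[[root]]
  state[root] <- sample.int(k, 1L, prob = w)
  # preorder = reverse postorder over edges
  for (e in rev(seq_len(nrow(edges)))) {
    p <- edges[e, 1]; ch <- edges[e, 2]
    if (ch <= ctx$ntip) next  # tip states observed
    w <- Pl[[e]][state[p], ] * partial[[ch]]
    state[ch] <- sample.int(k, 1L, prob = w)
  }
  state
}

#' Endpoint-conditioned CTMC path by uniformization
#'
#' Samples a dispersal path on a branch of length \code{t} that starts in
#' area \code{a} and ends in area \code{b}, by uniformization: dominating
#' rate \eqn{\Lambda = \max_i |q_{ii}|}, a Poisson number of candidate jumps
#' conditioned on the endpoints, uniform order-statistic jump times, and
#' removal of virtual self-jumps.
#'
#' @param q rate matrix.
#' @param t branch length (>= 0).
#' @param a,b start and end area indices (1-based).
#' @return matrix with columns \code{time}, \code{from}, \code{to} (possibly
#'   0 rows), times strictly increasing in (0, t).
#' @export
endpoint_conditioned_history <- function(q, t, a, b) {
  k <- nrow(q)
  if (t < 0) stop("t must be >= 0")
  empty <- matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("time", "from", "to")))
  if (t == 0) {
    if (a != b) stop("impossible endpoints: a != b on a zero-length branch")
    return(empty)
  }
  lam <- max(-diag(q))
  if (lam <= 0) {
    if (a != b) stop("impossible endpoints under a zero rate matrix")
    return(empty)
  }
  R <- diag(k) + q / lam
  # truncated uniformization series: P(N = n | a, b) proportional to
  # dpois(n, lam t) * R^n[a, b]; truncate where the Poisson tail is < 1e-12
  nmax <- max(4L, stats::qpois(1 - 1e-12, lam * t) + 2L)
  Rpow <- vector("list", nmax + 1L)
  Rpow[[1]] <- diag(k)
  for (i in seq_len(nmax)) Rpow[[i + 1L]] <- Rpow[[i]] %*% R
  terms <- vapply(0:nmax, function(n)
    stats::dpois(n, lam * t) * Rpow[[n + 1L]][a, b], numeric(1))
  pab <- sum(terms)
  if (pab <= 0) stop("impossible endpoint pair: P(t)[a,b] = 0")
  n <- sample.int(nmax + 1L, 1L, prob = terms) - 1L
  if (n == 0L) return(empty)
  times <- sort(stats::runif(n, 0, t))
  states <- integer(n + 1L)
  states[1] <- a
  for (i in seq_len(n)) {
    if (i == n) {
      w <- R[states[i], b] * 1
      states[i + 1L] <- b
    } else {
      w <- R[states[i], ] * Rpow[[n - i + 1L]][, b]
      states[i + 1L] <- sample.int(k, 1L, prob = w)
    }
  }
  real <- which(states[-1] != states[-(n + 1L)])
  if (!length(real)) return(empty)
  cbind(time = times[real], from = states[real], to = states[real + 1L])
}

#' Sample a full dispersal history conditional on the tip areas
#'
#' Joint node-state draw (\code{\link{sample_node_states}}) followed by an
#' endpoint-conditioned path on every branch.
#'
#' @param ctx a \code{\link{lik_context}}.
#' @param seed optional integer seed.
#' @return object of class \code{"dispersal_history"}: list with the
#'   postorder \code{tree}, \code{node_state}, and \code{events} (one
#'   time/from/to matrix per edge, times measured from the branch start).
#' @export
sample_full_mapping <- function(ctx, seed = NULL) {
  stopifnot(inherits(ctx, "lik_context"))
  if (!is.null(seed)) set.seed(seed)
  state <- sample_node_states(ctx)
  tree <- ctx$tree
  events <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    a <- state[tree$edge[e, 1]]
    b <- state[tree$edge[e, 2]]
    events[[e]] <- endpoint_conditioned_history(ctx$q, tree$edge.length[e],
                                                a, b)
  }
  structure(list(tree = tree, node_state = state, events = events,
                 k = ctx$k),
            class = "dispersal_history")
}

#' Count dispersal events between each ordered pair of areas
#'
#' @param history a \code{dispersal_history} (from
#'   \code{\link{sample_full_mapping}}) or a list with an \code{events}
#'   element of time/from/to matrices.
#' @param k number of areas (taken from the history when present).
#' @return object of class \code{"event_count_matrix"}: k x k integer
#'   matrix, zero diagonal, with attribute \code{total}.
#' @export
count_events_by_pair <- function(history, k = history$k) {
  m <- matrix(0L, k, k)
  for (ev in history$events) {
    if (NROW(ev) == 0) next
    for (r in seq_len(nrow(ev)))
      m[ev[r, "from"], ev[r, "to"]] <- m[ev[r, "from"], ev[r, "to"]] + 1L
  }
  structure(m, total = sum(m), class = c("event_count_matrix", "matrix"))
}

#' @export
print.event_count_matrix <- function(x, ...) {
  cat("Dispersal event counts (from row to column), total",
      attr(x, "total"), "\n")
  print(unclass(x))
  invisible(x)
}

#' Posterior distribution of dispersal-event counts
#'
#' For each of \code{n_draws} posterior samples (parameters and tree index),
#' one full stochastic mapping is drawn and its events counted. Summaries
#' are returned per ordered area pair and for the total.
#'
#' @param trace posterior trace data frame.
#' @param tree_set the \code{tree_set} the trace was run on.
#' @param tips observed \code{tip_areas}.
#' @param n_draws posterior draws (<= rows of trace).
#' @param seed integer seed.
#' @param prob HPD mass for the summaries.
#' @param symmetric,root_freqs model settings matching the fit.
#' @return list: \code{pair_summary} (data frame from/to/mean/hpd),
#'   \code{total_summary}, \code{totals} (vector of per-draw totals),
#'   \code{mean_matrix}.
#' @export
posterior_event_counts <- function(trace, tree_set, tips, n_draws = 100L,
                                   seed = 1L, prob = 0.95,
                                   symmetric = FALSE, root_freqs = NULL) {
  if (n_draws > nrow(trace))
    stop("n_draws (", n_draws, ") exceeds trace length (", nrow(trace), ")")
  if (inherits(tree_set, "phylo")) tree_set <- tree_set(tree_set)
  set.seed(seed)
  al <- attr(tips, "alphabet")
  k <- al$k
  rows <- sample.int(nrow(trace), n_draws)
  counts <- array(0L, c(n_draws, k, k))
  for (d in seq_along(rows)) {
    i <- rows[d]
    model <- .model_from_trace_row(trace, i, al, symmetric, root_freqs)
    ti <- if ("tree_index" %in% names(trace)) as.integer(trace$tree_index[i])
          else 1L
    ctx <- lik_context(tree_set[[ti]], tips, model)
    cm <- count_events_by_pair(sample_full_mapping(ctx))
    counts[d, , ] <- unclass(cm)
  }
  totals <- apply(counts, 1, sum)
  pairs <- which(!diag(TRUE, k), arr.ind = TRUE)
  pair_summary <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (i == j) return(NULL)
    x <- counts[, i, j]
    h <- hpd_interval(x, prob)
    data.frame(from = al$areas[i], to = al$areas[j], mean = mean(x),
               hpd_lower = h[1], hpd_upper = h[2], stringsAsFactors = FALSE)
  }))
  ht <- hpd_interval(totals, prob)
  list(pair_summary = pair_summary,
       total_summary = data.frame(mean = mean(totals), hpd_lower = ht[1],
                                  hpd_upper = ht[2]),
       totals = totals,
       mean_matrix = apply(counts, c(2, 3), mean))
}
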