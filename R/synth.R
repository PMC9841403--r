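## Seeded synthetic fixtures: coalescent trees, simulated tip areas, and a
## jittered stand-in for a posterior tree sample. Everything is generated in
## code so no external data are ever needed.

#' Simulate a neutral coalescent time tree
#'
#' Standard n-coalescent: while j lineages remain, the waiting time to the
#' next merger is Exponential with rate choose(j, 2) / pop_size; the result
#' is ultrametric with branch lengths in units of pop_size generations.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed.
#' @param pop_size coalescent population-size scaling (> 0).
#' @return an \code{ape::phylo} ultrametric tree with tips
#'   \code{t1 ... tn}.
#' @export
simulate_coalescent_tree <- function(n_tips, seed = NULL, pop_size = 1) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rcoal(n_tips)
  tr$edge.length <- tr$edge.length * pop_size
  tr
}

#' Fixture scenario: tree + simulated tip areas + known truth
#'
#' Generates a coalescent tree, builds the true dispersal model, and
#' simulates tip areas under it, returning the truth for recovery tests.
#' With \code{one_tip_per_area = TRUE} the areas are not simulated: k is
#' forced to n_tips and each tip is assigned its own distinct area (the
#' minimal-information design in which n areas force at least n - 1
#' dispersal events).
#'
#' @param n_tips number of tips (>= 2).
#' @param k number of areas (>= 2).
#' @param mu true average dispersal rate (> 0).
#' @param seed integer seed (drives both tree and tip simulation).
#' @param symmetric logical model symmetry.
#' @param rel_rates optional true relative rates (default equal).
#' @param pop_size coalescent scaling.
#' @param one_tip_per_area logical; see above.
#' @return list of class \code{"geo_scenario"}: \code{tree}, \code{tips},
#'   \code{model} (the truth), and the generating settings.
#' @export
make_scenario <- function(n_tips = 50L, k = 3L, mu = 0.5, seed = 1L,
                          symmetric = FALSE, rel_rates = NULL,
                          pop_size = 1, one_tip_per_area = FALSE) {
  stopifnot(n_tips >= 2, k >= 2, mu > 0)
  set.seed(seed)
  tree <- ape::rcoal(n_tips)
  tree$edge.length <- tree$edge.length * pop_size
  if (one_tip_per_area) {
    k <- n_tips
    alphabet <- geo_alphabet(paste0("area", seq_len(k)))
    model <- dispersal_model(alphabet, mu = mu, rel_rates = rel_rates,
                             symmetric = symmetric)
    tips <- tip_areas(stats::setNames(alphabet$areas, tree$tip.label),
                      alphabet = alphabet)
  } else {
    alphabet <- geo_alphabet(paste0("area", seq_len(k)))
    model <- dispersal_model(alphabet, mu = mu, rel_rates = rel_rates,
                             symmetric = symmetric)
    tips <- simulate_tip_data(tree, model)
  }
  structure(list(tree = tree, tips = tips, model = model,
                 settings = list(n_tips = n_tips, k = k, mu = mu,
                                 seed = seed, symmetric = symmetric,
                                 pop_size = pop_size,
                                 one_tip_per_area = one_tip_per_area)),
            class = "geo_scenario")
}

#' @export
print.geo_scenario <- function(x, ...) {
  s <- x$settings
  cat("Synthetic scenario:", s$n_tips, "tips,", x$model$alphabet$k,
      "areas, true mu =", s$mu, "(seed", s$seed, ")\n")
  invisible(x)
}

#' Serialize a scenario's settings to JSON (and back)
#'
#' The settings fully determine the scenario (generation is seeded), so the
#' JSON round trip restores it exactly.
#'
#' @param scenario a \code{geo_scenario}.
#' @return JSON string.
#' @export
scenario_to_json <- function(scenario) {
  jsonlite::toJSON(scenario$settings, auto_unbox = TRUE, digits = NA)
}

#' @param json JSON string from \code{\link{scenario_to_json}}.
#' @rdname scenario_to_json
#' @export
scenario_from_json <- function(json) {
  s <- jsonlite::fromJSON(json)
  make_scenario(n_tips = s$n_tips, k = s$k, mu = s$mu, seed = s$seed,
                symmetric = s$symmetric, pop_size = s$pop_size,
                one_tip_per_area = s$one_tip_per_area)
}

#' Jittered stand-in for a posterior sample of trees
#'
#' \code{n_trees} copies of a base tree with every branch length multiplied
#' by an iid lognormal(0, jitter) factor; topology is preserved and
#' \code{jitter = 0} gives identical copies. A controlled test stand-in for
#' marginalizing over phylogenetic uncertainty.
#'
#' @param base_tree a \code{phylo}.
#' @param n_trees number of copies (>= 1).
#' @param jitter lognormal sd of the branch-length factors (>= 0).
#' @param seed integer seed.
#' @return a \code{tree_set}.
#' @export
make_tree_posterior_stub <- function(base_tree, n_trees, jitter = 0.1,
                                     seed = 1L) {
  if (jitter < 0) stop("jitter must be >= 0")
  set.seed(seed)
  trees <- lapply(seq_len(n_trees), function(i) {
    tr <- base_tree
    if (jitter > 0)
      tr$edge.length <- tr$edge.length *
        stats::rlnorm(length(tr$edge.length), 0, jitter)
    tr
  })
  tree_set(trees)
}
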