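#' Parse a Newick string into a rooted binary time tree
#'
#' Thin wrapper over \code{ape::read.tree} that enforces the package's
#' time-tree contract: a single rooted tree with branch lengths in time
#' units; polytomies are resolved arbitrarily (left-to-right) by inserting
#' zero-length branches, which leaves the geographic likelihood unchanged.
#'
#' @param text a Newick string.
#' @return an \code{ape::phylo} tree, rooted and binary.
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error: could not read a tree from: ",
                        substr(text, 1, 60))
  .validate_timetree(tr)
}

.validate_timetree <- function(tr) {
  if (is.null(tr$edge.length))
    stop("tree has no branch lengths; a time-calibrated tree is required")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (any(tr$edge.length < 0)) stop("negative branch lengths are not allowed")
  if (!ape::is.binary(tr)) tr <- ape::multi2di(tr, random = FALSE)
  tr
}

#' Total tree length
#'
#' Sum of all branch lengths, in tree time units. This is the T of the
#' ctmc_reference prior and of the induced event-count mean \code{mu * T}.
#'
#' @param tree an \code{ape::phylo}.
#' @return numeric scalar.
#' @export
tree_length <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  sum(tree$edge.length)
}

#' Read a tree file (single tree or posterior sample) into a tree set
#'
#' Reads one-or-more trees from a Newick file (one tree per line) or a NEXUS
#' trees block (Translate tables are honoured), discards the first
#' \code{floor(burnin_fraction * N)} trees, and checks all remaining trees
#' share the same tip set. A single-tree file yields a tree set of one and is
#' usable everywhere a summary tree is.
#'
#' @param path file path.
#' @param format \code{"newick"} or \code{"nexus"}; \code{"auto"} (default)
#'   sniffs for a \code{#NEXUS} header.
#' @param burnin_fraction fraction of initial trees to discard, in [0, 1).
#' @return object of class \code{"tree_set"}: a list of \code{phylo} trees
#'   with attribute \code{burnin_discarded}.
#' @export
read_trees <- function(path, format = c("auto", "newick", "nexus"),
                       burnin_fraction = 0) {
  format <- match.arg(format)
  if (burnin_fraction < 0 || burnin_fraction >= 1)
    stop("burnin_fraction must be in [0, 1)")
  if (format == "auto") {
    first <- toupper(trimws(readLines(path, n = 1L)))
    format <- if (startsWith(first, "#NEXUS")) "nexus" else "newick"
  }
  trees <- if (format == "nexus") ape::read.nexus(path)
           else ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (inherits(trees, "multiPhylo") && !is.null(attr(trees, "TipLabel")))
    trees <- ape::.uncompressTipLabel(trees)
  trees <- unclass(trees)
  if (length(trees) == 0L) stop("no trees found in ", path)
  drop <- floor(burnin_fraction * length(trees))
  if (drop > 0) trees <- trees[-seq_len(drop)]
  tree_set(trees, burnin_discarded = drop > 0)
}

#' Construct a tree set from a list of trees
#'
#' @param trees list of \code{phylo} trees (or a single tree).
#' @param burnin_discarded logical flag recorded on the set.
#' @return object of class \code{"tree_set"}.
#' @export
tree_set <- function(trees, burnin_discarded = FALSE) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0L) stop("tree set must be nonempty")
  trees <- lapply(trees, .validate_timetree)
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees))
    if (!identical(sort(trees[[i]]$tip.label), ref))
      stop("inconsistent tip sets across trees (tree ", i, " differs)")
  structure(trees, class = "tree_set", burnin_discarded = burnin_discarded)
}

#' @export
print.tree_set <- function(x, ...) {
  cat("Tree set:", length(x), "tree(s),", length(x[[1]]$tip.label),
      "tips; mean length", format(mean(vapply(x, tree_length, numeric(1))),
                                  digits = 4), "\n")
  invisible(x)
}

#' Read a taxon-to-area table
#'
#' Expects a tab-separated file with a header row \code{taxon<TAB>area}.
#' Alternatively pass a data frame with those columns.
#'
#' @param path file path, or a data frame.
#' @param alphabet optional \code{geo_alphabet}; by default the sorted
#'   distinct observed areas.
#' @return object of class \code{"tip_areas"}: named character vector of area
#'   labels (names are taxa) with an \code{alphabet} attribute.
#' @export
read_tip_areas <- function(path, alphabet = NULL) {
  df <- if (is.data.frame(path)) path
        else utils::read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE,
                               colClasses = "character")
  if (nrow(df) == 0L) stop("empty tip-area table")
  if (!all(c("taxon", "area") %in% names(df)))
    stop("tip-area table must have columns 'taxon' and 'area'")
  if (anyDuplicated(df$taxon))
    stop("duplicate taxon rows: ",
         paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", "))
  tip_areas(stats::setNames(df$area, df$taxon), alphabet)
}

#' Construct a tip-area mapping
#' @param x named character vector, taxon -> area.
#' @param alphabet optional \code{geo_alphabet}.
#' @return object of class \code{"tip_areas"}.
#' @export
tip_areas <- function(x, alphabet = NULL) {
  x <- stats::setNames(as.character(x), names(x))
  if (is.null(names(x)) || any(names(x) == ""))
    stop("tip areas must be a named vector (taxon -> area)")
  if (is.null(alphabet)) alphabet <- geo_alphabet(sort(unique(x)))
  missing_areas <- setdiff(unique(x), alphabet$areas)
  if (length(missing_areas))
    stop("areas not in alphabet: ", paste(missing_areas, collapse = ", "))
  structure(x, class = "tip_areas", alphabet = alphabet)
}

#' @export
print.tip_areas <- function(x, ...) {
  al <- attr(x, "alphabet")
  cat("Tip areas:", length(x), "taxa in", al$k, "areas\n")
  print(utils::head(stats::setNames(as.character(x), names(x))))
  if (length(x) > 6L) cat("...\n")
  invisible(x)
}

# Bind tip areas to a tree: integer state index per tip, in tip order.
# Errors list any taxa missing from the table.
.bind_tips <- function(tree, tips) {
  al <- attr(tips, "alphabet")
  miss <- setdiff(tree$tip.label, names(tips))
  if (length(miss))
    stop("taxa in tree but not in tip-area table: ",
         paste(miss, collapse = ", "))
  match(as.character(unclass(tips)[tree$tip.label]), al$areas)
}

## ---------------------------------------------------------------------------
## MCMC trace logs (tab-delimited, BEAST-log compatible)
## ---------------------------------------------------------------------------

#' Write an MCMC trace to a tab-delimited log file
#'
#' Format: '#'-prefixed comment header lines (the likelihood power beta is
#' recorded as \code{#beta=...}), then a header row whose first column is
#' \code{state}, then tab-separated numeric rows at full precision.
#'
#' @param trace a data frame whose first column is \code{state}, with a
#'   \code{beta} attribute (default 1 if absent).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(is.data.frame(trace))
  if (names(trace)[1] != "state") stop("trace must have first column 'state'")
  beta <- attr(trace, "beta")
  if (is.null(beta)) beta <- 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# geopriors MCMC trace",
               sprintf("#beta=%.17g", beta)), con)
  writeLines(paste(names(trace), collapse = "\t"), con)
  cols <- lapply(trace, function(col) sprintf("%.17g", as.numeric(col)))
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Read a tab-delimited MCMC trace log
#'
#' Accepts this package's logs and BEAST-style logs: '#' comment lines are
#' skipped (a \code{#beta=} line, if present, is restored as the \code{beta}
#' attribute); the first data column must be named \code{state}.
#'
#' @param path file path.
#' @return data frame with attribute \code{beta}; iterations are checked to
#'   be strictly increasing.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  beta <- 1
  bline <- grep("^#beta=", lines, value = TRUE)
  if (length(bline)) beta <- as.numeric(sub("^#beta=", "", bline[1]))
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) < 2L) stop("trace file has no data rows: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "state")
    stop("trace format error: first column must be named 'state', got '",
         header[1], "'")
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  arity <- lengths(rows)
  if (any(arity != length(header)))
    stop("ragged trace row at data line ", which(arity != length(header))[1])
  m <- matrix(as.numeric(unlist(rows)), ncol = length(header), byrow = TRUE)
  df <- as.data.frame(m)
  names(df) <- header
  if (any(diff(df$state) <= 0))
    stop("trace 'state' column must be strictly increasing")
  attr(df, "beta") <- beta
  df
}
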