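# Star-threshold filtering, one-level drug-target expansion with
# multiplicity weights, and topology-preserving network randomization.

#' Keep only interactions at or above a confidence level
#'
#' The "N Stars UP" experimental condition: edges with `stars >= minStars`
#' survive, and the node set shrinks to the endpoints of surviving edges.
#'
#' @param net a [PPINetwork-class].
#' @param minStars integer in 1..5.
#' @return A [PPINetwork-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("protein_a\tprotein_b\tstars", "A\tB\t3", "B\tC\t2"), f)
#' filterByStars(readPpiTable(f), 3)
#' @export
filterByStars <- function(net, minStars) {
  stopifnot(is(net, "PPINetwork"))
  if (length(minStars) != 1L || is.na(minStars) ||
      minStars != as.integer(minStars) || minStars < 1 || minStars > 5)
    stop("minStars must be a single integer in 1..5")
  e <- ppiEdges(net)
  e <- e[e$stars >= minStars, , drop = FALSE]
  rownames(e) <- NULL
  new("PPINetwork", edges = e,
      nodes = sort(unique(c(e$protein_a, e$protein_b))))
}

#' Expand drug targets one level into the interaction network
#'
#' For each drug the expansion "tree" has the drug at the root, its direct
#' targets as branches, and every network neighbor of each direct target as
#' leaves. The new cell value for a protein is its multiplicity in that tree
#' — a protein that is both a direct target and a neighbor of another direct
#' target counts once per occurrence. This repeat number is the weight of the
#' drug-protein relationship at the network level. Columns grow to all
#' proteins occurring for at least one drug; with an empty network the input
#' is returned unchanged (up to lexical column order).
#'
#' @param dt a binary [FactsMatrix-class] of drug-target facts.
#' @param net a [PPINetwork-class] (typically already star-filtered).
#' @return An integer-weighted [FactsMatrix-class], `featureKind = "target"`.
#' @examples
#' fm <- newFactsMatrix(matrix(c(1L, 1L), 1, 2,
#'                      dimnames = list("d1", c("A", "B"))))
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("protein_a\tprotein_b\tstars", "A\tB\t5", "B\tC\t4"), f)
#' factValues(expandOneLevel(fm, readPpiTable(f)))  # A=2 B=2 C=1
#' @export
expandOneLevel <- function(dt, net) {
  stopifnot(is(dt, "FactsMatrix"), is(net, "PPINetwork"))
  v <- factValues(dt)
  if (length(v) && !all(v %in% c(0L, 1L)))
    stop("expandOneLevel requires a binary facts matrix")
  adj <- adjacencyList(net)
  targets <- colnames(v)
  nbrOf <- adj[targets]                       # NULL for off-network targets
  names(nbrOf) <- targets
  cols <- sort(unique(c(targets, unlist(nbrOf, use.names = FALSE))))
  # per input target, a multiplicity row over the output columns:
  # itself once plus each neighbor once
  contrib <- matrix(0L, length(targets), length(cols),
                    dimnames = list(targets, cols))
  contrib[cbind(targets, targets)] <- 1L
  for (t in targets) {
    nb <- nbrOf[[t]]
    if (length(nb)) {
      tb <- table(nb)                         # defensive; neighbors unique
      contrib[t, names(tb)] <- contrib[t, names(tb)] + as.integer(tb)
    }
  }
  out <- v %*% contrib
  newFactsMatrix(out, featureKind = "target")
}

#' Randomize a network while preserving its topology
#'
#' Returns a network with the identical abstract graph — the same adjacency
#' structure and star values — whose protein identities are a uniform random
#' permutation of the original labels. Used as the control condition: any
#' predictive signal surviving randomization is attributable to topology and
#' the retained drug-target facts, not to which proteins interact.
#'
#' @param net a [PPINetwork-class].
#' @param seed integer seed for the label permutation.
#' @return A [PPINetwork-class] over the same node set.
#' @export
randomizeNetwork <- function(net, seed) {
  stopifnot(is(net, "PPINetwork"))
  nodes <- ppiNodes(net)
  if (length(nodes) < 2L) return(net)
  relabel <- withr::with_seed(as.integer(seed),
                              stats::setNames(sample(nodes), nodes))
  e <- ppiEdges(net)
  newPPINetwork(relabel[e$protein_a], relabel[e$protein_b], e$stars)
}
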