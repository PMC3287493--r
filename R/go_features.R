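# GO term levels, "LvN threshold" features and "level-N rollup" features.

#' Compute GO term levels
#'
#' The level of a term is 1 plus the length of its shortest `is_a` path to
#' the root; the root ("biological process") is level 1. Shortest-path depth
#' is used because in a DAG a term can sit at several depths; the minimum is
#' deterministic.
#'
#' @param dag a [GODag-class].
#' @return Named integer vector, term id -> level.
#' @export
computeLevels <- function(dag) {
  stopifnot(is(dag, "GODag"))
  ids <- dag@terms
  edges <- data.frame(
    child = rep(ids, lengths(dag@parents[ids])),
    parent = unlist(dag@parents[ids], use.names = FALSE))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = ids)
  d <- igraph::distances(g, v = ids, to = dag@root, mode = "out")[, 1]
  if (any(!is.finite(d)))
    stop(sprintf("structural error: term(s) unreachable from root: %s",
                 paste(ids[!is.finite(d)], collapse = ", ")))
  stats::setNames(as.integer(d) + 1L, ids)
}

# drug x term counts from a protein -> term-set map: cell (drug, term) =
# number of the drug's direct targets whose set contains the term.
countsFromTermSets <- function(dt, termSets) {
  v <- factValues(dt)
  targets <- colnames(v)
  sets <- termSets[targets]
  names(sets) <- targets
  cols <- sort(unique(unlist(sets, use.names = FALSE)))
  ind <- matrix(0L, length(targets), length(cols),
                dimnames = list(targets, cols))
  for (t in targets) {
    s <- sets[[t]]
    if (length(s)) ind[t, s] <- 1L
  }
  newFactsMatrix(v %*% ind, featureKind = "go_term")
}

#' GO features at or below a depth threshold ("LvN")
#'
#' Feature columns are the GO terms of level `>= minLevel` directly
#' annotating at least one target in `dt`; the cell for (drug, term) counts
#' how many of the drug's direct targets carry that annotation.
#'
#' @param dt binary drug-target [FactsMatrix-class].
#' @param dag a [GODag-class].
#' @param levels named level vector from [computeLevels()].
#' @param minLevel minimum term level kept (1 keeps every annotated term).
#' @return A [FactsMatrix-class] with `featureKind = "go_term"`.
#' @export
thresholdFeatures <- function(dt, dag, levels, minLevel) {
  stopifnot(is(dt, "FactsMatrix"), is(dag, "GODag"), minLevel >= 1)
  keep <- names(levels)[levels >= minLevel]
  sets <- lapply(dag@annotations, function(s) intersect(s, keep))
  countsFromTermSets(dt, sets)
}

# Strict-ancestor closure of `term` filtered to exactly `level`, memoized.
# The closure follows every parent link: in a DAG a level-N ancestor may be
# reachable through an intermediate term whose own level is < N, so no
# pruning by intermediate levels.
levelAncestorClosure <- function(term, level, parents, levels, cache) {
  hit <- get0(term, envir = cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  res <- unique(unlist(lapply(parents[[term]], function(p) {
    c(if (levels[[p]] == level) p,
      levelAncestorClosure(p, level, parents, levels, cache))
  }), use.names = FALSE))
  if (is.null(res)) res <- character(0)
  cache[[term]] <- res
  res
}

# Rollup transform of a single annotated term: kept at the roll level,
# dropped below it, replaced by its level-N ancestor set above it.
ancestorsAtLevel <- function(term, level, parents, levels, cache) {
  if (levels[[term]] == level) return(term)
  if (levels[[term]] < level) return(character(0))
  levelAncestorClosure(term, level, parents, levels, cache)
}

#' GO features rolled up to a fixed depth ("LvN roll up")
#'
#' Every annotation deeper than `rollLevel` is replaced by all of its
#' ancestors at exactly `rollLevel`; annotations already at that level are
#' kept, shallower ones dropped. The transformed term set is deduplicated
#' per target, so a cell still reads as "number of the drug's targets
#' supporting this term". `rollLevel = 1` collapses everything onto the root.
#'
#' @inheritParams thresholdFeatures
#' @param rollLevel the level annotations are rolled up to.
#' @return A [FactsMatrix-class] with `featureKind = "go_term"`.
#' @export
rollupFeatures <- function(dt, dag, levels, rollLevel) {
  stopifnot(is(dt, "FactsMatrix"), is(dag, "GODag"), rollLevel >= 1)
  cache <- new.env(parent = emptyenv())
  sets <- lapply(dag@annotations, function(s) {
    unique(unlist(lapply(s, ancestorsAtLevel, level = rollLevel,
                         parents = dag@parents, levels = levels,
                         cache = cache),
                  use.names = FALSE))
  })
  countsFromTermSets(dt, sets)
}
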