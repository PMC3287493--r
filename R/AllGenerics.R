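#' Accessors for adrnet classes
#'
#' Small accessor generics so that slots are never reached into directly:
#' `drugIds()` and `featureIds()` return the row/column identities of a
#' [FactsMatrix-class], `factValues()` its integer matrix, `classLabels()`
#' the 0/1 vector of an [ADRClassLabels-class], `ppiEdges()` / `ppiNodes()`
#' the edge table and node set of a [PPINetwork-class], `pairTable()` the
#' pair data frame of the association maps, `icdEntries()` the ADR-to-ICD-10
#' table, `cvPredictions()` / `cvMetrics()` the two tables of a
#' [CVResult-class].
#'
#' @param x an adrnet object.
#' @return the corresponding slot content (see Description).
#' @name accessors
#' @aliases drugIds featureIds factValues featureKind classLabels ppiEdges
#'   ppiNodes pairTable icdEntries cvPredictions cvMetrics
#' @examples
#' fm <- newFactsMatrix(matrix(0:1, 1, 2, dimnames = list("d1", c("A", "B"))))
#' drugIds(fm); featureIds(fm)
NULL

#' @rdname accessors
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))
#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname accessors
#' @export
setGeneric("factValues", function(x) standardGeneric("factValues"))
#' @rdname accessors
#' @export
setGeneric("featureKind", function(x) standardGeneric("featureKind"))
#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setGeneric("ppiEdges", function(x) standardGeneric("ppiEdges"))
#' @rdname accessors
#' @export
setGeneric("ppiNodes", function(x) standardGeneric("ppiNodes"))
#' @rdname accessors
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))
#' @rdname accessors
#' @export
setGeneric("icdEntries", function(x) standardGeneric("icdEntries"))
#' @rdname accessors
#' @export
setGeneric("cvPredictions", function(x) standardGeneric("cvPredictions"))
#' @rdname accessors
#' @export
setGeneric("cvMetrics", function(x) standardGeneric("cvMetrics"))

#' @rdname accessors
setMethod("drugIds", "FactsMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("drugIds", "ADRClassLabels", function(x) x@drugIds)
#' @rdname accessors
setMethod("featureIds", "FactsMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("factValues", "FactsMatrix", function(x) x@values)
#' @rdname accessors
setMethod("featureKind", "FactsMatrix", function(x) x@featureKind)
#' @rdname accessors
setMethod("classLabels", "ADRClassLabels", function(x) {
  stats::setNames(x@labels, x@drugIds)
})
#' @rdname accessors
setMethod("ppiEdges", "PPINetwork", function(x) x@edges)
#' @rdname accessors
setMethod("ppiNodes", "PPINetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("pairTable", "DrugTargetMap", function(x) x@pairs)
#' @rdname accessors
setMethod("pairTable", "DrugADRMap", function(x) x@pairs)
#' @rdname accessors
setMethod("icdEntries", "ADRIcdMap", function(x) x@entries)
#' @rdname accessors
setMethod("cvPredictions", "CVResult", function(x) x@predictions)
#' @rdname accessors
setMethod("cvMetrics", "CVResult", function(x) x@metrics)

setMethod("show", "DrugTargetMap", function(object) {
  cat(sprintf("DrugTargetMap: %d pairs, %d drugs, %d targets\n",
              nrow(object@pairs), length(unique(object@pairs$drug_id)),
              length(unique(object@pairs$protein_id))))
})

setMethod("show", "DrugADRMap", function(object) {
  cat(sprintf("DrugADRMap: %d pairs, %d drugs, %d ADR names\n",
              nrow(object@pairs), length(unique(object@pairs$drug_id)),
              length(unique(object@pairs$adr_name))))
})

setMethod("show", "ADRIcdMap", function(object) {
  cat(sprintf("ADRIcdMap: %d ADR names mapped to ICD-10 codes\n",
              nrow(object@entries)))
})

setMethod("show", "PPINetwork", function(object) {
  st <- if (nrow(object@edges)) {
    tb <- table(factor(object@edges$stars, levels = 1:5))
    paste(sprintf("%d×%s", as.integer(tb), names(tb)), collapse = ", ")
  } else "none"
  cat(sprintf("PPINetwork: %d proteins, %d edges (stars: %s)\n",
              length(object@nodes), nrow(object@edges), st))
})

setMethod("show", "GODag", function(object) {
  cat(sprintf(
    "GODag: %d biological_process terms, root %s, %d annotated proteins\n",
    length(object@terms), object@root, length(object@annotations)))
})

setMethod("show", "FactsMatrix", function(object) {
  v <- object@values
  cat(sprintf("FactsMatrix [%s]: %d drugs × %d features (%s)\n",
              object@featureKind, nrow(v), ncol(v),
              if (length(v) && all(v %in% c(0, 1))) "binary"
              else "integer weights"))
})

setMethod("show", "ADRClassLabels", function(object) {
  cat(sprintf("ADRClassLabels: %d drugs, %d positive (%.1f%%)\n",
              length(object@labels), sum(object@labels),
              if (length(object@labels)) 100 * mean(object@labels) else 0))
})

setMethod("show", "ModelSpec", function(object) {
  h <- object@hyperparameters
  hp <- if (length(h)) paste(names(h), vapply(h, function(v)
    if (is.null(v)) "auto" else format(v), character(1)),
    sep = "=", collapse = ", ") else "defaults"
  cat(sprintf("ModelSpec: %s (%s)\n", object@family, hp))
})

setMethod("show", "CVResult", function(object) {
  m <- object@metrics
  cat(sprintf("CVResult: %d repeats × %d folds, median AUC %.3f\n",
              length(unique(m$repeat_id)),
              length(unique(object@predictions$fold)),
              stats::median(m$auc)))
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(
    paste0("SynthConfig: %d drugs, %d proteins in %d modules (%d toxic), ",
           "GO depth %d, noise %.2f, seed %d\n"),
    object@nDrugs, object@nProteins, object@nModules, object@toxicModules,
    object@goDepth, object@labelNoise, object@seed))
})
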