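#' @import methods
NULL

## ---------------------------------------------------------------------------
## Input tables
## ---------------------------------------------------------------------------

#' Drug-target association table
#'
#' Holds the deduplicated set of (drug, protein target) pairs extracted from a
#' DrugBank-like flat export. Rows of the underlying data frame are unique
#' pairs; the matrix of drug-target facts is built from this object with
#' [buildTargetFacts()].
#'
#' @slot pairs data.frame with character columns `drug_id` and `protein_id`.
#' @seealso [readDrugTargetTable()], [buildTargetFacts()]
#' @export
setClass("DrugTargetMap", representation(pairs = "data.frame"))

setValidity("DrugTargetMap", function(object) {
  p <- object@pairs
  if (!identical(colnames(p), c("drug_id", "protein_id")))
    return("pairs must have columns drug_id, protein_id")
  if (anyDuplicated(p)) return("duplicate drug-target pairs")
  if (nrow(p) && (any(!nzchar(p$drug_id)) || any(!nzchar(p$protein_id))))
    return("empty drug_id or protein_id")
  TRUE
})

#' Drug-ADR association table
#'
#' Deduplicated (drug, adverse-reaction name) pairs from a SIDER-like flat
#' export. ADR names are canonicalized (whitespace squeezed, case-folded) so
#' that label joins against an [ADRIcdMap-class] are insensitive to casing.
#'
#' @slot pairs data.frame with character columns `drug_id` and `adr_name`
#'   (canonical form).
#' @seealso [readDrugAdrTable()], [buildAdrClassLabels()]
#' @export
setClass("DrugADRMap", representation(pairs = "data.frame"))

setValidity("DrugADRMap", function(object) {
  p <- object@pairs
  if (!identical(colnames(p), c("drug_id", "adr_name")))
    return("pairs must have columns drug_id, adr_name")
  if (anyDuplicated(p)) return("duplicate drug-ADR pairs")
  if (nrow(p) && (any(!nzchar(p$drug_id)) || any(!nzchar(p$adr_name))))
    return("empty drug_id or adr_name")
  TRUE
})

#' ADR name to ICD-10 code map
#'
#' One ICD-10 code per adverse-reaction name. Codes follow the ICD-10 lexical
#' pattern (letter + two digits + optional decimal sub-code, e.g. `I46` or
#' `I08.8`) or a category range such as `I30-I52`; a range sorts by its lower
#' bound. The packaged cardiotoxicity map ships in
#' `system.file("extdata", "cardiotoxicity_icd10.tsv", package = "adrnet")`.
#'
#' @slot entries data.frame with columns `adr_name` (display form), `icd10`
#'   and `canonical` (case-folded join key).
#' @seealso [readIcd10Table()], [buildAdrClassLabels()]
#' @export
setClass("ADRIcdMap", representation(entries = "data.frame"))

setValidity("ADRIcdMap", function(object) {
  e <- object@entries
  if (!all(c("adr_name", "icd10", "canonical") %in% colnames(e)))
    return("entries must have columns adr_name, icd10, canonical")
  if (anyDuplicated(e$canonical)) return("more than one code for an ADR name")
  bad <- !vapply(e$icd10, isIcd10Code, logical(1))
  if (any(bad))
    return(paste0("malformed ICD-10 code(s): ",
                  paste(e$icd10[bad], collapse = ", ")))
  TRUE
})

## ---------------------------------------------------------------------------
## Networks and ontology
## ---------------------------------------------------------------------------

#' Protein-protein interaction network with confidence stars
#'
#' Undirected protein graph in which every edge carries an integer confidence
#' star rating from 1 (low confidence, mostly functional association) to 5
#' (high confidence, mostly physical interaction). Self-interactions are never
#' stored; when an unordered pair is reported more than once the maximum star
#' value is kept. The node set is the set of edge endpoints.
#'
#' @slot edges data.frame with columns `protein_a`, `protein_b` (character,
#'   with `protein_a < protein_b`) and `stars` (integer 1..5).
#' @slot nodes character vector of protein ids.
#' @seealso [readPpiTable()], [filterByStars()], [expandOneLevel()],
#'   [randomizeNetwork()]
#' @export
setClass("PPINetwork",
         representation(edges = "data.frame", nodes = "character"))

setValidity("PPINetwork", function(object) {
  e <- object@edges
  if (!identical(colnames(e), c("protein_a", "protein_b", "stars")))
    return("edges must have columns protein_a, protein_b, stars")
  if (nrow(e)) {
    if (any(e$protein_a == e$protein_b)) return("self-edges are not allowed")
    if (any(e$protein_a > e$protein_b))
      return("edges must be stored with protein_a < protein_b")
    if (anyDuplicated(e[, c("protein_a", "protein_b")]))
      return("duplicate unordered edges")
    if (any(e$stars < 1L | e$stars > 5L) || !is.integer(e$stars))
      return("stars must be integers in 1..5")
  }
  if (!setequal(object@nodes, unique(c(e$protein_a, e$protein_b))) &&
      nrow(e) > 0)
    return("nodes must be the set of edge endpoints")
  TRUE
})

#' Gene Ontology biological-process DAG with protein annotations
#'
#' A rooted, acyclic `is_a` hierarchy restricted to the biological_process
#' namespace, plus direct protein-to-term annotations. The root (the term with
#' no parents) is at level 1; [computeLevels()] assigns every other term the
#' length of its shortest `is_a` path to the root plus one.
#'
#' @slot terms character vector of GO term ids.
#' @slot termNames named character vector, term id -> human-readable name.
#' @slot parents named list, term id -> character vector of `is_a` parents.
#' @slot root the single parentless term id.
#' @slot annotations named list, protein id -> character vector of directly
#'   annotated term ids.
#' @seealso [readObo()], [computeLevels()], [thresholdFeatures()],
#'   [rollupFeatures()]
#' @export
setClass("GODag",
         representation(terms = "character", termNames = "character",
                        parents = "list", root = "character",
                        annotations = "list"))

setValidity("GODag", function(object) {
  if (length(object@root) != 1L) return("exactly one root required")
  if (!object@root %in% object@terms) return("root not among terms")
  if (!all(names(object@parents) %in% object@terms))
    return("parent links for unknown terms")
  if (!all(unlist(object@parents) %in% object@terms))
    return("parent term not in DAG")
  if (length(object@parents[[object@root]]))
    return("root must have no parents")
  ann <- unlist(object@annotations, use.names = FALSE)
  if (length(ann) && !all(ann %in% object@terms))
    return("annotation to a term absent from the DAG")
  TRUE
})

## ---------------------------------------------------------------------------
## Facts and labels
## ---------------------------------------------------------------------------

#' Drug-by-feature facts matrix
#'
#' The central exchange object of the pipeline: a non-negative integer matrix
#' with drugs as rows and features as columns. Built directly from drug-target
#' pairs the matrix is binary (drug n docks target k); after one-level network
#' expansion or GO annotation the cells are integer multiplicities ("repeat
#' numbers") weighting the drug-feature relationship.
#'
#' @slot values non-negative integer matrix; rownames are drug ids, colnames
#'   feature ids.
#' @slot featureKind one of `"target"`, `"go_term"`, `"adr"`.
#' @seealso [buildTargetFacts()], [expandOneLevel()], [thresholdFeatures()],
#'   [rollupFeatures()]
#' @export
setClass("FactsMatrix",
         representation(values = "matrix", featureKind = "character"))

setValidity("FactsMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (any(v < 0)) return("values must be non-negative")
  if (is.null(rownames(v))) return("rownames (drug ids) required")
  if (ncol(v) > 0 && is.null(colnames(v)))
    return("colnames (feature ids) required")
  if (anyDuplicated(rownames(v))) return("duplicate drug ids")
  if (ncol(v) && anyDuplicated(colnames(v))) return("duplicate feature ids")
  if (!object@featureKind %in% c("target", "go_term", "adr"))
    return("featureKind must be 'target', 'go_term' or 'adr'")
  TRUE
})

#' Binary ADR-class labels over a drug universe
#'
#' One label per drug: 1 if the drug has at least one adverse reaction whose
#' ICD-10 category falls in the class code range (e.g. I00-I99 for
#' circulatory-system disease, the cardiotoxicity class), else 0.
#'
#' @slot drugIds ordered character vector of drug ids.
#' @slot labels integer vector in {0,1}, aligned to `drugIds`.
#' @seealso [buildAdrClassLabels()]
#' @export
setClass("ADRClassLabels",
         representation(drugIds = "character", labels = "integer"))

setValidity("ADRClassLabels", function(object) {
  if (length(object@drugIds) != length(object@labels))
    return("drugIds and labels lengths differ")
  if (anyDuplicated(object@drugIds)) return("duplicate drug ids")
  if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
    return("labels must be 0/1")
  TRUE
})

## ---------------------------------------------------------------------------
## Modeling
## ---------------------------------------------------------------------------

#' Classifier specification
#'
#' @slot family `"svm_rbf"` (Gaussian radial-basis-function kernel SVM with
#'   fitted class probabilities) or `"logistic"` (unpenalized logistic
#'   regression).
#' @slot hyperparameters named list; for `svm_rbf`: `cost` (> 0, default 1)
#'   and optional `gamma` (> 0, default 1 / number of features at fit time).
#' @seealso [modelSpec()], [crossValidate()]
#' @export
setClass("ModelSpec",
         representation(family = "character", hyperparameters = "list"))

setValidity("ModelSpec", function(object) {
  if (!object@family %in% c("svm_rbf", "logistic"))
    return(sprintf("unknown model family '%s'", object@family))
  h <- object@hyperparameters
  if (!is.null(h$cost) && h$cost <= 0) return("cost must be > 0")
  if (!is.null(h$gamma) && h$gamma <= 0) return("gamma must be > 0")
  TRUE
})

#' Model specification constructor
#'
#' @param family `"svm_rbf"` or `"logistic"`.
#' @param cost SVM soft-margin cost (> 0).
#' @param gamma optional RBF kernel width; defaults to 1 / number of features
#'   at fit time when `NULL`.
#' @return A [ModelSpec-class] object.
#' @examples
#' modelSpec("svm_rbf", cost = 1)
#' modelSpec("logistic")
#' @export
modelSpec <- function(family = c("svm_rbf", "logistic"), cost = 1,
                      gamma = NULL) {
  family <- match.arg(family)
  h <- if (family == "svm_rbf") list(cost = cost, gamma = gamma) else list()
  new("ModelSpec", family = family, hyperparameters = h)
}

#' Repeated cross-validation result
#'
#' Out-of-fold predicted probabilities for every drug in every repeat, plus
#' per-repeat performance pooled over that repeat's validation folds (one ROC
#' from all out-of-fold predictions of the repeat).
#'
#' @slot predictions data.frame with columns `repeat_id`, `fold`, `drug_id`,
#'   `label`, `prob`.
#' @slot metrics data.frame with columns `repeat_id`, `auc`, `acc`, `sen`,
#'   `spe`.
#' @seealso [crossValidate()], [summarizeCV()]
#' @export
setClass("CVResult",
         representation(predictions = "data.frame", metrics = "data.frame"))

setValidity("CVResult", function(object) {
  p <- object@predictions
  need <- c("repeat_id", "fold", "drug_id", "label", "prob")
  if (!all(need %in% colnames(p)))
    return("predictions missing required columns")
  if (nrow(p)) {
    if (any(p$prob < 0 | p$prob > 1)) return("probabilities outside [0,1]")
    once <- tapply(p$drug_id, p$repeat_id, anyDuplicated)
    if (any(unlist(once) > 0))
      return("a drug appears in more than one validation fold of a repeat")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Synthetic data
## ---------------------------------------------------------------------------

#' Configuration of the planted-mechanism synthetic-data generator
#'
#' See [generateDataset()] for the generative model. Defaults describe a
#' modular protein interactome of 300 proteins in 12 modules (2 toxic), dense
#' high-confidence interactions within modules and sparse low-confidence ones
#' between, 200 drugs with 1-5 targets each, a depth-7 biological-process
#' ontology whose deep terms are module-specific, and 5% label noise.
#'
#' @slot nDrugs,nProteins,nModules,toxicModules integer sizes.
#' @slot targetsPerDrug integer range (min, max) of targets sampled per drug.
#' @slot pEdgeWithin,pEdgeBetween within- / between-module edge probabilities.
#' @slot starsWithin,starsBetween length-5 probability vectors over star
#'   ratings 1..5 for within- and between-module edges.
#' @slot goDepth depth of the generated ontology (root = level 1).
#' @slot labelNoise probability that a ground-truth label is flipped.
#' @slot seed integer seed driving all sampling.
#' @seealso [synthConfig()], [generateDataset()]
#' @export
setClass("SynthConfig",
         representation(nDrugs = "integer", nProteins = "integer",
                        nModules = "integer", toxicModules = "integer",
                        targetsPerDrug = "integer",
                        pEdgeWithin = "numeric", pEdgeBetween = "numeric",
                        starsWithin = "numeric", starsBetween = "numeric",
                        goDepth = "integer", labelNoise = "numeric",
                        seed = "integer"))

setValidity("SynthConfig", function(object) {
  if (object@toxicModules > object@nModules)
    return("toxicModules must be <= nModules")
  if (length(object@targetsPerDrug) != 2L ||
      object@targetsPerDrug[1] < 1L ||
      object@targetsPerDrug[2] > object@nProteins ||
      object@targetsPerDrug[1] > object@targetsPerDrug[2])
    return("targetsPerDrug must be a range within [1, nProteins]")
  pr <- c(object@pEdgeWithin, object@pEdgeBetween, object@labelNoise)
  if (any(pr < 0 | pr > 1)) return("probabilities must lie in [0,1]")
  for (s in list(object@starsWithin, object@starsBetween))
    if (length(s) != 5L || any(s < 0) || abs(sum(s) - 1) > 1e-8)
      return("star distributions must be length-5 probability vectors")
  if (object@goDepth < 2L) return("goDepth must be >= 2")
  TRUE
})

#' Synthetic-data configuration constructor
#'
#' @param nDrugs,nProteins,nModules,toxicModules,targetsPerDrug,pEdgeWithin,pEdgeBetween,starsWithin,starsBetween,goDepth,labelNoise,seed
#'   see [SynthConfig-class]; defaults are the package's reference study
#'   conditions.
#' @return A validated [SynthConfig-class].
#' @examples
#' cfg <- synthConfig(nDrugs = 50, seed = 7)
#' @export
synthConfig <- function(nDrugs = 200, nProteins = 300, nModules = 12,
                        toxicModules = 2, targetsPerDrug = c(1, 5),
                        pEdgeWithin = 0.3, pEdgeBetween = 0.01,
                        starsWithin = c(0.05, 0.10, 0.15, 0.30, 0.40),
                        starsBetween = c(0.40, 0.30, 0.15, 0.10, 0.05),
                        goDepth = 7, labelNoise = 0.05, seed = 42) {
  new("SynthConfig", nDrugs = as.integer(nDrugs),
      nProteins = as.integer(nProteins), nModules = as.integer(nModules),
      toxicModules = as.integer(toxicModules),
      targetsPerDrug = as.integer(targetsPerDrug),
      pEdgeWithin = pEdgeWithin, pEdgeBetween = pEdgeBetween,
      starsWithin = starsWithin, starsBetween = starsBetween,
      goDepth = as.integer(goDepth), labelNoise = labelNoise,
      seed = as.integer(seed))
}
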