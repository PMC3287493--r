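# Generator of DrugBank/SIDER/HAPPI/GO-shaped datasets with a planted,
# network- and annotation-mediated toxicity mechanism.

writeObo <- function(dag, path) {
  con <- file(path, open = "wb")  # "wb": byte-identical output across OSes
  on.exit(close(con))
  out <- c("format-version: 1.2", "")
  for (id in dag@terms) {
    stanza <- c("[Term]",
                paste0("id: ", id),
                paste0("name: ", dag@termNames[[id]]),
                "namespace: biological_process")
    for (p in dag@parents[[id]])
      stanza <- c(stanza,
                  paste0("is_a: ", p, " ! ", dag@termNames[[p]]))
    out <- c(out, stanza, "")
  }
  writeLines(out, con)
  invisible(path)
}

#' Generate a synthetic drug-safety dataset with a planted mechanism
#'
#' Emulates the shapes of the five pipeline inputs without any external
#' database. Proteins are partitioned into modules; interactions are sampled
#' densely within modules (star ratings skewed high — co-module interactions
#' stand in for well-attested physical PPIs) and sparsely between modules
#' (stars skewed low). A biological-process ontology of depth `goDepth` is
#' grown with shared shallow branches and one module-specific chain per
#' module; every protein is annotated with its module's deepest term (plus
#' occasional shared shallow noise annotations). Each drug samples targets
#' uniformly.
#'
#' The planted mechanism: a drug is toxic (pre-noise) iff at least one
#' target lies in a toxic module **or** is a direct interaction neighbor of
#' a toxic-module protein. Toxicity thus propagates exactly one interaction
#' hop — recoverable by one-level network expansion (and, through the
#' module-specific deep terms, by GO features), but only partially by the
#' raw target matrix. Labels are flipped with probability `labelNoise`;
#' toxic drugs receive an adverse-reaction name mapping to ICD-10 I99
#' (in the circulatory range), all drugs share a benign out-of-range ADR.
#'
#' @param cfg a [SynthConfig-class] (see [synthConfig()] for defaults).
#' @param outDir optional directory; when given, the six input files
#'   (`drug_targets.tsv`, `drug_adr.tsv`, `adr_icd10.tsv`, `ppi.tsv`,
#'   `annotations.tsv`, `ontology.obo`) and the truth record `truth.tsv`
#'   (columns `drug_id`, `label_prenoise`, `label`, `mechanism` in
#'   direct/one_hop/none) are written there, byte-identically for a given
#'   seed.
#' @return Invisibly, a list with the in-memory objects: `targets`
#'   ([DrugTargetMap-class]), `adrs` ([DrugADRMap-class]), `icd`
#'   ([ADRIcdMap-class]), `net` ([PPINetwork-class]), `dag`
#'   ([GODag-class]), `truth` (data.frame), `moduleOf` (named integer
#'   vector), and `files` (named paths, or `NULL`).
#' @examples
#' d <- generateDataset(synthConfig(nDrugs = 30, nProteins = 60,
#'                                  nModules = 6, seed = 7))
#' d$net
#' table(d$truth$mechanism)
#' @export
generateDataset <- function(cfg, outDir = NULL) {
  stopifnot(is(cfg, "SynthConfig"))
  if (cfg@pEdgeWithin == 0 && cfg@pEdgeBetween == 0)
    warning(paste("edge probabilities are both zero:",
                  "the one-hop toxicity mechanism cannot occur"))
  withr::with_seed(cfg@seed, {
    proteins <- sprintf("P%04d", seq_len(cfg@nProteins))
    moduleOf <- stats::setNames(
      rep(seq_len(cfg@nModules),
          each = ceiling(cfg@nProteins / cfg@nModules),
          length.out = cfg@nProteins)[seq_len(cfg@nProteins)],
      proteins)

    ## protein interactions
    pairs <- t(utils::combn(cfg@nProteins, 2L))
    within <- moduleOf[pairs[, 1]] == moduleOf[pairs[, 2]]
    pEdge <- ifelse(within, cfg@pEdgeWithin, cfg@pEdgeBetween)
    keep <- stats::runif(nrow(pairs)) < pEdge
    within <- within[keep]; pairs <- pairs[keep, , drop = FALSE]
    stars <- integer(nrow(pairs))
    stars[within] <- sample(1:5, sum(within), replace = TRUE,
                            prob = cfg@starsWithin)
    stars[!within] <- sample(1:5, sum(!within), replace = TRUE,
                             prob = cfg@starsBetween)
    net <- newPPINetwork(proteins[pairs[, 1]], proteins[pairs[, 2]], stars)

    ## ontology: root, 3 shared level-2 branches, one chain per module
    ## from level 3 down to goDepth
    mkId <- local({i <- 0L; function() {i <<- i + 1L; sprintf("GO:%07d", i)}})
    root <- mkId()
    ids <- root; nms <- "biological_process"
    parents <- list(); parents[[root]] <- character(0)
    nShared <- 3L
    shared <- character(nShared)
    for (b in seq_len(nShared)) {
      shared[b] <- mkId()
      ids <- c(ids, shared[b])
      nms <- c(nms, sprintf("shared process branch %d", b))
      parents[[shared[b]]] <- root
    }
    deepTerm <- character(cfg@nModules)
    for (m in seq_len(cfg@nModules)) {
      prev <- shared[(m - 1L) %% nShared + 1L]
      for (lv in 3:cfg@goDepth) {
        id <- mkId()
        ids <- c(ids, id)
        nms <- c(nms, sprintf("module %02d specific process level %d", m, lv))
        parents[[id]] <- prev
        prev <- id
      }
      deepTerm[m] <- prev
    }
    ann <- lapply(proteins, function(p) {
      terms <- deepTerm[moduleOf[[p]]]
      if (stats::runif(1) < 0.3)
        terms <- c(terms, sample(shared, 1L))
      sort(terms)
    })
    names(ann) <- proteins
    dag <- new("GODag", terms = ids,
               termNames = stats::setNames(nms, ids),
               parents = parents, root = root, annotations = ann)

    ## drugs and targets
    drugs <- sprintf("DR%04d", seq_len(cfg@nDrugs))
    tmin <- cfg@targetsPerDrug[1]; tmax <- cfg@targetsPerDrug[2]
    targetList <- lapply(drugs, function(d) {
      k <- tmin + sample.int(tmax - tmin + 1L, 1L) - 1L
      sort(sample(proteins, k))
    })
    names(targetList) <- drugs
    targetPairs <- data.frame(
      drug_id = rep(drugs, lengths(targetList)),
      protein_id = unlist(targetList, use.names = FALSE),
      stringsAsFactors = FALSE)
    targets <- new("DrugTargetMap", pairs = targetPairs)

    ## planted labels: direct / one-hop / none
    toxicProteins <- proteins[moduleOf <= cfg@toxicModules]
    adj <- adjacencyList(net)
    hopSet <- unique(unlist(adj[intersect(toxicProteins, names(adj))],
                            use.names = FALSE))
    mechanism <- vapply(targetList, function(tg) {
      if (any(tg %in% toxicProteins)) "direct"
      else if (any(tg %in% hopSet)) "one_hop"
      else "none"
    }, character(1))
    pre <- as.integer(mechanism != "none")
    flip <- stats::runif(cfg@nDrugs) < cfg@labelNoise
    label <- ifelse(flip, 1L - pre, pre)
    truth <- data.frame(drug_id = drugs, label_prenoise = pre,
                        label = label, mechanism = unname(mechanism),
                        stringsAsFactors = FALSE)

    ## ADR tables: toxic drugs get an in-range (I99) reaction, everyone a
    ## benign out-of-range one
    adrPairs <- rbind(
      data.frame(drug_id = drugs, adr_name = "Dizziness_Sim",
                 stringsAsFactors = FALSE),
      data.frame(drug_id = drugs[label == 1L],
                 adr_name = "Cardiotoxicity_Sim", stringsAsFactors = FALSE))
    adrPairs <- adrPairs[order(adrPairs$drug_id, adrPairs$adr_name), ]
    rownames(adrPairs) <- NULL
    adrDisplay <- adrPairs
    adrPairs$adr_name <- canonicalizeAdr(adrPairs$adr_name)
    adrs <- new("DrugADRMap", pairs = adrPairs)
    icdDf <- data.frame(adr_name = c("Cardiotoxicity_Sim", "Dizziness_Sim"),
                        icd10 = c("I99", "R42"), stringsAsFactors = FALSE)
    icdDf$canonical <- canonicalizeAdr(icdDf$adr_name)
    icd <- new("ADRIcdMap", entries = icdDf)

    files <- NULL
    if (!is.null(outDir)) {
      if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
      fp <- function(x) file.path(outDir, x)
      files <- c(drug_targets = fp("drug_targets.tsv"),
                 drug_adr = fp("drug_adr.tsv"),
                 adr_icd10 = fp("adr_icd10.tsv"),
                 ppi = fp("ppi.tsv"),
                 annotations = fp("annotations.tsv"),
                 ontology = fp("ontology.obo"),
                 truth = fp("truth.tsv"))
      writeTsv(targetPairs, files[["drug_targets"]])
      writeTsv(adrDisplay, files[["drug_adr"]])
      writeTsv(icdDf[, c("adr_name", "icd10")], files[["adr_icd10"]])
      writeTsv(ppiEdges(net), files[["ppi"]])
      annDf <- data.frame(
        protein_id = rep(proteins, lengths(ann)),
        go_id = unlist(ann, use.names = FALSE), stringsAsFactors = FALSE)
      writeTsv(annDf, files[["annotations"]])
      writeObo(dag, files[["ontology"]])
      writeTsv(truth, files[["truth"]])
    }
    invisible(list(config = cfg, targets = targets, adrs = adrs, icd = icd,
                   net = net, dag = dag, truth = truth,
                   moduleOf = moduleOf, files = files))
  })
}
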