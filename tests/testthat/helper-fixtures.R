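# Shared fixtures: all built in code, no stored binary data.

# Write lines to a temp TSV and return its path.
tmpTsv <- function(...) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(...), f)
  f
}

# PPINetwork from a compact edge spec: list(c("A","B",3), ...).
makeNet <- function(...) {
  rows <- list(...)
  f <- tmpTsv("protein_a\tprotein_b\tstars",
              vapply(rows, function(r) paste(r, collapse = "\t"),
                     character(1)))
  suppressMessages(readPpiTable(f))
}

# FactsMatrix from a named row list: list(d1 = c("A","B"), d2 = "A").
makeFacts <- function(targetsOf) {
  cols <- sort(unique(unlist(targetsOf)))
  m <- matrix(0L, length(targetsOf), length(cols),
              dimnames = list(names(targetsOf), cols))
  for (d in names(targetsOf)) m[d, targetsOf[[d]]] <- 1L
  newFactsMatrix(m)
}

# GODag via an OBO file: terms = named list id -> character parents,
# annotations = named list protein -> term ids.
makeDag <- function(parents, annotations = list(),
                    names = NULL) {
  lines <- c("format-version: 1.2", "")
  for (id in names(parents)) {
    lines <- c(lines, "[Term]", paste0("id: ", id),
               paste0("name: ", if (!is.null(names[[id]])) names[[id]]
                      else id),
               "namespace: biological_process",
               paste0("is_a: ", parents[[id]]), "")
  }
  obo <- tempfile(fileext = ".obo")
  writeLines(lines, obo)
  ann <- tmpTsv("protein_id\tgo_id",
                unlist(lapply(names(annotations), function(p)
                  paste(p, annotations[[p]], sep = "\t"))))
  suppressMessages(readObo(obo, ann))
}

# Independent expansion oracle: literally build the one-level expansion
# tree (drug -> direct targets -> their network neighbors) and count every
# occurrence of every protein in it.
bruteExpandDrug <- function(directTargets, net) {
  adj <- lapply(ppiNodes(net), function(p) {
    e <- ppiEdges(net)
    c(e$protein_b[e$protein_a == p], e$protein_a[e$protein_b == p])
  })
  names(adj) <- ppiNodes(net)
  occurrences <- character(0)
  for (t in directTargets) {
    occurrences <- c(occurrences, t)          # the branch node itself
    occurrences <- c(occurrences, adj[[t]])   # its leaves (NULL off-network)
  }
  table(occurrences)
}

# Named row of a facts matrix (robust to single-column matrices, where
# plain `[drug, ]` subsetting would drop the column name).
factsRow <- function(fm, drug) {
  v <- factValues(fm)
  stats::setNames(as.integer(v[drug, ]), colnames(v))
}

# Canonical row order for pair tables (order-insensitive comparison).
sortPairs <- function(df) {
  df <- df[do.call(order, df), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Random star-rated network over `proteins`, built through the file reader.
randomNet <- function(proteins, nEdges) {
  if (length(proteins) < 2 || nEdges == 0) return(makeNet())
  a <- sample(proteins, nEdges, replace = TRUE)
  b <- sample(proteins, nEdges, replace = TRUE)
  keep <- a != b
  if (!any(keep)) return(makeNet())
  f <- tmpTsv("protein_a\tprotein_b\tstars",
              paste(a[keep], b[keep],
                    sample(1:5, sum(keep), replace = TRUE), sep = "\t"))
  suppressMessages(readPpiTable(f))
}
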