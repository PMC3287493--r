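# Readers and writers for the five flat inputs (TSV with a header, UTF-8)
# and the facts-matrix exchange format.

# Read a TSV with a header and validate required character columns. Rows with
# a missing/empty value in a required column raise a format error naming the
# first offending file line (header = line 1).
readTsv <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          fill = TRUE, fileEncoding = "UTF-8",
                          check.names = FALSE)
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop(sprintf("format error in %s: missing column '%s'",
                 path, missing[1]))
  for (col in required) {
    bad <- which(is.na(df[[col]]) | !nzchar(trimws(df[[col]])))
    if (length(bad))
      stop(sprintf("format error in %s: empty '%s' field at line %d",
                   path, col, bad[1] + 1L))
  }
  df[required]
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "",
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read a drug-target association table
#'
#' Two tab-separated columns `drug_id`, `protein_id` with a header line.
#' Duplicate pairs are collapsed; an empty table is valid but warned about.
#'
#' @param path path to a TSV file.
#' @return A [DrugTargetMap-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("drug_id\tprotein_id", "d1\tpA", "d2\tpA", "d2\tpB"), f)
#' readDrugTargetTable(f)
#' @export
readDrugTargetTable <- function(path) {
  df <- readTsv(path, c("drug_id", "protein_id"))
  if (!nrow(df)) warning(sprintf("empty drug-target table: %s", path))
  df <- unique(df)
  rownames(df) <- NULL
  new("DrugTargetMap", pairs = df)
}

#' Read a drug-ADR association table
#'
#' Two tab-separated columns `drug_id`, `adr_name` with a header. ADR names
#' are canonicalized (whitespace squeezed, case-folded) before deduplication,
#' so `"Cardiac Arrest"` and `"cardiac arrest"` are one pair.
#'
#' @param path path to a TSV file.
#' @return A [DrugADRMap-class].
#' @export
readDrugAdrTable <- function(path) {
  df <- readTsv(path, c("drug_id", "adr_name"))
  if (!nrow(df)) warning(sprintf("empty drug-ADR table: %s", path))
  df$adr_name <- canonicalizeAdr(df$adr_name)
  df <- unique(df)
  rownames(df) <- NULL
  new("DrugADRMap", pairs = df)
}

#' Read a star-rated protein-interaction table
#'
#' Three tab-separated columns `protein_a`, `protein_b`, `stars` with a
#' header. The graph is undirected: an unordered pair reported twice keeps
#' the maximum star value (stars grade confidence, so the best evidence for
#' the pair wins). Self-interactions are dropped with a message reporting the
#' count. Stars must be integers in 1..5.
#'
#' @param path path to a TSV file.
#' @return A [PPINetwork-class].
#' @export
readPpiTable <- function(path) {
  df <- readTsv(path, c("protein_a", "protein_b", "stars"))
  stars <- suppressWarnings(as.numeric(df$stars))
  if (any(is.na(stars)) || any(stars != as.integer(stars)))
    stop(sprintf("format error in %s: non-integer star value", path))
  if (any(stars < 1 | stars > 5))
    stop(sprintf("format error in %s: star value outside 1..5", path))
  self <- df$protein_a == df$protein_b
  if (any(self))
    message(sprintf("readPpiTable: dropped %d self-interaction(s)",
                    sum(self)))
  df <- df[!self, , drop = FALSE]
  newPPINetwork(df$protein_a, df$protein_b, as.integer(stars[!self]))
}

#' Read an ADR-name to ICD-10 code map
#'
#' Two tab-separated columns `adr_name`, `icd10` with a header. Codes must
#' match the ICD-10 lexical pattern (`I46`, `I08.8`) or be a category range
#' (`I30-I52`). The cardiotoxicity map is packaged:
#' `system.file("extdata", "cardiotoxicity_icd10.tsv", package = "adrnet")`.
#'
#' @param path path to a TSV file.
#' @return An [ADRIcdMap-class].
#' @examples
#' icd <- readIcd10Table(system.file("extdata", "cardiotoxicity_icd10.tsv",
#'                                   package = "adrnet"))
#' nrow(icdEntries(icd))
#' @export
readIcd10Table <- function(path) {
  df <- readTsv(path, c("adr_name", "icd10"))
  bad <- !vapply(df$icd10, isIcd10Code, logical(1))
  if (any(bad))
    stop(sprintf("format error in %s: malformed ICD-10 code '%s'",
                 path, df$icd10[which(bad)[1]]))
  df$canonical <- canonicalizeAdr(df$adr_name)
  df <- df[!duplicated(df$canonical), , drop = FALSE]
  rownames(df) <- NULL
  new("ADRIcdMap", entries = df)
}

#' Read a biological-process ontology and protein annotations
#'
#' Parses an OBO 1.2 subset (`[Term]` stanzas with `id`, `name`, `namespace`,
#' `is_a`; obsolete terms skipped), keeps only the `biological_process`
#' namespace, and detects the root as the unique kept term without `is_a`
#' parents. Annotations (`protein_id`, `go_id` TSV) pointing at terms absent
#' from the kept DAG are dropped with a message reporting the count.
#'
#' @param oboPath path to an OBO file.
#' @param annotPath path to a TSV with columns `protein_id`, `go_id`.
#' @return A [GODag-class].
#' @export
readObo <- function(oboPath, annotPath) {
  if (!file.exists(oboPath)) stop(sprintf("file not found: %s", oboPath))
  lines <- readLines(oboPath, encoding = "UTF-8")
  starts <- which(lines == "[Term]")
  if (!length(starts)) stop(sprintf("no [Term] stanzas in %s", oboPath))
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(0); nms <- character(0); parents <- list()
  for (i in seq_along(starts)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "[")]
    field <- function(key) {
      v <- block[startsWith(block, paste0(key, ":"))]
      trimws(sub(paste0("^", key, ":"), "", v))
    }
    if (any(field("is_obsolete") == "true")) next
    ns <- field("namespace")
    if (!length(ns) || ns[1] != "biological_process") next
    id <- field("id")[1]
    if (is.na(id)) next
    isa <- field("is_a")
    isa <- trimws(sub("!.*$", "", isa))   # strip trailing name comments
    ids <- c(ids, id)
    nms <- c(nms, if (length(field("name"))) field("name")[1] else id)
    parents[[id]] <- isa
  }
  # drop is_a links that leave the kept namespace
  parents <- lapply(parents, function(p) p[p %in% ids])
  roots <- ids[lengths(parents[ids]) == 0L]
  if (length(roots) != 1L)
    stop(sprintf("structural error in %s: %d parentless terms (need 1)",
                 oboPath, length(roots)))
  edges <- data.frame(
    child = rep(ids, lengths(parents[ids])),
    parent = unlist(parents[ids], use.names = FALSE))
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = ids)
    if (!igraph::is_dag(g))
      stop(sprintf("structural error in %s: is_a cycle detected", oboPath))
  }
  adf <- readTsv(annotPath, c("protein_id", "go_id"))
  unknown <- !(adf$go_id %in% ids)
  if (any(unknown))
    message(sprintf("readObo: dropped %d annotation(s) to unknown terms",
                    sum(unknown)))
  adf <- unique(adf[!unknown, , drop = FALSE])
  ann <- lapply(split(adf$go_id, adf$protein_id), unique)
  new("GODag", terms = ids, termNames = stats::setNames(nms, ids),
      parents = parents, root = roots, annotations = ann)
}

## ---------------------------------------------------------------------------
## Writers (round-trip counterparts of the readers)
## ---------------------------------------------------------------------------

#' Write adrnet tables back to their TSV formats
#'
#' Each writer emits the exact format its reader consumes, so a write/read
#' round trip reproduces the in-memory object.
#'
#' @param x the object to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @name writers
NULL

#' @rdname writers
#' @export
writeDrugTargetTable <- function(x, path) {
  stopifnot(is(x, "DrugTargetMap"))
  writeTsv(pairTable(x), path)
}

#' @rdname writers
#' @export
writeDrugAdrTable <- function(x, path) {
  stopifnot(is(x, "DrugADRMap"))
  writeTsv(pairTable(x), path)
}

#' @rdname writers
#' @export
writePpiTable <- function(x, path) {
  stopifnot(is(x, "PPINetwork"))
  writeTsv(ppiEdges(x), path)
}

#' @rdname writers
#' @export
writeIcd10Table <- function(x, path) {
  stopifnot(is(x, "ADRIcdMap"))
  writeTsv(icdEntries(x)[, c("adr_name", "icd10")], path)
}

#' Write / read a facts matrix as TSV
#'
#' Drugs as rows (first column `drug_id`), features as columns.
#'
#' @param x a [FactsMatrix-class].
#' @param path file path.
#' @param featureKind feature kind to stamp on the matrix read back.
#' @return `writeFactsMatrix`: `path` invisibly; `readFactsMatrix`: a
#'   [FactsMatrix-class].
#' @export
writeFactsMatrix <- function(x, path) {
  stopifnot(is(x, "FactsMatrix"))
  v <- factValues(x)
  df <- data.frame(drug_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  writeTsv(df, path)
}

#' @rdname writeFactsMatrix
#' @export
readFactsMatrix <- function(path, featureKind = "target") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, fileEncoding = "UTF-8")
  if (!"drug_id" %in% colnames(df))
    stop(sprintf("format error in %s: missing column 'drug_id'", path))
  m <- as.matrix(df[, setdiff(colnames(df), "drug_id"), drop = FALSE])
  rownames(m) <- as.character(df$drug_id)
  newFactsMatrix(m, featureKind = featureKind)
}
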