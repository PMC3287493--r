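# Internal helpers shared across modules.

# Canonical ADR name: trim, collapse internal whitespace, case-fold.
canonicalizeAdr <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

# ICD-10 lexical pattern: letter + 2 digits + optional ".d+", or a category
# range "Axx-Ayy" (same letter on both sides).
isIcd10Code <- function(code) {
  single <- "^[A-Z][0-9]{2}(\\.[0-9]+)?$"
  if (grepl(single, code)) return(TRUE)
  if (grepl("^[A-Z][0-9]{2}-[A-Z][0-9]{2}$", code)) {
    parts <- strsplit(code, "-", fixed = TRUE)[[1]]
    return(substr(parts[1], 1, 1) == substr(parts[2], 1, 1))
  }
  FALSE
}

# 3-character ICD-10 category (letter + 2 digits); a range entry contributes
# its lower bound, a decimal sub-code is truncated.
icdCategory <- function(code) {
  substr(code, 1L, 3L)
}

# Is the category of `code` within [low, high] (categories, same letter)?
icdInRange <- function(code, low, high) {
  cat <- icdCategory(code)
  letter <- substr(cat, 1, 1)
  if (letter != substr(low, 1, 1)) return(FALSE)
  num <- as.integer(substr(cat, 2, 3))
  num >= as.integer(substr(low, 2, 3)) & num <= as.integer(substr(high, 2, 3))
}

#' Construct a facts matrix
#'
#' Low-level constructor validating a drug-by-feature matrix into a
#' [FactsMatrix-class]. Most users build facts with [buildTargetFacts()]
#' instead.
#'
#' @param values non-negative numeric matrix with drug ids as rownames and
#'   feature ids as colnames.
#' @param featureKind `"target"`, `"go_term"` or `"adr"`.
#' @return A [FactsMatrix-class].
#' @examples
#' m <- matrix(c(1, 0, 1, 1), 2, 2,
#'             dimnames = list(c("d1", "d2"), c("A", "B")))
#' newFactsMatrix(m)
#' @export
newFactsMatrix <- function(values, featureKind = "target") {
  storage.mode(values) <- "integer"
  new("FactsMatrix", values = values, featureKind = featureKind)
}

# Internal PPINetwork constructor from a raw (a, b, stars) table: canonical
# edge order a < b, max-stars dedup, self-edges must already be gone.
newPPINetwork <- function(a, b, stars) {
  a <- as.character(a); b <- as.character(b)
  lo <- pmin(a, b); hi <- pmax(a, b)
  e <- data.frame(protein_a = lo, protein_b = hi,
                  stars = as.integer(stars), stringsAsFactors = FALSE)
  if (nrow(e)) {
    key <- paste(e$protein_a, e$protein_b, sep = "\r")
    mx <- tapply(e$stars, key, max)
    e <- e[!duplicated(key), , drop = FALSE]
    e$stars <- as.integer(mx[paste(e$protein_a, e$protein_b, sep = "\r")])
    e <- e[order(e$protein_a, e$protein_b), , drop = FALSE]
    rownames(e) <- NULL
  }
  new("PPINetwork", edges = e,
      nodes = sort(unique(c(e$protein_a, e$protein_b))))
}

# Adjacency list of a PPINetwork: protein id -> character vector of neighbors.
adjacencyList <- function(net) {
  e <- ppiEdges(net)
  if (!nrow(e)) return(structure(list(), names = character(0)))
  ends <- c(e$protein_a, e$protein_b)
  nbrs <- c(e$protein_b, e$protein_a)
  split(nbrs, ends)
}
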