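# Drug-by-target fact matrices and the merged ICD-10 ADR-class label vector.

#' Build the binary drug-by-target facts matrix
#'
#' Cell (n, k) is 1 iff drug n docks target k. Columns are the union of the
#' targets of drugs in the universe, sorted lexically for reproducibility;
#' rows follow `drugUniverse` order. Drugs without any target keep an
#' all-zero row (reported via a message), and pairs whose drug is outside the
#' universe are ignored (also reported).
#'
#' @param targets a [DrugTargetMap-class].
#' @param drugUniverse ordered character vector of drug ids (matrix rows).
#' @return A binary [FactsMatrix-class] with `featureKind = "target"`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("drug_id\tprotein_id", "d1\tA", "d2\tA", "d2\tB"), f)
#' dt <- buildTargetFacts(readDrugTargetTable(f), c("d1", "d2"))
#' factValues(dt)
#' @export
buildTargetFacts <- function(targets, drugUniverse) {
  stopifnot(is(targets, "DrugTargetMap"))
  drugUniverse <- as.character(drugUniverse)
  if (!length(drugUniverse)) stop("drugUniverse must be non-empty")
  if (anyDuplicated(drugUniverse)) stop("duplicate ids in drugUniverse")
  p <- pairTable(targets)
  outside <- !(p$drug_id %in% drugUniverse)
  if (any(outside))
    message(sprintf(
      "buildTargetFacts: ignored %d pair(s) for drugs outside the universe",
      sum(outside)))
  p <- p[!outside, , drop = FALSE]
  cols <- sort(unique(p$protein_id))
  m <- matrix(0L, nrow = length(drugUniverse), ncol = length(cols),
              dimnames = list(drugUniverse, cols))
  if (nrow(p)) m[cbind(p$drug_id, p$protein_id)] <- 1L
  zero <- rownames(m)[rowSums(m) == 0]
  if (length(zero))
    message(sprintf("buildTargetFacts: %d drug(s) without targets",
                    length(zero)))
  newFactsMatrix(m, featureKind = "target")
}

#' Merge per-ADR indicators into one binary class label
#'
#' A drug is labeled 1 when at least one of its adverse reactions maps to an
#' ICD-10 code whose 3-character category (letter + two digits; decimal
#' sub-codes ignored, range entries represented by their lower bound) falls
#' within `codeRange`. The default range I00-I99 is the circulatory-system
#' chapter, i.e. the cardiotoxicity class. ADR names absent from the map
#' contribute nothing.
#'
#' @param adrs a [DrugADRMap-class].
#' @param icd an [ADRIcdMap-class].
#' @param codeRange length-2 character vector `(low, high)` of 3-character
#'   ICD-10 categories sharing a letter, e.g. `c("I00", "I99")`.
#' @param drugUniverse ordered character vector of drug ids.
#' @return An [ADRClassLabels-class] aligned to `drugUniverse`.
#' @examples
#' adr <- tempfile(fileext = ".tsv")
#' writeLines(c("drug_id\tadr_name", "d1\tCardiac Arrest", "d2\tNausea"), adr)
#' icd <- readIcd10Table(system.file("extdata", "cardiotoxicity_icd10.tsv",
#'                                   package = "adrnet"))
#' classLabels(buildAdrClassLabels(readDrugAdrTable(adr), icd,
#'                                 c("I00", "I99"), c("d1", "d2")))
#' @export
buildAdrClassLabels <- function(adrs, icd, codeRange = c("I00", "I99"),
                                drugUniverse) {
  stopifnot(is(adrs, "DrugADRMap"), is(icd, "ADRIcdMap"))
  if (length(codeRange) != 2L ||
      !grepl("^[A-Z][0-9]{2}$", codeRange[1]) ||
      !grepl("^[A-Z][0-9]{2}$", codeRange[2]) ||
      substr(codeRange[1], 1, 1) != substr(codeRange[2], 1, 1) ||
      codeRange[1] > codeRange[2])
    stop("invalid codeRange: need same-letter categories with low <= high")
  drugUniverse <- as.character(drugUniverse)
  e <- icdEntries(icd)
  inRange <- vapply(e$icd10, icdInRange, logical(1),
                    low = codeRange[1], high = codeRange[2])
  hot <- e$canonical[inRange]
  p <- pairTable(adrs)
  pos <- unique(p$drug_id[p$adr_name %in% hot])
  new("ADRClassLabels", drugIds = drugUniverse,
      labels = as.integer(drugUniverse %in% pos))
}
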