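# A small DAG used across cases:
#   root (1) <- A (2) <- B (3)
#   root (1) <- C, and A <- C  => C takes the shortest path, level 2
chainDag <- function(ann = list()) {
  makeDag(list(root = character(0), A = "root", B = "A"),
          annotations = ann)
}

# named row of a facts matrix (robust to single-column matrices)
rowVec <- function(fm, drug) {
  v <- factValues(fm)
  stats::setNames(as.integer(v[drug, ]), colnames(v))
}

test_that("term levels are shortest-path depth from the root", {
  dag <- chainDag()
  lv <- computeLevels(dag)
  expect_equal(lv[["root"]], 1L)
  expect_equal(lv[["B"]], 3L)

  diamond <- makeDag(list(root = character(0), A = "root",
                          C = c("A", "root")))
  expect_equal(computeLevels(diamond)[["C"]], 2L)
})

test_that("threshold features count annotated direct targets per term", {
  # P1 -> B (level 3), P2 -> A (level 2); drug targets both proteins
  dag <- chainDag(ann = list(P1 = "B", P2 = "A"))
  lv <- computeLevels(dag)
  dt <- makeFacts(list(d1 = c("P1", "P2")))

  f3 <- thresholdFeatures(dt, dag, lv, 3)
  expect_equal(rowVec(f3, "d1"), c(B = 1L))

  f1 <- thresholdFeatures(dt, dag, lv, 1)
  expect_equal(rowVec(f1, "d1"), c(A = 1L, B = 1L))

  # two targets with the same annotation: cell value 2
  dag2 <- chainDag(ann = list(P1 = "B", P2 = "B"))
  f <- thresholdFeatures(dt, dag2, computeLevels(dag2), 3)
  expect_equal(rowVec(f, "d1"), c(B = 2L))

  # nesting: deeper thresholds give column subsets
  cols <- function(minLv)
    featureIds(thresholdFeatures(dt, dag, lv, minLv))
  expect_true(all(cols(3) %in% cols(2)))
  expect_true(all(cols(2) %in% cols(1)))
})

test_that("rollup replaces deep terms by their level-N ancestors", {
  # chain root <- A <- B <- C5 (levels 1..4); annotation at the leaf
  dag <- makeDag(list(root = character(0), A = "root", B = "A", C5 = "B"),
                 annotations = list(P1 = "C5"))
  lv <- computeLevels(dag)
  dt <- makeFacts(list(d1 = "P1"))

  r3 <- rollupFeatures(dt, dag, lv, 3)
  expect_equal(rowVec(r3, "d1"), c(B = 1L))

  # everything rolls to the root at level 1
  r1 <- rollupFeatures(dt, dag, lv, 1)
  expect_equal(rowVec(r1, "d1"), c(root = 1L))

  # two deep annotations sharing one level-2 ancestor: deduped per target
  dag2 <- makeDag(list(root = character(0), A = "root",
                       t4 = "A", t4b = "A"),
                  annotations = list(P1 = c("t4", "t4b")))
  r2 <- rollupFeatures(dt, dag2, computeLevels(dag2), 2)
  expect_equal(rowVec(r2, "d1"), c(A = 1L))
})

test_that("rollup ancestors agree with all-paths enumeration on random DAGs", {
  # independent oracle: enumerate ancestors by breadth-first parent closure,
  # then keep those at the target level
  allAncestorsAt <- function(term, parents, lv, level) {
    if (lv[[term]] == level) return(term)
    if (lv[[term]] < level) return(character(0))
    seen <- character(0); frontier <- term
    while (length(frontier)) {
      up <- unique(unlist(parents[frontier], use.names = FALSE))
      frontier <- setdiff(up, seen)
      seen <- union(seen, up)
    }
    sort(seen[vapply(seen, function(t) lv[[t]] == level, logical(1))])
  }
  withr::with_seed(404, {
    for (i in 1:20) {
      nTerms <- sample(10:40, 1)
      ids <- sprintf("GO:%07d", seq_len(nTerms))
      parents <- list(); parents[[ids[1]]] <- character(0)
      for (j in 2:nTerms)   # each term links to 1-2 earlier terms: a DAG
        parents[[ids[j]]] <- sample(ids[seq_len(j - 1)],
                                    min(j - 1, sample(1:2, 1)))
      prot <- sprintf("P%d", 1:5)
      ann <- lapply(prot, function(p) sample(ids, sample(1:3, 1)))
      names(ann) <- prot
      dag <- makeDag(parents, annotations = ann)
      lv <- computeLevels(dag)
      dt <- makeFacts(list(drug = prot))
      level <- sample(2:4, 1)
      got <- rowVec(rollupFeatures(dt, dag, lv, level), "drug")
      sets <- lapply(prot, function(p) {
        unique(unlist(lapply(dag@annotations[[p]], allAncestorsAt,
                             parents = dag@parents, lv = lv,
                             level = level)))
      })
      want <- table(unlist(sets))
      expect_equal(sort(names(got[got > 0])), sort(names(want)))
      expect_equal(unname(got[sort(names(want))]),
                   as.integer(want[sort(names(want))]))
      # conservation: no emitted column sits at a different level
      expect_true(all(lv[names(got[got > 0])] == level))
      # every annotation at or below the roll level maps somewhere
      for (p in prot) {
        deepOrAt <- dag@annotations[[p]][lv[dag@annotations[[p]]] >= level]
        if (length(deepOrAt)) expect_gt(length(sets[[match(p, prot)]]), 0)
      }
    }
  })
})
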