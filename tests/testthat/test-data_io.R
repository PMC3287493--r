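test_that("drug-target reader parses, deduplicates and flags bad rows", {
  f <- tmpTsv("drug_id\tprotein_id", "d1\tpA", "d2\tpA", "d2\tpB")
  expect_equal(nrow(pairTable(readDrugTargetTable(f))), 3L)

  dup <- tmpTsv("drug_id\tprotein_id", "d1\tpA", "d1\tpA")
  expect_equal(nrow(pairTable(readDrugTargetTable(dup))), 1L)

  short <- tmpTsv("drug_id\tprotein_id", "d1\tpA", "d2")
  expect_error(readDrugTargetTable(short), "line 3")

  noCol <- tmpTsv("drug_id\ttarget", "d1\tpA")
  expect_error(readDrugTargetTable(noCol), "protein_id")

  empty <- tmpTsv("drug_id\tprotein_id")
  expect_warning(m <- readDrugTargetTable(empty), "empty")
  expect_equal(nrow(pairTable(m)), 0L)
})

test_that("ADR reader canonicalizes names case-insensitively", {
  f <- tmpTsv("drug_id\tadr_name", "d1\tCardiac Arrest", "d1\tNausea")
  expect_equal(nrow(pairTable(readDrugAdrTable(f))), 2L)

  fold <- tmpTsv("drug_id\tadr_name", "d1\tcardiac  arrest",
                 "d1\tCardiac Arrest")
  m <- readDrugAdrTable(fold)
  expect_equal(nrow(pairTable(m)), 1L)
  expect_equal(pairTable(m)$adr_name, "cardiac arrest")
})

test_that("PPI reader is undirected, keeps max stars, drops self-edges", {
  m <- makeNet(c("A", "B", 3), c("B", "A", 2))
  expect_equal(nrow(ppiEdges(m)), 1L)
  expect_equal(ppiEdges(m)$stars, 3L)

  f <- tmpTsv("protein_a\tprotein_b\tstars", "A\tA\t5", "A\tB\t2")
  expect_message(m2 <- readPpiTable(f), "1 self-interaction")
  expect_equal(nrow(ppiEdges(m2)), 1L)
  expect_equal(ppiNodes(m2), c("A", "B"))

  expect_error(readPpiTable(tmpTsv("protein_a\tprotein_b\tstars",
                                   "A\tB\t7")), "1..5")
  expect_error(readPpiTable(tmpTsv("protein_a\tprotein_b\tstars",
                                   "A\tB\t2.5")), "non-integer")
})

test_that("packaged cardiotoxicity ICD-10 map loads with expected content", {
  icd <- readIcd10Table(system.file("extdata", "cardiotoxicity_icd10.tsv",
                                    package = "adrnet"))
  e <- icdEntries(icd)
  expect_equal(nrow(e), 29L)
  expect_equal(e$icd10[e$adr_name == "Cardiac Arrest"], "I46")
  expect_equal(e$icd10[e$adr_name == "Valvular Heart Disease"], "I08.8")
  expect_true("I30-I52" %in% e$icd10)   # category-range entry

  expect_error(readIcd10Table(tmpTsv("adr_name\ticd10", "Thing\tX9")),
               "malformed")
})

test_that("OBO reader keeps the BP namespace, one root, known annotations", {
  dag <- makeDag(list(root = character(0), A = "root", B = "A"),
                 annotations = list(p1 = "B"))
  expect_equal(dag@root, "root")
  expect_equal(sort(dag@terms), c("A", "B", "root"))
  expect_equal(dag@annotations$p1, "B")

  # annotation to an unknown term is dropped with a message
  obo <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: GO:1", "name: root",
               "namespace: biological_process"), obo)
  ann <- tmpTsv("protein_id\tgo_id", "p1\tGO:9999999", "p2\tGO:1")
  expect_message(d2 <- readObo(obo, ann), "dropped 1")
  expect_equal(length(d2@annotations), 1L)

  # two parentless BP terms: structural error
  obo2 <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: GO:1", "name: a",
               "namespace: biological_process", "",
               "[Term]", "id: GO:2", "name: b",
               "namespace: biological_process"), obo2)
  expect_error(readObo(obo2, ann), "2 parentless")

  # a cycle among non-root terms: structural error
  obo3 <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: GO:1", "name: root",
               "namespace: biological_process", "",
               "[Term]", "id: GO:2", "name: x",
               "namespace: biological_process", "is_a: GO:1", "is_a: GO:3", "",
               "[Term]", "id: GO:3", "name: y",
               "namespace: biological_process", "is_a: GO:2"), obo3)
  expect_error(readObo(obo3, ann), "cycle")
})

test_that("write/read round-trips reproduce objects; parsing ignores order", {
  tm <- readDrugTargetTable(tmpTsv("drug_id\tprotein_id",
                                   "d2\tpB", "d1\tpA", "d2\tpA"))
  f <- tempfile(); writeDrugTargetTable(tm, f)
  expect_equal(sortPairs(pairTable(readDrugTargetTable(f))),
               sortPairs(pairTable(tm)))

  am <- readDrugAdrTable(tmpTsv("drug_id\tadr_name",
                                "d1\tHeadache", "d2\tCardiac Arrest"))
  f <- tempfile(); writeDrugAdrTable(am, f)
  expect_equal(sortPairs(pairTable(readDrugAdrTable(f))),
               sortPairs(pairTable(am)))

  net <- makeNet(c("B", "C", 2), c("A", "B", 5), c("A", "C", 1))
  f <- tempfile(); writePpiTable(net, f)
  expect_equal(readPpiTable(f), net)

  icd <- readIcd10Table(system.file("extdata", "cardiotoxicity_icd10.tsv",
                                    package = "adrnet"))
  f <- tempfile(); writeIcd10Table(icd, f)
  expect_equal(readIcd10Table(f), icd)

  # shuffled rows parse to the same objects
  lines <- c("d1\tpA", "d2\tpA", "d2\tpB", "d3\tpC")
  a <- readDrugTargetTable(tmpTsv("drug_id\tprotein_id", lines))
  b <- readDrugTargetTable(tmpTsv("drug_id\tprotein_id", rev(lines)))
  expect_equal(sortPairs(pairTable(a)), sortPairs(pairTable(b)))

  net2 <- makeNet(c("A", "B", 1), c("B", "C", 4))
  net3 <- makeNet(c("C", "B", 4), c("B", "A", 1))
  expect_equal(net2, net3)
})

test_that("facts matrices survive a TSV round trip", {
  fm <- makeFacts(list(d1 = c("A", "B"), d2 = "A"))
  f <- tempfile()
  writeFactsMatrix(fm, f)
  expect_equal(readFactsMatrix(f), fm)
})
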