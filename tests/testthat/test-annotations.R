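writeTsv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(rows, path)
  path
}

test_that("genetic interactions pass both curation and type filters", {
  path <- writeTsv(c(
    "gene_a\tgene_b\tcuration\tinteraction_type",
    "a\tb\tManual curation\tSynthetic Lethality",
    "a\tc\tHigh Throughput\tSynthetic Lethality",
    "c\td\tManual curation\tDosage Rescue",
    "b\ta\tManual curation\tSynthetic growth defect",
    "d\te\tManual curation\tSynthetic growth defect"))
  pairs <- readGeneticInteractions(path)
  expect_setequal(pairs, c("a|b", "d|e"))  # b-a collapses onto a-b
  bad <- writeTsv(c("gene_a\tgene_b\tcuration", "a\tb\tManual curation"))
  expect_error(readGeneticInteractions(bad), "must have columns")
})

test_that("ancestor closure propagates terms up an acyclic parent map", {
  parents <- data.frame(child = c("t1", "t2"), parent = c("t2", "root"))
  gt <- list(g1 = "t1", g2 = "t2", g3 = character())
  uni <- c("g1", "g2", "g3")
  closed <- goAncestorClosure(gt, parents, uni, minFreq = 1, maxFreq = 40)
  expect_setequal(closed$g1, c("t1", "t2", "root"))
  expect_setequal(closed$g2, c("t2", "root"))
  expect_equal(closed$g3, character())
})

test_that("the term-frequency window is inclusive and universe-scoped", {
  parents <- data.frame(child = character(), parent = character())
  gt <- list(g1 = c("rare", "common"), g2 = "common", g3 = "common")
  # with maxFreq 2 the 3-gene 'common' term is dropped; 'rare' (freq 1)
  # fails an inclusive minFreq of 2
  closed <- goAncestorClosure(gt, parents, c("g1", "g2", "g3"),
                              minFreq = 2, maxFreq = 2)
  expect_equal(closed$g1, character())
  # a term annotating exactly minFreq genes is retained
  closed2 <- goAncestorClosure(gt, parents, c("g1", "g2"),
                               minFreq = 2, maxFreq = 40)
  expect_setequal(closed2$g1, "common")
  expect_setequal(closed2$g2, "common")
})

test_that("ancestor closure is idempotent and detects cycles", {
  parents <- data.frame(child = c("t1", "t2"), parent = c("t2", "root"))
  gt <- list(g1 = "t1", g2 = c("t1", "t2"), g3 = "root", g4 = "root")
  uni <- sprintf("g%d", 1:4)
  once <- goAncestorClosure(gt, parents, uni, minFreq = 2, maxFreq = 3)
  twice <- goAncestorClosure(once, parents, uni, minFreq = 2, maxFreq = 3)
  expect_identical(lapply(once, sort), lapply(twice, sort))

  cyc <- data.frame(child = c("x", "y"), parent = c("y", "x"))
  expect_error(goAncestorClosure(list(g = "x"), cyc, "g"), "cycle")
})

test_that("the blanket viable phenotype is removed from every gene", {
  gt <- list(g1 = c("viable", "slow growth"), g2 = "viable",
             g3 = "heat sensitive")
  cleaned <- cleanPhenotypes(gt)
  expect_equal(cleaned$g1, "slow growth")
  expect_equal(cleaned$g2, character())
  expect_equal(cleaned$g3, "heat sensitive")
})

test_that("pair sharing covers term and pair channels and is symmetric", {
  ann <- AnnotationSet(
    geneTerms = list(complex = list(g1 = "SWR1-C", g2 = "SWR1-C",
                                    g3 = "NuA4")),
    pairRelations = list(physical_interaction = "g1|g3"))
  expect_true(pairShares(ann, "complex", "g1", "g2"))
  expect_true(pairShares(ann, "complex", "g2", "g1"))
  expect_false(pairShares(ann, "complex", "g1", "g3"))
  expect_true(pairShares(ann, "physical_interaction", "g3", "g1"))
  expect_false(pairShares(ann, "physical_interaction", "g1", "g2"))
  expect_error(pairShares(ann, "no_such_channel", "g1", "g2"),
               "unknown annotation channel")
  # genes absent from the channel share nothing
  expect_false(pairShares(ann, "complex", "g1", "unknown"))
})

test_that("frequency filtering happens before pair matching", {
  parents <- data.frame(child = character(), parent = character())
  gt <- c(list(a = "huge", b = "huge"),
          stats::setNames(as.list(rep("huge", 41)), sprintf("f%02d", 1:41)))
  uni <- names(gt)
  filtered <- goAncestorClosure(gt, parents, uni, minFreq = 2, maxFreq = 40)
  ann <- AnnotationSet(geneTerms = list(go_process = filtered))
  expect_false(pairShares(ann, "go_process", "a", "b"))
})

test_that("loaders normalize gene-term and pair files", {
  gtPath <- writeTsv(c("g1\tC1", "g1\tC2", "g2\tC1", "g1\tC1"))
  gt <- readGeneTerms(gtPath)
  expect_setequal(gt$g1, c("C1", "C2"))
  expect_equal(gt$g2, "C1")
  prPath <- writeTsv(c("a\tb", "b\ta", "c\tc", "a\tc"))
  expect_setequal(readPairList(prPath), c("a|b", "a|c"))
})
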