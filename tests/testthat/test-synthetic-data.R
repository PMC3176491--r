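test_that("a fixed seed fixes matrix, truth and annotations exactly", {
  a <- generateEmap(syntheticConfig(seed = 31L))
  b <- generateEmap(syntheticConfig(seed = 31L))
  expect_identical(scorePairs(a$scores), scorePairs(b$scores))
  expect_identical(a$truth, b$truth)
  expect_identical(a$annotation@geneTerms, b$annotation@geneTerms)
  expect_identical(a$annotation@pairRelations, b$annotation@pairRelations)
  c <- generateEmap(syntheticConfig(seed = 32L))
  expect_false(identical(scorePairs(a$scores), scorePairs(c$scores)))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- stats::runif(1)
  set.seed(99)
  invisible(generateEmap(syntheticConfig(seed = 31L)))
  expect_identical(stats::runif(1), before)
})

test_that("realized missingness hits the target fraction", {
  gen <- generateEmap(syntheticConfig(nGenes = 200, nComplexes = 0,
                                      nPathways = 0, nRegulators = 0,
                                      seed = 41L))
  expect_lt(abs(missingFraction(gen$scores) - 0.78), 0.02)
  big <- generateEmap(syntheticConfig(nGenes = 500, nComplexes = 0,
                                      nPathways = 0, nRegulators = 0,
                                      seed = 42L))
  expect_lt(abs(missingFraction(big$scores) - 0.78), 0.01)
})

test_that("a planted positive 4-clique yields exactly its 4 PPP triplets", {
  cfg <- syntheticConfig(nGenes = 40, nComplexes = 1, nPathways = 0,
                         nRegulators = 0, seed = 51L)
  gen <- generateEmap(cfg)
  net <- thresholdScores(gen$scores, percentile = 4)
  census <- enumerateTriplets(net)
  cx <- gen$truth$complexes[[1]]
  ppp <- tripletTable(census)
  ppp <- ppp[ppp$class == "PPP", ]
  expect_equal(nrow(ppp), 4L)
  expect_true(all(unlist(ppp[, c("gene_a", "gene_b", "gene_c")]) %in% cx))
})

test_that("a single pathway-regulator unit yields one NPP at the regulator", {
  cfg <- syntheticConfig(nGenes = 40, nComplexes = 0, nPathways = 1,
                         nRegulators = 1, seed = 52L)
  gen <- generateEmap(cfg)
  net <- thresholdScores(gen$scores, percentile = 2)
  census <- enumerateTriplets(net)
  expect_equal(unname(motifCounts(census)["NPP"]), 1L)
  expect_equal(roleGenes(census, "NPP", "positive_node"),
               gen$truth$regulators)
})

test_that("planted pairs are exempt from the missing mask by default", {
  cfg <- syntheticConfig(seed = 61L)
  gen <- generateEmap(cfg)
  tp <- gen$truth$planted_pairs
  p <- scorePairs(gen$scores)
  key <- paste(p$gene_a, p$gene_b, sep = "|")
  tkey <- paste(pmin(tp$gene_a, tp$gene_b), pmax(tp$gene_a, tp$gene_b),
                sep = "|")
  expect_true(all(tkey %in% key))
  # planted scores sit near their structural means
  sc <- p$score[match(tkey, key)]
  expect_true(all(abs(sc - tp$mean) < 6))
})

test_that("block missingness removes cross-block pairs", {
  cfg <- syntheticConfig(nGenes = 120, nComplexes = 0, nPathways = 0,
                         nRegulators = 0, blockMissing = TRUE,
                         blockSize = 40, missingFraction = 0.8,
                         seed = 71L)
  gen <- generateEmap(cfg)
  p <- scorePairs(gen$scores)
  blk <- function(g) (as.integer(sub("g", "", g)) - 1L) %/% 40L
  expect_true(all(blk(p$gene_a) == blk(p$gene_b)))
})

test_that("swapping structural sign conventions swaps NNP and NPP roles", {
  cfg <- syntheticConfig(seed = 81L)
  flipped <- syntheticConfig(intraComplexMean = -6, pathwayPairMean = 6,
                             bridgeMean = 6, regulatorMean = -6,
                             seed = 81L)
  countsOf <- function(cc) {
    gen <- generateEmap(cc)
    net <- filterLowDegree(thresholdScores(gen$scores, percentile = 5))
    motifCounts(enumerateTriplets(net))
  }
  a <- countsOf(cfg)
  b <- countsOf(flipped)
  expect_equal(unname(a["NNP"]), unname(b["NPP"]))
  expect_equal(unname(a["NPP"]), unname(b["NNP"]))
  expect_equal(unname(a["NNN"]), unname(b["PPP"]))
  expect_equal(unname(a["PPP"]), unname(b["NNN"]))
})

test_that("the recovery experiment finds the planted regulators", {
  rec <- recoveryExperiment(syntheticConfig(seed = 91L), nRandom = 150,
                            seed = 92L)
  expect_true(all(rec$z >= 2))
  expect_equal(rec$regulator_recovery, 1.0)
  expect_equal(rec$regulator_term_rank, 1L)
})

test_that("synthetic exports are readable by the package loaders", {
  dir <- withr::local_tempdir()
  gen <- generateEmap(syntheticConfig(nGenes = 30, nComplexes = 2,
                                      nPathways = 2, nRegulators = 2,
                                      seed = 101L))
  writeSyntheticData(gen, dir)
  back <- readScoreMatrix(file.path(dir, "scores.tsv"))
  expect_identical(scoreGenes(back), scoreGenes(gen$scores))
  expect_equal(scorePairs(back)$score, scorePairs(gen$scores)$score,
               tolerance = 1e-12)
  cx <- readGeneTerms(file.path(dir, "annotation_complex.tsv"))
  expect_identical(lapply(cx, sort),
                   lapply(gen$annotation@geneTerms$complex, sort))
  pp <- readPairList(file.path(dir, "pairs_physical_interaction.tsv"))
  expect_setequal(pp, gen$annotation@pairRelations$physical_interaction)
})
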