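# one NNP triplet a-b-c: a-b most negative (i), b-c middle (ii),
# a-c positive (iii)
nnpNet <- function() {
  SignedNetwork(edges = data.frame(
    gene_a = c("a", "b", "a"), gene_b = c("b", "c", "c"),
    sign = c("N", "N", "P"), score = c(-3, -1, 2)))
}

test_that("position codes follow the ascending-score edge order", {
  census <- enumerateTriplets(nnpNet())
  # only the positive pair (position iii) physically interacts -> 001
  ann <- AnnotationSet(pairRelations = list(physical_interaction = "a|c"))
  codes <- codeFeatures(census, ann)
  expect_equal(codes$code, "001")

  # all three genes share one complex -> 111
  ann2 <- AnnotationSet(geneTerms = list(
    complex = list(a = "CPX", b = "CPX", c = "CPX")))
  expect_equal(codeFeatures(census, ann2)$code, "111")

  # a,b share complex X; b,c share complex Y; a,c none -> 110
  ann3 <- AnnotationSet(geneTerms = list(
    complex = list(a = "X", b = c("X", "Y"), c = "Y")))
  codes3 <- codeFeatures(census, ann3)
  expect_equal(codes3$code, "110")
  expect_equal(sum(attr(codes3, "mixed_codes")), 1L)
})

test_that("code patterns partition the census per channel", {
  gen <- generateEmap(syntheticConfig(nGenes = 60, nComplexes = 3,
                                      nPathways = 3, nRegulators = 3,
                                      seed = 3L))
  net <- filterLowDegree(thresholdScores(gen$scores, percentile = 5))
  census <- enumerateTriplets(net)
  codes <- codeFeatures(census, gen$annotation)
  for (ch in unique(codes$channel)) {
    expect_equal(sum(codes$channel == ch), nrow(tripletTable(census)),
                 info = ch)
  }
})

test_that("fisher cross-tabulation computes the sample odds ratio", {
  census <- enumerateTriplets(nnpNet())
  # construct codes directly to pin the contingency table
  codes <- data.frame(triplet = 1, class = "NNP",
                      channel = "complex", code = "001",
                      stringsAsFactors = FALSE)
  rec <- fisherCrossTab(codes, census, "complex", "001", "NNP")
  expect_equal(rec$a, 1L)
  expect_true(rec$testable)

  # odds ratio from a synthetic table: a=2 b=3 c=4 d=1 -> (2*1)/(3*4)
  p <- emapMotifs:::fisherTwoSided(2, 3, 4, 1)
  expect_equal(p, fisherOracle(2, 3, 4, 1), tolerance = 1e-12)
})

test_that("two-sided fisher p matches the hypergeometric oracle", {
  set.seed(6)
  for (i in 1:40) {
    a <- sample(0:20, 1); b <- sample(0:20, 1)
    c <- sample(0:20, 1); d <- sample(0:20, 1)
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
    expect_equal(emapMotifs:::fisherTwoSided(a, b, c, d),
                 fisherOracle(a, b, c, d), tolerance = 1e-10,
                 info = sprintf("table %d %d %d %d", a, b, c, d))
  }
  # and against R's own implementation on a fixed table
  expect_equal(emapMotifs:::fisherTwoSided(10, 5, 2, 20),
               stats::fisher.test(matrix(c(10, 5, 2, 20), 2,
                                         byrow = TRUE))$p.value,
               tolerance = 1e-9)
})

test_that("zero cells trigger the Haldane odds-ratio correction", {
  census <- enumerateTriplets(nnpNet())
  codes <- data.frame(triplet = 1, class = "NNP", channel = "complex",
                      code = "000", stringsAsFactors = FALSE)
  rec <- fisherCrossTab(codes, census, "complex", "001", "NNP")
  expect_equal(rec$a, 0L)
  expect_equal(rec$odds_ratio,
               (0.5 * 0.5) / (1.5 * 0.5))
})

test_that("enrichment tables bonferroni-correct over the emitted family", {
  gen <- generateEmap(syntheticConfig(nGenes = 60, nComplexes = 3,
                                      nPathways = 3, nRegulators = 3,
                                      seed = 3L))
  net <- filterLowDegree(thresholdScores(gen$scores, percentile = 5))
  census <- enumerateTriplets(net)
  codes <- codeFeatures(census, gen$annotation)
  tab <- enrichmentTable(codes, census, channels = "complex",
                         patterns = c("001", "111"))
  fam <- attr(tab, "family_size")
  expect_equal(fam, sum(tab$testable))
  ok <- tab$testable
  expect_equal(tab$p_bonferroni[ok], pmin(1, tab$p_value[ok] * fam))
  expect_true(all(tab$a + tab$b + tab$c + tab$d ==
                    nrow(tripletTable(census))))
})

test_that("edge-context fold change is category over baseline fraction", {
  # one all-negative triangle (3 in-triplet N edges) + 10 baseline N edges
  e <- rbind(
    data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
               sign = "N", score = -(3:1), stringsAsFactors = FALSE),
    data.frame(gene_a = sprintf("u%02d", 1:10),
               gene_b = sprintf("v%02d", 1:10),
               sign = "N", score = -(1:10) / 2, stringsAsFactors = FALSE))
  net <- SignedNetwork(edges = e)
  census <- enumerateTriplets(net)
  # share a phenotype: 2 of 3 triangle edges, 1 of 10 baseline edges
  ann <- AnnotationSet(geneTerms = list(phenotype = list(
    a = "slow", b = "slow", c = "slow2", u01 = "slow", v01 = "slow")))
  # a-b shares, a-c no, b-c no ... adjust: a,b share 'slow'; c shares none
  fc <- edgeContextFoldChange(net, census, ann, "N",
                              channels = "phenotype")
  base <- fc[fc$category == "not_in_triplet", ]
  anyT <- fc[fc$category == "in_any_triplet", ]
  expect_equal(base$fraction, 1 / 10)
  expect_equal(anyT$fraction, 1 / 3)
  expect_equal(anyT$fold_change, (1 / 3) / (1 / 10))
  expect_equal(base$fold_change, 1.0)
})

test_that("empty baselines flag undefined fold changes", {
  tri <- nnpNet()  # all edges in the triplet, no baseline edges
  census <- enumerateTriplets(tri)
  ann <- AnnotationSet(pairRelations = list(physical_interaction = "a|c"))
  fc <- edgeContextFoldChange(tri, census, ann, "P",
                              channels = "physical_interaction")
  inAny <- fc[fc$category == "in_any_triplet", ]
  expect_false(inAny$fold_defined)
  expect_true(is.na(inAny$fold_change))
})

test_that("profile correlations recover exact monotone relations", {
  partners <- sprintf("p%02d", 1:12)
  mkPairs <- function(g, scores) {
    data.frame(gene_a = g, gene_b = partners, score = scores,
               stringsAsFactors = FALSE)
  }
  base <- seq(-2, 2, length.out = 12)
  # triplet-internal pairs are left unscored so the common-partner sets are
  # exactly the 12 shared profile genes
  pairs <- rbind(mkPairs("a", base), mkPairs("b", base),
                 mkPairs("c", rev(base)))
  sm <- ScoreMatrix(pairs = pairs)
  census <- enumerateTriplets(nnpNet())
  pc <- profileCorrelation(sm, census, "NNP", minCommon = 10)
  cors <- pc$correlations
  rhoAB <- cors$rho[cors$position == "i"]
  expect_equal(rhoAB, 1.0)       # identical profiles
  rhoBC <- cors$rho[cors$position == "ii"]
  expect_equal(rhoBC, -1.0)      # reversed ranks
  expect_equal(pc$summary$n[pc$summary$sign == "N"], 2L)
})

test_that("spearman matches a direct rank computation", {
  x <- 1:10
  y <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9)
  rho <- 1 - 6 * sum((rank(x) - rank(y))^2) / (10 * (10^2 - 1))
  partners <- sprintf("p%02d", 1:10)
  pairs <- rbind(
    data.frame(gene_a = "a", gene_b = partners, score = x),
    data.frame(gene_a = "b", gene_b = partners, score = y))
  sm <- ScoreMatrix(pairs = pairs)
  pc <- profileCorrelation(sm, enumerateTriplets(nnpNet()), "NNP",
                           minCommon = 10)
  expect_equal(pc$correlations$rho[pc$correlations$position == "i"], rho)
})

test_that("role genes identify the distinguished triplet node", {
  census <- enumerateTriplets(nnpNet())
  # NNP spanned node: incident to both N edges = b
  expect_equal(roleGenes(census, "NNP", "spanned_node"), "b")
  expect_error(roleGenes(census, "NNN", "positive_node"), "not defined")
  npp <- SignedNetwork(edges = data.frame(
    gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
    sign = c("N", "P", "P"), score = c(-2, 1, 3)))
  expect_equal(roleGenes(enumerateTriplets(npp), "NPP", "positive_node"),
               "c")
})

test_that("positional enrichment uses the one-sided hypergeometric", {
  # universe of 10 genes, 5 with term t; role set of 4, all with t
  npp <- SignedNetwork(edges = data.frame(
    gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
    sign = c("N", "P", "P"), score = c(-2, 1, 3)))
  census <- enumerateTriplets(npp)
  universe <- sprintf("g%02d", 1:10)
  gt <- stats::setNames(as.list(rep("t", 5)), universe[1:5])
  ann <- AnnotationSet(geneTerms = list(go_function = gt))
  # direct arithmetic check of the p-value machinery on a 4-gene set
  p <- stats::phyper(3, 5, 5, 4, lower.tail = FALSE)
  expect_equal(p, 5 / 210, tolerance = 1e-12)
  # role set {c}: 1 gene; term covers c?
  ann2 <- AnnotationSet(geneTerms = list(go_function = list(
    c = "t", a = "t", b = "other", x = "other")))
  tab <- positionGeneEnrichment(census, ann2, "NPP", "positive_node",
                                "go_function", universe = c("a", "b", "c",
                                                            "x"))
  tt <- tab[tab$term == "t", ]
  expect_equal(tt$n_set, 1L)
  expect_equal(tt$p_value, stats::phyper(0, 2, 2, 1, lower.tail = FALSE))
  expect_equal(tt$fold_enrichment, (1 / 1) / (2 / 4))
  # a term absent from the role set: fold 0, one-sided p 1
  oo <- tab[tab$term == "other", ]
  expect_equal(oo$fold_enrichment, 0)
  expect_equal(oo$p_value, 1)
})

test_that("physical edge fractions summarize per-class interaction content", {
  gen <- generateEmap(syntheticConfig(seed = 13L))
  net <- filterLowDegree(thresholdScores(gen$scores, percentile = 5))
  census <- enumerateTriplets(net)
  pf <- physicalEdgeFractions(census, gen$annotation)
  expect_equal(pf$class, c("NNN", "NNP", "NPP", "PPP"))
  # planted physical relation = intra-complex pairs: every PPP triplet is an
  # intra-complex triangle, every NNP has exactly one intra-complex edge
  expect_equal(pf$frac_ge1[pf$class == "PPP"], 1)
  expect_gt(pf$frac_ge1[pf$class == "NNP"],
            pf$frac_ge1[pf$class == "NPP"])
  rowSums <- pf$frac_0 + pf$frac_1 + pf$frac_2 + pf$frac_3
  expect_equal(rowSums[!is.na(rowSums)],
               rep(1, sum(!is.na(rowSums))))
})
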