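test_that("a complete all-negative 4-graph yields the 4 NNN triplets", {
  g <- c("a", "b", "c", "d")
  cmb <- utils::combn(g, 2)
  net <- SignedNetwork(edges = data.frame(
    gene_a = cmb[1, ], gene_b = cmb[2, ], sign = "N",
    score = -(1:6)))
  census <- enumerateTriplets(net)
  expect_equal(unname(motifCounts(census)["NNN"]), 4L)
  expect_equal(sum(motifCounts(census)), 4L)
})

test_that("edges within a triplet are ordered by ascending S-score", {
  net <- SignedNetwork(edges = data.frame(
    gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
    sign = c("N", "N", "P"), score = c(-3.2, -1.1, 2.5)))
  tr <- tripletTable(enumerateTriplets(net))
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$class, "NNP")
  expect_equal(c(tr$score_i, tr$score_ii, tr$score_iii), c(-3.2, -1.1, 2.5))
  expect_equal(tr$pair_i, "a|b")
  expect_equal(tr$pair_iii, "b|c")
})

test_that("enumeration agrees with the exhaustive triple-loop oracle", {
  for (s in 1:25) {
    net <- randomSignedNetwork(sample(4:12, 1), 0.4, seed = 1000 + s)
    census <- enumerateTriplets(net)
    expect_identical(censusStrings(census), bruteTriplets(net),
                     info = paste("seed", s))
  }
})

test_that("class counts are invariant under gene relabeling", {
  net <- randomSignedNetwork(10, 0.5, seed = 77)
  e <- networkEdges(net)
  perm <- stats::setNames(sprintf("z%02d", sample(10)), networkGenes(net))
  net2 <- SignedNetwork(edges = data.frame(
    gene_a = unname(perm[e$gene_a]), gene_b = unname(perm[e$gene_b]),
    sign = e$sign, score = e$score))
  expect_identical(motifCounts(enumerateTriplets(net)),
                   motifCounts(enumerateTriplets(net2)))
})

test_that("negating scores swaps NNP/NPP and NNN/PPP and flips order", {
  net <- randomSignedNetwork(12, 0.45, seed = 5)
  e <- networkEdges(net)
  flip <- SignedNetwork(edges = data.frame(
    gene_a = e$gene_a, gene_b = e$gene_b,
    sign = ifelse(e$sign == "N", "P", "N"), score = -e$score))
  a <- enumerateTriplets(net)
  b <- enumerateTriplets(flip)
  ca <- motifCounts(a); cb <- motifCounts(b)
  expect_equal(unname(ca["NNN"]), unname(cb["PPP"]))
  expect_equal(unname(ca["PPP"]), unname(cb["NNN"]))
  expect_equal(unname(ca["NNP"]), unname(cb["NPP"]))
  expect_equal(unname(ca["NPP"]), unname(cb["NNP"]))
  # per-triplet: position order reverses
  ta <- tripletTable(a); tb <- tripletTable(b)
  keyA <- paste(ta$gene_a, ta$gene_b, ta$gene_c)
  keyB <- paste(tb$gene_a, tb$gene_b, tb$gene_c)
  idx <- match(keyA, keyB)
  expect_false(anyNA(idx))
  expect_equal(tb$score_i[idx], -ta$score_iii)
  expect_equal(tb$score_iii[idx], -ta$score_i)
})

test_that("edge participation accounting is consistent", {
  net <- randomSignedNetwork(14, 0.4, seed = 11)
  census <- enumerateTriplets(net)
  ep <- edgeParticipation(census)
  expect_equal(sum(ep$n_triplets), 3L * nrow(tripletTable(census)))
  expect_equal(ep$n_triplets, ep$n_NNN + ep$n_NNP + ep$n_NPP + ep$n_PPP)
})

test_that("participation summary matches hand counts", {
  oneNNP <- SignedNetwork(edges = data.frame(
    gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
    sign = c("N", "N", "P"), score = c(-2, -1, 1)))
  s <- participationSummary(enumerateTriplets(oneNNP))
  expect_equal(s$fraction_negative, 2 / 3)
  expect_equal(s$mean_triplets_per_N_edge, 1)
  expect_equal(s$mean_triplets_per_P_edge, 1)

  # two all-negative triangles sharing edge a-b: 5 unique edges, shared
  # edge participates twice -> mean 6/5
  twoNNN <- SignedNetwork(edges = data.frame(
    gene_a = c("a", "a", "b", "a", "b"),
    gene_b = c("b", "c", "c", "d", "d"),
    sign = "N", score = -(1:5)))
  s2 <- participationSummary(enumerateTriplets(twoNNN))
  expect_equal(s2$n_edges_in_triplets, 5L)
  expect_equal(s2$mean_triplets_per_N_edge, 6 / 5)
  expect_true(is.na(s2$mean_triplets_per_P_edge))

  empty <- SignedNetwork(edges = data.frame(
    gene_a = "a", gene_b = "b", sign = "N", score = -1))
  s3 <- participationSummary(enumerateTriplets(empty))
  expect_false(s3$defined)
  expect_true(is.na(s3$fraction_negative))
})

test_that("gene sign polarity uses an exact two-sided binomial test", {
  net <- SignedNetwork(edges = data.frame(
    gene_a = "hub", gene_b = sprintf("x%d", 1:5),
    sign = "N", score = -(1:5)))
  pol <- geneSignPolarity(net)
  hub <- pol[pol$gene == "hub", ]
  expect_equal(hub$fraction_negative, 1.0)
  expect_equal(hub$p_value, 2 * 0.5^5)

  bal <- SignedNetwork(edges = data.frame(
    gene_a = "g", gene_b = sprintf("x%d", 1:6),
    sign = rep(c("N", "P"), 3), score = rep(c(-1, 1), 3)))
  pg <- geneSignPolarity(bal)
  expect_equal(pg$p_value[pg$gene == "g"], 1.0)
  expect_equal(pg$fraction_negative[pg$gene == "g"], 0.5)

  # isolated genes are excluded
  iso <- SignedNetwork(genes = c("a", "b", "lonely"),
                       edges = data.frame(gene_a = "a", gene_b = "b",
                                          sign = "P", score = 2))
  expect_false("lonely" %in% geneSignPolarity(iso)$gene)
})
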