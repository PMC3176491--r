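#' Enumerate and classify closed triplet motifs
#'
#' Finds every unordered gene triple whose three pairs are all edges of the
#' signed network, classifies each triangle by the multiset of its edge
#' signs (NNN, NNP, NPP, PPP), and orders its edges by ascending S-score:
#' position i is the most negative edge, position iii the most positive.
#' Ties in score are broken lexicographically on the sorted gene-pair
#' labels so position codes are deterministic.
#'
#' @param x a [SignedNetwork-class].
#' @return A [TripletCensus-class]. Its \code{edgeParticipation} table covers
#'   every network edge (zero counts for edges in no triangle), which is
#'   what the edge-context fold-change analysis needs as baseline.
#' @examples
#' net <- SignedNetwork(edges = data.frame(
#'   gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
#'   sign = c("N", "N", "P"), score = c(-3.2, -1.1, 2.5)))
#' motifCounts(enumerateTriplets(net))
#' @export
enumerateTriplets <- function(x) {
  stopifnot(is(x, "SignedNetwork"))
  e <- x@edges
  genes <- x@genes
  counts <- integer(4)
  names(counts) <- MOTIF_CLASSES
  zero <- integer(nrow(e))
  ep <- data.frame(gene_a = e$gene_a, gene_b = e$gene_b, sign = e$sign,
                   score = e$score, n_triplets = zero, n_NNN = zero,
                   n_NNP = zero, n_NPP = zero, n_PPP = zero,
                   stringsAsFactors = FALSE)
  emptyTriplets <- data.frame(
    gene_a = character(), gene_b = character(), gene_c = character(),
    class = character(), score_i = numeric(), score_ii = numeric(),
    score_iii = numeric(), pair_i = character(), pair_ii = character(),
    pair_iii = character(), stringsAsFactors = FALSE)
  if (length(genes) < 3L || nrow(e) < 3L)
    return(new("TripletCensus", triplets = emptyTriplets, counts = counts,
               edgeParticipation = ep))
  ia <- match(e$gene_a, genes)
  ib <- match(e$gene_b, genes)
  tri <- triangles_cpp(length(genes), ia, ib)
  if (!nrow(tri))
    return(new("TripletCensus", triplets = emptyTriplets, counts = counts,
               edgeParticipation = ep))
  edgeKey <- pairKey(e$gene_a, e$gene_b)
  lookup <- seq_len(nrow(e))
  names(lookup) <- edgeKey
  g1 <- genes[tri[, 1]]; g2 <- genes[tri[, 2]]; g3 <- genes[tri[, 3]]
  k12 <- pairKey(g1, g2); k13 <- pairKey(g1, g3); k23 <- pairKey(g2, g3)
  i12 <- lookup[k12]; i13 <- lookup[k13]; i23 <- lookup[k23]
  scoreMat <- cbind(e$score[i12], e$score[i13], e$score[i23])
  keyMat <- cbind(k12, k13, k23)
  isNeg <- cbind(e$sign[i12] == "N", e$sign[i13] == "N", e$sign[i23] == "N")
  cls <- classFromNegCount(rowSums(isNeg))
  # order the three edges of each triplet by (score, pair label)
  ord <- t(vapply(seq_len(nrow(scoreMat)), function(r) {
    order(scoreMat[r, ], keyMat[r, ])
  }, integer(3)))
  rows <- seq_len(nrow(scoreMat))
  sI <- scoreMat[cbind(rows, ord[, 1])]
  sII <- scoreMat[cbind(rows, ord[, 2])]
  sIII <- scoreMat[cbind(rows, ord[, 3])]
  pI <- keyMat[cbind(rows, ord[, 1])]
  pII <- keyMat[cbind(rows, ord[, 2])]
  pIII <- keyMat[cbind(rows, ord[, 3])]
  triplets <- data.frame(gene_a = g1, gene_b = g2, gene_c = g3,
                         class = cls, score_i = sI, score_ii = sII,
                         score_iii = sIII, pair_i = pI, pair_ii = pII,
                         pair_iii = pIII, stringsAsFactors = FALSE)
  tab <- table(factor(cls, levels = MOTIF_CLASSES))
  counts <- as.integer(tab)
  names(counts) <- MOTIF_CLASSES
  allIdx <- c(i12, i13, i23)
  allCls <- rep(cls, 3L)
  ep$n_triplets <- tabulate(allIdx, nbins = nrow(e))
  for (cl in MOTIF_CLASSES) {
    ep[[paste0("n_", cl)]] <-
      tabulate(allIdx[allCls == cl], nbins = nrow(e))
  }
  new("TripletCensus", triplets = triplets, counts = counts,
      edgeParticipation = ep)
}

#' Per-sign triplet participation of network edges
#'
#' Among edges participating in at least one triplet: the fraction that are
#' negative, and the mean number of triplets an N edge and a P edge take
#' part in. Negative epistatic pairs typically recur in more triplets than
#' positive ones, which inflates NNN/NNP counts relative to the pool of
#' unique negative edges.
#'
#' @param census a [TripletCensus-class].
#' @return list with \code{n_edges_in_triplets},
#'   \code{fraction_negative}, \code{mean_triplets_per_N_edge},
#'   \code{mean_triplets_per_P_edge} and \code{defined} (FALSE when the
#'   census has no triplets, in which case the statistics are NA).
#' @export
participationSummary <- function(census) {
  stopifnot(is(census, "TripletCensus"))
  ep <- census@edgeParticipation
  inTrip <- ep[ep$n_triplets > 0L, , drop = FALSE]
  if (!nrow(inTrip)) {
    return(list(n_edges_in_triplets = 0L, fraction_negative = NA_real_,
                mean_triplets_per_N_edge = NA_real_,
                mean_triplets_per_P_edge = NA_real_, defined = FALSE))
  }
  isN <- inTrip$sign == "N"
  list(n_edges_in_triplets = nrow(inTrip),
       fraction_negative = mean(isN),
       mean_triplets_per_N_edge =
         if (any(isN)) mean(inTrip$n_triplets[isN]) else NA_real_,
       mean_triplets_per_P_edge =
         if (any(!isN)) mean(inTrip$n_triplets[!isN]) else NA_real_,
       defined = TRUE)
}

#' Sign polarity of individual genes
#'
#' Many genes interact predominantly through negative or predominantly
#' through positive epistasis even when the network holds equal numbers of
#' each sign overall. For each gene with at least one edge this computes the
#' negative fraction of its edges and a two-sided exact binomial test
#' against an even 0.5 split, Bonferroni-corrected across genes.
#'
#' @param x a [SignedNetwork-class].
#' @return data.frame with columns \code{gene}, \code{n_degree},
#'   \code{p_degree}, \code{fraction_negative}, \code{p_value},
#'   \code{p_bonferroni}; genes with zero edges are excluded.
#' @export
geneSignPolarity <- function(x) {
  stopifnot(is(x, "SignedNetwork"))
  deg <- signedDegrees(x)
  deg <- deg[deg$degree > 0L, , drop = FALSE]
  if (!nrow(deg)) {
    return(data.frame(gene = character(), n_degree = integer(),
                      p_degree = integer(), fraction_negative = numeric(),
                      p_value = numeric(), p_bonferroni = numeric(),
                      stringsAsFactors = FALSE))
  }
  p <- vapply(seq_len(nrow(deg)), function(i) {
    stats::binom.test(deg$n_degree[i], deg$degree[i], p = 0.5)$p.value
  }, numeric(1))
  out <- data.frame(gene = deg$gene, n_degree = deg$n_degree,
                    p_degree = deg$p_degree,
                    fraction_negative = deg$n_degree / deg$degree,
                    p_value = p,
                    p_bonferroni = pmin(1, p * nrow(deg)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write the triplet table as TSV
#'
#' One row per triplet: the three genes, the motif class and the three
#' S-scores in position order (most negative first).
#'
#' @param census a [TripletCensus-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTripletTable <- function(census, path) {
  stopifnot(is(census, "TripletCensus"))
  cols <- c("gene_a", "gene_b", "gene_c", "class",
            "score_i", "score_ii", "score_iii")
  utils::write.table(census@triplets[, cols], file = path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
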