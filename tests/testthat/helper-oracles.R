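# Independent oracles and fixture builders used across test files.
# These deliberately use naive algorithms (triple loops, full enumeration)
# so they cannot share a bug with the package's implementations.

# random signed network: each pair kept with probability p, score N(0,2),
# sign from the score's side of zero
randomSignedNetwork <- function(nGenes, p, seed) {
  set.seed(seed)
  genes <- sprintf("n%02d", seq_len(nGenes))
  cmb <- utils::combn(genes, 2)
  keep <- stats::runif(ncol(cmb)) < p
  score <- stats::rnorm(sum(keep), 0, 2)
  score[score == 0] <- 0.1
  SignedNetwork(genes = genes,
                edges = data.frame(gene_a = cmb[1, keep],
                                   gene_b = cmb[2, keep],
                                   sign = ifelse(score < 0, "N", "P"),
                                   score = score,
                                   stringsAsFactors = FALSE))
}

# exhaustive triple-loop triplet oracle: returns a sorted character vector,
# one canonical string per closed triplet (genes, class, ordered scores)
bruteTriplets <- function(net) {
  e <- networkEdges(net)
  genes <- networkGenes(net)
  key <- paste(e$gene_a, e$gene_b, sep = "|")
  scoreOf <- stats::setNames(e$score, key)
  signOf <- stats::setNames(e$sign, key)
  out <- character()
  n <- length(genes)
  if (n < 3) return(out)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    g <- genes[c(i, j, k)]
    k1 <- paste(min(g[1], g[2]), max(g[1], g[2]), sep = "|")
    k2 <- paste(min(g[1], g[3]), max(g[1], g[3]), sep = "|")
    k3 <- paste(min(g[2], g[3]), max(g[2], g[3]), sep = "|")
    kk <- c(k1, k2, k3)
    if (!all(kk %in% key)) next
    sc <- scoreOf[kk]
    ord <- order(sc, kk)
    nneg <- sum(signOf[kk] == "N")
    cls <- c("PPP", "NPP", "NNP", "NNN")[nneg + 1]
    out <- c(out, paste(paste(sort(g), collapse = ","), cls,
                        paste(sprintf("%.9g", sc[ord]), collapse = ","),
                        sep = ";"))
  }
  sort(out)
}

# canonical strings for a TripletCensus, comparable with bruteTriplets()
censusStrings <- function(census) {
  tr <- tripletTable(census)
  if (!nrow(tr)) return(character())
  sort(paste(
    paste(tr$gene_a, tr$gene_b, tr$gene_c, sep = ","), tr$class,
    paste(sprintf("%.9g", tr$score_i), sprintf("%.9g", tr$score_ii),
          sprintf("%.9g", tr$score_iii), sep = ","),
    sep = ";"))
}

# exhaustive enumeration of every simple signed graph with the same signed
# degree sequence as `net` (N and P edge sets disjoint on pairs); returns
# the per-class triangle count of each graph as a matrix
enumerateSignedDegreeGraphs <- function(net) {
  genes <- networkGenes(net)
  n <- length(genes)
  e <- networkEdges(net)
  degOf <- function(sgn) {
    tab <- table(factor(c(e$gene_a[e$sign == sgn], e$gene_b[e$sign == sgn]),
                        levels = genes))
    as.integer(tab)
  }
  nDeg <- degOf("N"); pDeg <- degOf("P")
  mN <- sum(nDeg) / 2; mP <- sum(pDeg) / 2
  cmb <- utils::combn(n, 2)
  nPairs <- ncol(cmb)
  pairDeg <- function(idx) {
    tabulate(c(cmb[1, idx], cmb[2, idx]), nbins = n)
  }
  classCounts <- function(nIdx, pIdx) {
    sgn <- integer(nPairs)
    sgn[nIdx] <- 1L; sgn[pIdx] <- 2L
    cnt <- c(NNN = 0L, NNP = 0L, NPP = 0L, PPP = 0L)
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      idx <- c(which(cmb[1, ] == i & cmb[2, ] == j),
               which(cmb[1, ] == i & cmb[2, ] == k),
               which(cmb[1, ] == j & cmb[2, ] == k))
      s <- sgn[idx]
      if (any(s == 0L)) next
      nneg <- sum(s == 1L)
      cnt[c("PPP", "NPP", "NNP", "NNN")[nneg + 1]] <-
        cnt[c("PPP", "NPP", "NNP", "NNN")[nneg + 1]] + 1L
    }
    cnt
  }
  res <- list()
  nSets <- if (mN > 0) utils::combn(nPairs, mN, simplify = FALSE) else
    list(integer())
  for (nIdx in nSets) {
    if (!identical(pairDeg(nIdx), nDeg)) next
    remaining <- setdiff(seq_len(nPairs), nIdx)
    pSets <- if (mP > 0) utils::combn(remaining, mP, simplify = FALSE) else
      list(integer())
    for (pIdx in pSets) {
      if (!identical(pairDeg(pIdx), pDeg)) next
      res[[length(res) + 1L]] <- classCounts(nIdx, pIdx)
    }
  }
  do.call(rbind, res)
}

# triple-loop class counter from an edge-key/sign map (independent of the
# package's triangle code); returns counts named NNN, NNP, NPP, PPP
bruteTripletsSigns <- function(genes, edgeKeys, signs) {
  signOf <- stats::setNames(signs, edgeKeys)
  cnt <- c(NNN = 0L, NNP = 0L, NPP = 0L, PPP = 0L)
  n <- length(genes)
  if (n < 3) return(cnt)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    g <- genes[c(i, j, k)]
    kk <- c(paste(min(g[1], g[2]), max(g[1], g[2]), sep = "|"),
            paste(min(g[1], g[3]), max(g[1], g[3]), sep = "|"),
            paste(min(g[2], g[3]), max(g[2], g[3]), sep = "|"))
    s <- signOf[kk]
    if (anyNA(s)) next
    cls <- c("PPP", "NPP", "NNP", "NNN")[sum(s == "N") + 1]
    cnt[cls] <- cnt[cls] + 1L
  }
  cnt
}

# brute-force two-sided Fisher exact p: enumerate all 2x2 tables with the
# observed margins, sum the probabilities of tables no more probable than
# the observed one (with the conventional relative tolerance for FP ties)
fisherOracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; K <- a + c
  lo <- max(0, K - n); hi <- min(K, m)
  pk <- function(k) {
    exp(lchoose(m, k) + lchoose(n, K - k) - lchoose(m + n, K))
  }
  pObs <- pk(a)
  tot <- 0
  for (k in lo:hi) {
    p <- pk(k)
    if (p <= pObs * (1 + 1e-7)) tot <- tot + p
  }
  min(1, tot)
}

# tiny AnnotationSet builders
termChannel <- function(...) {
  lst <- list(...)
  lapply(lst, as.character)
}
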