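#' Construct a SignedNetwork directly from an edge table
#'
#' Mostly useful for tests and simulations; analysis networks are normally
#' produced by [thresholdScores()].
#'
#' @param genes character vector of node gene ids (defaults to the genes
#'   occurring in \code{edges}, sorted).
#' @param edges data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{sign} ("N"/"P") and \code{score}.
#' @param cutoffs named numeric \code{c(negative=, positive=)}; defaults to
#'   the observed extreme scores per sign.
#' @return A [SignedNetwork-class].
#' @export
SignedNetwork <- function(genes = NULL, edges = emptyEdges(),
                          cutoffs = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    a <- pmin(edges$gene_a, edges$gene_b)
    b <- pmax(edges$gene_a, edges$gene_b)
    edges <- data.frame(gene_a = a, gene_b = b,
                        sign = as.character(edges$sign),
                        score = as.numeric(edges$score),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  if (is.null(genes))
    genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  if (is.null(cutoffs)) {
    neg <- edges$score[edges$sign == "N"]
    pos <- edges$score[edges$sign == "P"]
    cutoffs <- c(negative = if (length(neg)) max(neg) else -Inf,
                 positive = if (length(pos)) min(pos) else Inf)
  }
  new("SignedNetwork", genes = as.character(genes), edges = edges,
      cutoffs = cutoffs)
}

#' Threshold an S-score matrix into a signed epistasis network
#'
#' Classifies gene pairs as positive, negative or neutral using symmetric
#' percentile cutoffs: with tail mass \code{percentile} = X per cent per
#' side, the lower cutoff is the X-th percentile and the upper cutoff the
#' (100-X)-th percentile of all stored scores (each unordered pair counted
#' once, nearest-rank estimator applied symmetrically from each end of the
#' sorted list). Pairs scoring at or below the lower cutoff become negative
#' (N) edges, at or above the upper cutoff positive (P) edges; everything in
#' between is neutral and excluded. This mirrors the usual choice of the
#' extreme 1\% of S-scores on each side.
#'
#' @param x a [ScoreMatrix-class] with at least one stored pair.
#' @param percentile tail mass per side, in percent; in (0, 50].
#' @return A [SignedNetwork-class] whose nodes are all genes incident to a
#'   retained edge, with the realized cutoffs recorded.
#' @details Cutoff comparisons are inclusive, so ties at a cutoff are always
#'   admitted. In the degenerate case where a score satisfies both cutoffs
#'   (possible when the distribution has a heavy atom) the edge is signed N
#'   when the score is <= 0 and P otherwise, keeping one edge per pair. A
#'   warning is issued if either side is empty.
#' @examples
#' sm <- ScoreMatrix(pairs = data.frame(
#'   gene_a = paste0("g", 1:10), gene_b = paste0("h", 1:10),
#'   score = c(-5:-1, 1:5)))
#' net <- thresholdScores(sm, percentile = 10)
#' networkEdges(net)
#' @export
thresholdScores <- function(x, percentile = 1) {
  stopifnot(is(x, "ScoreMatrix"))
  if (!nrow(x@pairs)) stop("ScoreMatrix has no stored pairs")
  if (percentile <= 0 || percentile > 50)
    stop("percentile must be in (0, 50]")
  s <- sort(x@pairs$score)
  n <- length(s)
  k <- ceiling(n * percentile / 100)
  lower <- s[k]
  upper <- s[n - k + 1L]
  p <- x@pairs
  isN <- p$score <= lower
  isP <- p$score >= upper
  both <- isN & isP
  if (any(both)) {
    isN[both] <- p$score[both] <= 0
    isP[both] <- !isN[both]
  }
  if (!any(isN)) warning("no negative edges at this percentile")
  if (!any(isP)) warning("no positive edges at this percentile")
  keep <- isN | isP
  edges <- data.frame(gene_a = p$gene_a[keep], gene_b = p$gene_b[keep],
                      sign = ifelse(isN[keep], "N", "P"),
                      score = p$score[keep], stringsAsFactors = FALSE)
  SignedNetwork(genes = sort(unique(c(edges$gene_a, edges$gene_b))),
                edges = edges,
                cutoffs = c(negative = lower, positive = upper))
}

#' Per-gene signed degrees of a network
#'
#' @param x a [SignedNetwork-class].
#' @return data.frame with columns \code{gene}, \code{n_degree},
#'   \code{p_degree}, \code{degree}, one row per network gene (including
#'   isolated genes, with zeros).
#' @export
signedDegrees <- function(x) {
  stopifnot(is(x, "SignedNetwork"))
  e <- x@edges
  gmap <- factor(c(e$gene_a, e$gene_b), levels = x@genes)
  sgn <- rep(e$sign, 2L)
  nd <- table(gmap[sgn == "N"])
  pd <- table(gmap[sgn == "P"])
  data.frame(gene = x@genes,
             n_degree = as.integer(nd),
             p_degree = as.integer(pd),
             degree = as.integer(nd) + as.integer(pd),
             stringsAsFactors = FALSE)
}

#' Remove genes with too few supra-threshold interactions
#'
#' Genes that do not achieve at least \code{minDegree} interaction scores
#' beyond the threshold (counting N and P edges together) are excluded with
#' all their incident edges. The default is a single pass computed on the
#' input network: genes are judged on their thresholded degree, so a gene is
#' retained even if removals drop its residual degree below the minimum.
#' Set \code{iterate = TRUE} to instead repeat the filter until a fixpoint.
#'
#' @param x a [SignedNetwork-class], usually from [thresholdScores()].
#' @param minDegree minimum total signed degree to keep a gene (default 2,
#'   the conventional "two or more interactions" noise filter).
#' @param iterate logical; re-filter on the reduced network until stable.
#' @return A [SignedNetwork-class]; never adds edges or nodes.
#' @export
filterLowDegree <- function(x, minDegree = 2, iterate = FALSE) {
  stopifnot(is(x, "SignedNetwork"))
  repeat {
    deg <- signedDegrees(x)
    keep <- deg$gene[deg$degree >= minDegree]
    if (length(keep) == length(x@genes)) break
    e <- x@edges
    e <- e[e$gene_a %in% keep & e$gene_b %in% keep, , drop = FALSE]
    rownames(e) <- NULL
    x <- new("SignedNetwork", genes = keep, edges = e, cutoffs = x@cutoffs)
    if (!iterate) break
  }
  x
}

#' Write a signed network as a long-form edge TSV
#'
#' One row per edge: \code{gene_a gene_b sign s_score}, the binary
#' interaction set underlying the triplet census.
#'
#' @param x a [SignedNetwork-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSignedEdges <- function(x, path) {
  stopifnot(is(x, "SignedNetwork"))
  e <- x@edges
  names(e)[names(e) == "score"] <- "s_score"
  utils::write.table(e, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
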