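#' Construct a ScoreMatrix from a long-form pair table
#'
#' Builds a [ScoreMatrix-class] from explicit gene/pair data. Pairs are
#' canonicalized to \code{gene_a < gene_b}; duplicate orientations of the
#' same unordered pair are averaged.
#'
#' @param genes character vector of gene identifiers (defaults to the genes
#'   occurring in \code{pairs}, sorted).
#' @param pairs data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{score} and optionally \code{n_sources} (default 1).
#' @return A [ScoreMatrix-class].
#' @examples
#' sm <- ScoreMatrix(pairs = data.frame(gene_a = "g2", gene_b = "g1",
#'                                      score = -2.5))
#' scorePairs(sm)
#' @export
ScoreMatrix <- function(genes = NULL, pairs = emptyPairs()) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (is.null(pairs$n_sources)) pairs$n_sources <- rep(1L, nrow(pairs))
  if (nrow(pairs)) {
    a <- pmin(pairs$gene_a, pairs$gene_b)
    b <- pmax(pairs$gene_a, pairs$gene_b)
    keep <- a != b
    pairs <- data.frame(gene_a = a[keep], gene_b = b[keep],
                        score = as.numeric(pairs$score[keep]),
                        n_sources = as.integer(pairs$n_sources[keep]),
                        stringsAsFactors = FALSE)
    key <- paste(pairs$gene_a, pairs$gene_b, sep = "\r")
    if (anyDuplicated(key)) {
      sc <- tapply(pairs$score, key, mean)
      ns <- tapply(pairs$n_sources, key, max)
      first <- !duplicated(key)
      ord <- match(key[first], names(sc))
      pairs <- data.frame(gene_a = pairs$gene_a[first],
                          gene_b = pairs$gene_b[first],
                          score = as.numeric(sc[ord]),
                          n_sources = as.integer(ns[ord]),
                          stringsAsFactors = FALSE)
    }
    pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  if (is.null(genes))
    genes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  new("ScoreMatrix", genes = as.character(genes), pairs = pairs)
}

#' Read an E-MAP S-score matrix from a gene-by-gene TSV file
#'
#' The expected layout is a rectangular tab-separated matrix with gene
#' labels in the first row (columns) and first column (rows); empty cells
#' denote missing measurements. Row and column gene sets need not coincide
#' (E-MAP exports are often rectangular). Self-cells are ignored. If both
#' orientations of a pair are present with different values their mean is
#' stored and a message is emitted.
#'
#' @param path path to the TSV file.
#' @param naStrings character values treated as missing in addition to the
#'   empty cell (real E-MAP exports vary).
#' @return A [ScoreMatrix-class]; each stored pair has \code{n_sources = 1}.
#' @details Duplicate gene labels among rows or among columns are an error,
#'   as is any non-empty cell that does not parse as a number (reported with
#'   its row and column label).
#' @seealso [writeScoreMatrix()] for the inverse, [mergeScoreMatrices()].
#' @export
readScoreMatrix <- function(path, naStrings = c("", "NA", "NaN")) {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  if (nrow(raw) < 2L || ncol(raw) < 2L)
    stop("matrix file must have at least one gene row and one gene column")
  colGenes <- as.character(raw[1, -1])
  rowGenes <- as.character(raw[-1, 1])
  if (anyDuplicated(colGenes))
    stop("duplicate gene labels in header: ",
         paste(unique(colGenes[duplicated(colGenes)]), collapse = ", "))
  if (anyDuplicated(rowGenes))
    stop("duplicate gene labels in first column: ",
         paste(unique(rowGenes[duplicated(rowGenes)]), collapse = ", "))
  cells <- as.matrix(raw[-1, -1, drop = FALSE])
  miss <- is.na(cells) | cells %in% naStrings
  vals <- suppressWarnings(as.numeric(cells))
  bad <- which(!miss & is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                 cells[bad[1, , drop = FALSE]],
                 rowGenes[bad[1, 1]], colGenes[bad[1, 2]]))
  idx <- which(!miss, arr.ind = TRUE)
  ga <- rowGenes[idx[, 1]]
  gb <- colGenes[idx[, 2]]
  sc <- vals[!miss]
  keep <- ga != gb
  ga <- ga[keep]; gb <- gb[keep]; sc <- sc[keep]
  key <- pairKey(ga, gb)
  if (anyDuplicated(key)) {
    rng <- tapply(sc, key, function(v) diff(range(v)))
    nconf <- sum(rng > 0)
    if (nconf)
      message(sprintf(
        "%d pair(s) measured in both orientations with differing values; means stored",
        nconf))
  }
  genes <- sort(unique(c(rowGenes, colGenes)))
  ScoreMatrix(genes = genes,
              pairs = data.frame(gene_a = ga, gene_b = gb, score = sc,
                                 stringsAsFactors = FALSE))
}

#' Merge several ScoreMatrix objects by averaging shared pairs
#'
#' Takes the union of gene sets; for each unordered pair the stored score is
#' the arithmetic mean of that pair's scores across all matrices in which
#' the pair is measured, and \code{n_sources} records how many matrices
#' contributed. This is the standard rule for assembling an E-MAP compendium
#' from multiple published screens.
#'
#' @param matrices non-empty list of [ScoreMatrix-class] objects.
#' @return A merged [ScoreMatrix-class]. The result is invariant to the
#'   order of the input list.
#' @export
mergeScoreMatrices <- function(matrices) {
  if (!length(matrices)) stop("need at least one ScoreMatrix to merge")
  stopifnot(all(vapply(matrices, is, logical(1), "ScoreMatrix")))
  allPairs <- do.call(rbind, lapply(matrices, function(m) {
    p <- m@pairs
    # a source that itself merged k datasets contributes k scores' mean with
    # weight n_sources, so the compendium mean is the weighted mean
    p
  }))
  genes <- sort(unique(unlist(lapply(matrices, scoreGenes))))
  if (!nrow(allPairs))
    return(ScoreMatrix(genes = genes))
  key <- paste(allPairs$gene_a, allPairs$gene_b, sep = "\r")
  w <- allPairs$n_sources
  num <- tapply(allPairs$score * w, key, sum)
  den <- tapply(w, key, sum)
  first <- !duplicated(key)
  ord <- match(key[first], names(num))
  pairs <- data.frame(gene_a = allPairs$gene_a[first],
                      gene_b = allPairs$gene_b[first],
                      score = as.numeric(num[ord] / den[ord]),
                      n_sources = as.integer(den[ord]),
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
  rownames(pairs) <- NULL
  new("ScoreMatrix", genes = genes, pairs = pairs)
}

#' Fraction of unmeasured gene pairs in a ScoreMatrix
#'
#' @param x a [ScoreMatrix-class].
#' @return \code{1 - stored_pairs / choose(n_genes, 2)}; NA for fewer than
#'   two genes.
#' @export
missingFraction <- function(x) {
  stopifnot(is(x, "ScoreMatrix"))
  n <- length(x@genes)
  if (n < 2L) return(NA_real_)
  1 - nrow(x@pairs) / choose(n, 2)
}

#' Write a ScoreMatrix as a wide gene-by-gene TSV
#'
#' Writes the full symmetric matrix with empty cells for missing pairs, the
#' format [readScoreMatrix()] reads back (read/write round-trips on the
#' stored pair map).
#'
#' @param x a [ScoreMatrix-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeScoreMatrix <- function(x, path) {
  stopifnot(is(x, "ScoreMatrix"))
  genes <- x@genes
  m <- matrix("", length(genes), length(genes),
              dimnames = list(genes, genes))
  p <- x@pairs
  if (nrow(p)) {
    sc <- format(p$score, trim = TRUE, digits = 15)
    m[cbind(p$gene_a, p$gene_b)] <- sc
    m[cbind(p$gene_b, p$gene_a)] <- sc
  }
  out <- cbind(gene = genes, m)
  utils::write.table(rbind(colnames(out), out), file = path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a ScoreMatrix in canonical long form
#'
#' One row per stored pair: \code{gene_a gene_b score n_sources}, with
#' \code{gene_a < gene_b} lexicographically.
#'
#' @param x a [ScoreMatrix-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeScorePairs <- function(x, path) {
  stopifnot(is(x, "ScoreMatrix"))
  utils::write.table(x@pairs, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
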