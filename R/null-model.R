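#' Signed-degree-preserving network randomization
#'
#' Rewires a signed network by edge switching: repeatedly picks two edges of
#' the same sign and exchanges their endpoints, rejecting any switch that
#' would create a self-loop or place a second edge (of either sign) on an
#' occupied gene pair. Every node's negative degree and positive degree are
#' preserved exactly, and the graph stays simple. The N and P edge sets are
#' switched as independent chains; chains for the two signs are run in
#' alternating blocks so the pair-occupancy constraint between signs is
#' itself resampled (a Gibbs-style scan whose stationary distribution is
#' uniform over simple signed graphs with the given signed degree sequence).
#'
#' @param x a [SignedNetwork-class].
#' @param q attempted switches per edge and per sign class (default 100,
#'   a standard mixing allowance for switching chains).
#' @param seed integer seed; fixing it fixes the draw.
#' @param rounds number of alternating N/P blocks the q switches per edge
#'   are divided over (default 3).
#' @return A [SignedNetwork-class] with the same genes and cutoffs; edge
#'   S-scores travel with the switched edge slots, so the score multiset per
#'   sign is preserved. The number of rejected switch attempts is attached
#'   as attribute \code{"rejected"}.
#' @export
randomizeNetwork <- function(x, q = 100, seed = 1L, rounds = 3L) {
  stopifnot(is(x, "SignedNetwork"))
  if (q <= 0) stop("q must be positive")
  e <- x@edges
  genes <- x@genes
  idx <- list(N = which(e$sign == "N"), P = which(e$sign == "P"))
  if (max(lengths(idx)) < 2L)
    stop("network needs >= 2 edges of at least one sign")
  # 0-based endpoint indices per sign class
  ends <- lapply(idx, function(i) {
    list(a = match(e$gene_a[i], genes) - 1L,
         b = match(e$gene_b[i], genes) - 1L,
         score = e$score[i])
  })
  perRound <- lapply(idx, function(i) {
    tot <- q * length(i)
    base <- rep(tot %/% rounds, rounds)
    base[seq_len(tot %% rounds)] <- base[seq_len(tot %% rounds)] + 1L
    base
  })
  rejected <- 0L
  counter <- 0L
  for (r in seq_len(rounds)) {
    for (sgn in c("N", "P")) {
      other <- if (sgn == "N") "P" else "N"
      att <- perRound[[sgn]][r]
      if (att == 0L || length(ends[[sgn]]$a) < 2L) next
      counter <- counter + 1L
      res <- switch_edges_cpp(ends[[sgn]]$a, ends[[sgn]]$b,
                              ends[[other]]$a, ends[[other]]$b,
                              length(genes), as.integer(att),
                              deriveSeed(seed, counter))
      ends[[sgn]]$a <- res$gene_a
      ends[[sgn]]$b <- res$gene_b
      rejected <- rejected + res$rejected
    }
  }
  newEdges <- do.call(rbind, lapply(c("N", "P"), function(sgn) {
    en <- ends[[sgn]]
    if (!length(en$a)) return(NULL)
    data.frame(gene_a = genes[en$a + 1L], gene_b = genes[en$b + 1L],
               sign = sgn, score = en$score, stringsAsFactors = FALSE)
  }))
  out <- SignedNetwork(genes = genes, edges = newEdges, cutoffs = x@cutoffs)
  attr(out, "rejected") <- rejected
  out
}

#' Motif enrichment against the degree-preserving null ensemble
#'
#' Compares the observed triplet count of each motif class with its
#' distribution over \code{nRandom} independent randomizations of the
#' network (each draw from [randomizeNetwork()] with a seed derived from
#' \code{seed}). The z-score is the number of null standard deviations
#' (sample SD, n-1 denominator) separating the observed count from the null
#' mean; |z| of about 2 corresponds to a two-sided normal p of about 0.05.
#'
#' @param x a [SignedNetwork-class].
#' @param nRandom ensemble size (default 1000; at least 2 so an SD exists).
#' @param q attempted switches per edge and sign class per draw.
#' @param seed integer seed for the ensemble streams.
#' @return A [NullSummary-class]. z is NA where the null SD is zero (e.g. a
#'   rigid degree sequence realized by a single simple graph).
#' @export
motifEnrichment <- function(x, nRandom = 1000, q = 100, seed = 1L) {
  stopifnot(is(x, "SignedNetwork"))
  if (nRandom < 2) stop("nRandom must be >= 2 for a null SD to exist")
  observed <- motifCounts(enumerateTriplets(x))
  draws <- matrix(0L, nRandom, 4L, dimnames = list(NULL, MOTIF_CLASSES))
  # a network with < 2 edges in both sign classes is rigid under edge
  # switching: the ensemble is the observed graph itself
  rigid <- max(table(factor(x@edges$sign, levels = c("N", "P")))) < 2L
  if (rigid) draws[] <- rep(observed, each = nRandom)
  for (i in if (rigid) integer() else seq_len(nRandom)) {
    r <- randomizeNetwork(x, q = q, seed = deriveSeed(seed, i * 7L))
    e <- r@edges
    cc <- triangle_class_counts_cpp(length(r@genes),
                                    match(e$gene_a, r@genes),
                                    match(e$gene_b, r@genes),
                                    as.integer(e$sign == "N"))
    # counts indexed by number of negative edges 0..3 = PPP NPP NNP NNN
    draws[i, ] <- cc[c(4L, 3L, 2L, 1L)]
  }
  mu <- colMeans(draws)
  sdev <- apply(draws, 2, stats::sd)
  z <- ifelse(sdev > 0, (observed - mu) / sdev, NA_real_)
  tab <- data.frame(class = MOTIF_CLASSES,
                    observed = as.integer(observed),
                    mean = as.numeric(mu), sd = as.numeric(sdev),
                    z = as.numeric(z), stringsAsFactors = FALSE)
  new("NullSummary", table = tab, nRandom = as.integer(nRandom),
      q = as.integer(q), seed = as.integer(seed))
}

#' Write a null-model summary as TSV (and optionally JSON parameters)
#'
#' @param x a [NullSummary-class].
#' @param path output TSV path (\code{class observed mean sd z}).
#' @param jsonPath optional path for a JSON record of the ensemble
#'   parameters alongside the table.
#' @return \code{path}, invisibly.
#' @export
writeNullSummary <- function(x, path, jsonPath = NULL) {
  stopifnot(is(x, "NullSummary"))
  utils::write.table(x@table, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(jsonPath)) {
    jsonlite::write_json(
      list(n_random = x@nRandom, q = x@q, seed = x@seed,
           classes = x@table),
      jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
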