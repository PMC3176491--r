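#' Accessors for emapMotifs objects
#'
#' @param x a [ScoreMatrix-class], [SignedNetwork-class],
#'   [TripletCensus-class], [NullSummary-class] or [AnnotationSet-class].
#' @return \code{scoreGenes}/\code{networkGenes}: character vector of gene
#'   ids. \code{scorePairs}: data.frame of stored pairs.
#'   \code{networkEdges}: data.frame of signed edges. \code{networkCutoffs}:
#'   the realized (negative, positive) score thresholds.
#'   \code{tripletTable}: data.frame of classified triplets.
#'   \code{motifCounts}: named integer of class counts.
#'   \code{edgeParticipation}: per-edge triplet participation table.
#'   \code{nullTable}: observed/mean/sd/z table of the null ensemble.
#'   \code{annotationChannels}: character vector of channel names.
#'
#' @name accessors
#' @aliases scoreGenes scorePairs networkGenes networkEdges networkCutoffs
#'   tripletTable motifCounts edgeParticipation nullTable annotationChannels
NULL

#' @rdname accessors
#' @export
setGeneric("scoreGenes", function(x) standardGeneric("scoreGenes"))
#' @rdname accessors
#' @export
setGeneric("scorePairs", function(x) standardGeneric("scorePairs"))
#' @rdname accessors
#' @export
setGeneric("networkGenes", function(x) standardGeneric("networkGenes"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("networkCutoffs", function(x) standardGeneric("networkCutoffs"))
#' @rdname accessors
#' @export
setGeneric("tripletTable", function(x) standardGeneric("tripletTable"))
#' @rdname accessors
#' @export
setGeneric("motifCounts", function(x) standardGeneric("motifCounts"))
#' @rdname accessors
#' @export
setGeneric("edgeParticipation",
           function(x) standardGeneric("edgeParticipation"))
#' @rdname accessors
#' @export
setGeneric("nullTable", function(x) standardGeneric("nullTable"))
#' @rdname accessors
#' @export
setGeneric("annotationChannels",
           function(x) standardGeneric("annotationChannels"))

#' @rdname accessors
setMethod("scoreGenes", "ScoreMatrix", function(x) x@genes)
#' @rdname accessors
setMethod("scorePairs", "ScoreMatrix", function(x) x@pairs)
#' @rdname accessors
setMethod("networkGenes", "SignedNetwork", function(x) x@genes)
#' @rdname accessors
setMethod("networkEdges", "SignedNetwork", function(x) x@edges)
#' @rdname accessors
setMethod("networkCutoffs", "SignedNetwork", function(x) x@cutoffs)
#' @rdname accessors
setMethod("tripletTable", "TripletCensus", function(x) x@triplets)
#' @rdname accessors
setMethod("motifCounts", "TripletCensus", function(x) x@counts)
#' @rdname accessors
setMethod("edgeParticipation", "TripletCensus",
          function(x) x@edgeParticipation)
#' @rdname accessors
setMethod("nullTable", "NullSummary", function(x) x@table)
#' @rdname accessors
setMethod("annotationChannels", "AnnotationSet", function(x) {
  c(names(x@geneTerms), names(x@pairRelations))
})

setMethod("show", "ScoreMatrix", function(object) {
  n <- length(object@genes)
  m <- nrow(object@pairs)
  cat(sprintf("ScoreMatrix: %d genes, %d scored pairs (%.1f%% missing)\n",
              n, m, 100 * missingFraction(object)))
  if (m) {
    cat(sprintf("  score range [%.3g, %.3g]\n",
                min(object@pairs$score), max(object@pairs$score)))
  }
})

setMethod("show", "SignedNetwork", function(object) {
  tab <- table(factor(object@edges$sign, levels = c("N", "P")))
  cat(sprintf("SignedNetwork: %d genes, %d edges (%d N, %d P)\n",
              length(object@genes), nrow(object@edges), tab["N"], tab["P"]))
  cat(sprintf("  cutoffs: negative <= %.4g, positive >= %.4g\n",
              object@cutoffs["negative"], object@cutoffs["positive"]))
})

setMethod("show", "TripletCensus", function(object) {
  cat(sprintf("TripletCensus: %d triplets\n", nrow(object@triplets)))
  cat(sprintf("  %s\n", paste(names(object@counts), object@counts,
                              sep = "=", collapse = "  ")))
})

setMethod("show", "NullSummary", function(object) {
  cat(sprintf("NullSummary: %d randomizations, q = %d, seed = %d\n",
              object@nRandom, object@q, object@seed))
  print(object@table, row.names = FALSE, digits = 4)
})

setMethod("show", "AnnotationSet", function(object) {
  cat("AnnotationSet\n")
  for (ch in names(object@geneTerms)) {
    gt <- object@geneTerms[[ch]]
    cat(sprintf("  term channel %-16s: %d genes, %d distinct terms\n",
                ch, length(gt), length(unique(unlist(gt, use.names = FALSE)))))
  }
  for (ch in names(object@pairRelations)) {
    cat(sprintf("  pair channel %-16s: %d pairs\n",
                ch, length(object@pairRelations[[ch]])))
  }
})
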