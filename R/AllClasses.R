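#' @import methods
NULL

#' ScoreMatrix: a sparse symmetric gene-by-gene S-score map
#'
#' Stores a quantitative epistasis (E-MAP) score matrix in long form: each
#' measured unordered gene pair appears exactly once, with its S-score (the
#' dimensionless deviation of double-mutant colony size from the neutral
#' expectation) and the number of source datasets that contributed to the
#' (averaged) score. Missing measurements are simply absent pairs; real
#' E-MAP compendia are sparse (roughly three quarters of pairs untested).
#'
#' @slot genes character vector of unique gene identifiers.
#' @slot pairs data.frame with columns \code{gene_a}, \code{gene_b} (with
#'   \code{gene_a < gene_b} lexicographically), \code{score} (numeric) and
#'   \code{n_sources} (integer >= 1).
#'
#' @seealso [readScoreMatrix()], [mergeScoreMatrices()], [thresholdScores()]
#' @export
setClass("ScoreMatrix",
  slots = c(genes = "character", pairs = "data.frame"))

setValidity("ScoreMatrix", function(object) {
  p <- object@pairs
  need <- c("gene_a", "gene_b", "score", "n_sources")
  if (!all(need %in% names(p)))
    return(sprintf("pairs must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(object@genes))
    return("duplicate gene identifiers")
  if (nrow(p)) {
    if (any(p$gene_a == p$gene_b))
      return("self-pairs are not allowed")
    if (any(p$gene_a > p$gene_b))
      return("pairs must be ordered gene_a < gene_b")
    if (anyDuplicated(paste(p$gene_a, p$gene_b, sep = "\r")))
      return("duplicate gene pairs")
    if (!all(c(p$gene_a, p$gene_b) %in% object@genes))
      return("pair genes missing from the gene list")
    if (any(p$n_sources < 1L))
      return("n_sources must be >= 1 for every stored pair")
    if (any(!is.finite(p$score)))
      return("non-finite scores are not allowed")
  }
  TRUE
})

#' SignedNetwork: genes plus P/N-signed scored epistatic edges
#'
#' The result of thresholding a [ScoreMatrix-class] at symmetric percentile
#' cutoffs: every retained gene pair is an edge carrying its S-score and a
#' sign, \code{"N"} (negative epistasis, synthetic sick/lethal-like) or
#' \code{"P"} (positive epistasis, suppression/masking). At most one edge
#' per pair. The realized score cutoffs are recorded.
#'
#' @slot genes character vector of node gene identifiers.
#' @slot edges data.frame with columns \code{gene_a}, \code{gene_b}
#'   (\code{gene_a < gene_b}), \code{sign} ("N"/"P"), \code{score}.
#' @slot cutoffs named numeric of length 2, \code{c(negative=, positive=)}.
#'
#' @seealso [thresholdScores()], [filterLowDegree()], [enumerateTriplets()]
#' @export
setClass("SignedNetwork",
  slots = c(genes = "character", edges = "data.frame", cutoffs = "numeric"))

setValidity("SignedNetwork", function(object) {
  e <- object@edges
  need <- c("gene_a", "gene_b", "sign", "score")
  if (!all(need %in% names(e)))
    return(sprintf("edges must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(object@genes))
    return("duplicate gene identifiers")
  if (length(object@cutoffs) != 2L ||
      !all(c("negative", "positive") %in% names(object@cutoffs)))
    return("cutoffs must be named c(negative=, positive=)")
  if (nrow(e)) {
    if (any(e$gene_a >= e$gene_b))
      return("edges must be ordered gene_a < gene_b, no self-loops")
    if (anyDuplicated(paste(e$gene_a, e$gene_b, sep = "\r")))
      return("at most one edge per gene pair")
    if (!all(e$sign %in% c("N", "P")))
      return("edge signs must be 'N' or 'P'")
    if (!all(c(e$gene_a, e$gene_b) %in% object@genes))
      return("edge endpoints missing from the gene list")
  }
  TRUE
})

#' TripletCensus: classified closed triplets of a signed network
#'
#' Every unordered gene triple whose three pairs are all edges of the
#' network, classified by the multiset of edge signs into NNN, NNP, NPP or
#' PPP. Within a triplet the three edges are ordered by ascending S-score:
#' position i is the most negative edge, position iii the most positive.
#'
#' @slot triplets data.frame, one row per triplet: \code{gene_a},
#'   \code{gene_b}, \code{gene_c} (sorted), \code{class},
#'   \code{score_i}, \code{score_ii}, \code{score_iii}, and the pair keys
#'   \code{pair_i}, \code{pair_ii}, \code{pair_iii} of the edges at each
#'   position (two gene ids joined by "|", smaller first).
#' @slot counts named integer, triplet count per class (NNN, NNP, NPP, PPP).
#' @slot edgeParticipation data.frame, one row per network edge:
#'   \code{gene_a}, \code{gene_b}, \code{sign}, \code{score},
#'   \code{n_triplets} and per-class counts \code{n_NNN} ... \code{n_PPP}.
#'
#' @seealso [enumerateTriplets()], [participationSummary()]
#' @export
setClass("TripletCensus",
  slots = c(triplets = "data.frame", counts = "integer",
            edgeParticipation = "data.frame"))

setValidity("TripletCensus", function(object) {
  cls <- c("NNN", "NNP", "NPP", "PPP")
  if (!identical(names(object@counts), cls))
    return("counts must be named NNN, NNP, NPP, PPP")
  if (sum(object@counts) != nrow(object@triplets))
    return("counts must sum to the number of triplets")
  ep <- object@edgeParticipation
  if (nrow(ep) && sum(ep$n_triplets) != 3L * nrow(object@triplets))
    return("edge participation must sum to 3 x triplet count")
  TRUE
})

#' NullSummary: motif counts against a degree-preserving null ensemble
#'
#' Observed triplet counts per motif class together with the mean and SD of
#' the counts over an ensemble of signed-degree-preserving randomizations,
#' and the resulting z-scores (number of SDs of the observed count from the
#' null mean). z is NA when the null SD is zero (rigid degree sequence).
#'
#' @slot table data.frame with columns \code{class}, \code{observed},
#'   \code{mean}, \code{sd}, \code{z}.
#' @slot nRandom integer, ensemble size.
#' @slot q integer, attempted edge switches per edge and sign class.
#' @slot seed integer seed the ensemble streams were derived from.
#'
#' @seealso [motifEnrichment()], [randomizeNetwork()]
#' @export
setClass("NullSummary",
  slots = c(table = "data.frame", nRandom = "integer", q = "integer",
            seed = "integer"))

setValidity("NullSummary", function(object) {
  if (object@nRandom < 1L) return("nRandom must be >= 1")
  need <- c("class", "observed", "mean", "sd", "z")
  if (!all(need %in% names(object@table)))
    return(sprintf("table must have columns %s", paste(need, collapse = ", ")))
  TRUE
})

#' AnnotationSet: functional annotation channels for pair-sharing tests
#'
#' Two kinds of channel. Term channels map each gene to a set of terms
#' (protein complex membership, pathway, knockout phenotype, GO function /
#' process / location); two genes "share" the feature when their term sets
#' intersect. Pair channels are explicit unordered gene-pair relations
#' (physical interaction, curated genetic interaction, sequence homology);
#' two genes share the feature when the pair is in the relation.
#'
#' @slot geneTerms named list; each element is a named list mapping gene id
#'   to a character vector of terms. Conventional channel names:
#'   \code{complex}, \code{pathway}, \code{phenotype}, \code{go_function},
#'   \code{go_process}, \code{go_location}.
#' @slot pairRelations named list; each element is a character vector of
#'   canonical pair keys (two gene ids joined by "|", smaller first).
#'   Conventional channel names: \code{physical_interaction},
#'   \code{genetic_interaction}, \code{homology}.
#'
#' @seealso [pairShares()], [goAncestorClosure()], [codeFeatures()]
#' @export
setClass("AnnotationSet",
  slots = c(geneTerms = "list", pairRelations = "list"))

setValidity("AnnotationSet", function(object) {
  for (ch in names(object@geneTerms)) {
    gt <- object@geneTerms[[ch]]
    if (length(gt) && is.null(names(gt)))
      return(sprintf("geneTerms channel '%s' must be a named list", ch))
    if (any(vapply(gt, function(v) any(!nzchar(v)), logical(1))))
      return(sprintf("empty term string in channel '%s'", ch))
  }
  for (ch in names(object@pairRelations)) {
    keys <- object@pairRelations[[ch]]
    gg <- strsplit(keys, "|", fixed = TRUE)
    if (any(vapply(gg, function(x) length(x) != 2L || x[1] == x[2],
                   logical(1))))
      return(sprintf("channel '%s' has a malformed or self pair", ch))
  }
  TRUE
})
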