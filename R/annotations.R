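#' Construct an AnnotationSet
#'
#' @param geneTerms named list of term channels; each element either a named
#'   list (gene -> character vector of terms) or a two-column data.frame
#'   \code{gene, term}.
#' @param pairRelations named list of pair channels; each element either a
#'   character vector of canonical pair keys or a two-column data.frame
#'   \code{gene_a, gene_b}. Self-pairs are dropped; pairs are deduplicated
#'   as unordered.
#' @return An [AnnotationSet-class].
#' @export
AnnotationSet <- function(geneTerms = list(), pairRelations = list()) {
  geneTerms <- lapply(geneTerms, function(ch) {
    if (is.data.frame(ch)) {
      ch <- ch[nzchar(ch[[2]]), , drop = FALSE]
      split(as.character(ch[[2]]), as.character(ch[[1]]))
    } else {
      lapply(ch, function(v) unique(as.character(v)))
    }
  })
  geneTerms <- lapply(geneTerms, function(ch) lapply(ch, unique))
  pairRelations <- lapply(pairRelations, function(ch) {
    if (is.data.frame(ch)) {
      keep <- ch[[1]] != ch[[2]]
      ch <- unique(pairKey(as.character(ch[[1]][keep]),
                           as.character(ch[[2]][keep])))
    }
    sort(unique(as.character(ch)))
  })
  new("AnnotationSet", geneTerms = geneTerms, pairRelations = pairRelations)
}

#' Extract one channel of an AnnotationSet
#'
#' @param annotation an [AnnotationSet-class].
#' @param channel channel name.
#' @return For a term channel, the named list gene -> terms; for a pair
#'   channel, the character vector of pair keys.
#' @export
annotationChannel <- function(annotation, channel) {
  stopifnot(is(annotation, "AnnotationSet"))
  if (channel %in% names(annotation@geneTerms))
    return(annotation@geneTerms[[channel]])
  if (channel %in% names(annotation@pairRelations))
    return(annotation@pairRelations[[channel]])
  stop(sprintf("unknown annotation channel '%s'", channel))
}

#' Read a complex catalogue (gene to complex membership TSV)
#'
#' Expects the complexcat-style two-column layout \code{gene<TAB>complex_id}
#' (header optional, detected by the literal column names).
#'
#' @param path input TSV.
#' @return named list gene -> character vector of complex ids, suitable as a
#'   \code{geneTerms} channel.
#' @export
readComplexCatalogue <- function(path) {
  readGeneTerms(path)
}

#' Read a generic gene-to-term TSV
#'
#' Two columns, gene then term; used for pathway, phenotype and GO channels.
#' A header row is skipped when the first field is literally \code{gene}.
#'
#' @param path input TSV.
#' @return named list gene -> character vector of terms.
#' @export
readGeneTerms <- function(path) {
  d <- utils::read.delim(path, header = FALSE, colClasses = "character",
                         quote = "", stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("expected two tab-separated columns: gene, term")
  if (nrow(d) && d[1, 1] == "gene") d <- d[-1, , drop = FALSE]
  d <- d[nzchar(d[[1]]) & nzchar(d[[2]]), , drop = FALSE]
  lapply(split(d[[2]], d[[1]]), unique)
}

#' Read a two-column gene-pair list (physical interactions, homologs)
#'
#' @param path input TSV with columns gene_a, gene_b (header optional).
#' @return character vector of canonical unordered pair keys; self-pairs
#'   dropped, duplicates (either orientation) collapsed.
#' @export
readPairList <- function(path) {
  d <- utils::read.delim(path, header = FALSE, colClasses = "character",
                         quote = "", stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("expected two tab-separated columns: gene_a, gene_b")
  if (nrow(d) && d[1, 1] %in% c("gene_a", "gene1")) d <- d[-1, , drop = FALSE]
  keep <- d[[1]] != d[[2]] & nzchar(d[[1]]) & nzchar(d[[2]])
  sort(unique(pairKey(d[[1]][keep], d[[2]][keep])))
}

#' Read and filter a curated genetic-interaction list
#'
#' Reads a four-column TSV with header \code{gene_a, gene_b, curation,
#' interaction_type} and keeps only rows whose curation and interaction type
#' match the filters. The defaults retain manually curated synthetic
#' lethality / synthetic growth defect pairs, the conventional
#' high-confidence subset of genetic-interaction databases.
#'
#' @param path input TSV; the four required columns must be present.
#' @param curationFilter curation values to keep.
#' @param typeFilter interaction types to keep.
#' @return character vector of canonical unordered pair keys.
#' @export
readGeneticInteractions <- function(
    path,
    curationFilter = "Manual curation",
    typeFilter = c("Synthetic Lethality", "Synthetic growth defect")) {
  d <- utils::read.delim(path, header = TRUE, colClasses = "character",
                         quote = "", check.names = FALSE,
                         stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "curation", "interaction_type")
  if (!all(need %in% names(d)))
    stop("genetic-interaction file must have columns: ",
         paste(need, collapse = ", "))
  keep <- d$curation %in% curationFilter &
    d$interaction_type %in% typeFilter &
    d$gene_a != d$gene_b
  sort(unique(pairKey(d$gene_a[keep], d$gene_b[keep])))
}

#' Read a child-parent term edge list for an ontology DAG
#'
#' @param path TSV with columns child, parent (header optional).
#' @return data.frame with columns \code{child}, \code{parent}.
#' @export
readTermParents <- function(path) {
  d <- utils::read.delim(path, header = FALSE, colClasses = "character",
                         quote = "", stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("expected two tab-separated columns: child, parent")
  if (nrow(d) && d[1, 1] == "child") d <- d[-1, , drop = FALSE]
  data.frame(child = d[[1]], parent = d[[2]], stringsAsFactors = FALSE)
}

#' Propagate GO terms to ancestors and apply the term-frequency window
#'
#' Each gene's term set is first closed under the parent relation (a gene
#' annotated to a term is implicitly annotated to all its ancestors). Then
#' terms annotating fewer than \code{minFreq} or more than \code{maxFreq}
#' genes of the analysis universe are dropped from every gene: very rare
#' terms carry no statistical power and very common ones no specificity.
#' The 2-40 window is inclusive on both ends.
#'
#' @param geneTerms named list gene -> character vector of directly
#'   annotated terms.
#' @param parentMap data.frame with columns \code{child}, \code{parent};
#'   must be acyclic.
#' @param universe character vector of analysis genes over which term
#'   frequencies are counted (genes outside the universe keep their closed,
#'   filtered term sets but do not contribute to frequencies).
#' @param minFreq,maxFreq inclusive term-frequency window (defaults 2, 40).
#' @return named list gene -> filtered ancestor-closed term set; genes with
#'   all terms filtered away keep an empty set.
#' @details Closure and filtering interact: removing an over-frequent term
#'   can strand genes, lowering the frequencies recomputed after the next
#'   closure. The pass is therefore repeated until the annotation is a
#'   fixpoint of close-then-filter, which makes the operation idempotent.
#' @export
goAncestorClosure <- function(geneTerms, parentMap, universe,
                              minFreq = 2L, maxFreq = 40L) {
  stopifnot(is.data.frame(parentMap),
            all(c("child", "parent") %in% names(parentMap)))
  parents <- split(parentMap$parent, parentMap$child)
  closureCache <- new.env(parent = emptyenv())
  closure <- function(term, path = character()) {
    hit <- closureCache[[term]]
    if (!is.null(hit)) return(hit)
    if (term %in% path)
      stop(sprintf("cycle in term parent map involving '%s'", term))
    ps <- parents[[term]]
    out <- term
    for (p in ps) out <- c(out, closure(p, c(path, term)))
    out <- unique(out)
    closureCache[[term]] <- out
    out
  }
  canon <- function(x) lapply(x, function(v) as.character(sort(unique(v))))
  current <- canon(geneTerms)
  for (iter in seq_len(100L)) {
    closed <- lapply(current, function(terms) {
      unique(unlist(lapply(unique(terms), closure), use.names = FALSE))
    })
    uniGenes <- intersect(names(closed), universe)
    freq <- table(unlist(closed[uniGenes], use.names = FALSE))
    keepTerms <- names(freq)[freq >= minFreq & freq <= maxFreq]
    nxt <- canon(lapply(closed, function(terms)
      terms[terms %in% keepTerms]))
    if (identical(nxt, current)) return(nxt)
    current <- nxt
  }
  stop("term filtering did not converge")
}

#' Remove the uninformative 'viable' phenotype term
#'
#' The blanket knockout phenotype \code{viable} annotates most non-essential
#' genes and carries no pair-sharing information; it is removed from every
#' gene's phenotype set (genes may be left with empty sets).
#'
#' @param geneTerms named list gene -> character vector of phenotype terms.
#' @param drop term(s) to remove (default \code{"viable"}).
#' @return the cleaned named list.
#' @export
cleanPhenotypes <- function(geneTerms, drop = "viable") {
  lapply(geneTerms, function(terms) terms[!terms %in% drop])
}

#' Do two genes share a feature on a channel?
#'
#' For term channels the genes share the feature when their term sets
#' intersect; for pair channels when the unordered pair is in the relation.
#' Symmetric in the two genes.
#'
#' @param annotation an [AnnotationSet-class].
#' @param channel channel name.
#' @param geneA,geneB gene identifiers (vectorized, recycled).
#' @return logical vector.
#' @export
pairShares <- function(annotation, channel, geneA, geneB) {
  stopifnot(is(annotation, "AnnotationSet"))
  if (channel %in% names(annotation@geneTerms)) {
    gt <- annotation@geneTerms[[channel]]
    n <- max(length(geneA), length(geneB))
    geneA <- rep_len(geneA, n); geneB <- rep_len(geneB, n)
    vapply(seq_len(n), function(i) {
      ta <- gt[[geneA[i]]]
      if (is.null(ta) || !length(ta)) return(FALSE)
      tb <- gt[[geneB[i]]]
      if (is.null(tb) || !length(tb)) return(FALSE)
      any(ta %in% tb)
    }, logical(1))
  } else if (channel %in% names(annotation@pairRelations)) {
    pairKey(geneA, geneB) %in% annotation@pairRelations[[channel]]
  } else {
    stop(sprintf("unknown annotation channel '%s'", channel))
  }
}
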