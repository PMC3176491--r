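#' Position codes: which triplet edges share a feature
#'
#' For every triplet and annotation channel, builds a 3-character code over
#' \{0,1\}: position k is 1 when the gene pair of the edge at position k
#' (edges ordered from most negative to most positive S-score) shares the
#' channel's feature. For example "001" means only the most positive edge's
#' pair shares the feature. For transitive channels (shared term sets built
#' from a single term per gene) any two 1s force the third, so codes 110,
#' 101 and 011 indicate either multi-term annotation or pair relations; their
#' frequency is attached as the \code{"mixed_codes"} attribute as a
#' diagnostic.
#'
#' @param census a [TripletCensus-class].
#' @param annotation an [AnnotationSet-class].
#' @param channels channels to code (default: all channels of
#'   \code{annotation}).
#' @return data.frame with columns \code{triplet}, \code{class},
#'   \code{channel}, \code{code}. Genes absent from a term channel simply
#'   share nothing (bits 0).
#' @export
codeFeatures <- function(census, annotation,
                         channels = annotationChannels(annotation)) {
  stopifnot(is(census, "TripletCensus"), is(annotation, "AnnotationSet"))
  tr <- census@triplets
  if (!nrow(tr)) {
    out <- data.frame(triplet = integer(), class = character(),
                      channel = character(), code = character(),
                      stringsAsFactors = FALSE)
    attr(out, "mixed_codes") <- integer()
    return(out)
  }
  # evaluate pair sharing once per unique pair key per channel
  keys <- unique(c(tr$pair_i, tr$pair_ii, tr$pair_iii))
  kg <- splitPairKey(keys)
  out <- do.call(rbind, lapply(channels, function(ch) {
    sh <- pairShares(annotation, ch, kg$gene_a, kg$gene_b)
    names(sh) <- keys
    bits <- cbind(sh[tr$pair_i], sh[tr$pair_ii], sh[tr$pair_iii])
    data.frame(triplet = seq_len(nrow(tr)), class = tr$class, channel = ch,
               code = paste0(bits[, 1] + 0L, bits[, 2] + 0L, bits[, 3] + 0L),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  mixed <- table(out$code[out$code %in% c("110", "101", "011")])
  attr(out, "mixed_codes") <- mixed
  out
}

# two-sided Fisher exact p for a 2x2 table via the hypergeometric
# distribution: sum of point probabilities not exceeding the observed
# table's (with the usual relative tolerance guarding FP ties)
fisherTwoSided <- function(a, b, c, d) {
  m <- a + b          # row 1 margin
  n <- c + d          # row 2 margin
  k <- a + c          # column 1 margin
  if (m + n == 0 || k == 0 || k == m + n) return(1)
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  pObs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Fisher exact cross-tabulation of a position code against a motif class
#'
#' Tests whether triplets of one motif class carry a given feature code more
#' (or less) often than the remaining triplets: the 2x2 table has rows
#' \{in class, not in class\} and columns \{code matches pattern, not\}.
#' The odds ratio is the sample odds ratio (a d)/(b c) with the Haldane 0.5
#' continuity correction applied to all cells when any cell is zero; the
#' p-value is the two-sided Fisher exact probability.
#'
#' @param codes code table from [codeFeatures()].
#' @param census the [TripletCensus-class] the codes were computed on.
#' @param channel annotation channel to test.
#' @param pattern either a 3-character code such as \code{"001"}, or a
#'   position aggregate \code{"any-bit-at-i"} / \code{"any-bit-at-ii"} /
#'   \code{"any-bit-at-iii"} matching any code with a 1 at that position.
#' @param motifClass one of NNN, NNP, NPP, PPP.
#' @param nTests Bonferroni family size (default 1; [enrichmentTable()]
#'   fills in the number of tests emitted in a run).
#' @return one-row data.frame: \code{channel, pattern, class, a, b, c, d,
#'   odds_ratio, p_value, p_bonferroni, testable}. A class with zero
#'   triplets is flagged untestable (p NA).
#' @export
fisherCrossTab <- function(codes, census, channel, pattern, motifClass,
                           nTests = 1L) {
  stopifnot(is(census, "TripletCensus"))
  cc <- codes[codes$channel == channel, , drop = FALSE]
  total <- nrow(census@triplets)
  match3 <- function(code) {
    switch(pattern,
      "any-bit-at-i" = substr(code, 1, 1) == "1",
      "any-bit-at-ii" = substr(code, 2, 2) == "1",
      "any-bit-at-iii" = substr(code, 3, 3) == "1",
      code == pattern)
  }
  inClass <- cc$class == motifClass
  hits <- match3(cc$code)
  a <- sum(inClass & hits)
  b <- sum(inClass & !hits)
  c <- sum(!inClass & hits)
  d <- sum(!inClass & !hits)
  testable <- (a + b) > 0L
  if (!testable) {
    return(data.frame(channel = channel, pattern = pattern,
                      class = motifClass, a = a, b = b, c = c, d = d,
                      odds_ratio = NA_real_, p_value = NA_real_,
                      p_bonferroni = NA_real_, testable = FALSE,
                      stringsAsFactors = FALSE))
  }
  if (any(c(a, b, c, d) == 0L)) {
    orr <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    orr <- (a * d) / (b * c)
  }
  p <- fisherTwoSided(a, b, c, d)
  data.frame(channel = channel, pattern = pattern, class = motifClass,
             a = a, b = b, c = c, d = d, odds_ratio = orr, p_value = p,
             p_bonferroni = min(1, p * nTests), testable = TRUE,
             stringsAsFactors = FALSE)
}

#' All position-code Fisher tests for a run
#'
#' Runs [fisherCrossTab()] over every combination of channel, pattern and
#' motif class and Bonferroni-corrects over the whole family of tests
#' emitted (the family size is the number of testable combinations).
#'
#' @param codes code table from [codeFeatures()].
#' @param census the corresponding [TripletCensus-class].
#' @param channels channels to test (default: those present in
#'   \code{codes}).
#' @param patterns code patterns / aggregates to test. The default tests the
#'   single-position codes, full sharing, and the any-sharing position
#'   aggregates.
#' @return data.frame, one row per test.
#' @export
enrichmentTable <- function(codes, census,
                            channels = unique(codes$channel),
                            patterns = c("100", "010", "001", "111",
                                         "any-bit-at-i", "any-bit-at-ii",
                                         "any-bit-at-iii")) {
  grid <- expand.grid(channel = channels, pattern = patterns,
                      class = MOTIF_CLASSES, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    fisherCrossTab(codes, census, grid$channel[i], grid$pattern[i],
                   grid$class[i])
  })
  out <- do.call(rbind, rows)
  fam <- sum(out$testable)
  out$p_bonferroni <- pmin(1, out$p_value * fam)
  attr(out, "family_size") <- fam
  out
}

#' Edge-context fold changes of feature sharing
#'
#' For edges of one sign, compares the fraction of pairs sharing each
#' feature between edge categories defined by triplet context: edges in no
#' triplet (the baseline), edges in any triplet, and edges inside NPP, NNP
#' and NNN (or PPP, for positive edges) triplets. Fold change is the
#' category fraction over the baseline fraction; each category is tested
#' against the baseline with a two-sided Fisher exact test,
#' Bonferroni-corrected over all tests in the call, with significance
#' declared at corrected p < 0.01.
#'
#' @param network the [SignedNetwork-class] the census came from.
#' @param census a [TripletCensus-class] of that network.
#' @param annotation an [AnnotationSet-class].
#' @param sign "N" or "P".
#' @param channels channels to evaluate (default all).
#' @return data.frame with columns \code{channel, category, n_edges,
#'   n_sharing, fraction, fold_change, p_value, p_bonferroni, significant}.
#'   Fold changes are NA (flagged by \code{fold_defined = FALSE}) when the
#'   baseline fraction is zero or the baseline category is empty.
#' @export
edgeContextFoldChange <- function(network, census, annotation, sign,
                                  channels = annotationChannels(annotation)) {
  stopifnot(is(network, "SignedNetwork"), is(census, "TripletCensus"),
            sign %in% c("N", "P"))
  ep <- census@edgeParticipation
  ep <- ep[ep$sign == sign, , drop = FALSE]
  ownClass <- if (sign == "N") "NNN" else "PPP"
  cats <- list(
    not_in_triplet = ep$n_triplets == 0L,
    in_any_triplet = ep$n_triplets > 0L,
    in_NPP = ep$n_NPP > 0L,
    in_NNP = ep$n_NNP > 0L)
  cats[[paste0("in_", ownClass)]] <- ep[[paste0("n_", ownClass)]] > 0L
  share <- lapply(channels, function(ch)
    pairShares(annotation, ch, ep$gene_a, ep$gene_b))
  names(share) <- channels
  rows <- list()
  for (ch in channels) {
    s <- share[[ch]]
    base <- cats$not_in_triplet
    baseFrac <- if (any(base)) mean(s[base]) else NA_real_
    for (cat in names(cats)) {
      sel <- cats[[cat]]
      frac <- if (any(sel)) mean(s[sel]) else NA_real_
      fold <- if (!is.na(frac) && !is.na(baseFrac) && baseFrac > 0)
        frac / baseFrac else NA_real_
      p <- if (cat == "not_in_triplet") 1 else if (any(sel) && any(base))
        fisherTwoSided(sum(s[sel]), sum(!s[sel]),
                       sum(s[base]), sum(!s[base])) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ch, category = cat, n_edges = sum(sel),
        n_sharing = sum(s[sel]), fraction = frac, fold_change = fold,
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  tested <- out$category != "not_in_triplet" & !is.na(out$p_value)
  out$p_bonferroni <- pmin(1, out$p_value * sum(tested))
  out$p_bonferroni[!tested] <- NA_real_
  out$fold_defined <- !is.na(out$fold_change)
  out$significant <- tested & !is.na(out$p_bonferroni) &
    out$p_bonferroni < 0.01
  rownames(out) <- NULL
  out
}

#' Within-triplet epistatic profile correlations
#'
#' For each triplet of a motif class and each of its edges, computes the
#' Spearman rank correlation between the two genes' S-score profiles over
#' the partners measured for both in the pre-threshold score matrix
#' (requiring at least \code{minCommon} common partners; the two triplet
#' genes themselves are excluded from the profiles). Correlations are
#' summarized per edge sign within the class as mean, SD and SE. Highly
#' correlated profiles indicate aligned function of the pair.
#'
#' @param x the pre-threshold [ScoreMatrix-class].
#' @param census a [TripletCensus-class].
#' @param motifClass class to analyse (e.g. "NNP").
#' @param minCommon minimum common measured partners (default 10; below
#'   this, rank correlations at E-MAP sparsity are too unstable).
#' @return list with \code{correlations} (data.frame \code{triplet,
#'   position, sign, rho, n_common}) and \code{summary} (data.frame
#'   \code{sign, n, mean_rho, sd_rho, se_rho}).
#' @export
profileCorrelation <- function(x, census, motifClass, minCommon = 10L) {
  stopifnot(is(x, "ScoreMatrix"), is(census, "TripletCensus"))
  tr <- census@triplets[census@triplets$class == motifClass, , drop = FALSE]
  p <- x@pairs
  profiles <- new.env(parent = emptyenv())
  getProfile <- function(g) {
    hit <- profiles[[g]]
    if (!is.null(hit)) return(hit)
    ia <- p$gene_a == g
    ib <- p$gene_b == g
    v <- c(stats::setNames(p$score[ia], p$gene_b[ia]),
           stats::setNames(p$score[ib], p$gene_a[ib]))
    profiles[[g]] <- v
    v
  }
  rows <- list()
  if (nrow(tr)) {
    for (i in seq_len(nrow(tr))) {
      keys <- c(tr$pair_i[i], tr$pair_ii[i], tr$pair_iii[i])
      sgns <- edgeSignsOfTriplet(tr$class[i])
      for (k in 1:3) {
        gg <- strsplit(keys[k], "|", fixed = TRUE)[[1]]
        va <- getProfile(gg[1])
        vb <- getProfile(gg[2])
        common <- setdiff(intersect(names(va), names(vb)), gg)
        if (length(common) < minCommon) next
        rho <- stats::cor(va[common], vb[common], method = "spearman")
        rows[[length(rows) + 1L]] <- data.frame(
          triplet = i, position = c("i", "ii", "iii")[k], sign = sgns[k],
          rho = rho, n_common = length(common), stringsAsFactors = FALSE)
      }
    }
  }
  cors <- if (length(rows)) do.call(rbind, rows) else
    data.frame(triplet = integer(), position = character(),
               sign = character(), rho = numeric(), n_common = integer(),
               stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(c("N", "P"), function(s) {
    r <- cors$rho[cors$sign == s]
    data.frame(sign = s, n = length(r),
               mean_rho = if (length(r)) mean(r) else NA_real_,
               sd_rho = if (length(r) > 1) stats::sd(r) else NA_real_,
               se_rho = if (length(r) > 1) stats::sd(r) / sqrt(length(r))
                        else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(correlations = cors, summary = summ)
}

# edge signs at positions i, ii, iii for a class (ascending score order)
edgeSignsOfTriplet <- function(class) {
  switch(class,
    NNN = c("N", "N", "N"),
    NNP = c("N", "N", "P"),
    NPP = c("N", "P", "P"),
    PPP = c("P", "P", "P"),
    stop("unknown motif class ", class))
}

#' Genes occupying a structural role in a motif class
#'
#' In mixed triplets one gene is structurally distinguished: in an NPP
#' triplet the \code{positive_node} is the gene incident to both positive
#' edges (the putative regulator acting on the negatively interacting
#' pathway pair); in an NNP triplet the \code{spanned_node} is the gene
#' incident to both negative edges (typically a member of a second complex
#' bridged to the positive pair's complex).
#'
#' @param census a [TripletCensus-class].
#' @param motifClass "NPP" or "NNP".
#' @param role \code{"positive_node"} (NPP) or \code{"spanned_node"} (NNP).
#' @return character vector: the role gene of each triplet of the class (in
#'   triplet order, possibly with repeats).
#' @export
roleGenes <- function(census, motifClass, role) {
  stopifnot(is(census, "TripletCensus"))
  valid <- (motifClass == "NPP" && role == "positive_node") ||
    (motifClass == "NNP" && role == "spanned_node")
  if (!valid)
    stop(sprintf("role '%s' is not defined for class %s", role, motifClass))
  tr <- census@triplets[census@triplets$class == motifClass, , drop = FALSE]
  if (!nrow(tr)) return(character())
  # NPP: common gene of the two P edges (positions ii and iii);
  # NNP: common gene of the two N edges (positions i and ii)
  k1 <- if (motifClass == "NPP") tr$pair_ii else tr$pair_i
  k2 <- if (motifClass == "NPP") tr$pair_iii else tr$pair_ii
  g1 <- splitPairKey(k1)
  g2 <- splitPairKey(k2)
  vapply(seq_len(nrow(tr)), function(i) {
    common <- intersect(c(g1$gene_a[i], g1$gene_b[i]),
                        c(g2$gene_a[i], g2$gene_b[i]))
    common[1]
  }, character(1))
}

#' Term enrichment among genes at a motif position
#'
#' Takes the distinct genes occupying a structural role across all triplets
#' of a class (see [roleGenes()]) and tests each term of an annotation
#' channel for over-representation in that gene set against the analysis
#' universe with a one-sided hypergeometric test, Bonferroni-corrected
#' across terms. Reports the percentage of the role set annotated and the
#' fold enrichment over the universe fraction.
#'
#' @param census a [TripletCensus-class].
#' @param annotation an [AnnotationSet-class].
#' @param motifClass,role as in [roleGenes()].
#' @param channel a term channel of \code{annotation}.
#' @param universe character vector of analysis genes (e.g. the network's
#'   genes); the role set is intersected with it.
#' @return data.frame sorted by p-value: \code{term, n_set, n_universe,
#'   percent, p_value, p_bonferroni, fold_enrichment}.
#' @export
positionGeneEnrichment <- function(census, annotation, motifClass, role,
                                   channel, universe) {
  stopifnot(is(census, "TripletCensus"), is(annotation, "AnnotationSet"))
  if (!channel %in% names(annotation@geneTerms))
    stop(sprintf("'%s' is not a term channel", channel))
  gt <- annotation@geneTerms[[channel]]
  set <- intersect(unique(roleGenes(census, motifClass, role)), universe)
  nSet <- length(set)
  nUni <- length(universe)
  termsByGene <- gt[intersect(names(gt), universe)]
  uniFreq <- table(unlist(termsByGene, use.names = FALSE))
  setFreq <- table(unlist(gt[intersect(names(gt), set)], use.names = FALSE))
  terms <- names(uniFreq)
  k <- as.integer(setFreq[terms])
  k[is.na(k)] <- 0L
  K <- as.integer(uniFreq)
  p <- vapply(seq_along(terms), function(i) {
    if (nSet == 0L) return(1)
    stats::phyper(k[i] - 1L, K[i], nUni - K[i], nSet, lower.tail = FALSE)
  }, numeric(1))
  out <- data.frame(term = terms, n_set = k, n_universe = K,
                    percent = if (nSet) 100 * k / nSet else NA_real_,
                    p_value = p,
                    p_bonferroni = pmin(1, p * length(terms)),
                    fold_enrichment = if (nSet)
                      (k / nSet) / (K / nUni) else NA_real_,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, -out$fold_enrichment), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of triplets containing physically interacting pairs
#'
#' Per motif class, the fraction of triplets with at least one edge whose
#' gene pair is in the physical-interaction relation (and the full
#' distribution over 0-3 physically interacting edges). NNP triplets are
#' typically the most likely to contain a physical interaction while NPP
#' triplets, despite two positive edges, are the least.
#'
#' @param census a [TripletCensus-class].
#' @param annotation an [AnnotationSet-class] with a
#'   \code{physical_interaction} pair channel (override with
#'   \code{channel}).
#' @param channel pair channel name.
#' @return data.frame: \code{class, n_triplets, frac_ge1, frac_0, frac_1,
#'   frac_2, frac_3}.
#' @export
physicalEdgeFractions <- function(census, annotation,
                                  channel = "physical_interaction") {
  codes <- codeFeatures(census, annotation, channels = channel)
  nbits <- nchar(gsub("0", "", codes$code))
  do.call(rbind, lapply(MOTIF_CLASSES, function(cl) {
    nb <- nbits[codes$class == cl]
    n <- length(nb)
    data.frame(class = cl, n_triplets = n,
               frac_ge1 = if (n) mean(nb >= 1) else NA_real_,
               frac_0 = if (n) mean(nb == 0) else NA_real_,
               frac_1 = if (n) mean(nb == 1) else NA_real_,
               frac_2 = if (n) mean(nb == 2) else NA_real_,
               frac_3 = if (n) mean(nb == 3) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
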