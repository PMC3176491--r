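#' Run the full motif analysis pipeline from a configuration
#'
#' Orchestrates merge, threshold, degree filter, triplet census, null-model
#' comparison, feature coding and the enrichment analyses, writing every
#' intermediate table to the output directory together with a manifest
#' recording parameters, input checksums and output row counts. Any stage
#' error aborts with the stage name; tables written before the failure are
#' preserved.
#'
#' @param config either a list or the path to a YAML file with (all
#'   optional unless noted) fields:
#'   \describe{
#'     \item{matrices}{character vector of score-matrix TSV paths, or}
#'     \item{synthetic}{list of [syntheticConfig()] arguments used when no
#'       matrices are given,}
#'     \item{annotations}{list with optional \code{gene_terms} (named list
#'       channel -> gene-term TSV path), \code{pairs} (named list channel ->
#'       pair TSV path), \code{genetic_interactions} (4-column TSV path),}
#'     \item{percentile}{tail mass per side (default 1),}
#'     \item{min_degree}{gene filter (default 2),}
#'     \item{n_random, q}{null-model parameters (defaults 1000, 100),}
#'     \item{out_dir}{output directory (required),}
#'     \item{seed}{integer seed (default 1).}
#'   }
#' @return the manifest, invisibly (also written as
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config must set out_dir")
  outDir <- config$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  percentile <- config$percentile %||% 1
  minDegree <- config$min_degree %||% 2
  nRandom <- config$n_random %||% 1000
  q <- config$q %||% 100
  seed <- as.integer(config$seed %||% 1L)
  manifest <- list(package_version = as.character(
                     utils::packageVersion("emapMotifs")),
                   parameters = list(percentile = percentile,
                                     min_degree = minDegree,
                                     n_random = nRandom, q = q, seed = seed),
                   inputs = list(), outputs = list())
  outputs <- character()
  emit <- function(name, writer) {
    path <- file.path(outDir, name)
    writer(path)
    outputs[[length(outputs) + 1L]] <<- path
    path
  }
  countRows <- function(path) {
    max(0L, length(readLines(path, warn = FALSE)) - 1L)
  }
  stage <- "input"
  tryCatch({
    annotation <- NULL
    if (!is.null(config$matrices)) {
      manifest$inputs$matrices <- lapply(config$matrices, function(p)
        list(path = p, md5 = unname(tools::md5sum(p))))
      mats <- lapply(config$matrices, readScoreMatrix)
      scores <- if (length(mats) > 1L) mergeScoreMatrices(mats) else mats[[1]]
    } else {
      synArgs <- config$synthetic %||% list()
      if (is.null(synArgs$seed)) synArgs$seed <- seed
      gen <- generateEmap(do.call(syntheticConfig, synArgs))
      scores <- gen$scores
      annotation <- gen$annotation
      manifest$inputs$synthetic <- synArgs
    }
    if (!is.null(config$annotations)) {
      stage <- "annotations"
      an <- config$annotations
      gtChannels <- lapply(an$gene_terms, readGeneTerms)
      prChannels <- lapply(an$pairs, readPairList)
      if (!is.null(an$genetic_interactions))
        prChannels$genetic_interaction <-
          readGeneticInteractions(an$genetic_interactions)
      annotation <- AnnotationSet(geneTerms = gtChannels,
                                  pairRelations = prChannels)
    }
    message(sprintf("[input] %d genes, %d scored pairs",
                    length(scoreGenes(scores)), nrow(scorePairs(scores))))
    emit("merged_scores.tsv", function(p) writeScorePairs(scores, p))

    stage <- "threshold"
    net <- thresholdScores(scores, percentile = percentile)
    stage <- "filter"
    net <- filterLowDegree(net, minDegree = minDegree)
    sgn <- table(factor(networkEdges(net)$sign, levels = c("N", "P")))
    message(sprintf("[network] %d genes, %d N + %d P edges",
                    length(networkGenes(net)), sgn["N"], sgn["P"]))
    emit("signed_edges.tsv", function(p) writeSignedEdges(net, p))

    stage <- "census"
    census <- enumerateTriplets(net)
    message(sprintf("[census] %s",
                    paste(names(motifCounts(census)), motifCounts(census),
                          sep = "=", collapse = " ")))
    emit("triplets.tsv", function(p) writeTripletTable(census, p))
    emit("census.json", function(p) jsonlite::write_json(
      list(counts = as.list(motifCounts(census)),
           participation = participationSummary(census)),
      p, auto_unbox = TRUE, digits = NA))
    emit("gene_polarity.tsv", function(p) utils::write.table(
      geneSignPolarity(net), p, sep = "\t", quote = FALSE,
      row.names = FALSE))

    stage <- "null"
    ns <- motifEnrichment(net, nRandom = nRandom, q = q, seed = seed)
    emit("null_summary.tsv", function(p)
      writeNullSummary(ns, p, jsonPath = file.path(outDir,
                                                   "null_summary.json")))
    outputs[[length(outputs) + 1L]] <- file.path(outDir,
                                                 "null_summary.json")

    if (!is.null(annotation)) {
      stage <- "codes"
      codes <- codeFeatures(census, annotation)
      emit("feature_codes.tsv", function(p) utils::write.table(
        codes, p, sep = "\t", quote = FALSE, row.names = FALSE))
      stage <- "enrichment"
      emit("fisher_enrichment.tsv", function(p) utils::write.table(
        enrichmentTable(codes, census), p, sep = "\t", quote = FALSE,
        row.names = FALSE))
      for (s in c("N", "P")) {
        emit(sprintf("foldchange_%s.tsv", s), function(p)
          utils::write.table(
            edgeContextFoldChange(net, census, annotation, s), p,
            sep = "\t", quote = FALSE, row.names = FALSE))
      }
    }
    stage <- "export"
    emit("network.sif", function(p) exportNetwork(net, census, p,
                                                  format = "sif"))
    emit("network.graphml", function(p) exportNetwork(net, census, p,
                                                      format = "graphml"))
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  manifest$outputs <- lapply(stats::setNames(outputs, basename(unlist(outputs))),
                             function(p) list(rows = countRows(p),
                                              md5 = unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a signed network (with triplet context) to SIF or GraphML
#'
#' Nodes carry gene ids; edges carry the sign, the S-score and the number of
#' triplets the edge participates in. A class filter restricts the export to
#' edges inside triplets of one motif class (e.g. the NNP subnetwork).
#'
#' @param network a [SignedNetwork-class].
#' @param census a [TripletCensus-class] of the network (participation
#'   attributes; may be NULL, in which case participation is omitted).
#' @param path output file path.
#' @param format \code{"sif"} or \code{"graphml"}.
#' @param motifClass optional class (NNN/NNP/NPP/PPP): keep only edges in at
#'   least one triplet of that class.
#' @return \code{path}, invisibly.
#' @export
exportNetwork <- function(network, census = NULL, path,
                          format = c("sif", "graphml"), motifClass = NULL) {
  stopifnot(is(network, "SignedNetwork"))
  format <- match.arg(format)
  e <- networkEdges(network)
  e$n_triplets <- 0L
  if (!is.null(census)) {
    ep <- edgeParticipation(census)
    idx <- match(pairKey(e$gene_a, e$gene_b), pairKey(ep$gene_a, ep$gene_b))
    e$n_triplets <- ifelse(is.na(idx), 0L, ep$n_triplets[idx])
    if (!is.null(motifClass)) {
      stopifnot(motifClass %in% MOTIF_CLASSES)
      cls <- ep[[paste0("n_", motifClass)]][idx]
      e <- e[!is.na(cls) & cls > 0L, , drop = FALSE]
    }
  } else if (!is.null(motifClass)) {
    stop("a census is required to filter by motif class")
  }
  if (format == "sif") {
    lines <- if (nrow(e))
      sprintf("%s\t%s\t%s", e$gene_a, tolower(e$sign), e$gene_b)
    else character()
    writeLines(lines, path)
  } else {
    g <- igraph::graph_from_data_frame(
      e[, c("gene_a", "gene_b")], directed = FALSE,
      vertices = data.frame(name = networkGenes(network)))
    igraph::E(g)$sign <- e$sign
    igraph::E(g)$s_score <- e$score
    igraph::E(g)$n_triplets <- e$n_triplets
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
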