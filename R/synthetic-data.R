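# run expr with a fixed RNG state, restoring the caller's state afterwards
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Configuration for the synthetic E-MAP generator
#'
#' Defines an E-MAP-like study: a sparse symmetric S-score matrix with
#' planted biological structure. Planted units mirror the two interpretive
#' models for mixed motifs: protein complexes as positive cliques, bridged
#' to a neighbouring complex by negative edges (the complex-coordination
#' arrangement that yields NNP triplets); redundant pathway pairs as
#' negative edges whose members a regulator gene suppresses via positive
#' edges (the pathway-regulator arrangement that yields NPP triplets).
#' Adjacent pathway units are additionally bridged by negative edges, giving
#' all-negative (NNN) triangles, and complexes alone give all-positive (PPP)
#' ones, so every motif class has planted instances.
#'
#' @param nGenes total genes (default 100).
#' @param nComplexes,complexSize number and size range (inclusive) of
#'   positive cliques (defaults 5 complexes of exactly 4).
#' @param nPathways,pathwaySize number and size range of redundant pathway
#'   units (defaults 5 pairs, size exactly 2).
#' @param nRegulators regulator genes, each positively linked to every
#'   member of a neighbourhood of two adjacent pathway units (one unit when
#'   only one pathway exists), cycling over pathways (default 5); since
#'   adjacent units are negatively bridged, each regulator seeds a block of
#'   NPP triplets with itself at the positive node.
#' @param intraComplexMean,pathwayPairMean,bridgeMean,regulatorMean means of
#'   the Gaussian structural score distributions (defaults +6, -6, -6, +6;
#'   chosen so extreme-percentile cutoffs cleanly separate planted edges
#'   from background).
#' @param noiseSD SD of the structural score draws (default 1).
#' @param backgroundSD SD of the mean-zero background scores (default 1).
#' @param missingFraction target fraction of unmeasured pairs (default
#'   0.78, the sparsity of published E-MAP compendia).
#' @param keepPlanted exempt planted pairs from the missing mask (default
#'   TRUE, guaranteeing testable structure at small n).
#' @param blockMissing emulate the fragmented block structure of real
#'   compendia (each study screens a gene subset): only within-block pairs
#'   are candidates for measurement (default FALSE = uniform missingness).
#' @param blockSize genes per block when \code{blockMissing} (default 40).
#' @param seed integer seed; fixing it fixes matrix, truth and annotations.
#' @return a \code{SyntheticConfig} list.
#' @export
syntheticConfig <- function(nGenes = 100, nComplexes = 5,
                            complexSize = c(4, 4), nPathways = 5,
                            pathwaySize = c(2, 2), nRegulators = 5,
                            intraComplexMean = 6, pathwayPairMean = -6,
                            bridgeMean = -6, regulatorMean = 6,
                            noiseSD = 1, backgroundSD = 1,
                            missingFraction = 0.78, keepPlanted = TRUE,
                            blockMissing = FALSE, blockSize = 40,
                            seed = 1L) {
  stopifnot(missingFraction >= 0, missingFraction < 1,
            all(complexSize >= 2), all(pathwaySize >= 2),
            length(complexSize) == 2, length(pathwaySize) == 2)
  structure(list(
    nGenes = nGenes, nComplexes = nComplexes, complexSize = complexSize,
    nPathways = nPathways, pathwaySize = pathwaySize,
    nRegulators = nRegulators, intraComplexMean = intraComplexMean,
    pathwayPairMean = pathwayPairMean, bridgeMean = bridgeMean,
    regulatorMean = regulatorMean, noiseSD = noiseSD,
    backgroundSD = backgroundSD, missingFraction = missingFraction,
    keepPlanted = keepPlanted, blockMissing = blockMissing,
    blockSize = blockSize, seed = as.integer(seed)),
    class = "SyntheticConfig")
}

#' Generate a synthetic E-MAP with planted structure and ground truth
#'
#' Produces a sparse symmetric [ScoreMatrix-class] in which planted pairs
#' draw from their structural Gaussian (see [syntheticConfig()]) and all
#' other measured pairs from the mean-zero background; a missing mask then
#' removes pairs uniformly at random down to the target missingness
#' (sparing planted pairs by default). Matching ground-truth annotations are
#' returned so every downstream stage can be validated: complex and pathway
#' membership as term channels, a \code{go_function}-like channel labelling
#' regulators, module-level phenotypes (every gene also carries the blanket
#' term \code{viable}), intra-complex pairs as the physical-interaction
#' relation and planted negative pairs as the genetic-interaction relation.
#'
#' @param config a [syntheticConfig()] list.
#' @return list with elements \code{scores} ([ScoreMatrix-class]),
#'   \code{truth} (gene role labels and planted pair/motif inventory) and
#'   \code{annotation} ([AnnotationSet-class]).
#' @export
generateEmap <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  withSeed(config$seed, generateEmapImpl(config))
}

generateEmapImpl <- function(cfg) {
  genes <- sprintf("g%04d", seq_len(cfg$nGenes))
  nextGene <- 1L
  take <- function(k) {
    if (nextGene + k - 1L > cfg$nGenes)
      stop("planted structure needs more genes than nGenes provides")
    out <- genes[nextGene:(nextGene + k - 1L)]
    nextGene <<- nextGene + k
    out
  }
  # guard against sample(n, 1) scalar expansion when the range is a point
  pickSize <- function(rng) {
    if (rng[1] >= rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
  }
  complexes <- lapply(seq_len(cfg$nComplexes), function(i)
    take(pickSize(cfg$complexSize)))
  pathways <- lapply(seq_len(cfg$nPathways), function(i)
    take(pickSize(cfg$pathwaySize)))
  regulators <- if (cfg$nRegulators > 0) take(cfg$nRegulators) else character()

  allPairs <- function(v) {
    if (length(v) < 2) return(NULL)
    cmb <- utils::combn(v, 2)
    data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
               stringsAsFactors = FALSE)
  }
  bipartite <- function(u, v) {
    g <- expand.grid(gene_a = u, gene_b = v, stringsAsFactors = FALSE)
    g[g$gene_a != g$gene_b, , drop = FALSE]
  }
  planted <- list()
  addPlanted <- function(df, kind, mean) {
    if (is.null(df) || !nrow(df)) return(invisible())
    df$kind <- kind
    df$mean <- mean
    planted[[length(planted) + 1L]] <<- df
  }
  for (cx in complexes)
    addPlanted(allPairs(cx), "intra_complex", cfg$intraComplexMean)
  for (pw in pathways)
    addPlanted(allPairs(pw), "pathway_pair", cfg$pathwayPairMean)
  # each regulator acts on a neighbourhood of adjacent pathway units (a
  # regulator typically governs several related pathways); with adjacent
  # units also bridged negatively below, every pair among the regulated
  # genes is negative, so each regulator seeds a block of NPP triplets
  regPathways <- function(i) {
    k1 <- ((i - 1L) %% cfg$nPathways) + 1L
    if (cfg$nPathways < 2) return(k1)
    unique(c(k1, (k1 %% cfg$nPathways) + 1L))
  }
  if (length(regulators)) {
    for (i in seq_along(regulators)) {
      pw <- unlist(pathways[regPathways(i)])
      addPlanted(bipartite(regulators[i], pw), "regulator_link",
                 cfg$regulatorMean)
    }
  }
  # bridges: one gene of the next complex negatively linked to every gene of
  # this complex (-> NNP); full bipartite negative links between adjacent
  # pathway units (-> NNN)
  if (cfg$nComplexes >= 2) {
    for (k in seq_len(cfg$nComplexes)) {
      nxt <- complexes[[(k %% cfg$nComplexes) + 1L]]
      addPlanted(bipartite(nxt[1], complexes[[k]]), "complex_bridge",
                 cfg$bridgeMean)
    }
  }
  if (cfg$nPathways >= 2) {
    for (k in seq_len(cfg$nPathways)) {
      nxt <- pathways[[(k %% cfg$nPathways) + 1L]]
      addPlanted(bipartite(pathways[[k]], nxt), "pathway_bridge",
                 cfg$bridgeMean)
    }
  }
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(gene_a = character(), gene_b = character(),
               kind = character(), mean = numeric(),
               stringsAsFactors = FALSE)
  if (nrow(planted)) {
    key <- pairKey(planted$gene_a, planted$gene_b)
    planted <- planted[!duplicated(key), , drop = FALSE]
  }
  totalPairs <- choose(cfg$nGenes, 2)
  if (nrow(planted) > totalPairs)
    stop("planted structure exceeds the number of available gene pairs")

  # all unordered pairs, planted flagged
  cmb <- utils::combn(genes, 2)
  pairDf <- data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
                       stringsAsFactors = FALSE)
  key <- pairKey(pairDf$gene_a, pairDf$gene_b)
  plantedKey <- if (nrow(planted)) pairKey(planted$gene_a, planted$gene_b)
                else character()
  isPlanted <- key %in% plantedKey

  nMissing <- round(cfg$missingFraction * totalPairs)
  candidates <- if (cfg$keepPlanted) which(!isPlanted) else
    seq_len(totalPairs)
  if (cfg$blockMissing) {
    block <- ((match(pairDf$gene_a, genes) - 1L) %/% cfg$blockSize)
    blockB <- ((match(pairDf$gene_b, genes) - 1L) %/% cfg$blockSize)
    crossBlock <- which(block != blockB)
    forced <- intersect(candidates, crossBlock)
    rest <- setdiff(candidates, forced)
    extra <- max(0L, nMissing - length(forced))
    missingIdx <- c(forced, rest[sample.int(length(rest),
                                            min(extra, length(rest)))])
  } else {
    missingIdx <- candidates[sample.int(length(candidates),
                                        min(nMissing, length(candidates)))]
  }
  measured <- setdiff(seq_len(totalPairs), missingIdx)
  md <- pairDf[measured, , drop = FALSE]
  mkey <- key[measured]
  score <- stats::rnorm(length(measured), 0, cfg$backgroundSD)
  hit <- match(mkey, plantedKey)
  pl <- which(!is.na(hit))
  if (length(pl))
    score[pl] <- stats::rnorm(length(pl), planted$mean[hit[pl]],
                              cfg$noiseSD)
  md$score <- score
  sm <- ScoreMatrix(genes = genes, pairs = md)

  roles <- rep("background", cfg$nGenes)
  names(roles) <- genes
  for (k in seq_along(complexes)) roles[complexes[[k]]] <- "complex"
  for (k in seq_along(pathways)) roles[pathways[[k]]] <- "pathway"
  roles[regulators] <- "regulator"
  truth <- list(
    roles = roles,
    complexes = complexes,
    pathways = pathways,
    regulators = regulators,
    planted_pairs = planted,
    expected_classes = c(
      PPP = if (cfg$nComplexes > 0)
        sum(vapply(complexes, function(v) choose(length(v), 3), numeric(1)))
        else 0,
      NPP = if (length(regulators) && cfg$nPathways > 0) {
        sum(vapply(seq_along(regulators), function(i) {
          ng <- length(unlist(pathways[regPathways(i)]))
          if (cfg$nPathways >= 2) choose(ng, 2) else
            choose(ng, 2) # single pathway: all pairs internal, still N
        }, numeric(1)))
      } else 0,
      NNP = if (cfg$nComplexes >= 2)
        sum(vapply(complexes, function(v) choose(length(v), 2), numeric(1)))
        else 0,
      NNN = NA))

  gt <- list(complex = list(), pathway = list(), go_function = list(),
             phenotype = list())
  addTerm <- function(channel, gs, term) {
    for (g in gs)
      gt[[channel]][[g]] <<- unique(c(gt[[channel]][[g]], term))
  }
  for (k in seq_along(complexes)) {
    addTerm("complex", complexes[[k]], sprintf("CPLX_%02d", k))
    addTerm("phenotype", complexes[[k]], sprintf("pheno_complex_%02d", k))
    addTerm("go_function", complexes[[k]], "complex_subunit")
  }
  for (k in seq_along(pathways)) {
    addTerm("pathway", pathways[[k]], sprintf("PWY_%02d", k))
    addTerm("phenotype", pathways[[k]], sprintf("pheno_pathway_%02d", k))
    addTerm("go_function", pathways[[k]], "pathway_component")
  }
  if (length(regulators)) {
    for (i in seq_along(regulators)) {
      for (k in regPathways(i))
        addTerm("phenotype", regulators[i],
                sprintf("pheno_pathway_%02d", k))
    }
    addTerm("go_function", regulators, "pathway_regulator")
  }
  addTerm("phenotype", genes, "viable")
  physical <- planted[planted$kind == "intra_complex", , drop = FALSE]
  genetic <- planted[planted$mean < 0, , drop = FALSE]
  annotation <- AnnotationSet(
    geneTerms = gt,
    pairRelations = list(
      physical_interaction = if (nrow(physical))
        pairKey(physical$gene_a, physical$gene_b) else character(),
      genetic_interaction = if (nrow(genetic))
        pairKey(genetic$gene_a, genetic$gene_b) else character()))
  list(scores = sm, truth = truth, annotation = annotation)
}

#' End-to-end recovery experiment on synthetic data
#'
#' Runs the full pipeline on one synthetic E-MAP: generate, threshold,
#' filter low-degree genes, enumerate triplets, compare against the
#' degree-preserving null, and check whether the planted structure is
#' recovered: motif z-scores per class, the fraction of planted regulators
#' found at the positive node of an NPP triplet, and the rank of the planted
#' regulator term in the NPP positive-node enrichment.
#'
#' @param config a [syntheticConfig()] list.
#' @param percentile tail mass per side for [thresholdScores()] (default 5;
#'   wide enough to admit every planted edge at the default structural
#'   means and sparsity).
#' @param minDegree gene filter threshold (default 2).
#' @param nRandom null ensemble size (default 500).
#' @param q switches per edge (default 100).
#' @param seed seed for the null ensemble.
#' @return list with \code{network}, \code{census}, \code{null}
#'   ([NullSummary-class]), \code{z} (named per class),
#'   \code{regulator_recovery} (fraction of planted regulators at the NPP
#'   positive node), \code{regulator_term_rank} (rank of the planted
#'   regulator label in the positional enrichment; NA if absent) and
#'   \code{enrichment} (the positional term-enrichment table).
#' @export
recoveryExperiment <- function(config = syntheticConfig(), percentile = 5,
                               minDegree = 2, nRandom = 500, q = 100,
                               seed = 1L) {
  gen <- generateEmap(config)
  net <- filterLowDegree(thresholdScores(gen$scores, percentile),
                         minDegree = minDegree)
  census <- enumerateTriplets(net)
  ns <- motifEnrichment(net, nRandom = nRandom, q = q, seed = seed)
  z <- stats::setNames(ns@table$z, ns@table$class)
  posNodes <- unique(roleGenes(census, "NPP", "positive_node"))
  regs <- gen$truth$regulators
  recovery <- if (length(regs)) mean(regs %in% posNodes) else NA_real_
  enr <- positionGeneEnrichment(census, gen$annotation, "NPP",
                                "positive_node", channel = "go_function",
                                universe = networkGenes(net))
  rank <- match("pathway_regulator", enr$term)
  list(network = net, census = census, null = ns, z = z,
       regulator_recovery = recovery, regulator_term_rank = rank,
       enrichment = enr)
}

#' Write synthetic data in the formats the loaders consume
#'
#' Emits the wide score matrix TSV, a truth JSON, and annotation TSVs
#' (gene-term channels and pair channels).
#'
#' @param gen result of [generateEmap()].
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
writeSyntheticData <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  p <- file.path(dir, "scores.tsv")
  writeScoreMatrix(gen$scores, p)
  paths <- c(paths, p)
  p <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(roles = as.list(gen$truth$roles),
         regulators = gen$truth$regulators,
         planted_pairs = gen$truth$planted_pairs),
    p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  for (ch in names(gen$annotation@geneTerms)) {
    gtl <- gen$annotation@geneTerms[[ch]]
    df <- data.frame(gene = rep(names(gtl), lengths(gtl)),
                     term = unlist(gtl, use.names = FALSE),
                     stringsAsFactors = FALSE)
    p <- file.path(dir, sprintf("annotation_%s.tsv", ch))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    paths <- c(paths, p)
  }
  for (ch in names(gen$annotation@pairRelations)) {
    df <- splitPairKey(gen$annotation@pairRelations[[ch]])
    p <- file.path(dir, sprintf("pairs_%s.tsv", ch))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
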