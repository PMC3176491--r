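# internal helpers shared across modules

# canonical unordered pair key; "|" is safe for ORF/standard gene names
pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

splitPairKey <- function(key) {
  if (!length(key))
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  m <- do.call(rbind, strsplit(key, "|", fixed = TRUE))
  data.frame(gene_a = m[, 1], gene_b = m[, 2], stringsAsFactors = FALSE)
}

MOTIF_CLASSES <- c("NNN", "NNP", "NPP", "PPP")

# class label from the number of negative edges in a triangle
classFromNegCount <- function(nNeg) {
  c("PPP", "NPP", "NNP", "NNN")[nNeg + 1L]
}

# canonical empty pairs/edges frames
emptyPairs <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             score = numeric(), n_sources = integer(),
             stringsAsFactors = FALSE)
}

emptyEdges <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             sign = character(), score = numeric(),
             stringsAsFactors = FALSE)
}

# seeds for ensemble streams, derived from one user seed by counter offset;
# kept within the 32-bit integer range
deriveSeed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + counter) %% 2147483647)
}
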