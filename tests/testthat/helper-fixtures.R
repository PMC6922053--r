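`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared fixtures and independent oracles. Oracles are deliberately
# written as naive dense loops so they share no code path with the
# implementation they check.

# dictionary for the worked normalization sentence
workedDictionary <- function() {
  conceptDictionary(
    c("bronchopulmonary dysplasia", "lung", "injury", "preterm infant",
      "resulting from", "oxygen", "mechanical ventilation"),
    c("C0006287", "C0024109", "C3263722", "C0021294", "C0678226",
      "C0030054", "C0199470"))
}

workedSentence <- paste(
  "Bronchopulmonary Dysplasia was first described by Northway and",
  "colleagues in 1967 as a lung injury in a preterm infant resulting",
  "from oxygen and mechanical ventilation.")

workedNormalized <- paste(
  "C0006287 was first described by northway and colleagues in 1967 as",
  "a C0024109 C3263722 in a C0021294 C0678226 C0030054 and C0199470")

# random symmetric integer count matrix with zero diagonal
rsymCounts <- function(n, density = 0.3, maxCount = 9L, seed = 1L) {
  set.seed(seed)
  up <- matrix(0, n, n)
  cells <- which(upper.tri(up))
  on <- sample(cells, max(1L, round(density * length(cells))))
  up[on] <- sample.int(maxCount, length(on), replace = TRUE)
  m <- up + t(up)
  dimnames(m) <- list(sprintf("C%07d", seq_len(n)), sprintf("C%07d", seq_len(n)))
  m
}

# brute-force PMI: dense loops over all pairs, straight from the
# definition (joint = count / event total, margins = participations)
densePMIOracle <- function(counts, alpha) {
  n <- nrow(counts)
  N <- sum(counts) / 2
  marg <- rowSums(counts)
  pa <- marg^alpha
  pa <- pa / sum(pa)
  out <- matrix(NA_real_, n, n, dimnames = dimnames(counts))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (counts[i, j] > 0)
      out[i, j] <- log((counts[i, j] / N) / (pa[i] * pa[j]))
  }
  out
}

# brute-force GloVe loss: dense triple loop over every ordered cell
denseGloveLossOracle <- function(model, counts, yMax = 100, alphaW = 0.75) {
  W <- model@wordVectors; C <- model@contextVectors
  bw <- model@wordBias; bc <- model@contextBias
  total <- 0
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    y <- counts[i, j]
    if (y <= 0) next
    f <- if (y < yMax) (y / yMax)^alphaW else 1
    pred <- 0
    for (k in seq_len(ncol(W))) pred <- pred + W[i, k] * C[j, k]
    total <- total + f * (pred + bw[i] + bc[j] - log(y))^2
  }
  total
}

# GloVe model with prescribed (default zero) parameters
makeGloveModel <- function(vocab, d, value = 0) {
  nv <- length(vocab)
  new("GloVeModel",
      wordVectors = matrix(value, nv, d),
      contextVectors = matrix(value, nv, d),
      wordBias = rep(value, nv), contextBias = rep(value, nv),
      vocab = vocab)
}

# isotropic Gaussian embeddings over categorized concepts
gaussianEmbedding <- function(nConcepts = 500L, d = 50L, nCats = 4L,
                              seed = 123L) {
  set.seed(seed)
  V <- matrix(rnorm(nConcepts * d), nConcepts, d,
              dimnames = list(sprintf("C%07d", seq_len(nConcepts)), NULL))
  types <- paste0("CAT_", rep_len(seq_len(nCats), nConcepts))
  names(types) <- rownames(V)
  list(emb = conceptEmbedding(V), types = types)
}

# random category-matched concept pairs (no planted signal)
randomMatchedPairs <- function(types, nPairs, seed = 42L) {
  set.seed(seed)
  cats <- split(names(types), types)
  pairs <- t(replicate(nPairs, {
    cl <- sample(length(cats), 1L)
    sample(cats[[cl]], 2L)
  }))
  data.frame(cui1 = pairs[, 1L], cui2 = pairs[, 2L])
}

# synthetic corpus -> SPPMI+SVD embedding, returning the pieces the
# recovery tests need
pipelineEmbedding <- function(spec, d = 50L) {
  th <- generateThesaurus(spec)
  corp <- generateCorpus(spec, th$dictionary)
  streams <- lapply(corp$documents, normalizeText, dict = th$dictionary)
  wins <- unlist(lapply(streams, chunkWindows, L = spec$windowLength),
                 recursive = FALSE)
  cm <- textCooccurrence(wins, sort(th$dictionary@cuis))
  emb <- svdEmbeddings(sppmiMatrix(cm), d = d)$embedding
  list(embedding = emb, typeMap = th$typeMap,
       plantedPairs = corp$plantedPairs, counts = cm)
}

# random patient event stream (no planted structure)
randomEventStream <- function(nPatients, eventsPerPatient, nCuis,
                              horizon = 200L, seed = 1L) {
  set.seed(seed)
  n <- nPatients * eventsPerPatient
  data.frame(
    patient_id = rep(sprintf("P%03d", seq_len(nPatients)),
                     each = eventsPerPatient),
    cui = sample(sprintf("C%07d", seq_len(nCuis)), n, replace = TRUE),
    day = sample.int(horizon, n, replace = TRUE) - 1L)
}
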