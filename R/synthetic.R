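#' Specification for the synthetic study data
#'
#' Bundles and validates the parameters of the synthetic corpus /
#' event-stream generators.  The generators are pure functions of this
#' spec: the same spec always yields the same thesaurus, documents,
#' planted pairs and events.
#'
#' Defaults describe a small but fully structured study: 100 concepts
#' in 4 semantic-type clusters; 240 documents of 100 tokens whose
#' 10-token windows are cluster-themed; 20 planted related pairs whose
#' members are co-inserted into a window with probability
#' \code{lambda}; and a claims-style stream of 2000 patients over a
#' two-year horizon in which planted comorbid pairs co-occur within
#' \code{spanDays} days with probability \code{lambda}.
#'
#' @param nConcepts number of synthetic concepts (CUIs in the
#'   \code{C9xxxxxx} range).
#' @param nClusters number of semantic-type clusters partitioning the
#'   concepts.
#' @param nDocuments number of corpus documents.
#' @param docLength tokens per document (in normalized token space);
#'   must be a multiple of \code{windowLength}.
#' @param windowLength co-occurrence window length in tokens.
#' @param conceptRate probability that a token slot carries a concept
#'   rather than a background word.
#' @param clusterPurity probability that a concept token is drawn from
#'   its window's theme cluster rather than uniformly.
#' @param backgroundVocab number of distinct background words.
#' @param zipfExponent exponent of the Zipf-like background word
#'   distribution (rank^-exponent), mimicking natural text margins.
#' @param nPlantedPairs number of planted related concept pairs
#'   (within-cluster, concept-disjoint).
#' @param lambda planting strength in [0, 1]: probability that the
#'   partner concept is co-inserted (same window / within
#'   \code{spanDays} days).
#' @param nPatients number of patients in the event stream.
#' @param eventsPerPatient background events per patient (may be 0).
#' @param carrierRate probability that a patient carries a given
#'   planted pair's index concept.
#' @param horizonDays event-day horizon (default two years).
#' @param spanDays co-occurrence period length in days.
#' @param seed integer seed from which all generator randomness flows.
#' @return a validated list of class \code{"SyntheticSpec"}.
#' @export
syntheticSpec <- function(nConcepts = 100L, nClusters = 4L,
                          nDocuments = 240L, docLength = 100L,
                          windowLength = 10L, conceptRate = 0.3,
                          clusterPurity = 0.8, backgroundVocab = 200L,
                          zipfExponent = 1.1, nPlantedPairs = 20L,
                          lambda = 0.9, nPatients = 2000L,
                          eventsPerPatient = 20L, carrierRate = 0.25,
                          horizonDays = 730L, spanDays = 30L, seed = 1L) {
  spec <- list(nConcepts = as.integer(nConcepts),
               nClusters = as.integer(nClusters),
               nDocuments = as.integer(nDocuments),
               docLength = as.integer(docLength),
               windowLength = as.integer(windowLength),
               conceptRate = conceptRate, clusterPurity = clusterPurity,
               backgroundVocab = as.integer(backgroundVocab),
               zipfExponent = zipfExponent,
               nPlantedPairs = as.integer(nPlantedPairs),
               lambda = lambda, nPatients = as.integer(nPatients),
               eventsPerPatient = as.integer(eventsPerPatient),
               carrierRate = carrierRate,
               horizonDays = as.integer(horizonDays),
               spanDays = as.integer(spanDays), seed = as.integer(seed))
  with(spec, {
    stopifnot(nConcepts >= 2L, nClusters >= 1L, nClusters <= nConcepts,
              nDocuments >= 1L, docLength >= windowLength,
              windowLength >= 2L, backgroundVocab >= 1L,
              nPatients >= 1L, eventsPerPatient >= 0L,
              horizonDays > 4L * spanDays, spanDays >= 1L,
              conceptRate > 0, conceptRate <= 1,
              clusterPurity >= 0, clusterPurity <= 1,
              carrierRate > 0, carrierRate <= 1,
              lambda >= 0, lambda <= 1, zipfExponent > 0,
              nPlantedPairs >= 0L)
    if (docLength %% windowLength != 0L)
      stop("docLength must be a multiple of windowLength")
    if (2L * nPlantedPairs > nConcepts)
      stop("too many planted pairs for the concept count")
  })
  structure(spec, class = "SyntheticSpec")
}

.synthCuis <- function(spec) sprintf("C9%06d", seq_len(spec$nConcepts))

# even partition of concepts into clusters, no RNG
.synthClusters <- function(spec)
  sort(rep_len(seq_len(spec$nClusters), spec$nConcepts))

.fillerWords <- c("chronic", "acute", "severe", "mild", "primary",
                  "secondary", "syndrome", "disorder", "disease",
                  "deficiency", "infection", "injury", "failure",
                  "therapy", "agent", "virus", "pain", "lesion",
                  "tumor", "fracture")

#' Planted related concept pairs of a synthetic spec
#'
#' Deterministic in the spec: pairs are within-cluster and
#' concept-disjoint (no concept belongs to two pairs), assigned to
#' clusters round-robin.  Shared by the corpus and event-stream
#' generators so both pathways plant the same ground truth.
#'
#' @param spec a [syntheticSpec()].
#' @return data.frame with columns \code{cui1}, \code{cui2},
#'   \code{lambda}.
#' @export
plantedPairs <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  cuis <- .synthCuis(spec)
  clusters <- .synthClusters(spec)
  set.seed(spec$seed + 1L)
  # round-robin over clusters, taking two unused concepts each time
  free <- lapply(split(seq_len(spec$nConcepts), clusters), sample)
  c1 <- integer(0); c2 <- integer(0)
  cl <- 1L
  for (p in seq_len(spec$nPlantedPairs)) {
    tries <- 0L
    while (length(free[[cl]]) < 2L) {
      cl <- cl %% spec$nClusters + 1L
      tries <- tries + 1L
      if (tries > spec$nClusters)
        stop("not enough within-cluster concepts to plant the requested pairs")
    }
    c1[p] <- free[[cl]][1L]; c2[p] <- free[[cl]][2L]
    free[[cl]] <- free[[cl]][-(1:2)]
    cl <- cl %% spec$nClusters + 1L
  }
  data.frame(cui1 = cuis[c1], cui2 = cuis[c2],
             lambda = rep(spec$lambda, spec$nPlantedPairs))
}

#' Generate a synthetic thesaurus and semantic-type map
#'
#' Synthetic CUIs in the \code{C9xxxxxx} range with unique 1-3-token
#' surface phrases (each phrase opens with a concept-specific head
#' word, so greedy longest-match normalization inverts the rendering
#' exactly), and one category label per concept assigned by cluster.
#'
#' @param spec a [syntheticSpec()].
#' @return list with elements \code{dictionary} (a
#'   [ConceptDictionary-class]) and \code{typeMap} (named character
#'   vector CUI -> category label).
#' @export
generateThesaurus <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  cuis <- .synthCuis(spec)
  clusters <- .synthClusters(spec)
  set.seed(spec$seed)
  heads <- paste0("term", seq_len(spec$nConcepts))
  extra <- sample(0:2, spec$nConcepts, replace = TRUE)
  phrases <- vapply(seq_len(spec$nConcepts), function(i) {
    paste(c(heads[i], sample(.fillerWords, extra[i])), collapse = " ")
  }, character(1))
  typeMap <- paste0("TYPE_", clusters)
  names(typeMap) <- cuis
  list(dictionary = conceptDictionary(phrases, cuis), typeMap = typeMap)
}

#' Generate a synthetic concept-bearing corpus with planted pairs
#'
#' Each document is built in normalized token space as a sequence of
#' \code{windowLength}-token blocks: every slot carries a concept
#' (with probability \code{conceptRate}; drawn from the block's theme
#' cluster with probability \code{clusterPurity}) or a background word
#' from a Zipf-like distribution.  For each planted pair (a, b):
#' whenever a appears in a block, b is inserted into the same block
#' with probability \code{lambda}.  The token stream is then rendered
#' as raw text by expanding each concept to its surface phrase,
#' capitalizing the document opening and closing with a period — so
#' [normalizeText()] followed by [chunkWindows()] recovers the planted
#' block structure exactly.
#'
#' @param spec a [syntheticSpec()].
#' @param dict the [ConceptDictionary-class] from
#'   [generateThesaurus()] (must come from the same spec).
#' @return list with elements \code{documents} (character vector of
#'   raw text), \code{plantedPairs} (ground-truth data.frame, see
#'   [plantedPairs()]).
#' @export
generateCorpus <- function(spec, dict) {
  stopifnot(inherits(spec, "SyntheticSpec"), is(dict, "ConceptDictionary"))
  cuis <- .synthCuis(spec)
  clusters <- .synthClusters(spec)
  byCluster <- split(seq_along(cuis), clusters)
  planted <- plantedPairs(spec)
  partnerOf <- structure(planted$cui2, names = planted$cui1)
  phraseOf <- structure(dict@phrases, names = dict@cuis)
  bgWords <- paste0("word", seq_len(spec$backgroundVocab))
  bgProb <- seq_len(spec$backgroundVocab)^(-spec$zipfExponent)
  L <- spec$windowLength
  nBlocks <- spec$docLength %/% L
  set.seed(spec$seed + 2L)
  docs <- character(spec$nDocuments)
  for (dIdx in seq_len(spec$nDocuments)) {
    blocks <- vector("list", nBlocks)
    for (b in seq_len(nBlocks)) {
      theme <- sample.int(spec$nClusters, 1L)
      isConcept <- stats::runif(L) < spec$conceptRate
      slot <- sample(bgWords, L, replace = TRUE, prob = bgProb)
      nc <- sum(isConcept)
      if (nc) {
        fromTheme <- stats::runif(nc) < spec$clusterPurity
        pick <- integer(nc)
        pick[fromTheme] <- sample(byCluster[[theme]], sum(fromTheme),
                                  replace = TRUE)
        pick[!fromTheme] <- sample.int(spec$nConcepts, sum(!fromTheme),
                                       replace = TRUE)
        slot[isConcept] <- cuis[pick]
      }
      # co-insert partners of planted index concepts present in the block
      present <- intersect(unique(slot[isConcept]), names(partnerOf))
      for (a in present) {
        b2 <- partnerOf[[a]]
        if (b2 %in% slot) next
        if (stats::runif(1) < spec$lambda) {
          cand <- which(!(slot %in% c(a, b2)))
          if (!length(cand)) next
          bg <- intersect(which(!(slot %in% cuis)), cand)
          slot[if (length(bg)) bg[sample.int(length(bg), 1L)]
               else cand[sample.int(length(cand), 1L)]] <- b2
        }
      }
      blocks[[b]] <- slot
    }
    toks <- unlist(blocks)
    words <- ifelse(toks %in% dict@cuis, phraseOf[toks], toks)
    txt <- paste(words, collapse = " ")
    substr(txt, 1L, 1L) <- toupper(substr(txt, 1L, 1L))
    docs[dIdx] <- paste0(txt, ".")
  }
  list(documents = docs, plantedPairs = planted)
}

#' Generate a synthetic patient event stream with planted comorbidities
#'
#' Background events are uniform over the non-planted concepts and a
#' two-year day horizon.  For each planted pair (a, b) and each
#' patient: with probability \code{carrierRate} the patient receives
#' an event of a at a uniform day, and then with probability
#' \code{lambda} an event of b within \code{spanDays} days — otherwise
#' an event of b far away (more than twice \code{spanDays}), so the
#' within-period co-occurrence rate among carriers of a is exactly
#' \code{lambda} in expectation.
#'
#' @param spec a [syntheticSpec()].
#' @return list with elements \code{events} (data.frame
#'   \code{patient_id}, \code{cui}, \code{day}) and
#'   \code{plantedPairs} (ground truth, identical to the corpus
#'   generator's for the same spec).
#' @export
generateEventStream <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  cuis <- .synthCuis(spec)
  planted <- plantedPairs(spec)
  pool <- setdiff(cuis, c(planted$cui1, planted$cui2))
  if (!length(pool)) pool <- cuis
  pid <- sprintf("P%05d", seq_len(spec$nPatients))
  set.seed(spec$seed + 3L)
  nBg <- spec$nPatients * spec$eventsPerPatient
  parts <- list()
  if (nBg > 0L)
    parts[[1L]] <- data.frame(
      patient_id = rep(pid, each = spec$eventsPerPatient),
      cui = sample(pool, nBg, replace = TRUE),
      day = sample.int(spec$horizonDays, nBg, replace = TRUE) - 1L)
  h <- spec$horizonDays
  for (p in seq_len(nrow(planted))) {
    carrier <- which(stats::runif(spec$nPatients) < spec$carrierRate)
    if (!length(carrier)) next
    dayA <- sample.int(h, length(carrier), replace = TRUE) - 1L
    near <- stats::runif(length(carrier)) < spec$lambda
    off <- sample(0:spec$spanDays, length(carrier), replace = TRUE) *
      sample(c(-1L, 1L), length(carrier), replace = TRUE)
    dayB <- pmin(pmax(dayA + off, 0L), h - 1L)  # clamping keeps |diff| <= span
    far <- !near
    if (any(far)) {
      dayB[far] <- vapply(dayA[far], function(d0) {
        cand <- setdiff(0:(h - 1L),
                        max(0L, d0 - 2L * spec$spanDays):(d0 + 2L * spec$spanDays))
        cand[sample.int(length(cand), 1L)]
      }, integer(1))
    }
    parts[[length(parts) + 1L]] <- data.frame(
      patient_id = rep(pid[carrier], 2L),
      cui = rep(c(planted$cui1[p], planted$cui2[p]), each = length(carrier)),
      day = c(dayA, dayB))
  }
  events <- if (length(parts)) do.call(rbind, parts) else
    data.frame(patient_id = character(), cui = character(), day = integer())
  events <- events[order(events$patient_id, events$day, events$cui), ]
  rownames(events) <- NULL
  list(events = events, plantedPairs = planted)
}
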