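#' @describeIn vocabulary vocabulary of a co-occurrence matrix
#' @export
setMethod("vocabulary", "CoocMatrix", function(x) x@vocab)

#' @describeIn vocabulary vocabulary of an SPPMI matrix
#' @export
setMethod("vocabulary", "SPPMIMatrix", function(x) x@vocab)

#' @describeIn vocabulary vocabulary of an embedding (row order)
#' @export
setMethod("vocabulary", "ConceptEmbedding", function(x) rownames(x@vectors))

#' @describeIn vocabulary vocabulary of a GloVe model
#' @export
setMethod("vocabulary", "GloVeModel", function(x) x@vocab)

#' @describeIn coocCounts sparse count matrix of a CoocMatrix
#' @export
setMethod("coocCounts", "CoocMatrix", function(x) x@counts)

#' @describeIn sourceTag source tag of a CoocMatrix
#' @export
setMethod("sourceTag", "CoocMatrix", function(x) x@sourceTag)

#' @describeIn sppmiValues sparse SPPMI values
#' @export
setMethod("sppmiValues", "SPPMIMatrix", function(x) x@values)

#' @describeIn embeddingVectors dense embedding matrix
#' @export
setMethod("embeddingVectors", "ConceptEmbedding", function(x) x@vectors)

#' @describeIn embeddingDim number of latent dimensions
#' @export
setMethod("embeddingDim", "ConceptEmbedding", function(x) ncol(x@vectors))

setMethod("show", "ConceptDictionary", function(object) {
  cat("ConceptDictionary with", length(object@phrases), "entries",
      sprintf("(longest phrase: %d token%s)\n", object@maxTokens,
              if (object@maxTokens == 1L) "" else "s"))
  n <- min(3L, length(object@phrases))
  for (i in seq_len(n))
    cat(sprintf("  '%s' -> %s\n", object@phrases[i], object@cuis[i]))
  if (length(object@phrases) > n) cat("  ...\n")
})

setMethod("show", "CoocMatrix", function(object) {
  nz <- length(object@counts@x)
  cat(sprintf("CoocMatrix [%s]: %d concepts, %d stored cells, total pair count %g\n",
              object@sourceTag, length(object@vocab), nz,
              sum(object@counts) / 2))
})

setMethod("show", "SPPMIMatrix", function(object) {
  cat(sprintf("SPPMIMatrix: %d concepts, %d positive cells (alpha=%g, k=%g)\n",
              length(object@vocab), length(object@values@x),
              object@alpha, object@k))
})

setMethod("show", "ConceptEmbedding", function(object) {
  cat(sprintf("ConceptEmbedding: %d concepts x %d dimensions\n",
              nrow(object@vectors), ncol(object@vectors)))
})

setMethod("show", "GloVeModel", function(object) {
  cat(sprintf("GloVeModel: %d concepts, d=%d (word+context vectors, two bias terms)\n",
              length(object@vocab), ncol(object@wordVectors)))
})
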