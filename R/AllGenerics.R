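#' Vocabulary accessor
#'
#' Returns the concept-ID vocabulary of a container, in row order.
#'
#' @param x a [CoocMatrix-class], [SPPMIMatrix-class],
#'   [ConceptEmbedding-class] or [GloVeModel-class].
#' @return character vector of concept IDs.
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))

#' Co-occurrence count accessor
#'
#' @param x a [CoocMatrix-class].
#' @return the sparse symmetric count matrix.
#' @export
setGeneric("coocCounts", function(x) standardGeneric("coocCounts"))

#' Source tag accessor
#'
#' @param x a [CoocMatrix-class].
#' @return single string naming the data source the counts came from.
#' @export
setGeneric("sourceTag", function(x) standardGeneric("sourceTag"))

#' SPPMI value accessor
#'
#' @param x an [SPPMIMatrix-class].
#' @return the sparse symmetric matrix of SPPMI values.
#' @export
setGeneric("sppmiValues", function(x) standardGeneric("sppmiValues"))

#' Embedding matrix accessor
#'
#' @param x a [ConceptEmbedding-class].
#' @return numeric matrix, one row per concept.
#' @export
setGeneric("embeddingVectors", function(x) standardGeneric("embeddingVectors"))

#' Embedding dimension accessor
#'
#' @param x a [ConceptEmbedding-class].
#' @return integer, the number of latent dimensions d.
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))
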