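#' @import methods
#' @importClassesFrom Matrix sparseMatrix
NULL

.CUI_PATTERN <- "^C[0-9]+$"

#' ConceptDictionary: surface phrases mapped to concept identifiers
#'
#' Maps lowercase, punctuation-free surface phrases (one or more word
#' tokens) to UMLS-style concept unique identifiers (CUIs, pattern
#' \code{C} followed by digits).  Used by [normalizeText()] to collapse
#' multi-word medical concepts into single concept-ID tokens by greedy
#' longest-match scanning.
#'
#' @slot phrases character vector of space-joined surface phrases
#'   (lowercase, no punctuation).
#' @slot cuis character vector of concept IDs, parallel to
#'   \code{phrases}.
#' @slot maxTokens integer, the longest phrase length in tokens (cached
#'   to bound the longest-match scan).
#' @aliases ConceptDictionary-class
#' @exportClass ConceptDictionary
setClass("ConceptDictionary",
  representation(phrases = "character", cuis = "character",
                 maxTokens = "integer"))

setValidity("ConceptDictionary", function(object) {
  msgs <- character()
  if (length(object@phrases) != length(object@cuis))
    msgs <- c(msgs, "phrases and cuis must have equal length")
  if (length(object@phrases) == 0L)
    msgs <- c(msgs, "dictionary must contain at least one entry")
  if (anyDuplicated(object@phrases))
    msgs <- c(msgs, "duplicate surface phrases are not allowed")
  bad <- object@phrases[!grepl("^[a-z0-9-]+( [a-z0-9-]+)*$", object@phrases)]
  if (length(bad))
    msgs <- c(msgs, paste0("phrases must be lowercase space-separated tokens ",
                           "without punctuation; offenders: ",
                           paste(utils::head(bad, 3), collapse = ", ")))
  if (!all(grepl(.CUI_PATTERN, object@cuis)))
    msgs <- c(msgs, "all concept IDs must match the CUI pattern C<digits>")
  if (length(msgs)) msgs else TRUE
})

#' Construct a concept dictionary
#'
#' @param phrases character vector of surface phrases; multi-word
#'   phrases are space-separated, all lowercase, punctuation-free.
#' @param cuis character vector of concept IDs (\code{C} + digits),
#'   parallel to \code{phrases}.
#' @return A [ConceptDictionary-class] object.
#' @examples
#' conceptDictionary(c("heart", "heart disease"), c("C0018787", "C0018799"))
#' @export
conceptDictionary <- function(phrases, cuis) {
  new("ConceptDictionary",
      phrases = as.character(phrases), cuis = as.character(cuis),
      maxTokens = if (length(phrases))
        max(lengths(strsplit(as.character(phrases), " ", fixed = TRUE)))
      else 0L)
}

#' CoocMatrix: symmetric concept co-occurrence counts
#'
#' A sparse symmetric matrix of nonnegative integer co-occurrence
#' counts over a concept vocabulary.  The diagonal is identically zero:
#' self co-occurrence carries no information for similarity benchmarks.
#' This object is the hub of the pipeline — it is produced from text
#' windows ([textCooccurrence()]) or timestamped patient events
#' ([temporalCooccurrence()]), merged across sources
#' ([mergeCooccurrence()]), and consumed by every factorizer.
#'
#' @slot counts sparse symmetric matrix (\pkg{Matrix}) of counts,
#'   dimension |V| x |V|, zero diagonal, nonnegative integral entries.
#' @slot vocab character vector of concept IDs; \code{vocab[i]} labels
#'   row/column \code{i}.
#' @slot sourceTag character scalar naming the data source
#'   (e.g. \code{"text"}, \code{"claims"}, \code{"merged"}).
#' @aliases CoocMatrix-class
#' @exportClass CoocMatrix
setClass("CoocMatrix",
  representation(counts = "sparseMatrix", vocab = "character",
                 sourceTag = "character"))

setValidity("CoocMatrix", function(object) {
  msgs <- character()
  cts <- object@counts
  if (nrow(cts) != ncol(cts))
    msgs <- c(msgs, "counts must be square")
  if (nrow(cts) != length(object@vocab))
    msgs <- c(msgs, "vocabulary length must equal matrix dimension")
  if (anyDuplicated(object@vocab))
    msgs <- c(msgs, "vocabulary entries must be unique")
  x <- cts@x
  if (length(x)) {
    if (any(x < 0)) msgs <- c(msgs, "counts must be nonnegative")
    if (any(abs(x - round(x)) > 1e-9)) msgs <- c(msgs, "counts must be integral")
  }
  if (!Matrix::isSymmetric(cts, tol = 0))
    msgs <- c(msgs, "counts must be exactly symmetric")
  if (any(Matrix::diag(cts) != 0))
    msgs <- c(msgs, "diagonal must be all zero (no self co-occurrence)")
  if (length(object@sourceTag) != 1L)
    msgs <- c(msgs, "sourceTag must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CoocMatrix
#'
#' @param counts square sparse (or dense, coerced) symmetric matrix of
#'   nonnegative integer counts with zero diagonal.
#' @param vocab character vector of concept IDs labelling rows/columns;
#'   defaults to the matrix rownames.
#' @param sourceTag single string tagging the data source.
#' @return A [CoocMatrix-class].
#' @export
CoocMatrix <- function(counts, vocab = rownames(counts), sourceTag = "unknown") {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(vocab)) stop("a vocabulary is required (or name the matrix rows)")
  dimnames(counts) <- list(vocab, vocab)
  new("CoocMatrix", counts = Matrix::drop0(counts),
      vocab = as.character(vocab), sourceTag = sourceTag)
}

#' SPPMIMatrix: shifted positive pointwise mutual information
#'
#' The factorization target for word2vec-style embeddings: a sparse
#' symmetric matrix holding \eqn{\max(\mathrm{PMI}(w,c) - \log k, 0)}
#' on the cells where the underlying co-occurrence count is nonzero.
#' Cells clipped to zero are dropped from storage (zero is also the
#' implicit value, so factorization is unaffected).
#'
#' @slot values sparse symmetric nonnegative real matrix.
#' @slot vocab character vector of concept IDs.
#' @slot alpha smoothing exponent applied to the singleton frequencies.
#' @slot k shift constant (number of negative samples in the implicit
#'   skip-gram objective).
#' @aliases SPPMIMatrix-class
#' @exportClass SPPMIMatrix
setClass("SPPMIMatrix",
  representation(values = "sparseMatrix", vocab = "character",
                 alpha = "numeric", k = "numeric"))

setValidity("SPPMIMatrix", function(object) {
  msgs <- character()
  v <- object@values
  if (nrow(v) != ncol(v) || nrow(v) != length(object@vocab))
    msgs <- c(msgs, "values must be square with one vocabulary entry per row")
  if (length(v@x) && any(v@x < 0))
    msgs <- c(msgs, "SPPMI values must be nonnegative")
  if (!Matrix::isSymmetric(v, tol = 1e-12))
    msgs <- c(msgs, "values must be symmetric")
  if (object@alpha <= 0 || object@alpha > 1)
    msgs <- c(msgs, "alpha must lie in (0, 1]")
  if (object@k < 1) msgs <- c(msgs, "k must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' ConceptEmbedding: a dense concept-by-dimension embedding matrix
#'
#' The product of all three factorizers ([svdEmbeddings()],
#' [trainGlove()], [pcaEmbeddings()]) and the input to the benchmark
#' module.  Rows are concepts (rownames carry the concept IDs), columns
#' are latent dimensions.
#'
#' @slot vectors numeric matrix, |V| x d, all entries finite, rownames
#'   = concept IDs.
#' @aliases ConceptEmbedding-class
#' @exportClass ConceptEmbedding
setClass("ConceptEmbedding", representation(vectors = "matrix"))

setValidity("ConceptEmbedding", function(object) {
  msgs <- character()
  v <- object@vectors
  if (is.null(rownames(v))) msgs <- c(msgs, "vectors must have concept-ID rownames")
  else if (anyDuplicated(rownames(v))) msgs <- c(msgs, "concept IDs must be unique")
  if (!is.numeric(v)) msgs <- c(msgs, "vectors must be numeric")
  else if (any(!is.finite(v))) msgs <- c(msgs, "vectors must contain no non-finite entries")
  if (ncol(v) < 1L) msgs <- c(msgs, "embedding dimension must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ConceptEmbedding
#'
#' @param vectors numeric matrix with one row per concept.
#' @param vocab optional character vector of concept IDs; defaults to
#'   the existing rownames.
#' @return A [ConceptEmbedding-class].
#' @export
conceptEmbedding <- function(vectors, vocab = rownames(vectors)) {
  vectors <- as.matrix(vectors)
  rownames(vectors) <- vocab
  new("ConceptEmbedding", vectors = vectors)
}

#' GloVeModel: parameters of the weighted least-squares fit
#'
#' Holds the word vectors, context vectors and the two bias terms fit
#' by [trainGlove()].  The released embedding is the row-wise sum of
#' word and context vectors.
#'
#' @slot wordVectors |V| x d matrix.
#' @slot contextVectors |V| x d matrix.
#' @slot wordBias numeric length |V|.
#' @slot contextBias numeric length |V|.
#' @slot vocab character vector of concept IDs.
#' @aliases GloVeModel-class
#' @exportClass GloVeModel
setClass("GloVeModel",
  representation(wordVectors = "matrix", contextVectors = "matrix",
                 wordBias = "numeric", contextBias = "numeric",
                 vocab = "character"))

setValidity("GloVeModel", function(object) {
  msgs <- character()
  nv <- length(object@vocab)
  if (nrow(object@wordVectors) != nv || nrow(object@contextVectors) != nv ||
      length(object@wordBias) != nv || length(object@contextBias) != nv)
    msgs <- c(msgs, "all parameter blocks must have one row/entry per concept")
  if (ncol(object@wordVectors) != ncol(object@contextVectors))
    msgs <- c(msgs, "word and context vectors must share a dimension")
  if (any(!is.finite(object@wordVectors)) || any(!is.finite(object@contextVectors)) ||
      any(!is.finite(object@wordBias)) || any(!is.finite(object@contextBias)))
    msgs <- c(msgs, "all parameters must be finite")
  if (length(msgs)) msgs else TRUE
})
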