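#' Smoothed pointwise mutual information on nonzero cells
#'
#' Computes PMI on every nonzero cell of a symmetric co-occurrence
#' matrix, in natural log.  The joint probability of a pair is its
#' count divided by the total co-occurrence event count
#' \eqn{N = \sum_{i<j} n_{ij}}; the singleton frequency of a concept
#' is its participation (row sum) divided by the total participation
#' \eqn{2N}.  Each margin is raised to the smoothing exponent
#' \code{alpha} and the powered margins renormalized to sum to one
#' before entering the denominator — because the matrix is symmetric,
#' word and context margins coincide and both are smoothed.
#'
#' \deqn{\mathrm{PMI}(w,c) = \log\frac{p(w,c)}{p_\alpha(w)\,p_\alpha(c)}}
#'
#' @param counts a [CoocMatrix-class] with at least one nonzero cell.
#' @param alpha smoothing exponent in (0, 1]; \code{alpha = 1} is the
#'   unsmoothed definition. Default 0.75.
#' @return a sparse symmetric matrix holding PMI values (possibly
#'   negative) exactly on the nonzero cells of \code{counts}, with the
#'   vocabulary as dimnames.
#' @examples
#' cm <- textCooccurrence(list(c("A","B"), c("A","B"), c("A","C")),
#'                        vocab = c("A","B","C"))
#' pmiMatrix(cm, alpha = 1)["A", "B"]  # log 4
#' @export
pmiMatrix <- function(counts, alpha = 0.75) {
  stopifnot(is(counts, "CoocMatrix"))
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  cts <- methods::as(coocCounts(counts), "TsparseMatrix")
  if (!length(cts@x) || sum(cts@x) == 0)
    stop("empty input: co-occurrence matrix has no nonzero cell")
  nEvents <- sum(cts@x) / 2                      # each unordered pair stored twice
  marg <- Matrix::rowSums(cts)                   # participations; sum = 2N
  pA <- marg^alpha
  pA <- pA / sum(pA)                             # renormalized powered margins
  pj <- cts@x / nEvents
  val <- log(pj) - log(pA[cts@i + 1L]) - log(pA[cts@j + 1L])
  out <- Matrix::sparseMatrix(i = cts@i + 1L, j = cts@j + 1L, x = val,
                              dims = dim(cts))
  dimnames(out) <- list(vocabulary(counts), vocabulary(counts))
  out
}

#' Shifted positive PMI transform
#'
#' Applies \eqn{\mathrm{SPPMI}(w,c) = \max(\mathrm{PMI}(w,c) - \log k,
#' 0)} cell-wise.  With \code{k = 1} there is no shift and the
#' transform is a plain positive clip.  Cells that become zero are
#' dropped from storage; zero is also the implicit value, so the
#' factorization is unaffected.
#'
#' @param pmi sparse symmetric PMI matrix as returned by
#'   [pmiMatrix()] (concept IDs as dimnames).
#' @param k shift constant, >= 1. Default 1.
#' @param alpha the smoothing exponent used to build \code{pmi}
#'   (recorded in the result). Default 0.75.
#' @return an [SPPMIMatrix-class].
#' @export
sppmiTransform <- function(pmi, k = 1, alpha = 0.75) {
  if (k < 1) stop("invalid shift: k must be >= 1")
  pmi <- methods::as(methods::as(pmi, "generalMatrix"), "CsparseMatrix")
  pmi@x <- pmax(pmi@x - log(k), 0)
  new("SPPMIMatrix", values = Matrix::drop0(pmi),
      vocab = rownames(pmi), alpha = alpha, k = k)
}

#' Counts to SPPMI in one step
#'
#' Convenience wrapper chaining [pmiMatrix()] and [sppmiTransform()].
#'
#' @inheritParams pmiMatrix
#' @inheritParams sppmiTransform
#' @return an [SPPMIMatrix-class].
#' @export
sppmiMatrix <- function(counts, alpha = 0.75, k = 1)
  sppmiTransform(pmiMatrix(counts, alpha = alpha), k = k, alpha = alpha)

.truncatedSVD <- function(X, d) {
  d <- as.integer(d)
  if (is.na(d) || d < 1L || d > min(dim(X)))
    stop("invalid rank: d must lie in [1, matrix dimension]")
  # Dense exact SVD (LAPACK), truncated to rank d; deterministic.
  s <- svd(as.matrix(X))
  list(u = s$u[, seq_len(d), drop = FALSE],
       d = s$d[seq_len(d)],
       v = s$v[, seq_len(d), drop = FALSE])
}

#' Word2vec-style embeddings by truncated SVD of an SPPMI matrix
#'
#' Factorizes the SPPMI matrix as \eqn{U_d \Sigma_d V_d^T} and forms
#' word vectors \eqn{\tilde W = U_d \Sigma_d^p}, context vectors
#' \eqn{\tilde C = V_d \Sigma_d^p} and the released embedding
#' \eqn{W = \tilde W + \tilde C} (the symmetrically scaled sum of the
#' word and context vectors).  The default exponent \eqn{p = 0.5}
#' splits the singular values evenly between the two factors; set
#' \code{sigmaPower = 1} to load them entirely onto the word side.
#'
#' @param sppmi an [SPPMIMatrix-class].
#' @param d embedding dimension, 1 <= d <= vocabulary size.
#' @param sigmaPower exponent p applied to the singular values.
#'   Default 0.5.
#' @return list with elements \code{factorization} (list \code{u},
#'   \code{d}, \code{v}, \code{sigmaPower}, \code{Wtilde},
#'   \code{Ctilde}) and \code{embedding}, a [ConceptEmbedding-class].
#' @export
svdEmbeddings <- function(sppmi, d, sigmaPower = 0.5) {
  stopifnot(is(sppmi, "SPPMIMatrix"))
  f <- .truncatedSVD(sppmiValues(sppmi), d)
  sp <- f$d^sigmaPower
  Wt <- sweep(f$u, 2L, sp, "*")
  Ct <- sweep(f$v, 2L, sp, "*")
  emb <- conceptEmbedding(Wt + Ct, vocab = vocabulary(sppmi))
  list(factorization = c(f, list(sigmaPower = sigmaPower,
                                 Wtilde = Wt, Ctilde = Ct)),
       embedding = emb)
}

#' PCA baseline: truncated SVD of the raw count matrix
#'
#' Applies the truncated SVD directly to the raw co-occurrence counts
#' and returns \eqn{U_d \Sigma_d} as the embedding.
#'
#' @param counts a [CoocMatrix-class].
#' @param d embedding dimension, 1 <= d <= vocabulary size.
#' @return a [ConceptEmbedding-class].
#' @export
pcaEmbeddings <- function(counts, d) {
  stopifnot(is(counts, "CoocMatrix"))
  f <- .truncatedSVD(coocCounts(counts), d)
  conceptEmbedding(sweep(f$u, 2L, f$d, "*"), vocab = vocabulary(counts))
}
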