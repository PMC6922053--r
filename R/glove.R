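#' GloVe weighting function
#'
#' \eqn{f(y) = (y/y_{max})^{\alpha}} for \eqn{y < y_{max}}, else 1.
#' Nondecreasing in \eqn{y} and capped at one; zero cells never enter
#' the objective, so \eqn{y \le 0} is rejected.
#'
#' @param y positive co-occurrence count(s).
#' @param yMax weighting cap (default 100).
#' @param alphaW weighting exponent in (0, 1] (default 0.75).
#' @return numeric in [0, 1], vectorized over \code{y}.
#' @examples
#' gloveWeight(c(50, 100, 150))  # 0.5^0.75, 1, 1
#' @export
gloveWeight <- function(y, yMax = 100, alphaW = 0.75) {
  if (any(y <= 0)) stop("invalid cell: weighting is defined for y > 0 only")
  if (yMax <= 0) stop("yMax must be positive")
  if (alphaW <= 0 || alphaW > 1) stop("alphaW must lie in (0, 1]")
  ifelse(y < yMax, (y / yMax)^alphaW, 1)
}

.nonzeroCells <- function(counts) {
  cts <- if (is(counts, "CoocMatrix")) coocCounts(counts) else
    Matrix::Matrix(counts, sparse = TRUE)
  cts <- methods::as(methods::as(cts, "generalMatrix"), "TsparseMatrix")
  list(i = cts@i + 1L, j = cts@j + 1L, y = cts@x, n = nrow(cts),
       vocab = if (is(counts, "CoocMatrix")) vocabulary(counts)
               else rownames(cts) %||% sprintf("V%d", seq_len(nrow(cts))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' GloVe weighted least-squares loss
#'
#' Evaluates the objective
#' \deqn{\sum_{(w,c):\,y_{wc}>0} f(y_{wc})\,
#'   (\vec w \cdot \vec c + b_w + b_c - \log y_{wc})^2}
#' over every nonzero ordered cell of the count matrix (a symmetric
#' matrix contributes both orientations of each off-diagonal pair).
#'
#' @param model a [GloVeModel-class].
#' @param counts a [CoocMatrix-class], or a plain (square, possibly
#'   1x1) numeric matrix of counts for toy problems.
#' @param yMax,alphaW weighting parameters, see [gloveWeight()].
#' @return nonnegative scalar loss.
#' @export
gloveLoss <- function(model, counts, yMax = 100, alphaW = 0.75) {
  stopifnot(is(model, "GloVeModel"))
  cells <- .nonzeroCells(counts)
  if (cells$n != length(model@vocab))
    stop("dimension mismatch between model and count matrix vocabulary")
  if (!length(cells$y)) return(0)
  W <- model@wordVectors; C <- model@contextVectors
  pred <- rowSums(W[cells$i, , drop = FALSE] * C[cells$j, , drop = FALSE]) +
    model@wordBias[cells$i] + model@contextBias[cells$j]
  sum(gloveWeight(cells$y, yMax, alphaW) * (pred - log(cells$y))^2)
}

#' Train GloVe-style embeddings on a co-occurrence matrix
#'
#' Fits word vectors, context vectors and two bias terms by AdaGrad
#' stochastic gradient descent on the weighted least-squares
#' objective (see [gloveLoss()]).  Parameters are initialized from a
#' uniform distribution on \eqn{(-0.5/d, 0.5/d)} seeded by
#' \code{seed}.  Each epoch visits every nonzero unordered cell once
#' in a freshly shuffled order and applies the gradient updates for
#' both orientations of the cell (one orientation for a diagonal
#' cell), matching the full-sum objective without double counting.
#' Training is single-threaded and bit-reproducible: identical seeds
#' yield identical models.
#'
#' @param counts a [CoocMatrix-class] or a plain square numeric count
#'   matrix with at least one nonzero cell.
#' @param d embedding dimension.
#' @param yMax,alphaW weighting parameters, see [gloveWeight()].
#' @param epochs number of passes over the nonzero cells (default 50).
#' @param learningRate AdaGrad base step size (default 0.05).
#' @param seed integer RNG seed for initialization and shuffling.
#' @return list with elements \code{model} (a [GloVeModel-class]) and
#'   \code{embedding} (a [ConceptEmbedding-class] whose rows are the
#'   sums of word and context vectors).
#' @export
trainGlove <- function(counts, d = 50L, yMax = 100, alphaW = 0.75,
                       epochs = 50L, learningRate = 0.05, seed = 1L) {
  d <- as.integer(d); epochs <- as.integer(epochs)
  if (d < 1L) stop("embedding dimension must be >= 1")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (learningRate <= 0) stop("learningRate must be positive")
  cells <- .nonzeroCells(counts)
  if (!length(cells$y)) stop("nothing to train: count matrix has no nonzero cell")
  # keep one representative per unordered cell; both orientations are
  # updated when the cell is visited
  keep <- cells$i <= cells$j
  ci <- cells$i[keep]; cj <- cells$j[keep]; cy <- cells$y[keep]
  nv <- cells$n
  logy <- log(cy)
  fy <- gloveWeight(cy, yMax, alphaW)
  set.seed(seed)
  lim <- 0.5 / d
  W <- matrix(stats::runif(nv * d, -lim, lim), nv, d)
  C <- matrix(stats::runif(nv * d, -lim, lim), nv, d)
  bw <- stats::runif(nv, -lim, lim)
  bc <- stats::runif(nv, -lim, lim)
  gW <- matrix(1, nv, d); gC <- matrix(1, nv, d)
  gbw <- rep(1, nv); gbc <- rep(1, nv)
  lr <- learningRate
  for (ep in seq_len(epochs)) {
    for (q in sample.int(length(cy))) {
      i <- ci[q]; j <- cj[q]
      orientations <- if (i == j) list(c(i, j)) else list(c(i, j), c(j, i))
      for (o in orientations) {
        wi <- o[1L]; cjx <- o[2L]
        e <- sum(W[wi, ] * C[cjx, ]) + bw[wi] + bc[cjx] - logy[q]
        g <- 2 * fy[q] * e
        dw <- g * C[cjx, ]; dc <- g * W[wi, ]
        W[wi, ] <- W[wi, ] - lr * dw / sqrt(gW[wi, ])
        C[cjx, ] <- C[cjx, ] - lr * dc / sqrt(gC[cjx, ])
        gW[wi, ] <- gW[wi, ] + dw^2
        gC[cjx, ] <- gC[cjx, ] + dc^2
        bw[wi] <- bw[wi] - lr * g / sqrt(gbw[wi])
        bc[cjx] <- bc[cjx] - lr * g / sqrt(gbc[cjx])
        gbw[wi] <- gbw[wi] + g^2
        gbc[cjx] <- gbc[cjx] + g^2
      }
    }
  }
  model <- new("GloVeModel", wordVectors = W, contextVectors = C,
               wordBias = bw, contextBias = bc, vocab = cells$vocab)
  list(model = model,
       embedding = conceptEmbedding(W + C, vocab = cells$vocab))
}
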