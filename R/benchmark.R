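#' Cosine similarity between two vectors
#'
#' \eqn{\cos(v_1, v_2) = v_1 v_2^T / (\|v_1\|_2 \|v_2\|_2)}: 1 for
#' identical vectors, 0 for orthogonal ones, -1 for antiparallel.
#'
#' @param v1,v2 nonzero numeric vectors of equal dimension.
#' @return scalar in [-1, 1].
#' @export
cosineSimilarity <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("invalid input: dimension mismatch")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("invalid input: zero vector has no direction")
  sum(v1 * v2) / (n1 * n2)
}

.rowNormalize <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  if (any(nrm == 0)) stop("embedding contains a zero vector")
  M / nrm
}

.asCategoryMap <- function(categories) {
  if (is.data.frame(categories)) {
    stopifnot(ncol(categories) >= 2L)
    out <- as.character(categories[[2L]])
    names(out) <- as.character(categories[[1L]])
    out
  } else {
    stopifnot(!is.null(names(categories)))
    categories
  }
}

#' Bootstrap null distribution of cosine similarities
#'
#' Draws \code{n} independent pairs, one concept uniformly with
#' replacement from category \code{catX} and one from \code{catY}
#' (resampling until the two drawn concepts differ), and records their
#' embedding cosines.  Reproducible given \code{seed}.
#'
#' @param emb a [ConceptEmbedding-class].
#' @param categories semantic-type map: named character vector
#'   (names = CUIs, values = category labels) or a two-column
#'   data.frame (cui, category).
#' @param catX,catY category labels to sample from; each must contain
#'   at least two embedded concepts.
#' @param n number of bootstrap draws (default 10000).
#' @param seed integer RNG seed.
#' @return numeric vector of \code{n} cosine similarities in [-1, 1].
#' @export
bootstrapNull <- function(emb, categories, catX, catY, n = 10000L,
                          seed = 1L) {
  stopifnot(is(emb, "ConceptEmbedding"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  categories <- .asCategoryMap(categories)
  U <- .rowNormalize(embeddingVectors(emb))
  mx <- intersect(names(categories)[categories == catX], rownames(U))
  my <- intersect(names(categories)[categories == catY], rownames(U))
  if (length(mx) < 2L || length(my) < 2L)
    stop("degenerate null: category with fewer than two embedded concepts")
  set.seed(seed)
  sx <- sample(mx, n, replace = TRUE)
  sy <- sample(my, n, replace = TRUE)
  while (any(same <- sx == sy))          # distinct concepts in each draw
    sy[same] <- sample(my, sum(same), replace = TRUE)
  rowSums(U[sx, , drop = FALSE] * U[sy, , drop = FALSE])
}

.nullThreshold <- function(samples, level) {
  # empirical (1 - level) quantile as the order statistic at
  # ceiling((1 - level) * n); distribution-free and dialect-free
  sort(samples)[ceiling((1 - level) * length(samples))]
}

#' Statistical power to detect known concept relationships
#'
#' For each relationship pair (x, y) with both concepts embedded, a
#' bootstrap null distribution of cosines is built for the category
#' pair (category(x), category(y)) — cached per unordered category
#' pair, \code{n} draws each — and the pair is declared discovered iff
#' its cosine strictly exceeds the empirical (1 - level) quantile of
#' that null.  Power is the discovered fraction of evaluable pairs; a
#' pair with a missing embedding or category is excluded and shows up
#' in \code{nTotal - nEvaluable}.  With \code{nullMode = "marginal"}
#' (the same-semantic-type benchmark) a single null is used for all
#' pairs, drawn from concepts of differing categories.
#'
#' @param emb a [ConceptEmbedding-class].
#' @param rels relationship set: data.frame whose first two columns
#'   are the concept IDs of each known pair (an optional third column
#'   labels the relation).
#' @param categories semantic-type map, see [bootstrapNull()].
#' @param n bootstrap draws per null distribution (default 10000).
#' @param level one-sided false-positive tolerance (default 0.05).
#' @param seed integer RNG seed (nulls are drawn in a deterministic
#'   order, so the whole computation is reproducible).
#' @param nullMode \code{"matched"} (default; null matched to each
#'   pair's category pair) or \code{"marginal"} (one null from
#'   different-category concept pairs).
#' @return data.frame with columns \code{metric} ("power"),
#'   \code{value}, \code{nEvaluable}, \code{nTotal}.
#' @export
relationshipPower <- function(emb, rels, categories, n = 10000L,
                              level = 0.05, seed = 1L,
                              nullMode = c("matched", "marginal")) {
  stopifnot(is(emb, "ConceptEmbedding"))
  nullMode <- match.arg(nullMode)
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  categories <- .asCategoryMap(categories)
  cx <- as.character(rels[[1L]]); cy <- as.character(rels[[2L]])
  if (!length(cx)) stop("empty benchmark: no relationship pairs")
  U <- .rowNormalize(embeddingVectors(emb))
  ok <- cx %in% rownames(U) & cy %in% rownames(U) &
    cx %in% names(categories) & cy %in% names(categories)
  nTotal <- length(cx)
  cx <- cx[ok]; cy <- cy[ok]
  if (!length(cx)) stop("empty benchmark: no evaluable pairs")
  cosObs <- rowSums(U[cx, , drop = FALSE] * U[cy, , drop = FALSE])
  if (nullMode == "marginal") {
    thr <- .nullThreshold(.marginalNull(U, categories, n, seed), level)
    disc <- cosObs > thr
  } else {
    keyOf <- function(a, b) paste(sort(c(a, b)), collapse = "\r")
    keys <- mapply(keyOf, categories[cx], categories[cy])
    cache <- new.env(hash = TRUE, parent = emptyenv())
    offset <- 0L
    for (key in unique(keys)) {               # deterministic order of first use
      cats <- strsplit(key, "\r", fixed = TRUE)[[1]]
      offset <- offset + 1L
      assign(key, .nullThreshold(
        bootstrapNull(emb, categories, cats[1L],
                      cats[length(cats)], n = n, seed = seed + offset),
        level), envir = cache)
    }
    disc <- cosObs > vapply(keys, function(k)
      get(k, envir = cache, inherits = FALSE), numeric(1))
  }
  data.frame(metric = "power", value = mean(disc),
             nEvaluable = length(cx), nTotal = nTotal)
}

.marginalNull <- function(U, categories, n, seed) {
  pool <- intersect(names(categories), rownames(U))
  if (length(unique(categories[pool])) < 2L)
    stop("degenerate null: marginal mode needs at least two categories")
  set.seed(seed)
  sx <- sample(pool, n, replace = TRUE)
  sy <- sample(pool, n, replace = TRUE)
  while (any(same <- categories[sx] == categories[sy]))
    sy[same] <- sample(pool, sum(same), replace = TRUE)
  rowSums(U[sx, , drop = FALSE] * U[sy, , drop = FALSE])
}

#' Spearman correlation with human similarity judgements
#'
#' Rank correlation (average-rank treatment of ties) between mean
#' human similarity scores and embedding cosines over the pairs whose
#' concepts are both embedded.
#'
#' @param emb a [ConceptEmbedding-class].
#' @param human data.frame whose first three columns are concept ID,
#'   concept ID, mean human score.
#' @return data.frame with columns \code{metric} ("spearman_rho"),
#'   \code{value}, \code{nEvaluable}, \code{nTotal}.
#' @export
humanSimilarityCorrelation <- function(emb, human) {
  stopifnot(is(emb, "ConceptEmbedding"))
  cx <- as.character(human[[1L]]); cy <- as.character(human[[2L]])
  score <- as.numeric(human[[3L]])
  U <- .rowNormalize(embeddingVectors(emb))
  ok <- cx %in% rownames(U) & cy %in% rownames(U)
  nTotal <- length(cx)
  cx <- cx[ok]; cy <- cy[ok]; score <- score[ok]
  if (length(cx) < 3L) stop("insufficient data: fewer than 3 evaluable pairs")
  if (length(unique(score)) < 2L)
    stop("degenerate ranking: all human scores are tied")
  cosv <- rowSums(U[cx, , drop = FALSE] * U[cy, , drop = FALSE])
  data.frame(metric = "spearman_rho",
             value = stats::cor(score, cosv, method = "spearman"),
             nEvaluable = length(cx), nTotal = nTotal)
}
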