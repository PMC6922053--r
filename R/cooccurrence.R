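#' Build a symmetric co-occurrence matrix from index pairs
#'
#' @param ii,jj integer vectors of 1-based indices with ii != jj
#'   element-wise (order irrelevant); each element contributes one
#'   count to the unordered pair.
#' @keywords internal
.pairsToCounts <- function(ii, jj, vocab, sourceTag) {
  nv <- length(vocab)
  if (!length(ii)) {
    cts <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(nv, nv))
  } else {
    lo <- pmin(ii, jj); hi <- pmax(ii, jj)
    up <- Matrix::sparseMatrix(i = lo, j = hi, x = rep(1, length(lo)),
                               dims = c(nv, nv))
    cts <- up + Matrix::t(up)
  }
  CoocMatrix(cts, vocab = vocab, sourceTag = sourceTag)
}

#' Count concept co-occurrences in text windows
#'
#' For each window, every unordered pair of distinct concept tokens
#' co-present in the window increments that pair's cell by one — once
#' per window regardless of how many times either token appears
#' (presence counting, not token products).  The result is symmetric
#' with a zero diagonal.
#'
#' @param windows list of character token vectors, as produced by
#'   [chunkWindows()].
#' @param vocab character vector of concept IDs to count over.
#' @param conceptOnly if \code{TRUE} (default), tokens absent from
#'   \code{vocab} (residual words, unknown concepts) are skipped; if
#'   \code{FALSE}, every token must be in \code{vocab} or an error is
#'   signalled.
#' @param multiplicity \code{"presence"} (default; once per window) or
#'   \code{"product"}: each pair cell is incremented by the product of
#'   the two tokens' occurrence counts in the window, for sensitivity
#'   checks.
#' @return a [CoocMatrix-class] with \code{sourceTag = "text"}.
#' @examples
#' w <- list(c("A", "B"), c("A", "B"), c("A", "C"))
#' coocCounts(textCooccurrence(w, vocab = c("A", "B", "C")))
#' @export
textCooccurrence <- function(windows, vocab, conceptOnly = TRUE,
                             multiplicity = c("presence", "product")) {
  multiplicity <- match.arg(multiplicity)
  vocab <- as.character(vocab)
  idx <- seq_along(vocab); names(idx) <- vocab
  ii <- vector("list", length(windows))
  jj <- vector("list", length(windows))
  xx <- vector("list", length(windows))
  for (w in seq_along(windows)) {
    toks <- windows[[w]]
    known <- toks %in% vocab
    if (!conceptOnly && !all(known))
      stop("vocabulary mismatch: token(s) not in vocabulary: ",
           paste(unique(toks[!known]), collapse = ", "))
    toks <- toks[known]
    if (multiplicity == "presence") {
      u <- unique(toks)
      if (length(u) < 2L) next
      pr <- utils::combn(idx[u], 2L)
      ii[[w]] <- pr[1L, ]; jj[[w]] <- pr[2L, ]
      xx[[w]] <- rep(1, ncol(pr))
    } else {
      tb <- table(toks)
      if (length(tb) < 2L) next
      pr <- utils::combn(seq_along(tb), 2L)
      ii[[w]] <- idx[names(tb)[pr[1L, ]]]
      jj[[w]] <- idx[names(tb)[pr[2L, ]]]
      xx[[w]] <- as.numeric(tb[pr[1L, ]]) * as.numeric(tb[pr[2L, ]])
    }
  }
  ii <- unlist(ii); jj <- unlist(jj); xx <- unlist(xx)
  nv <- length(vocab)
  if (!length(ii)) {
    up <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                               dims = c(nv, nv))
  } else {
    up <- Matrix::sparseMatrix(i = pmin(ii, jj), j = pmax(ii, jj), x = xx,
                               dims = c(nv, nv))
  }
  CoocMatrix(up + Matrix::t(up), vocab = vocab, sourceTag = "text")
}

#' Count temporal concept co-occurrences from patient event streams
#'
#' Counts a distinct CUI pair for a patient when two of that patient's
#' events fall close in time.  In \code{"rolling"} mode (claims-style)
#' the pair is counted once per patient if any two of their events
#' carrying the two CUIs are at most \code{spanDays} days apart.  In
#' \code{"calendar"} mode (notes-style) days are partitioned into fixed
#' bins of width \code{spanDays} anchored at each patient's first event
#' day, and the pair is counted when both CUIs occur in the same bin —
#' by default once per patient (so rolling counts dominate calendar
#' counts cell-wise), or once per (patient, bin) with
#' \code{perPeriod = TRUE}.  Pairs never cross patients.
#'
#' @param events data.frame with columns \code{patient_id},
#'   \code{cui}, \code{day} (integer day numbers).
#' @param vocab character vector of concept IDs; every event CUI must
#'   be present.
#' @param spanDays period length in days (default 30); must be >= 1.
#' @param mode \code{"rolling"} or \code{"calendar"}.
#' @param perPeriod calendar mode only: count once per (patient, bin)
#'   instead of once per patient.
#' @return a [CoocMatrix-class] tagged with the mode.
#' @examples
#' ev <- data.frame(patient_id = "p1", cui = c("C1", "C2"), day = c(0, 25))
#' coocCounts(temporalCooccurrence(ev, vocab = c("C1", "C2")))
#' @export
temporalCooccurrence <- function(events, vocab, spanDays = 30L,
                                 mode = c("rolling", "calendar"),
                                 perPeriod = FALSE) {
  mode <- match.arg(mode)
  spanDays <- as.integer(spanDays)
  if (is.na(spanDays) || spanDays < 1L)
    stop("invalid parameter: spanDays must be >= 1")
  vocab <- as.character(vocab)
  stopifnot(all(c("patient_id", "cui", "day") %in% names(events)))
  if (nrow(events)) {
    unknown <- setdiff(unique(events$cui), vocab)
    if (length(unknown))
      stop("vocabulary mismatch: unknown CUI(s): ",
           paste(unknown, collapse = ", "))
    if (any(!is.finite(events$day))) stop("event days must be finite")
  }
  idx <- seq_along(vocab); names(idx) <- vocab
  ii <- list(); jj <- list(); k <- 0L
  for (pe in split(events[c("cui", "day")], events$patient_id)) {
    cuis <- unique(pe$cui)
    if (length(cuis) < 2L) next
    daysBy <- split(pe$day, pe$cui)
    if (mode == "rolling") {
      pr <- utils::combn(cuis, 2L)
      for (q in seq_len(ncol(pr))) {
        da <- daysBy[[pr[1L, q]]]; db <- daysBy[[pr[2L, q]]]
        if (min(abs(outer(da, db, "-"))) <= spanDays) {
          k <- k + 1L
          ii[[k]] <- idx[[pr[1L, q]]]; jj[[k]] <- idx[[pr[2L, q]]]
        }
      }
    } else {
      bin <- (pe$day - min(pe$day)) %/% spanDays
      perBin <- split(pe$cui, bin)
      seen <- character()
      for (bc in perBin) {
        u <- unique(bc)
        if (length(u) < 2L) next
        pr <- utils::combn(sort(u), 2L)
        for (q in seq_len(ncol(pr))) {
          key <- paste(pr[1L, q], pr[2L, q])
          if (!perPeriod && key %in% seen) next
          seen <- c(seen, key)
          k <- k + 1L
          ii[[k]] <- idx[[pr[1L, q]]]; jj[[k]] <- idx[[pr[2L, q]]]
        }
      }
    }
  }
  .pairsToCounts(unlist(ii), unlist(jj), vocab,
                 sourceTag = paste0("events-", mode))
}

#' Merge co-occurrence matrices across sources
#'
#' The output vocabulary is the sorted union of the input
#' vocabularies; each cell is the element-wise sum of the inputs'
#' cells after index alignment.  Symmetry and the zero diagonal are
#' preserved.  Merging is commutative and associative.
#'
#' @param matrices non-empty list of [CoocMatrix-class] objects.
#' @return a [CoocMatrix-class] with \code{sourceTag = "merged"}.
#' @export
mergeCooccurrence <- function(matrices) {
  if (!length(matrices)) stop("nothing to merge: empty list")
  stopifnot(all(vapply(matrices, is, logical(1), "CoocMatrix")))
  vocab <- sort(unique(unlist(lapply(matrices, vocabulary))))
  nv <- length(vocab)
  acc <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(nv, nv))
  for (m in matrices) {
    pos <- match(vocabulary(m), vocab)
    cts <- methods::as(coocCounts(m), "TsparseMatrix")
    if (length(cts@x))
      acc <- acc + Matrix::sparseMatrix(i = pos[cts@i + 1L], j = pos[cts@j + 1L],
                                        x = cts@x, dims = c(nv, nv))
  }
  CoocMatrix(acc, vocab = vocab, sourceTag = "merged")
}
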