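#' Write a co-occurrence matrix as Matrix Market plus vocabulary
#'
#' The counts go to \code{mtxFile} in Matrix Market coordinate format;
#' the vocabulary to \code{vocabFile}, one CUI per line, line number =
#' matrix index.
#'
#' @param x a [CoocMatrix-class].
#' @param mtxFile path for the \code{.mtx} file.
#' @param vocabFile path for the vocabulary file; defaults to
#'   \code{<mtxFile>.vocab}.
#' @return \code{mtxFile}, invisibly.
#' @export
writeCoocMatrix <- function(x, mtxFile, vocabFile = paste0(mtxFile, ".vocab")) {
  stopifnot(is(x, "CoocMatrix"))
  Matrix::writeMM(methods::as(coocCounts(x), "TsparseMatrix"), mtxFile)
  writeLines(vocabulary(x), vocabFile)
  invisible(mtxFile)
}

#' Read a co-occurrence matrix from Matrix Market plus vocabulary
#'
#' Validates that the file content is symmetric (an asymmetric cell is
#' reported with its indices), that every count is a nonnegative
#' integer, and that the vocabulary has exactly one line per matrix
#' row.
#'
#' @param mtxFile path to the \code{.mtx} file.
#' @param vocabFile path to the vocabulary file; defaults to
#'   \code{<mtxFile>.vocab}.
#' @param sourceTag source tag for the result.
#' @return a [CoocMatrix-class].
#' @export
readCoocMatrix <- function(mtxFile, vocabFile = paste0(mtxFile, ".vocab"),
                           sourceTag = "file") {
  m <- Matrix::readMM(mtxFile)
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  vocab <- readLines(vocabFile)
  if (length(vocab) != nrow(m))
    stop(sprintf("vocabulary length mismatch: %d lines for a %dx%d matrix",
                 length(vocab), nrow(m), ncol(m)))
  asym <- methods::as(abs(m - Matrix::t(m)), "TsparseMatrix")
  if (length(asym@x) && max(asym@x) > 0) {
    w <- which.max(asym@x)
    stop(sprintf("non-symmetric content: cell (%d, %d) differs from (%d, %d)",
                 asym@i[w] + 1L, asym@j[w] + 1L, asym@j[w] + 1L, asym@i[w] + 1L))
  }
  CoocMatrix(m, vocab = vocab, sourceTag = sourceTag)
}

#' Write embeddings in word2vec text or TSV format
#'
#' word2vec text: a header line \code{"<count> <dim>"} followed by one
#' \code{"CUI v1 ... vd"} row per concept.  TSV: one row per concept,
#' CUI first, no header.  Values are printed with 12 significant
#' digits, so a round-trip is lossless to ~1e-12 relative precision.
#'
#' @param emb a [ConceptEmbedding-class].
#' @param path output file path.
#' @param format \code{"word2vec"} (default) or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
writeEmbeddings <- function(emb, path, format = c("word2vec", "tsv")) {
  stopifnot(is(emb, "ConceptEmbedding"))
  format <- match.arg(format)
  V <- embeddingVectors(emb)
  sep <- if (format == "word2vec") " " else "\t"
  rows <- paste(rownames(V),
                apply(V, 1L, function(r)
                  paste(sprintf("%.12g", r), collapse = sep)),
                sep = sep)
  if (format == "word2vec") rows <- c(paste(nrow(V), ncol(V)), rows)
  writeLines(rows, path)
  invisible(path)
}

#' Read embeddings from word2vec text or TSV format
#'
#' @param path input file path.
#' @param format \code{"word2vec"} (default) or \code{"tsv"}.
#' @return a [ConceptEmbedding-class].
#' @export
readEmbeddings <- function(path, format = c("word2vec", "tsv")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "word2vec") {
    hdr <- scan(text = lines[1L], what = integer(), quiet = TRUE)
    if (length(hdr) != 2L) stop("malformed word2vec header")
    lines <- lines[-1L]
    if (length(lines) != hdr[1L])
      stop(sprintf("header/body mismatch: header promises %d rows, found %d",
                   hdr[1L], length(lines)))
  }
  sep <- if (format == "word2vec") " " else "\t"
  parts <- strsplit(lines, sep, fixed = TRUE)
  if (length(unique(lengths(parts))) != 1L)
    stop("ragged embedding rows")
  cuis <- vapply(parts, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(parts, function(p) as.numeric(p[-1L]),
           numeric(length(parts[[1L]]) - 1L)))
  vals <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = 1L)
  if (any(!is.finite(vals))) stop("non-numeric field in embedding file")
  if (format == "word2vec" && ncol(vals) != hdr[2L])
    stop("header/body mismatch: wrong embedding dimension")
  conceptEmbedding(vals, vocab = cuis)
}

#' Read a patient event stream from TSV
#'
#' Three tab-separated columns, no header: patient_id, cui, day.
#'
#' @param path input file path.
#' @return data.frame with columns \code{patient_id}, \code{cui},
#'   \code{day}.
#' @export
readEventStream <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "",
                           col.names = c("patient_id", "cui", "day"),
                           colClasses = c("character", "character", "integer"))
  tab
}

#' Write a patient event stream to TSV
#'
#' @param events data.frame with columns \code{patient_id},
#'   \code{cui}, \code{day}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeEventStream <- function(events, path) {
  utils::write.table(events[c("patient_id", "cui", "day")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a relationship set from TSV
#'
#' Columns: cui_x, cui_y, relation (no header).
#'
#' @param path input file path.
#' @return data.frame with columns \code{cui1}, \code{cui2},
#'   \code{relation}.
#' @export
readRelationships <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                    comment.char = "",
                    col.names = c("cui1", "cui2", "relation"),
                    colClasses = "character")
}

#' Write a relationship set to TSV
#' @param rels data.frame whose first two (or three) columns are
#'   cui_x, cui_y and optionally a relation label.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeRelationships <- function(rels, path) {
  if (ncol(rels) < 3L) rels$relation <- "related"
  utils::write.table(rels[, 1:3], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a semantic-type map from TSV
#'
#' Columns: cui, category (no header).
#'
#' @param path input file path.
#' @return named character vector, names = CUIs, values = category
#'   labels.
#' @export
readSemanticTypes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "", colClasses = "character")
  out <- tab[[2L]]
  names(out) <- tab[[1L]]
  out
}

#' Write a semantic-type map to TSV
#' @param typeMap named character vector (names = CUIs).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSemanticTypes <- function(typeMap, path) {
  utils::write.table(data.frame(names(typeMap), unname(typeMap)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read human concept-similarity scores from TSV
#'
#' Columns: cui_x, cui_y, mean human score (no header).
#'
#' @param path input file path.
#' @return data.frame with columns \code{cui1}, \code{cui2},
#'   \code{score}.
#' @export
readHumanScores <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                    comment.char = "",
                    col.names = c("cui1", "cui2", "score"),
                    colClasses = c("character", "character", "numeric"))
}
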