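#' Tokenize raw text for concept normalization
#'
#' Lowercases, treats every non-alphanumeric character except
#' intra-token hyphens as a separator, and keeps digits as tokens.
#' Tokens already matching the concept-ID pattern (C followed by
#' digits) pass through verbatim with case preserved, so
#' pre-normalized corpora can be re-ingested.
#'
#' @param raw a single character string.
#' @return character vector of tokens (possibly empty).
#' @keywords internal
.tokenize <- function(raw) {
  if (is.na(raw) || !nzchar(raw)) return(character())
  pieces <- strsplit(raw, "[^A-Za-z0-9-]+")[[1]]
  pieces <- gsub("^-+|-+$", "", pieces)        # hyphens only intra-token
  pieces <- pieces[nzchar(pieces)]
  if (!length(pieces)) return(character())
  ifelse(grepl(.CUI_PATTERN, pieces), pieces, tolower(pieces))
}

#' Normalize raw text against a concept dictionary
#'
#' Converts text to a token stream in which every maximal dictionary
#' phrase occurrence is replaced by its concept ID.  The scan is
#' left-to-right greedy longest-match: at each position the longest
#' matching surface phrase wins and the scan resumes after it.
#' Remaining words are lowercased with punctuation stripped; token
#' order is preserved.  Empty input yields an empty stream.
#'
#' @param raw a single character string of raw text.
#' @param dict a [ConceptDictionary-class].
#' @return character vector of tokens, each either a concept ID or a
#'   lowercase residual word.
#' @examples
#' d <- conceptDictionary(c("heart", "heart disease"),
#'                        c("C0018787", "C0018799"))
#' normalizeText("Heart disease runs in families.", d)
#' @export
normalizeText <- function(raw, dict) {
  stopifnot(is(dict, "ConceptDictionary"))
  toks <- .tokenize(raw)
  n <- length(toks)
  if (n == 0L) return(character())
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(dict@phrases)) assign(dict@phrases[i], dict@cuis[i], envir = lookup)
  maxLen <- dict@maxTokens
  out <- character(n)
  k <- 0L
  i <- 1L
  while (i <= n) {
    hit <- NULL
    for (len in seq.int(min(maxLen, n - i + 1L), 1L)) {
      key <- paste(toks[i:(i + len - 1L)], collapse = " ")
      if (exists(key, envir = lookup, inherits = FALSE)) {
        hit <- get(key, envir = lookup, inherits = FALSE)
        break
      }
    }
    k <- k + 1L
    if (is.null(hit)) {
      out[k] <- toks[i]
      i <- i + 1L
    } else {
      out[k] <- hit
      i <- i + len
    }
  }
  out[seq_len(k)]
}

#' Chunk a token stream into fixed-length windows
#'
#' Splits a token stream into consecutive non-overlapping windows of
#' length \code{L}; the final window may be shorter.  Concatenating the
#' windows reproduces the stream exactly.  Windows are chunked, not
#' sliding: each token belongs to exactly one window.
#'
#' @param stream character vector of tokens.
#' @param L window length in tokens; must be >= 2 (a window of one
#'   token can produce no co-occurrence pairs). Default 10.
#' @return list of character vectors, each of length at most \code{L};
#'   empty list for an empty stream.
#' @examples
#' chunkWindows(letters[1:25], L = 10)  # sizes 10, 10, 5
#' @export
chunkWindows <- function(stream, L = 10L) {
  L <- as.integer(L)
  if (is.na(L) || L < 2L) stop("invalid window length: L must be >= 2")
  if (!length(stream)) return(list())
  unname(split(stream, (seq_along(stream) - 1L) %/% L))
}

#' Read a concept dictionary from TSV
#'
#' Two tab-separated columns without header: surface phrase
#' (space-separated lowercase tokens) and concept ID.
#'
#' @param path file path.
#' @return a [ConceptDictionary-class].
#' @export
readConceptDictionary <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(tab) != 2L) stop("dictionary TSV must have exactly two columns")
  conceptDictionary(tab[[1]], tab[[2]])
}

#' Write a concept dictionary to TSV
#'
#' @param dict a [ConceptDictionary-class].
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeConceptDictionary <- function(dict, path) {
  stopifnot(is(dict, "ConceptDictionary"))
  utils::write.table(data.frame(dict@phrases, dict@cuis),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
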