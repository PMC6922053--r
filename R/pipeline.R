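.CONFIG_DEFAULTS <- list(
  window = 10L, spanDays = 30L, mode = "rolling", alpha = 0.75, k = 1,
  d = 50L, sigmaPower = 0.5, method = "svd", yMax = 100, alphaW = 0.75,
  gloveEpochs = 30L, gloveLearningRate = 0.05, benchN = 10000L,
  benchLevel = 0.05, seed = 1L)

#' Read and validate a pipeline run configuration
#'
#' The configuration is a flat key-value YAML file.  Path keys:
#' \code{corpus} (one-document-per-line text) and \code{dictionary}
#' (phrase TSV) and/or \code{events} (event TSV); optional
#' \code{relationships}, \code{types}, \code{human} for the benchmark
#' stage; \code{outDir} for artifacts.  Parameter keys (all optional,
#' with defaults): \code{window}, \code{spanDays}, \code{mode},
#' \code{alpha}, \code{k}, \code{d}, \code{sigmaPower}, \code{method}
#' (\code{svd}/\code{glove}/\code{pca}), \code{yMax}, \code{alphaW},
#' \code{gloveEpochs}, \code{gloveLearningRate}, \code{benchN},
#' \code{benchLevel}, \code{seed}.
#'
#' @param path YAML file path.
#' @return validated named list of class \code{"RunConfig"}.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(runConfig, cfg)
}

#' Construct a pipeline run configuration in code
#'
#' @param ... configuration entries, see [readRunConfig()].
#' @return validated named list of class \code{"RunConfig"}.
#' @export
runConfig <- function(...) {
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, list(...))
  if (is.null(cfg$outDir)) stop("config must name an outDir")
  hasText <- !is.null(cfg$corpus)
  if (hasText && is.null(cfg$dictionary))
    stop("a text corpus requires a dictionary")
  if (!hasText && is.null(cfg$events))
    stop("config must provide a corpus and dictionary, and/or events")
  for (key in c("corpus", "dictionary", "events", "relationships",
                "types", "human"))
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop(sprintf("config path not resolvable: %s = %s", key, cfg[[key]]))
  if (cfg$alpha <= 0 || cfg$alpha > 1) stop("config rejected: alpha must lie in (0, 1]")
  if (cfg$k < 1) stop("config rejected: k must be >= 1")
  if (cfg$window < 2) stop("config rejected: window must be >= 2")
  if (cfg$spanDays < 1) stop("config rejected: spanDays must be >= 1")
  if (cfg$d < 1) stop("config rejected: d must be >= 1")
  if (!cfg$method %in% c("svd", "glove", "pca"))
    stop("config rejected: method must be svd, glove or pca")
  if (!cfg$mode %in% c("rolling", "calendar"))
    stop("config rejected: mode must be rolling or calendar")
  if (cfg$benchLevel <= 0 || cfg$benchLevel >= 1)
    stop("config rejected: benchLevel must lie in (0, 1)")
  structure(cfg, class = "RunConfig")
}

.stageSeeds <- function(seed)
  list(glove = seed + 101L, bench = seed + 202L)

#' Run the full embedding pipeline from a configuration
#'
#' Executes normalize -> co-occurrence -> merge -> factorize
#' (SPPMI+SVD, GloVe or raw-SVD PCA) -> benchmark, in order, writing
#' every artifact under \code{outDir} together with a YAML manifest
#' recording all parameters and the per-stage seeds.  A rerun with an
#' identical configuration reproduces identical outputs (single
#' thread).  Any stage failure aborts with the stage name and cause.
#'
#' @param config a \code{"RunConfig"} from [runConfig()] or
#'   [readRunConfig()].
#' @return invisibly, a list with the merged [CoocMatrix-class], the
#'   [ConceptEmbedding-class], the benchmark results data.frame (or
#'   NULL) and the manifest list.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  seeds <- .stageSeeds(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  mats <- list()
  vocabText <- character()
  if (!is.null(config$corpus)) {
    dict <- stage("normalize", readConceptDictionary(config$dictionary))
    docs <- stage("normalize", readLines(config$corpus))
    streams <- stage("normalize", lapply(docs, normalizeText, dict = dict))
    windows <- stage("cooc", unlist(lapply(
      streams[lengths(streams) > 0L], chunkWindows, L = config$window),
      recursive = FALSE))
    vocabText <- sort(unique(dict@cuis))
    mats$text <- stage("cooc", textCooccurrence(windows, vocabText))
  }
  if (!is.null(config$events)) {
    events <- stage("cooc", readEventStream(config$events))
    vocabEv <- sort(unique(c(vocabText, events$cui)))
    mats$events <- stage("cooc", temporalCooccurrence(
      events, vocabEv, spanDays = config$spanDays, mode = config$mode))
  }
  master <- stage("merge", mergeCooccurrence(unname(mats)))
  writeCoocMatrix(master, file.path(config$outDir, "cooccurrence.mtx"))
  emb <- switch(config$method,
    svd = stage("factorize", {
      sp <- sppmiMatrix(master, alpha = config$alpha, k = config$k)
      Matrix::writeMM(methods::as(sppmiValues(sp), "TsparseMatrix"),
                      file.path(config$outDir, "sppmi.mtx"))
      svdEmbeddings(sp, d = config$d,
                    sigmaPower = config$sigmaPower)$embedding
    }),
    glove = stage("glove", trainGlove(
      master, d = config$d, yMax = config$yMax, alphaW = config$alphaW,
      epochs = config$gloveEpochs,
      learningRate = config$gloveLearningRate,
      seed = seeds$glove)$embedding),
    pca = stage("factorize", pcaEmbeddings(master, d = config$d)))
  writeEmbeddings(emb, file.path(config$outDir, "embeddings.w2v"),
                  format = "word2vec")
  writeEmbeddings(emb, file.path(config$outDir, "embeddings.tsv"),
                  format = "tsv")
  bench <- NULL
  if (!is.null(config$relationships) && !is.null(config$types)) {
    bench <- stage("bench", {
      rels <- readRelationships(config$relationships)
      types <- readSemanticTypes(config$types)
      relationshipPower(emb, rels, types, n = config$benchN,
                        level = config$benchLevel, seed = seeds$bench)
    })
  }
  if (!is.null(config$human)) {
    bench <- rbind(bench, stage("bench",
      humanSimilarityCorrelation(emb, readHumanScores(config$human))))
  }
  if (!is.null(bench))
    utils::write.table(bench, file.path(config$outDir, "benchmark.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c(unclass(config), list(stageSeeds = seeds,
                                      vocabularySize = length(vocabulary(master)),
                                      artifacts = list.files(config$outDir)))
  yaml::write_yaml(manifest, file.path(config$outDir, "manifest.yaml"))
  invisible(list(cooccurrence = master, embedding = emb,
                 benchmark = bench, manifest = manifest))
}
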