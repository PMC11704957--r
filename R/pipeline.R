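# End-to-end orchestration: train on labelled sequences, filter and
# de-duplicate candidates, embed, predict, rank, and write outputs.

.configDefaults <- list(
    trainFasta = NULL, trainLabels = NULL, candidatesFasta = NULL,
    hitsM8 = NULL, queryId = NULL, outputDir = NULL,
    measureName = "fitness", transform = "identity",
    embedderDim = 128L, embedderLayers = 3L, embedderSeed = 1L,
    layer = "auto", family = "rfr", grid = NULL, cvFolds = 5L,
    maxEvalue = 1e-3, minBidirCov = 0.9, redundancyThreshold = 0.9,
    trainFraction = 0.8, seed = 1L)

.configError <- function(msg) {
    stop(errorCondition(msg, class = c("embedrank_config_error", "error")))
}

#' Assemble and validate a pipeline configuration
#'
#' @param trainFasta labelled training FASTA (header dialect of
#'   [readFitnessFasta()], unless `trainLabels` is given).
#' @param candidatesFasta FASTA of candidate homologs to rank.
#' @param outputDir directory for all outputs (created if needed).
#' @param trainLabels optional TSV sidecar of `id`, `value`.
#' @param hitsM8 optional precomputed homology-search result (m8) used to
#'   filter candidates before ranking.
#' @param queryId optional candidate/query id used for the
#'   identity-to-query column.
#' @param measureName,transform measure metadata, see [FitnessDataset()].
#' @param embedderDim,embedderLayers,embedderSeed surrogate embedder
#'   settings, see [SurrogateEmbedder()].
#' @param layer 0-based layer, or `"auto"` to pick by cross-validation
#'   ([selectBestLayer()]).
#' @param family,grid,cvFolds regressor settings, see [regressorSpec()].
#' @param maxEvalue,minBidirCov hit-filter thresholds, see [filterHits()].
#' @param redundancyThreshold identity threshold for
#'   [redundancyFilter()], or `NA` to skip de-duplication.
#' @param trainFraction train/test split fraction, see [splitDataset()].
#' @param seed master seed recorded in all outputs.
#' @return a validated config list of class `embedrank_config`.
#' @export
pipelineConfig <- function(trainFasta, candidatesFasta, outputDir,
                           trainLabels = NULL, hitsM8 = NULL,
                           queryId = NULL, measureName = "fitness",
                           transform = "identity", embedderDim = 128L,
                           embedderLayers = 3L, embedderSeed = 1L,
                           layer = "auto", family = "rfr", grid = NULL,
                           cvFolds = 5L, maxEvalue = 1e-3,
                           minBidirCov = 0.9, redundancyThreshold = 0.9,
                           trainFraction = 0.8, seed = 1L) {
    config <- mget(names(formals()))
    for (p in c("trainFasta", "candidatesFasta")) {
        if (!is.character(config[[p]]) || !file.exists(config[[p]]))
            .configError(sprintf("%s: file not found", p))
    }
    for (p in c("trainLabels", "hitsM8")) {
        if (!is.null(config[[p]]) && !file.exists(config[[p]]))
            .configError(sprintf("%s: file not found", p))
    }
    if (!config$transform %in% c("identity", "log10"))
        .configError("transform must be 'identity' or 'log10'")
    if (!config$family %in% c("knn", "svr", "rfr"))
        .configError("family must be one of knn, svr, rfr")
    if (!identical(config$layer, "auto")) {
        config$layer <- suppressWarnings(as.integer(config$layer))
        if (is.na(config$layer) || config$layer < 0L ||
            config$layer >= config$embedderLayers)
            .configError("layer must be 'auto' or a valid 0-based index")
    }
    class(config) <- "embedrank_config"
    config
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipelineConfig()]; unknown keys are an
#' error. Relative paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @param overrides named list of values taking precedence over the file.
#' @return a validated config, as from [pipelineConfig()].
#' @export
readPipelineConfig <- function(path, overrides = list()) {
    if (!file.exists(path)) .configError(sprintf("config not found: %s", path))
    vals <- yaml::read_yaml(path)
    unknown <- setdiff(names(vals), names(.configDefaults))
    if (length(unknown))
        .configError(sprintf("unknown config key '%s'", unknown[1L]))
    vals[names(overrides)] <- overrides
    base <- dirname(normalizePath(path))
    for (p in c("trainFasta", "trainLabels", "candidatesFasta", "hitsM8",
                "outputDir")) {
        if (!is.null(vals[[p]]) && !grepl("^/", vals[[p]]))
            vals[[p]] <- file.path(base, vals[[p]])
    }
    do.call(pipelineConfig, vals)
}

#' Run the full ranking pipeline
#'
#' Stages: read labelled training data; choose the embedding layer (fixed
#' or by cross-validation); split train/test and report both evaluation
#' statistics; read candidates; optionally filter them by the m8 homology
#' hits (E-value and bidirectional coverage) and remove redundancy by
#' greedy identity clustering; embed, predict and rank the survivors; and
#' write `ranked.tsv`, `evaluation.tsv`, `exclusions.tsv` and a
#' `manifest.json` recording the seed, chosen layer, chosen
#' hyperparameters and the candidate counts after each stage.
#'
#' @param config a config from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @return invisibly, a list with the manifest, the ranked table and the
#'   trained model.
#' @export
runPipeline <- function(config) {
    if (!inherits(config, "embedrank_config"))
        .configError("config must come from pipelineConfig()")
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(seed = config$seed, family = config$family,
                     transform = config$transform,
                     counts = list(), stage = "start")
    writeManifest <- function() {
        jsonlite::write_json(manifest,
                             file.path(config$outputDir, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    stageTry <- function(stage, expr) {
        manifest$stage <<- stage
        tryCatch(expr, error = function(e) {
            writeManifest()
            stop(errorCondition(
                sprintf("stage '%s': %s", stage, conditionMessage(e)),
                class = c("embedrank_data_error", "error")))
        })
    }

    train <- stageTry("read-training-data",
        readFitnessFasta(config$trainFasta, labels = config$trainLabels,
                         measureName = config$measureName,
                         transform = config$transform))
    manifest$counts$training_sequences <- length(train)

    embedder <- SurrogateEmbedder(dim = config$embedderDim,
                                  nLayers = config$embedderLayers,
                                  seed = config$embedderSeed)
    spec <- regressorSpec(config$family, grid = config$grid,
                          cvFolds = config$cvFolds, seed = config$seed)

    layer <- stageTry("select-layer", {
        if (identical(config$layer, "auto")) {
            sel <- selectBestLayer(train, embedder, spec,
                                   seed = config$seed)
            manifest$per_layer_scores <- round(sel$perLayerScores, 6)
            sel$bestLayer
        } else config$layer
    })
    manifest$layer <- layer

    evalReport <- NULL
    model <- stageTry("train-model", {
        parts <- splitDataset(train, trainFraction = config$trainFraction,
                              seed = config$seed)
        embTrain <- embedDataset(parts$train, embedder, layer)
        m <- trainRanker(parts$train, embTrain, spec)
        embTest <- embedDataset(parts$test, embedder, layer)
        evalReport <- evaluateModel(m, embTest, parts$test)
        # refit on everything for ranking
        embAll <- embedDataset(train, embedder, layer)
        trainRanker(train, embAll, spec)
    })
    manifest$hyperparameters <- model@hyperparameters
    manifest$evaluation <- list(spearman = evalReport@spearman,
                                r_squared = evalReport@rsq,
                                n_test = evalReport@nTest)
    utils::write.table(
        data.frame(metric = c("spearman_rho", "r_squared", "n_test"),
                   value = c(evalReport@spearman, evalReport@rsq,
                             evalReport@nTest)),
        file.path(config$outputDir, "evaluation.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)

    candidates <- stageTry("read-candidates",
                           readFasta(config$candidatesFasta))
    manifest$counts$candidates_input <- length(candidates)
    excluded <- data.frame(id = character(), stage = character(),
                           stringsAsFactors = FALSE)

    if (!is.null(config$hitsM8)) {
        candidates <- stageTry("filter-hits", {
            hits <- readHitsM8(config$hitsM8, targetSeqs = candidates)
            kept <- filterHits(hits, maxEvalue = config$maxEvalue,
                               minBidirCov = config$minBidirCov)
            keepIds <- intersect(names(candidates),
                                 unique(kept$target_id))
            dropped <- setdiff(names(candidates), keepIds)
            excluded <- rbind(excluded,
                               data.frame(id = dropped,
                                          stage = "evalue_coverage"))
            candidates[keepIds]
        })
    }
    manifest$counts$candidates_after_hit_filter <- length(candidates)

    if (!is.na(config$redundancyThreshold)) {
        candidates <- stageTry("dedupe", {
            red <- redundancyFilter(candidates,
                                    threshold = config$redundancyThreshold)
            dropped <- setdiff(names(candidates),
                               names(red$representatives))
            excluded <- rbind(excluded,
                               data.frame(id = dropped,
                                          stage = "redundancy"))
            red$representatives
        })
    }
    manifest$counts$candidates_after_redundancy <- length(candidates)

    ranked <- stageTry("rank", {
        if (length(candidates) == 0L)
            stop("no sequences", call. = FALSE)
        embCand <- embedDataset(candidates, embedder, layer)
        r <- rankCandidates(model, embCand, candidates)
        if (!is.null(config$queryId) &&
            config$queryId %in% names(candidates)) {
            q <- as.character(candidates[[config$queryId]])
            r$identity_to_query <- vapply(
                r$id,
                function(id) pairwiseIdentity(
                    as.character(candidates[[id]]), q),
                numeric(1L))
        }
        r
    })
    manifest$counts$ranked <- nrow(ranked)

    writeRankedTable(ranked, file.path(config$outputDir, "ranked.tsv"))
    utils::write.table(excluded,
                       file.path(config$outputDir, "exclusions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stage <- "done"
    writeManifest()
    invisible(list(manifest = manifest, ranked = ranked, model = model))
}
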