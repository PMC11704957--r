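# Pipeline fixture builders shared by the pipeline and acceptance tests.

makePipelineFixtures <- function(seed = 11, nTrain = 60, nCand = 30) {
    dirBase <- tempfile("pipeline")
    dir.create(dirBase)
    ls <- generateLandscape(seed = seed, n = nTrain)
    trainFa <- file.path(dirBase, "train.fasta")
    writeFitnessFasta(landscapeDataset(ls), trainFa)

    panel <- sampleVariants(ls, n = nCand, seed = seed + 1)
    candFa <- file.path(dirBase, "candidates.fasta")
    writeFasta(landscapeDataset(panel), candFa)

    # m8 hits for the candidates: first third fails E-value, second third
    # fails coverage, rest pass
    ids <- names(landscapeDataset(panel))
    L <- nchar(panel@reference)
    rows <- vapply(seq_along(ids), function(i) {
        third <- ceiling(length(ids) / 3)
        if (i <= third) { ev <- 0.5; qe <- L; te <- L }
        else if (i <= 2 * third) { ev <- 1e-20; qe <- L; te <- floor(0.8 * L) }
        else { ev <- 1e-20; qe <- L; te <- L }
        paste(c("query", ids[i], 95, L, 3, 0, 1, qe, 1, te,
                sprintf("%.3e", ev), 200, L, L), collapse = "\t")
    }, "")
    hitsFile <- file.path(dirBase, "hits.m8")
    writeLines(rows, hitsFile)
    list(dir = dirBase, train = trainFa, cand = candFa, hits = hitsFile,
         ids = ids, nPassing = length(ids) - 2 * ceiling(length(ids) / 3))
}

pipelineTestConfig <- function(fx, out, seed = 2) {
    pipelineConfig(trainFasta = fx$train, candidatesFasta = fx$cand,
                   outputDir = out, hitsM8 = fx$hits, layer = 1,
                   family = "knn",
                   grid = list(k = 5L, distance = "euclidean"),
                   transform = "identity", redundancyThreshold = NA,
                   seed = seed)
}

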