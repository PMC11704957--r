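# Surrogate embedder backend, mean pooling, dataset embedding and
# per-layer selection.

#' Construct the deterministic surrogate embedder
#'
#' See [SurrogateEmbedder-class] for the construction. Defaults (dim 128,
#' 3 layers) are small enough for desk-scale testing while honouring the
#' multi-layer contract; layer 0 is the noisy layer.
#'
#' @param dim per-residue representation width (>= 8).
#' @param nLayers number of addressable layers (0-based indexing).
#' @param seed integer master seed for all projections.
#' @param residueGain,siteGain,neighborGain,layerZeroNoiseSd construction
#'   scales; see the class documentation.
#' @return a [SurrogateEmbedder-class].
#' @examples
#' emb <- SurrogateEmbedder(dim = 32, seed = 7)
#' residueRepresentations(emb, "MKV", layer = 1)[, 1:4]
#' @export
SurrogateEmbedder <- function(dim = 128L, nLayers = 3L, seed = 1L,
                              residueGain = 0.05, siteGain = 4,
                              neighborGain = 0.05, layerZeroNoiseSd = 1) {
    new("SurrogateEmbedder", name = "surrogate", dim = as.integer(dim),
        nLayers = as.integer(nLayers), deterministic = TRUE,
        seed = as.integer(seed), residueGain = residueGain,
        siteGain = siteGain, neighborGain = neighborGain,
        layerZeroNoiseSd = layerZeroNoiseSd)
}

# Layer-specific fixed projections, derived deterministically from
# (seed, layer, dim): dense residue and neighbour channels, a dense
# physicochemical channel, and an injective position -> coordinate map
# with per-coordinate signs for the hydropathy channel.
.surrogateProjections <- function(dim, layer, seed, residueGain,
                                  neighborGain) {
    .withSeed(.deriveSeed("surrogate-proj", seed, layer, dim), {
        list(
            Wres  = matrix(stats::rnorm(21L * dim, 0, residueGain), 21L, dim),
            Wprev = matrix(stats::rnorm(21L * dim, 0, neighborGain), 21L, dim),
            Wnext = matrix(stats::rnorm(21L * dim, 0, neighborGain), 21L, dim),
            Wphys = matrix(stats::rnorm(5L * dim, 0, residueGain), 5L, dim),
            perm  = sample.int(dim),
            sgn   = sample(c(-1, 1), dim, replace = TRUE))
    })
}

#' Surrogate per-residue representations
#'
#' Deterministic stand-in for a protein language model backend. Row `i` is a
#' function of the residue at `i`, its two neighbours, the position `i`, the
#' layer and the seed: a dense projection of the residue one-hot and its
#' five physicochemical scalars, a small mixing of the neighbour one-hots,
#' and a position-addressed channel writing the residue's standardized
#' hydropathy onto one layer-specific coordinate. Layer 0 additionally adds
#' Gaussian noise seeded by the sequence content, so that higher layers are
#' strictly more informative by construction.
#'
#' @param sequence amino-acid string (20 standard residues plus X).
#' @param layer 0-based layer index.
#' @param dim representation width (>= 8).
#' @param seed integer seed.
#' @param residueGain,siteGain,neighborGain,layerZeroNoiseSd construction
#'   scales, as in [SurrogateEmbedder()].
#' @return L x dim numeric matrix, one row per residue.
#' @export
surrogateResidues <- function(sequence, layer, dim = 128L, seed = 1L,
                              residueGain = 0.05, siteGain = 4,
                              neighborGain = 0.05, layerZeroNoiseSd = 1) {
    seq <- .asSequenceString(sequence)
    .checkResidues(seq)
    dim <- as.integer(dim)
    if (dim < 8L) stop("dim must be >= 8", call. = FALSE)
    if (layer < 0L) stop("layer must be >= 0", call. = FALSE)
    ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
    L <- length(ch)
    ri <- match(ch, .AA21)
    pr <- .surrogateProjections(dim, layer, seed, residueGain, neighborGain)
    H <- pr$Wres[ri, , drop = FALSE] +
        .physTable[ri, , drop = FALSE] %*% pr$Wphys
    # neighbour mixing: previous and next residue identities
    if (L > 1L) {
        H[-1L, ] <- H[-1L, ] + pr$Wprev[ri[-L], , drop = FALSE]
        H[-L, ] <- H[-L, ] + pr$Wnext[ri[-1L], , drop = FALSE]
    }
    # position-addressed hydropathy channel (injective for L <= dim)
    d <- pr$perm[((seq_len(L) - 1L) %% dim) + 1L]
    H[cbind(seq_len(L), d)] <- H[cbind(seq_len(L), d)] +
        siteGain * pr$sgn[d] * .physTable[ri, "hydropathy"]
    if (layer == 0L && layerZeroNoiseSd > 0) {
        noiseSeed <- .deriveSeed("surrogate-noise", seed, .strHash(seq))
        H <- H + .withSeed(noiseSeed,
            matrix(stats::rnorm(L * dim, 0, layerZeroNoiseSd), L, dim))
    }
    rownames(H) <- NULL
    H
}

#' @describeIn SurrogateEmbedder-class the embedder-contract method; see
#'   [surrogateResidues()].
#' @param embedder a `SurrogateEmbedder`.
#' @param sequence amino-acid string.
#' @param layer 0-based layer index.
#' @export
setMethod("residueRepresentations", "SurrogateEmbedder",
    function(embedder, sequence, layer) {
        layer <- as.integer(layer)
        if (layer < 0L || layer >= embedder@nLayers)
            stop(sprintf("layer %d out of range [0, %d)", layer,
                         embedder@nLayers), call. = FALSE)
        surrogateResidues(sequence, layer, dim = embedder@dim,
                          seed = embedder@seed,
                          residueGain = embedder@residueGain,
                          siteGain = embedder@siteGain,
                          neighborGain = embedder@neighborGain,
                          layerZeroNoiseSd = embedder@layerZeroNoiseSd)
    })

#' Mean-pool a residue representation matrix
#'
#' Averages all residue representations across the whole protein: element
#' `j` of the result is the arithmetic mean of column `j` over the L residue
#' rows. Special (begin/end) tokens are never part of the input by the
#' embedder contract.
#'
#' @param residues L x dim numeric matrix, L >= 1.
#' @return numeric vector of length `dim`.
#' @examples
#' poolMean(rbind(c(0, 0), c(2, 4)))  # c(1, 2)
#' @export
poolMean <- function(residues) {
    if (!is.matrix(residues) || nrow(residues) < 1L)
        stop("residue matrix must have at least one row", call. = FALSE)
    if (any(!is.finite(residues)))
        stop("residue matrix must be finite", call. = FALSE)
    colMeans(residues)
}

#' Embed a sequence collection at one layer
#'
#' Computes one mean-pooled vector per record, order preserved. Each row
#' depends only on its own sequence, so embedding a singleton equals the
#' corresponding row of a batch, and deterministic backends give
#' bit-identical output across calls.
#'
#' @param x named `AAStringSet`, named character vector, or
#'   [FitnessDataset-class].
#' @param embedder an [Embedder-class] backend.
#' @param layer 0-based layer index.
#' @return an [EmbeddingMatrix-class] with one row per input sequence.
#' @examples
#' emb <- SurrogateEmbedder(dim = 32)
#' embedDataset(c(a = "MKV", b = "MKVW"), emb, layer = 1)
#' @export
embedDataset <- function(x, embedder, layer) {
    if (is(x, "FitnessDataset")) x <- sequenceSet(x)
    if (is.character(x)) x <- Biostrings::AAStringSet(toupper(x))
    ids <- names(x)
    if (is.null(ids) || any(!nzchar(ids)))
        stop("sequences must be named", call. = FALSE)
    layer <- as.integer(layer)
    if (layer < 0L || layer >= embedderLayers(embedder))
        stop(sprintf("layer %d out of range [0, %d)", layer,
                     embedderLayers(embedder)), call. = FALSE)
    seqs <- as.character(x)
    X <- matrix(NA_real_, length(seqs), embedderDim(embedder),
                dimnames = list(ids, NULL))
    for (k in seq_along(seqs)) {
        H <- tryCatch(residueRepresentations(embedder, seqs[k], layer),
                      error = function(e) {
                          stop(sprintf("embedding failed for '%s': %s",
                                       ids[k], conditionMessage(e)),
                               call. = FALSE)
                      })
        X[k, ] <- poolMean(H)
    }
    new("EmbeddingMatrix", X = X, layer = layer)
}

#' Select the most predictive embedding layer by cross-validation
#'
#' For each addressable layer of the embedder, the labelled dataset is
#' embedded, a fixed k-fold partition (seeded, keyed to sorted sequence ids
#' so it is invariant to record order) is evaluated by training the given
#' regressor specification on the in-fold data and scoring the out-of-fold
#' Spearman correlation, and the layer with the highest mean out-of-fold
#' correlation wins; ties go to the lowest layer index.
#'
#' @param dataset a [FitnessDataset-class].
#' @param embedder an [Embedder-class].
#' @param spec a [RegressorSpec-class] used within each fold.
#' @param folds number of folds (default 5).
#' @param seed integer seed for the fold partition.
#' @return list with `bestLayer` (0-based integer) and `perLayerScores`
#'   (numeric vector of length `embedderLayers(embedder)`).
#' @export
selectBestLayer <- function(dataset, embedder, spec, folds = 5L, seed = 1L) {
    n <- length(dataset)
    folds <- as.integer(folds)
    if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
    if (n < folds)
        stop(sprintf("need at least %d sequences for %d-fold CV", folds,
                     folds), call. = FALSE)
    ids <- sort(names(dataset))
    shuffled <- .withSeed(.deriveSeed("layer-folds", seed), sample(ids))
    foldOf <- stats::setNames(rep_len(seq_len(folds), n), shuffled)
    y <- trainingValues(dataset)
    nl <- embedderLayers(embedder)
    scores <- numeric(nl)
    for (layer in seq_len(nl) - 1L) {
        emb <- embedDataset(dataset, embedder, layer)
        X <- embMatrix(emb)
        rho <- rep(NA_real_, folds)
        for (f in seq_len(folds)) {
            testIds <- names(foldOf)[foldOf == f]
            trainIds <- setdiff(names(dataset), testIds)
            model <- gridSearchTrain(X[trainIds, , drop = FALSE],
                                     y[trainIds], spec,
                                     layer = layer,
                                     transform = valueTransform(dataset))
            pred <- predictFitness(model, X[testIds, , drop = FALSE])
            rho[f] <- tryCatch(spearmanRho(pred, y[testIds]),
                               error = function(e) NA_real_)
        }
        scores[layer + 1L] <- mean(rho, na.rm = TRUE)
    }
    list(bestLayer = which.max(scores) - 1L, perLayerScores = scores)
}
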