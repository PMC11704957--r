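# Accessors, show and subsetting methods for the core classes.

#' @describeIn FitnessDataset-class the underlying `AAStringSet`.
#' @param x,object a `FitnessDataset`.
#' @export
setMethod("sequenceSet", "FitnessDataset", function(x) x@sequences)

#' @describeIn FitnessDataset-class raw (untransformed) measurement values,
#'   named by sequence id.
#' @export
setMethod("fitnessValues", "FitnessDataset", function(x) {
    stats::setNames(x@values, names(x@sequences))
})

#' @describeIn FitnessDataset-class values with the dataset's transform
#'   applied; this is what regressors are trained on.
#' @export
setMethod("trainingValues", "FitnessDataset", function(x) {
    v <- fitnessValues(x)
    if (x@transform == "log10") log10(v) else v
})

#' @describeIn FitnessDataset-class name of the experimental measure.
#' @export
setMethod("measureName", "FitnessDataset", function(x) x@measureName)

#' @describeIn FitnessDataset-class the value transform
#'   (`"identity"` or `"log10"`).
#' @export
setMethod("valueTransform", "FitnessDataset", function(x) x@transform)

#' @describeIn FitnessDataset-class number of sequences.
#' @export
setMethod("length", "FitnessDataset", function(x) length(x@sequences))

#' @describeIn FitnessDataset-class sequence ids.
#' @export
setMethod("names", "FitnessDataset", function(x) names(x@sequences))

#' @describeIn FitnessDataset-class subset by index, logical, or id.
#' @param i index, logical or character vector of ids.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "FitnessDataset", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) {
        miss <- setdiff(i, names(x@sequences))
        if (length(miss))
            stop(sprintf("unknown sequence id '%s'", miss[1L]), call. = FALSE)
        i <- match(i, names(x@sequences))
    }
    new("FitnessDataset", sequences = x@sequences[i], values = x@values[i],
        measureName = x@measureName, transform = x@transform)
})

setMethod("show", "FitnessDataset", function(object) {
    cat(sprintf("FitnessDataset with %d sequences\n", length(object)))
    cat(sprintf("  measure: %s (transform: %s)\n",
                object@measureName, object@transform))
    cat(sprintf("  lengths: %d-%d aa; values: [%.4g, %.4g]\n",
                min(Biostrings::width(object@sequences)),
                max(Biostrings::width(object@sequences)),
                min(object@values), max(object@values)))
})

#' @describeIn EmbeddingMatrix-class the pooled n x dim matrix.
#' @param x,object an `EmbeddingMatrix`.
#' @export
setMethod("embMatrix", "EmbeddingMatrix", function(x) x@X)

#' @describeIn EmbeddingMatrix-class the 0-based source layer.
#' @export
setMethod("embLayer", "EmbeddingMatrix", function(x) x@layer)

#' @describeIn EmbeddingMatrix-class sequence ids (row names).
#' @export
setMethod("names", "EmbeddingMatrix", function(x) rownames(x@X))

#' @describeIn EmbeddingMatrix-class number of embedded sequences.
#' @export
setMethod("length", "EmbeddingMatrix", function(x) nrow(x@X))

#' @describeIn EmbeddingMatrix-class subset rows by index or id.
#' @param i index, logical or character vector of ids.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "EmbeddingMatrix", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) {
        miss <- setdiff(i, rownames(x@X))
        if (length(miss))
            stop(sprintf("no embedding for id '%s'", miss[1L]), call. = FALSE)
    }
    new("EmbeddingMatrix", X = x@X[i, , drop = FALSE], layer = x@layer)
})

setMethod("show", "EmbeddingMatrix", function(object) {
    cat(sprintf("EmbeddingMatrix: %d sequences x %d dims (layer %d)\n",
                nrow(object@X), ncol(object@X), object@layer))
})

#' @describeIn Embedder-class backend name.
#' @param x,object an `Embedder`.
#' @export
setMethod("embedderName", "Embedder", function(x) x@name)

#' @describeIn Embedder-class per-residue representation width.
#' @export
setMethod("embedderDim", "Embedder", function(x) x@dim)

#' @describeIn Embedder-class number of addressable layers (0-based
#'   indexing, so valid layers are `0:(embedderLayers(x) - 1)`).
#' @export
setMethod("embedderLayers", "Embedder", function(x) x@nLayers)

#' @describeIn Embedder-class whether repeated calls are bit-identical.
#' @export
setMethod("isDeterministic", "Embedder", function(x) x@deterministic)

setMethod("show", "Embedder", function(object) {
    cat(sprintf("%s embedder: dim %d, %d layers, %s\n",
                object@name, object@dim, object@nLayers,
                if (object@deterministic) "deterministic" else "stochastic"))
})

setMethod("show", "RegressorSpec", function(object) {
    combos <- prod(vapply(object@grid, length, 1L))
    cat(sprintf("RegressorSpec: %s, %d grid combinations, %d-fold CV, seed %d\n",
                object@family, combos, object@cvFolds, object@seed))
})

setMethod("show", "TrainedRanker", function(object) {
    hp <- paste(names(object@hyperparameters),
                vapply(object@hyperparameters, format, ""),
                sep = "=", collapse = ", ")
    cat(sprintf("TrainedRanker: %s (%s)\n", object@family, hp))
    cat(sprintf("  trained on %d sequences, layer %s, transform %s\n",
                length(object@trainIds),
                ifelse(is.na(object@layer), "<none>", object@layer),
                object@transform))
})

setMethod("show", "EvaluationReport", function(object) {
    cat(sprintf("Evaluation on %d test sequences: Spearman rho = %.4f, R2 = %.4f\n",
                object@nTest, object@spearman, object@rsq))
})

setMethod("show", "SubsampleCurve", function(object) {
    cat(sprintf("SubsampleCurve: %d sizes (%d-%d), %d replicates each\n",
                length(object@sizes), min(object@sizes), max(object@sizes),
                object@reps))
})

#' @describeIn SyntheticLandscape-class the labelled dataset.
#' @param x,object a `SyntheticLandscape`.
#' @export
setMethod("landscapeDataset", "SyntheticLandscape", function(x) x@dataset)

#' @describeIn SyntheticLandscape-class noise-free fitness per variant,
#'   named by variant id.
#' @export
setMethod("trueFitness", "SyntheticLandscape", function(x) {
    stats::setNames(x@trueFitness, names(x@dataset))
})

setMethod("show", "SyntheticLandscape", function(object) {
    cat(sprintf(
        "SyntheticLandscape: %d variants of a %d-aa reference, %d functional sites\n",
        length(object@dataset), nchar(object@reference),
        length(object@sites)))
    cat(sprintf("  noise sd %.3g, seed %d\n", object@noiseSd, object@seed))
})
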