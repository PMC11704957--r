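#' @importFrom Biostrings AAStringSet readBStringSet writeXStringSet
#'   pairwiseAlignment alignedPattern alignedSubject width
#' @importFrom stats cor predict qt rnorm runif sd var
#' @importFrom utils read.delim write.table
NULL

#' Labelled protein sequence set
#'
#' Pairs an `AAStringSet` of protein sequences with one real-valued
#' experimental measure per sequence (for example catalytic efficiency
#' kcat/KM in 1/(uM s), a brightness, or a melting temperature), plus the
#' transform applied to the values before regression.
#'
#' @slot sequences `AAStringSet`, uniquely named; residues restricted to the
#'   20 standard amino acids plus `X`.
#' @slot values numeric, one finite raw value per sequence.
#' @slot measureName single string naming the measure.
#' @slot transform `"identity"` or `"log10"`; with `"log10"` all raw values
#'   must be positive. The transform is applied lazily by
#'   [trainingValues()], never stored back into `values`.
#'
#' @seealso [FitnessDataset()], [readFitnessFasta()], [splitDataset()]
#' @export
setClass("FitnessDataset",
    slots = c(sequences = "AAStringSet",
              values = "numeric",
              measureName = "character",
              transform = "character"))

setValidity("FitnessDataset", function(object) {
    ids <- names(object@sequences)
    if (length(object@sequences) < 1L)
        return("dataset must contain at least one sequence")
    if (is.null(ids) || any(!nzchar(ids)))
        return("all sequences must have non-empty ids")
    if (anyDuplicated(ids))
        return(sprintf("duplicate sequence id '%s'", ids[duplicated(ids)][1L]))
    if (length(object@values) != length(object@sequences))
        return("length(values) must equal the number of sequences")
    if (any(!is.finite(object@values)))
        return("all values must be finite")
    if (any(Biostrings::width(object@sequences) < 1L))
        return("all sequences must have length >= 1")
    if (length(object@measureName) != 1L)
        return("measureName must be a single string")
    if (length(object@transform) != 1L ||
        !object@transform %in% c("identity", "log10"))
        return("transform must be 'identity' or 'log10'")
    if (object@transform == "log10" && any(object@values <= 0))
        return("log10 transform requires all raw values > 0")
    TRUE
})

#' Construct a FitnessDataset
#'
#' @param sequences named `AAStringSet` or named character vector of
#'   amino-acid strings.
#' @param values numeric vector of raw measurements, one per sequence.
#' @param measureName name of the measure (free text).
#' @param transform `"identity"` or `"log10"` (applied at training time).
#' @return a [FitnessDataset-class].
#' @examples
#' d <- FitnessDataset(c(wt = "MKV", mut = "MRV"), c(4.2, 1.1),
#'                     measureName = "kcat/KM", transform = "log10")
#' trainingValues(d)
#' @export
FitnessDataset <- function(sequences, values, measureName = "fitness",
                           transform = c("identity", "log10")) {
    transform <- match.arg(transform)
    if (is.character(sequences))
        sequences <- Biostrings::AAStringSet(toupper(sequences))
    new("FitnessDataset", sequences = sequences, values = as.numeric(values),
        measureName = measureName, transform = transform)
}

#' Pooled sequence embeddings at one layer
#'
#' An n x dim numeric matrix of mean-pooled per-sequence representations,
#' with sequence ids as row names and the 0-based source layer recorded.
#'
#' @slot X numeric matrix; row names are unique sequence ids, entries finite.
#' @slot layer 0-based layer the representations were taken from.
#' @export
setClass("EmbeddingMatrix",
    slots = c(X = "matrix", layer = "integer"))

setValidity("EmbeddingMatrix", function(object) {
    if (!is.numeric(object@X)) return("X must be numeric")
    ids <- rownames(object@X)
    if (is.null(ids) || any(!nzchar(ids)))
        return("X must have non-empty row names (sequence ids)")
    if (anyDuplicated(ids))
        return("duplicate sequence ids in embedding rows")
    if (any(!is.finite(object@X)))
        return("all embedding entries must be finite")
    if (length(object@layer) != 1L || is.na(object@layer) || object@layer < 0L)
        return("layer must be a single non-negative integer")
    TRUE
})

#' Embedder backends
#'
#' `Embedder` is the virtual contract every backend conforms to: it exposes a
#' name, a per-residue representation width, a number of addressable layers
#' (0-based), and whether it is deterministic. The packaged concrete backend
#' is [SurrogateEmbedder-class]; an adapter for a pretrained protein language
#' model can implement the same four accessors plus
#' [residueRepresentations()].
#'
#' @aliases Embedder
#' @export
setClass("Embedder",
    representation("VIRTUAL",
                   name = "character",
                   dim = "integer",
                   nLayers = "integer",
                   deterministic = "logical"))

setValidity("Embedder", function(object) {
    if (object@dim < 1L) return("dim must be >= 1")
    if (object@nLayers < 1L) return("nLayers must be >= 1")
    TRUE
})

#' Deterministic surrogate embedder
#'
#' A self-contained, seed-deterministic stand-in for a protein language
#' model, used for testing and simulation. Each residue row combines (i) a
#' small dense projection of the residue identity and its physicochemical
#' profile, (ii) a small mixing of the two neighbouring residues, and (iii) a
#' position-addressed channel that writes the residue's standardized
#' hydropathy onto one layer-specific coordinate (the analogue of a
#' transformer's positional encoding). Layer 0 additionally receives
#' sequence-seeded Gaussian noise, so higher layers are strictly more
#' informative by construction.
#'
#' @slot seed integer master seed for all projections.
#' @slot residueGain scale of the dense residue-identity channel.
#' @slot siteGain scale of the position-addressed hydropathy channel.
#' @slot neighborGain scale of the neighbour-mixing channel.
#' @slot layerZeroNoiseSd sd of the noise injected into layer 0.
#' @seealso [SurrogateEmbedder()], [surrogateResidues()]
#' @export
setClass("SurrogateEmbedder",
    contains = "Embedder",
    slots = c(seed = "integer",
              residueGain = "numeric",
              siteGain = "numeric",
              neighborGain = "numeric",
              layerZeroNoiseSd = "numeric"))

setValidity("SurrogateEmbedder", function(object) {
    if (object@dim < 8L) return("surrogate dim must be >= 8")
    TRUE
})

#' Regressor family and tuning grid
#'
#' @slot family `"knn"`, `"svr"` or `"rfr"`.
#' @slot grid named list of candidate hyperparameter values; the Cartesian
#'   product is searched exhaustively in declaration order.
#' @slot cvFolds number of cross-validation folds used for tuning.
#' @slot seed integer seed controlling fold assignment and stochastic fits.
#' @seealso [regressorSpec()], [defaultGrid()], [gridSearchTrain()]
#' @export
setClass("RegressorSpec",
    slots = c(family = "character", grid = "list",
              cvFolds = "integer", seed = "integer"))

setValidity("RegressorSpec", function(object) {
    if (!object@family %in% c("knn", "svr", "rfr"))
        return("family must be one of 'knn', 'svr', 'rfr'")
    if (length(object@grid) == 0L)
        return("grid must be non-empty")
    if (is.null(names(object@grid)) || any(!nzchar(names(object@grid))))
        return("grid must be a named list")
    if (object@cvFolds < 2L) return("cvFolds must be >= 2")
    TRUE
})

#' Fitted fitness ranker
#'
#' A tuned regressor together with everything needed to reproduce and apply
#' it: the family, the selected hyperparameters, the embedding layer it was
#' trained on, the exact training ids, the value transform, and the full
#' cross-validation table of the grid search.
#'
#' @slot family regressor family.
#' @slot hyperparameters named list, the grid combination that won.
#' @slot layer 0-based embedding layer (NA if trained on a bare matrix).
#' @slot fit opaque fitted-model handle.
#' @slot trainIds ids of the training sequences.
#' @slot transform value transform the model predicts in.
#' @slot cvTable data.frame of all grid combinations and their mean
#'   out-of-fold R-squared.
#' @slot seed integer seed the search was run under.
#' @slot dim number of embedding columns the model expects.
#' @export
setClass("TrainedRanker",
    slots = c(family = "character", hyperparameters = "list",
              layer = "integer", fit = "ANY", trainIds = "character",
              transform = "character", cvTable = "data.frame",
              seed = "integer", dim = "integer"))

#' Test-set evaluation of a ranker
#'
#' @slot spearman Spearman rank correlation on the test set.
#' @slot rsq coefficient of determination on the test set.
#' @slot nTest number of test examples.
#' @export
setClass("EvaluationReport",
    slots = c(spearman = "numeric", rsq = "numeric", nTest = "integer"))

#' Subsampling learning curve
#'
#' Replicate test-set Spearman correlations of rankers trained on random
#' subsamples of increasing size, against one fixed held-out test split.
#'
#' @slot sizes increasing integer vector of training-set sizes.
#' @slot rho matrix of Spearman correlations, `length(sizes)` rows x `reps`
#'   columns (NA where the correlation was undefined).
#' @slot reps number of replicates per size.
#' @slot seed integer seed of the whole protocol.
#' @seealso [subsampleCorrelations()], [ciWidths()], [successRates()],
#'   [minAdequateSize()]
#' @export
setClass("SubsampleCurve",
    slots = c(sizes = "integer", rho = "matrix",
              reps = "integer", seed = "integer"))

setValidity("SubsampleCurve", function(object) {
    if (nrow(object@rho) != length(object@sizes))
        return("rho must have one row per size")
    if (ncol(object@rho) != object@reps)
        return("rho must have one column per replicate")
    if (is.unsorted(object@sizes, strictly = TRUE))
        return("sizes must be strictly increasing")
    TRUE
})

#' Synthetic fitness landscape
#'
#' A mutant cloud around a random reference sequence with additive,
#' site-library fitness: a fixed set of functional sites each carries one
#' alternative residue, every variant includes each library substitution
#' independently, and the true fitness is the sum over functional sites of a
#' site coefficient times the standardized hydropathy of the residue present,
#' plus Gaussian measurement noise.
#'
#' @slot dataset the generated [FitnessDataset-class] (noisy labels,
#'   identity transform).
#' @slot reference the unmutated reference sequence.
#' @slot sites 1-based positions of the functional sites.
#' @slot siteWeights per-site coefficients multiplying residue hydropathy.
#' @slot altResidues the library's alternative residue at each site.
#' @slot trueFitness noise-free fitness per variant.
#' @slot noise the recorded noise draws (labels = trueFitness + noise).
#' @slot noiseSd sd of the measurement noise.
#' @slot seed integer seed; regeneration from it is bit-identical.
#' @seealso [generateLandscape()]
#' @export
setClass("SyntheticLandscape",
    slots = c(dataset = "FitnessDataset", reference = "character",
              sites = "integer", siteWeights = "numeric",
              altResidues = "character", trueFitness = "numeric",
              noise = "numeric", noiseSd = "numeric", seed = "integer"))

setValidity("SyntheticLandscape", function(object) {
    if (length(object@sites) != length(object@siteWeights) ||
        length(object@sites) != length(object@altResidues))
        return("sites, siteWeights and altResidues must be parallel")
    y <- fitnessValues(object@dataset)
    if (max(abs(y - (object@trueFitness + object@noise))) > 1e-9)
        return("labels must equal trueFitness + noise")
    TRUE
})
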