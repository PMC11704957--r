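#' @import methods
NULL

#' @export
setGeneric("sequenceSet", function(x) standardGeneric("sequenceSet"))

#' @export
setGeneric("fitnessValues", function(x) standardGeneric("fitnessValues"))

#' @export
setGeneric("trainingValues", function(x) standardGeneric("trainingValues"))

#' @export
setGeneric("measureName", function(x) standardGeneric("measureName"))

#' @export
setGeneric("valueTransform", function(x) standardGeneric("valueTransform"))

#' @export
setGeneric("embMatrix", function(x) standardGeneric("embMatrix"))

#' @export
setGeneric("embLayer", function(x) standardGeneric("embLayer"))

#' @export
setGeneric("embedderName", function(x) standardGeneric("embedderName"))

#' @export
setGeneric("embedderDim", function(x) standardGeneric("embedderDim"))

#' @export
setGeneric("embedderLayers", function(x) standardGeneric("embedderLayers"))

#' @export
setGeneric("isDeterministic", function(x) standardGeneric("isDeterministic"))

#' Per-residue representations of one sequence at one layer
#'
#' The embedder contract: given a protein sequence and a 0-based layer index,
#' return an L x dim numeric matrix with one row per residue (special tokens,
#' if the backend has any, are excluded).
#'
#' @param embedder an [Embedder-class] backend.
#' @param sequence a single amino-acid string (character, `AAString`, or a
#'   length-one `AAStringSet`).
#' @param layer 0-based layer index, in `[0, embedderLayers(embedder))`.
#' @return numeric matrix with `nchar(sequence)` rows and
#'   `embedderDim(embedder)` columns; all entries finite.
#' @export
setGeneric("residueRepresentations",
           function(embedder, sequence, layer)
               standardGeneric("residueRepresentations"))

#' @export
setGeneric("ciWidths",
           function(x, level = 0.95) standardGeneric("ciWidths"))

#' @export
setGeneric("successRates",
           function(x, threshold = 0.5) standardGeneric("successRates"))

#' @export
setGeneric("curveSummary", function(x, ...) standardGeneric("curveSummary"))

#' @export
setGeneric("landscapeDataset",
           function(x) standardGeneric("landscapeDataset"))

#' @export
setGeneric("trueFitness", function(x) standardGeneric("trueFitness"))
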