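# Data-requirements protocol: subsampling curves, CI-width stopping rule,
# success rate, skewness diagnostic.

#' Subsampling learning curve of rank correlation
#'
#' Draws one fixed held-out test split (default 20%) from the full dataset,
#' then for every training-set size and replicate samples that many
#' examples without replacement from the remaining pool (seeded by the
#' protocol seed, the size and the replicate index), trains via
#' [gridSearchTrain()] and records the test-set Spearman correlation.
#' Keeping the test split fixed across all sizes and replicates makes the
#' curve comparable along the size axis.
#'
#' @param dataset a [FitnessDataset-class].
#' @param embeddings an [EmbeddingMatrix-class] covering the dataset.
#' @param sizes strictly increasing integer vector of training sizes; all
#'   at least 10 (cross-validation is infeasible below that) and at most
#'   the pool size.
#' @param reps replicates per size (default 10).
#' @param spec a [RegressorSpec-class].
#' @param seed integer protocol seed.
#' @param testFraction held-out fraction (default 0.2).
#' @return a [SubsampleCurve-class].
#' @export
subsampleCorrelations <- function(dataset, embeddings, sizes, reps = 10L,
                                  spec, seed = 1L, testFraction = 0.2) {
    sizes <- as.integer(sizes)
    reps <- as.integer(reps)
    if (reps < 2L) stop("reps must be >= 2", call. = FALSE)
    if (any(sizes < 10L))
        stop("sizes below 10 are not supported (cross-validation infeasible)",
             call. = FALSE)
    if (is.unsorted(sizes, strictly = TRUE))
        stop("sizes must be strictly increasing", call. = FALSE)
    n <- length(dataset)
    ids <- names(dataset)
    nTest <- max(2L, as.integer(round(n * testFraction)))
    perm <- .withSeed(.deriveSeed("holdout", seed), sample.int(n))
    testIds <- ids[perm[seq_len(nTest)]]
    poolIds <- ids[perm[(nTest + 1L):n]]
    if (max(sizes) > length(poolIds))
        stop(sprintf("largest size %d exceeds the pool of %d after holdout",
                     max(sizes), length(poolIds)), call. = FALSE)
    y <- trainingValues(dataset)
    X <- embMatrix(embeddings[ids])
    rho <- matrix(NA_real_, length(sizes), reps,
                  dimnames = list(sizes, NULL))
    for (si in seq_along(sizes)) {
        s <- sizes[si]
        for (r in seq_len(reps)) {
            sub <- .withSeed(.deriveSeed("subsample", seed, s, r),
                             sample(poolIds, s))
            model <- gridSearchTrain(X[sub, , drop = FALSE], y[sub], spec,
                                     layer = embLayer(embeddings),
                                     transform = valueTransform(dataset))
            pred <- predictFitness(model, X[testIds, , drop = FALSE])
            rho[si, r] <- tryCatch(spearmanRho(pred, y[testIds]),
                                   error = function(e) NA_real_)
        }
    }
    new("SubsampleCurve", sizes = sizes, rho = rho, reps = reps,
        seed = as.integer(seed))
}

#' Width of the t confidence interval for a mean
#'
#' `2 * t_{(1+level)/2, n-1} * sd / sqrt(n)`: the upper-minus-lower width
#' of the t-distribution confidence interval for the mean of the values.
#'
#' @param values numeric vector, length >= 2.
#' @param level confidence level (default 0.95).
#' @return non-negative width; 0 for constant values.
#' @export
ciWidth <- function(values, level = 0.95) {
    values <- values[is.finite(values)]
    n <- length(values)
    if (n < 2L) stop("need at least 2 values", call. = FALSE)
    2 * stats::qt((1 + level) / 2, df = n - 1L) * stats::sd(values) / sqrt(n)
}

#' Fraction of trials strictly above a threshold
#'
#' The success rate of the subsampling protocol: the ratio of trials whose
#' Spearman correlation exceeds the threshold (strictly).
#'
#' @param values numeric vector, length >= 1 (NAs count as failures).
#' @param threshold default 0.5.
#' @return rate in \[0, 1\].
#' @examples
#' successRate(c(0.6, 0.4, 0.55))  # 2/3
#' @export
successRate <- function(values, threshold = 0.5) {
    if (length(values) < 1L) stop("need at least 1 value", call. = FALSE)
    sum(values > threshold, na.rm = TRUE) / length(values)
}

#' @describeIn SubsampleCurve-class per-size CI widths of the replicate
#'   correlations (see [ciWidth()]).
#' @param x,object a `SubsampleCurve`.
#' @param level confidence level.
#' @export
setMethod("ciWidths", "SubsampleCurve", function(x, level = 0.95) {
    stats::setNames(apply(x@rho, 1L, ciWidth, level = level), x@sizes)
})

#' @describeIn SubsampleCurve-class per-size success rates (see
#'   [successRate()]).
#' @param threshold success threshold.
#' @export
setMethod("successRates", "SubsampleCurve", function(x, threshold = 0.5) {
    stats::setNames(apply(x@rho, 1L, successRate, threshold = threshold),
                    x@sizes)
})

#' @describeIn SubsampleCurve-class summary data.frame with one row per
#'   size: `size`, `mean_rho`, `ci_width`, `success_rate`.
#' @param ... passed on to nothing; present for the generic.
#' @export
setMethod("curveSummary", "SubsampleCurve", function(x, ...) {
    data.frame(size = x@sizes,
               mean_rho = rowMeans(x@rho, na.rm = TRUE),
               ci_width = as.numeric(ciWidths(x)),
               success_rate = as.numeric(successRates(x)))
})

#' Smallest stably adequate training-set size
#'
#' The smallest sampled size whose replicate-correlation confidence
#' interval is narrower than `maxCiWidth` AND for which every larger
#' sampled size also satisfies the criterion (the stable reading avoids
#' noise-induced early crossings).
#'
#' @param curve a [SubsampleCurve-class].
#' @param maxCiWidth strict upper bound on the CI width (default 0.1).
#' @return the size as an integer, or `NA` if no size qualifies.
#' @export
minAdequateSize <- function(curve, maxCiWidth = 0.1) {
    ok <- ciWidths(curve) < maxCiWidth
    stable <- rev(cumprod(rev(ok))) == 1
    if (!any(stable)) return(NA_integer_)
    curve@sizes[which(stable)[1L]]
}

#' Fisher's moment coefficient of skewness
#'
#' The unadjusted `g1 = m3 / m2^(3/2)` with central moments
#' `m_k = mean((v - mean(v))^k)`. Invariant under positive affine
#' transforms, sign-flipping under negation.
#'
#' @param values numeric vector, length >= 3, non-zero variance.
#' @return the skewness coefficient.
#' @examples
#' fisherSkewness(c(1, 2, 3))  # 0
#' @export
fisherSkewness <- function(values) {
    if (length(values) < 3L) stop("need at least 3 values", call. = FALSE)
    if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
    m <- mean(values)
    m2 <- mean((values - m)^2)
    if (m2 == 0) stop("undefined skewness: zero variance", call. = FALSE)
    mean((values - m)^3) / m2^1.5
}

#' Serialise a subsampling curve as TSV
#'
#' Writes the long table (`size`, `rep`, `rho`) and the per-size summary
#' (`size`, `mean_rho`, `ci_width`, `success_rate`).
#'
#' @param curve a [SubsampleCurve-class].
#' @param repPath path for the long replicate table.
#' @param summaryPath path for the summary table.
#' @return invisibly, `c(repPath, summaryPath)`.
#' @export
writeCurveTables <- function(curve, repPath, summaryPath) {
    long <- data.frame(size = rep(curve@sizes, curve@reps),
                       rep = rep(seq_len(curve@reps),
                                 each = length(curve@sizes)),
                       rho = as.vector(curve@rho))
    long <- long[order(long$size, long$rep), ]
    utils::write.table(long, repPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(curveSummary(curve), summaryPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(c(repPath, summaryPath))
}
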