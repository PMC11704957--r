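# Regressor families (kNN / SVR / RFR), grid-search training, prediction
# and evaluation statistics.

#' Default hyperparameter grids
#'
#' Small exhaustive grids reproducible at desk scale. For `svr` the kernel
#' is radial and `gammaFactor` multiplies the scale heuristic
#' `1 / (d * var(X))`; for `rfr`, `mtryRule` selects `sqrt(d)` or `d/3`
#' candidate features per split.
#'
#' @param family `"knn"`, `"svr"` or `"rfr"`.
#' @return named list of candidate values, in declaration order.
#' @export
defaultGrid <- function(family = c("knn", "svr", "rfr")) {
    switch(match.arg(family),
        knn = list(k = c(1L, 3L, 5L, 7L, 11L, 15L),
                   distance = c("euclidean", "cosine")),
        svr = list(C = c(0.1, 1, 10, 100),
                   gammaFactor = c(0.1, 1, 10),
                   epsilon = c(0.01, 0.1)),
        rfr = list(ntree = c(200L, 500L),
                   mtryRule = c("sqrt", "third"),
                   nodesize = c(1L, 3L)))
}

#' Construct a regressor specification
#'
#' @param family `"knn"`, `"svr"` or `"rfr"`.
#' @param grid named list of candidate hyperparameter values; defaults to
#'   [defaultGrid()] for the family.
#' @param cvFolds folds used by the internal tuning CV (default 5).
#' @param seed integer seed controlling fold assignment and stochastic fits.
#' @return a [RegressorSpec-class].
#' @examples
#' regressorSpec("rfr", grid = list(ntree = 300L, mtryRule = "third",
#'                                  nodesize = 1L))
#' @export
regressorSpec <- function(family = c("knn", "svr", "rfr"), grid = NULL,
                          cvFolds = 5L, seed = 1L) {
    family <- match.arg(family)
    if (is.null(grid)) grid <- defaultGrid(family)
    new("RegressorSpec", family = family, grid = grid,
        cvFolds = as.integer(cvFolds), seed = as.integer(seed))
}

#' Split a labelled dataset into train and test sets
#'
#' A seeded shuffle partitions the records into a training set of size
#' `round(n * trainFraction)` and a test set of the remainder; the same seed
#' always yields the same split.
#'
#' @param dataset a [FitnessDataset-class] with at least 5 records.
#' @param trainFraction fraction in (0, 1), default 0.8.
#' @param seed integer seed.
#' @return list with elements `train` and `test`, both `FitnessDataset`s;
#'   disjoint and jointly exhaustive.
#' @examples
#' d <- FitnessDataset(setNames(rep("MKVW", 10), paste0("s", 1:10)), 1:10)
#' lapply(splitDataset(d, seed = 1), length)
#' @export
splitDataset <- function(dataset, trainFraction = 0.8, seed = 1L) {
    n <- length(dataset)
    if (n < 5L) stop("need at least 5 records to split", call. = FALSE)
    .assertScalarNumber(trainFraction, "trainFraction")
    if (trainFraction <= 0 || trainFraction >= 1)
        stop("trainFraction must be in (0, 1)", call. = FALSE)
    nTrain <- round(n * trainFraction)
    if (nTrain < 1L || nTrain > n - 1L)
        stop("split leaves an empty partition", call. = FALSE)
    perm <- .withSeed(.deriveSeed("split", seed), sample.int(n))
    list(train = dataset[sort(perm[seq_len(nTrain)])],
         test = dataset[sort(perm[(nTrain + 1L):n])])
}

## ---- family fit/predict backends -------------------------------------

.knnDistance <- function(A, B, distance) {
    # rows of A vs rows of B
    if (distance == "euclidean") {
        an <- rowSums(A^2); bn <- rowSums(B^2)
        d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
        sqrt(pmax(d2, 0))
    } else {  # cosine
        an <- sqrt(rowSums(A^2)); bn <- sqrt(rowSums(B^2))
        an[an == 0] <- 1e-300; bn[bn == 0] <- 1e-300
        1 - tcrossprod(A / an, B / bn)
    }
}

.fitFamily <- function(family, X, y, hp, seed) {
    switch(family,
        knn = list(X = X, y = y, k = hp$k, distance = hp$distance),
        svr = {
            v <- stats::var(as.vector(X))
            gamma <- if (is.finite(v) && v > 0)
                hp$gammaFactor / (ncol(X) * v) else hp$gammaFactor
            e1071::svm(x = X, y = y, type = "eps-regression",
                       kernel = "radial", cost = hp$C, gamma = gamma,
                       epsilon = hp$epsilon, scale = FALSE)
        },
        rfr = {
            d <- ncol(X)
            mtry <- max(1L, if (hp$mtryRule == "sqrt") floor(sqrt(d))
                        else floor(d / 3))
            .withSeed(seed,
                randomForest::randomForest(x = X, y = y, ntree = hp$ntree,
                                           mtry = mtry,
                                           nodesize = hp$nodesize))
        })
}

.predictFamily <- function(family, fit, X) {
    switch(family,
        knn = {
            D <- .knnDistance(X, fit$X, fit$distance)
            k <- min(fit$k, ncol(D))
            apply(D, 1L, function(d) {
                # stable tie-break: lowest training index first
                mean(fit$y[order(d)[seq_len(k)]])
            })
        },
        svr = as.numeric(stats::predict(fit, X)),
        rfr = as.numeric(stats::predict(fit, X)))
}

## ---- grid search ------------------------------------------------------

#' Train a regressor by exhaustive grid search
#'
#' Searches the Cartesian product of the grid in declaration order, scoring
#' each combination by the mean out-of-fold coefficient of determination
#' (R-squared) on one fixed, seeded fold partition, then refits the best
#' combination (ties broken by declaration order) on all of the data.
#' Model selection optimises R-squared; reporting elsewhere uses the
#' Spearman correlation.
#'
#' @param X an [EmbeddingMatrix-class] or a plain numeric matrix with row
#'   names, rows aligned to `y`.
#' @param y numeric response in transformed space (see
#'   [trainingValues()]).
#' @param spec a [RegressorSpec-class].
#' @param layer 0-based embedding layer to record (taken from `X` when it
#'   is an `EmbeddingMatrix`).
#' @param transform transform label to record in the model.
#' @return a [TrainedRanker-class].
#' @seealso [trainRanker()] for the dataset-level convenience wrapper.
#' @export
gridSearchTrain <- function(X, y, spec, layer = NA_integer_,
                            transform = "identity") {
    if (is(X, "EmbeddingMatrix")) {
        layer <- embLayer(X)
        X <- embMatrix(X)
    }
    if (!is.matrix(X)) stop("X must be a matrix", call. = FALSE)
    n <- nrow(X)
    if (n != length(y))
        stop("rows(X) must equal length(y)", call. = FALSE)
    if (n < spec@cvFolds)
        stop(sprintf("need at least %d samples for %d-fold CV",
                     spec@cvFolds, spec@cvFolds), call. = FALSE)
    grid <- expand.grid(spec@grid, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    foldId <- .withSeed(.deriveSeed("cv-folds", spec@seed),
                        sample(rep_len(seq_len(spec@cvFolds), n)))
    if (min(table(foldId)) < 2L)
        stop("every CV fold needs at least 2 samples", call. = FALSE)
    constantY <- stats::var(y) == 0
    scores <- rep(NA_real_, nrow(grid))
    if (!constantY) {
        for (g in seq_len(nrow(grid))) {
            hp <- as.list(grid[g, , drop = FALSE])
            r2 <- rep(NA_real_, spec@cvFolds)
            for (f in seq_len(spec@cvFolds)) {
                tr <- foldId != f
                fit <- .fitFamily(spec@family, X[tr, , drop = FALSE], y[tr],
                                  hp, .deriveSeed(spec@seed, "fit", g, f))
                pred <- .predictFamily(spec@family, fit,
                                       X[!tr, , drop = FALSE])
                r2[f] <- tryCatch(rSquared(y[!tr], pred),
                                  error = function(e) NA_real_)
            }
            scores[g] <- if (all(is.na(r2))) -Inf else mean(r2, na.rm = TRUE)
        }
        best <- which.max(scores)  # first maximum: declaration order wins
    } else {
        best <- 1L
    }
    hp <- as.list(grid[best, , drop = FALSE])
    fit <- .fitFamily(spec@family, X, y, hp,
                      .deriveSeed(spec@seed, "refit", best))
    cvTable <- cbind(grid, meanR2 = scores)
    new("TrainedRanker", family = spec@family,
        hyperparameters = hp[names(spec@grid)],
        layer = as.integer(layer), fit = fit,
        trainIds = if (is.null(rownames(X))) character() else rownames(X),
        transform = transform, cvTable = cvTable, seed = spec@seed,
        dim = ncol(X))
}

#' Train a ranker from a dataset and its embeddings
#'
#' Convenience wrapper: aligns embedding rows to the dataset, applies the
#' dataset's value transform and calls [gridSearchTrain()].
#'
#' @param dataset a [FitnessDataset-class].
#' @param embeddings an [EmbeddingMatrix-class] covering all dataset ids.
#' @param spec a [RegressorSpec-class].
#' @return a [TrainedRanker-class].
#' @export
trainRanker <- function(dataset, embeddings, spec) {
    ids <- names(dataset)
    miss <- setdiff(ids, names(embeddings))
    if (length(miss))
        stop(sprintf("no embedding for id '%s'", miss[1L]), call. = FALSE)
    gridSearchTrain(embeddings[ids], trainingValues(dataset), spec,
                    transform = valueTransform(dataset))
}

#' Predict fitness for embedded sequences
#'
#' One finite value per row, in the model's transformed space, order
#' preserved.
#'
#' @param model a [TrainedRanker-class].
#' @param X an [EmbeddingMatrix-class] or numeric matrix with the training
#'   dimensionality.
#' @return named numeric vector of predictions.
#' @export
predictFitness <- function(model, X) {
    if (is(X, "EmbeddingMatrix")) X <- embMatrix(X)
    if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
    if (ncol(X) != model@dim)
        stop(sprintf("embedding dim %d does not match training dim %d",
                     ncol(X), model@dim), call. = FALSE)
    p <- .predictFamily(model@family, model@fit, X)
    stats::setNames(as.numeric(p), rownames(X))
}

#' @describeIn TrainedRanker-class `predict` method, delegating to
#'   [predictFitness()].
#' @param object a `TrainedRanker`.
#' @param newdata an [EmbeddingMatrix-class] or numeric matrix.
#' @param ... ignored.
#' @export
setMethod("predict", "TrainedRanker", function(object, newdata, ...) {
    predictFitness(object, newdata)
})

## ---- statistics -------------------------------------------------------

#' Spearman rank correlation
#'
#' The Pearson correlation of mid-ranks (average ranks for ties). Errors if
#' either vector has zero rank variance, where the correlation is
#' undefined.
#'
#' @param x,y equal-length numeric vectors, length >= 2.
#' @return correlation in \[-1, 1\].
#' @examples
#' spearmanRho(c(1, 2, 3), c(10, 20, 30))  # 1
#' @export
spearmanRho <- function(x, y) {
    if (length(x) != length(y)) stop("equal lengths required", call. = FALSE)
    if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
    if (any(!is.finite(x)) || any(!is.finite(y)))
        stop("inputs must be finite", call. = FALSE)
    if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0)
        stop("undefined correlation: zero rank variance", call. = FALSE)
    as.numeric(stats::cor(x, y, method = "spearman"))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`, with the total sum of squares about
#' `mean(yTrue)`. Can be negative for predictions worse than the mean;
#' errors when `yTrue` has zero variance.
#'
#' @param yTrue,yPred equal-length numeric vectors, length >= 2.
#' @return R-squared, at most 1.
#' @export
rSquared <- function(yTrue, yPred) {
    if (length(yTrue) != length(yPred))
        stop("equal lengths required", call. = FALSE)
    if (length(yTrue) < 2L) stop("need at least 2 observations", call. = FALSE)
    ssTot <- sum((yTrue - mean(yTrue))^2)
    if (ssTot == 0)
        stop("undefined R-squared: zero variance in yTrue", call. = FALSE)
    1 - sum((yTrue - yPred)^2) / ssTot
}

#' Evaluate a trained ranker on a test partition
#'
#' Predicts the test embeddings and reports both the Spearman rank
#' correlation and the coefficient of determination in the model's
#' transformed space.
#'
#' @param model a [TrainedRanker-class].
#' @param embeddings an [EmbeddingMatrix-class] covering the test ids.
#' @param testset a [FitnessDataset-class] (its transform is applied), or a
#'   named numeric vector already in transformed space.
#' @return an [EvaluationReport-class].
#' @export
evaluateModel <- function(model, embeddings, testset) {
    if (is(testset, "FitnessDataset")) {
        y <- trainingValues(testset)
    } else {
        y <- testset
    }
    if (is.null(names(y))) stop("test values must be named", call. = FALSE)
    pred <- predictFitness(model, embeddings[names(y)])
    new("EvaluationReport", spearman = spearmanRho(pred, y),
        rsq = rSquared(y, pred), nTest = length(y))
}
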