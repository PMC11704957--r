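test_that("train/test splitting is sized, seeded, disjoint and exhaustive", {
    d159 <- landscapeDataset(generateLandscape(seed = 1, n = 159))
    parts <- splitDataset(d159, 0.8, seed = 5)
    expect_equal(length(parts$train), 127L)
    expect_equal(length(parts$test), 32L)

    p1 <- splitDataset(d159, 0.8, seed = 10)
    p2 <- splitDataset(d159, 0.8, seed = 10)
    expect_identical(names(p1$train), names(p2$train))

    base <- landscapeDataset(generateLandscape(seed = 2, n = 80))
    set.seed(77)
    for (k in 1:50) {
        n <- sample(5:80, 1)
        d <- base[seq_len(n)]
        p <- splitDataset(d, runif(1, 0.2, 0.9), seed = sample(1e6, 1))
        expect_equal(sort(c(names(p$train), names(p$test))),
                     sort(names(d)))
        expect_length(intersect(names(p$train), names(p$test)), 0)
    }
    expect_error(splitDataset(base[1:4]), "at least 5")
})

test_that("spearmanRho matches a mid-rank Pearson oracle and its invariances", {
    expect_equal(spearmanRho(1:3, c(10, 20, 30)), 1.0)
    expect_equal(spearmanRho(1:3, c(3, 2, 1)), -1.0)
    expect_error(spearmanRho(c(1, 1, 1), 1:3), "undefined correlation")
    expect_error(spearmanRho(1:3, 1:4), "equal lengths")

    set.seed(8)
    for (k in 1:25) {
        n <- sample(5:40, 1)
        x <- sample(1:8, n, replace = TRUE) + rnorm(n) * (k %% 2)
        y <- sample(1:5, n, replace = TRUE) + rnorm(n) * (k %% 3 == 0)
        if (length(unique(x)) < 2 || length(unique(y)) < 2) next
        expect_equal(spearmanRho(x, y), oracleSpearman(x, y),
                     tolerance = 1e-12)
        expect_equal(spearmanRho(x, y), spearmanRho(y, x))
        expect_lte(abs(spearmanRho(x, y)), 1)
        # invariant under strictly increasing transforms
        expect_equal(spearmanRho(exp(x / 10), y), spearmanRho(x, y))
        expect_equal(spearmanRho(x^3, y), spearmanRho(x, y))
        expect_equal(spearmanRho(2 * x + 5, y), spearmanRho(x, y))
    }
})

test_that("rSquared matches the definition computed by independent loop", {
    y <- c(1, 2, 3, 4)
    expect_equal(rSquared(y, y), 1.0)
    expect_equal(rSquared(y, rep(mean(y), 4)), 0.0)
    expect_error(rSquared(rep(2, 4), y), "zero variance")

    set.seed(12)
    for (k in 1:25) {
        n <- sample(4:30, 1)
        yt <- rnorm(n); yp <- rnorm(n)
        expect_equal(rSquared(yt, yp), oracleR2(yt, yp), tolerance = 1e-12)
    }
})

test_that("grid search handles degenerate targets and memorises with k=1", {
    set.seed(5)
    X <- matrix(rnorm(40), 10, 4, dimnames = list(sprintf("r%02d", 1:10)))
    # constant target: knn and rfr predict that constant
    for (fam in c("knn", "rfr")) {
        m <- suppressWarnings(  # constant target triggers a backend note
            gridSearchTrain(X, rep(3.5, 10), regressorSpec(fam, seed = 1)))
        expect_equal(unname(predictFitness(m, X)), rep(3.5, 10))
    }
    # knn with k = 1 returns training values exactly
    y <- rnorm(10)
    m1 <- gridSearchTrain(X, y, regressorSpec("knn",
        grid = list(k = 1L, distance = "euclidean"), seed = 1))
    expect_equal(unname(predictFitness(m1, X)), y)
    # duplicate rows give duplicate predictions
    Xd <- X[c(1, 1, 2), ]; rownames(Xd) <- c("a", "b", "c")
    p <- predictFitness(m1, Xd)
    expect_equal(p[["a"]], p[["b"]])

    expect_error(predictFitness(m1, X[, 1:2]), "does not match")
    expect_error(gridSearchTrain(X[1:3, ], y[1:3],
                                 regressorSpec("knn", seed = 1)),
                 "at least 5")
})

test_that("grid search is deterministic and batch-order invariant", {
    set.seed(31)
    X <- matrix(rnorm(60 * 6), 60, 6,
                dimnames = list(sprintf("r%02d", 1:60)))
    y <- X[, 1] - X[, 2] + rnorm(60, 0, 0.1)
    spec <- regressorSpec("rfr", grid = list(ntree = c(100L, 200L),
                                             mtryRule = "sqrt",
                                             nodesize = c(1L, 3L)),
                          seed = 9)
    m1 <- gridSearchTrain(X, y, spec)
    m2 <- gridSearchTrain(X, y, spec)
    expect_identical(m1@hyperparameters, m2@hyperparameters)
    expect_equal(predictFitness(m1, X), predictFitness(m2, X))
    expect_equal(m1@cvTable$meanR2, m2@cvTable$meanR2)

    # rfr prediction is invariant to prediction batch order
    pAll <- predictFitness(m1, X)
    pOne <- vapply(seq_len(10), function(i)
        predictFitness(m1, X[i, , drop = FALSE])[[1]], numeric(1))
    expect_equal(unname(pAll[1:10]), pOne)
})

test_that("all three families recover a 1-D monotone relationship", {
    x <- matrix(seq(-2, 2, length.out = 60))
    rownames(x) <- sprintf("s%02d", 1:60)
    y <- 2 * as.numeric(x)
    tr <- seq_len(60) %% 3 != 0
    for (fam in c("knn", "svr", "rfr")) {
        m <- gridSearchTrain(x[tr, , drop = FALSE], y[tr],
                             regressorSpec(fam, seed = 3))
        p <- predictFitness(m, x[!tr, , drop = FALSE])
        expect_equal(spearmanRho(p, y[!tr]), 1.0)
    }
})

test_that("held-out correlation degrades with label noise", {
    rhoAt <- function(noise, s) {
        ls <- generateLandscape(seed = s, n = 150, noiseSd = noise)
        d <- landscapeDataset(ls)
        X <- embedDataset(d, SurrogateEmbedder(seed = 99), layer = 1)
        parts <- splitDataset(d, seed = s)
        m <- trainRanker(parts$train, X[names(parts$train)],
                         cheapRfrSpec())
        evaluateModel(m, X, parts$test)@spearman
    }
    lo <- vapply(1:5, function(s) rhoAt(0.05, s), numeric(1))
    hi <- vapply(1:5, function(s) rhoAt(1.0, s), numeric(1))
    expect_gt(mean(lo), mean(hi))
})

test_that("a perfect model scores rho = 1 and R2 = 1", {
    set.seed(2)
    X <- matrix(rnorm(40), 20, 2, dimnames = list(sprintf("t%02d", 1:20)))
    y <- setNames(X[, 1], rownames(X))
    m <- gridSearchTrain(X, y, regressorSpec("knn",
        grid = list(k = 1L, distance = "euclidean"), seed = 1))
    emb <- new("EmbeddingMatrix", X = X, layer = 0L)
    rep <- evaluateModel(m, emb, y)
    expect_equal(rep@spearman, 1.0)
    expect_equal(rep@rsq, 1.0)
    expect_equal(rep@nTest, 20L)
})
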