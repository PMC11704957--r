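test_that("ciWidth equals the t-interval width and scales with n", {
    expect_equal(ciWidth(c(2, 2, 2, 2)), 0.0)
    v <- c(0, 1)
    expect_equal(ciWidth(v), 2 * qt(0.975, 1) * sd(v) / sqrt(2))
    expect_equal(ciWidth(v), oracleCiWidth(v))

    set.seed(16)
    for (k in 1:25) {
        x <- rnorm(sample(3:30, 1))
        lvl <- sample(c(0.9, 0.95, 0.99), 1)
        expect_equal(ciWidth(x, lvl), oracleCiWidth(x, lvl),
                     tolerance = 1e-12)
    }

    # duplicating the sample (sd preserved, n doubled) narrows the interval
    x <- rnorm(10)
    expect_lt(ciWidth(c(x, x)), ciWidth(x))
    expect_error(ciWidth(1), "at least 2")

    # width shrinks as replicate count grows on iid draws
    set.seed(30)
    w <- vapply(c(5, 20, 80), function(n) ciWidth(rnorm(n, 0.7, 0.1)),
                numeric(1))
    expect_true(all(diff(w) < 0))
})

test_that("successRate counts strict exceedances and aggregates linearly", {
    expect_equal(successRate(c(0.6, 0.4, 0.55)), 2 / 3)
    expect_equal(successRate(rep(0.5, 4)), 0.0)  # strict boundary
    set.seed(44)
    v <- runif(12)
    expect_equal(successRate(sample(v)), successRate(v))
    a <- runif(5); b <- runif(15)
    expect_equal(successRate(c(a, b)),
                 (5 * successRate(a) + 15 * successRate(b)) / 20)
    # binomial sanity: 1000 uniform draws, rate within 3 sigma of 0.5
    u <- runif(1000)
    expect_lt(abs(successRate(u) - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("minAdequateSize applies the stable CI-width criterion", {
    mkCurve <- function(rhoRows)
        new("SubsampleCurve", sizes = as.integer(10 * seq_len(nrow(rhoRows)) + 10),
            rho = rhoRows, reps = ncol(rhoRows), seed = 1L)
    tight <- matrix(0.8 + 0.001 * rnorm(15, 0, 1), 3, 5)
    expect_equal(minAdequateSize(mkCurve(tight)), 20L)

    wide <- matrix(rep(c(0, 1), 15), 3, 10)
    expect_true(is.na(minAdequateSize(mkCurve(wide))))

    # an early noise-induced crossing is ignored: only sizes from which
    # every larger size also qualifies count
    mixed <- rbind(rep(c(0.79, 0.81), 5),      # narrow
                   rep(c(0.1, 0.9), 5),        # wide again
                   rep(c(0.70, 0.72), 5),      # narrow from here on
                   rep(c(0.80, 0.82), 5))
    expect_equal(minAdequateSize(mkCurve(mixed)), 40L)
})

test_that("fisherSkewness is the unadjusted g1 with its symmetries", {
    expect_equal(fisherSkewness(c(1, 2, 3)), 0.0)
    v <- c(0, 0, 0, 1)
    expect_equal(fisherSkewness(v), oracleSkew(v), tolerance = 1e-12)
    set.seed(17)
    for (k in 1:25) {
        x <- rexp(sample(5:50, 1))
        expect_equal(fisherSkewness(x), oracleSkew(x), tolerance = 1e-12)
        expect_equal(fisherSkewness(-x), -fisherSkewness(x))
        expect_equal(fisherSkewness(3 * x + 7), fisherSkewness(x),
                     tolerance = 1e-10)
    }
    expect_error(fisherSkewness(c(2, 2, 2)), "zero variance")
    expect_error(fisherSkewness(c(1, 2)), "at least 3")
})

test_that("subsampling curves have the declared shape and are seeded", {
    ls <- generateLandscape(seed = 2, n = 100)
    d <- landscapeDataset(ls)
    X <- embedDataset(d, SurrogateEmbedder(seed = 99), layer = 1)
    spec <- cheapKnnSpec()
    c1 <- subsampleCorrelations(d, X, sizes = 20L, reps = 2L, spec = spec,
                                seed = 5)
    expect_equal(dim(c1@rho), c(1L, 2L))
    c2 <- subsampleCorrelations(d, X, sizes = 20L, reps = 2L, spec = spec,
                                seed = 5)
    expect_identical(c1@rho, c2@rho)
    expect_error(subsampleCorrelations(d, X, sizes = 5L, reps = 2L,
                                       spec = spec, seed = 1), "below 10")
    expect_error(subsampleCorrelations(d, X, sizes = 90L, reps = 2L,
                                       spec = spec, seed = 1),
                 "exceeds the pool")

    smry <- curveSummary(c1)
    expect_named(smry, c("size", "mean_rho", "ci_width", "success_rate"))
    f1 <- tempfile(); f2 <- tempfile()
    writeCurveTables(c1, f1, f2)
    expect_equal(nrow(read.delim(f1)), 2L)
})

test_that("learning curves improve with training-set size", {
    # mean held-out correlation grows with size at moderate label noise;
    # the success rate transitions upward at heavier noise, where
    # small-sample models straddle the 0.5 threshold (at low noise the
    # rate saturates at 1 and the trend is undefined). The two label
    # sets share variants, so each seed is embedded once.
    hits <- 0L; trendHits <- 0L
    for (s in 1:5) {
        lsMod <- generateLandscape(seed = 10 + s, n = 230, noiseSd = 0.5)
        lsHard <- generateLandscape(seed = 10 + s, n = 230, noiseSd = 1.0)
        dMod <- landscapeDataset(lsMod)
        X <- embedDataset(dMod, SurrogateEmbedder(seed = 99), layer = 1)
        curve <- subsampleCorrelations(dMod, X,
            sizes = seq(20L, 170L, by = 30L), reps = 4L,
            spec = cheapKnnSpec(), seed = s)
        m <- rowMeans(curve@rho, na.rm = TRUE)
        if (m[length(m)] > m[1L]) hits <- hits + 1L

        curveH <- subsampleCorrelations(landscapeDataset(lsHard), X,
            sizes = seq(10L, 160L, by = 30L), reps = 6L,
            spec = cheapKnnSpec(), seed = s)
        sr <- successRates(curveH)
        trend <- suppressWarnings(cor(curveH@sizes, sr,
                                      method = "spearman"))
        if (!is.na(trend) && trend > 0) trendHits <- trendHits + 1L
    }
    expect_gte(hits, 4L)
    expect_gte(trendHits, 4L)
})
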