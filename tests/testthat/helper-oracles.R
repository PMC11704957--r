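# Independent brute-force oracles and fixture builders used across the
# suite. Deliberately written as plain loops, sharing no code with the
# package implementations they check.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# mid-ranks by explicit counting: rank of x_i = (#smaller) + (#equal + 1)/2
oracleMidranks <- function(x) {
    n <- length(x)
    r <- numeric(n)
    for (i in seq_len(n)) {
        smaller <- sum(x < x[i])
        equal <- sum(x == x[i])
        r[i] <- smaller + (equal + 1) / 2
    }
    r
}

oraclePearson <- function(a, b) {
    n <- length(a)
    ma <- sum(a) / n; mb <- sum(b) / n
    num <- sum((a - ma) * (b - mb))
    num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

oracleSpearman <- function(x, y) {
    oraclePearson(oracleMidranks(x), oracleMidranks(y))
}

oracleR2 <- function(yt, yp) {
    m <- sum(yt) / length(yt)
    ssr <- 0; sst <- 0
    for (i in seq_along(yt)) {
        ssr <- ssr + (yt[i] - yp[i])^2
        sst <- sst + (yt[i] - m)^2
    }
    1 - ssr / sst
}

# CI width via stats::t.test (an independent code path from the formula)
oracleCiWidth <- function(v, level = 0.95) {
    ci <- stats::t.test(v, conf.level = level)$conf.int
    ci[2] - ci[1]
}

oracleSkew <- function(v) {
    n <- length(v)
    m <- sum(v) / n
    m2 <- 0; m3 <- 0
    for (x in v) {
        m2 <- m2 + (x - m)^2 / n
        m3 <- m3 + (x - m)^3 / n
    }
    m3 / m2^(3 / 2)
}

# per-hit filter predicate, coded independently of filterHits
oracleHitPasses <- function(hit, maxE = 1e-3, minCov = 0.9) {
    qcov <- (hit$q_end - hit$q_start + 1) / hit$q_len
    tcov <- (hit$t_end - hit$t_start + 1) / hit$t_len
    (hit$evalue < maxE) && (qcov >= minCov) && (tcov >= minCov)
}

randomSequences <- function(n, minLen = 5, maxLen = 40, seed = 1) {
    set.seed(seed)
    lens <- sample(minLen:maxLen, n, replace = TRUE)
    seqs <- vapply(lens, function(L)
        paste(sample(AA20, L, replace = TRUE), collapse = ""), "")
    names(seqs) <- sprintf("seq%03d", seq_len(n))
    seqs
}

writeTempFasta <- function(seqs, values = NULL) {
    f <- tempfile(fileext = ".fasta")
    lines <- character()
    for (i in seq_along(seqs)) {
        hdr <- if (is.null(values)) sprintf(">%s", names(seqs)[i])
               else sprintf(">%s %.17g", names(seqs)[i], values[i])
        lines <- c(lines, hdr, seqs[[i]])
    }
    writeLines(lines, f)
    f
}

# small embedder + singleton-grid specs reused by the slower tests
cheapKnnSpec <- function(seed = 7L)
    regressorSpec("knn", grid = list(k = 5L, distance = "euclidean"),
                  seed = seed)

cheapRfrSpec <- function(seed = 42L)
    regressorSpec("rfr", grid = list(ntree = 200L, mtryRule = "third",
                                     nodesize = 1L), seed = seed)
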