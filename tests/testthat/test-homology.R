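test_that("m8 parsing validates shape and round-trips generated hits", {
    f <- tempfile(fileext = ".m8")
    writeLines(c(
        "q1\tt1\t95.5\t100\t4\t1\t1\t100\t1\t100\t1e-30\t200\t100\t105",
        "q1\tt2\t80.0\t90\t18\t0\t5\t94\t2\t91\t1e-5\t150\t100\t95",
        "q2\tt3\t50.0\t80\t40\t2\t1\t80\t10\t89\t0.01\t90\t85\t120"), f)
    hits <- readHitsM8(f)
    expect_equal(nrow(hits), 3L)
    expect_equal(hits$evalue, c(1e-30, 1e-5, 0.01))
    expect_equal(hits$t_len, c(105, 95, 120))

    writeLines(c(paste(rep("x", 11), collapse = "\t")), f)
    expect_error(readHitsM8(f), "line 1 has 11 columns")

    writeLines(c("q\tt\tNA\t1\t1\t1\t1\t1\t1\t1\t1\t1\t5\t5"), f)
    expect_error(readHitsM8(f), "unparseable")

    # 12-column dialect takes lengths from the FASTA
    writeLines("q1\tt1\t95.5\t100\t4\t1\t1\t100\t1\t100\t1e-30\t200", f)
    seqs <- Biostrings::AAStringSet(c(t1 = paste(rep("A", 105),
                                                 collapse = "")))
    h12 <- readHitsM8(f, targetSeqs = seqs)
    expect_equal(h12$t_len, 105)
    expect_true(is.na(h12$q_len))

    # write -> parse round trip on 200 synthetic hits
    toy <- generateToyHits(seed = 4, n = 200, 0.25, 0.25)
    out <- tempfile(fileext = ".m8")
    writeHitsM8(toy$hits, out)
    expect_equal(readHitsM8(out), toy$hits)
})

test_that("hit filtering applies the strict E-value and inclusive coverage rules", {
    mk <- function(ev, qs, qe, ql, ts, te, tl)
        data.frame(query_id = "q", target_id = "t", percent_identity = 90,
                   aln_len = qe - qs + 1, mismatches = 0, gap_opens = 0,
                   q_start = qs, q_end = qe, t_start = ts, t_end = te,
                   evalue = ev, bit_score = 100, q_len = ql, t_len = tl)
    # boundary E-value is removed (strict <)
    expect_equal(nrow(filterHits(mk(1e-3, 1, 100, 100, 1, 100, 100))), 0L)
    # full coverage both sides, tiny E-value: kept
    expect_equal(nrow(filterHits(mk(1e-10, 1, 100, 100, 1, 100, 100))), 1L)
    # exactly 90% coverage is kept (inclusive >=)
    expect_equal(nrow(filterHits(mk(1e-10, 1, 90, 100, 1, 100, 100))), 1L)
    expect_equal(nrow(filterHits(mk(1e-10, 1, 89, 100, 1, 100, 100))), 0L)

    h <- mk(1e-10, 1, 100, 100, 1, 100, 100)
    h$q_len <- NA
    expect_error(filterHits(h), "missing sequence length")

    # 500 randomised hits against the independent per-hit predicate
    set.seed(14)
    n <- 500
    ql <- sample(50:300, n, TRUE); tl <- sample(50:300, n, TRUE)
    qs <- pmin(sample(1:60, n, TRUE), ql)
    qe <- pmin(qs + sample(30:300, n, TRUE), ql)
    ts <- pmin(sample(1:60, n, TRUE), tl)
    te <- pmin(ts + sample(30:300, n, TRUE), tl)
    hits <- data.frame(query_id = "q",
                       target_id = sprintf("t%03d", seq_len(n)),
                       percent_identity = 90, aln_len = qe - qs + 1,
                       mismatches = 0, gap_opens = 0, q_start = qs,
                       q_end = qe, t_start = ts, t_end = te,
                       evalue = 10^runif(n, -40, 1), bit_score = 1,
                       q_len = ql, t_len = tl)
    kept <- filterHits(hits)
    oracle <- vapply(seq_len(n),
                     function(i) oracleHitPasses(hits[i, ]), logical(1))
    expect_identical(kept$target_id, hits$target_id[oracle])
    # subset of input and idempotent
    expect_true(all(kept$target_id %in% hits$target_id))
    expect_identical(filterHits(kept), kept)
})

test_that("global-alignment identity behaves like a similarity measure", {
    expect_equal(pairwiseIdentity("MKVW", "MKVW"), 1.0)
    expect_equal(pairwiseIdentity("AAAAAAAAAA", "AAAAAAAAAC"), 0.9)
    set.seed(6)
    for (k in 1:10) {
        a <- paste(sample(AA20, 30, TRUE), collapse = "")
        b <- paste(sample(AA20, 25, TRUE), collapse = "")
        idn <- pairwiseIdentity(a, b)
        expect_equal(idn, pairwiseIdentity(b, a))
        expect_gte(idn, 0); expect_lt(idn, 1)
    }
    expect_error(pairwiseIdentity("", "MK"), "non-empty")
})

test_that("greedy redundancy filtering recovers planted clusters", {
    # identical pair collapses to one representative
    recs <- Biostrings::AAStringSet(c(a = "MKVWMKVW", b = "MKVWMKVW"))
    red <- redundancyFilter(recs)
    expect_equal(length(red$representatives), 1L)
    expect_equal(unname(red$assignment[c("a", "b")]), c("a", "a"))

    # threshold 1.0 keeps pairwise-distinct sequences apart
    set.seed(19)
    distinct <- setNames(vapply(1:5, function(i)
        paste(sample(AA20, 20, TRUE), collapse = ""), ""),
        paste0("d", 1:5))
    red5 <- redundancyFilter(Biostrings::AAStringSet(distinct),
                             threshold = 1.0)
    expect_equal(length(red5$representatives), 5L)

    # 8 planted clusters of 5 variants each at <= 5% mutations
    set.seed(23)
    seqs <- character(); labels <- character()
    for (cl in 1:8) {
        seed <- sample(AA20, 80, replace = TRUE)
        for (v in 1:5) {
            s <- seed
            nm <- sample(0:4, 1)
            if (nm > 0) {
                pos <- sample(80, nm)
                s[pos] <- vapply(s[pos], function(r)
                    sample(setdiff(AA20, r), 1), "")
            }
            id <- sprintf("c%d_v%d", cl, v)
            seqs[id] <- paste(s, collapse = "")
            labels[id] <- sprintf("c%d", cl)
        }
    }
    red8 <- redundancyFilter(Biostrings::AAStringSet(seqs),
                             threshold = 0.9)
    expect_equal(length(red8$representatives), 8L)
    # assignment respects the generating clusters
    for (id in names(seqs)) {
        repId <- red8$assignment[[id]]
        expect_equal(labels[[repId]], labels[[id]])
    }
    # brute-force invariant: each member has >= threshold identity to
    # its representative
    for (id in names(seqs)) {
        expect_gte(pairwiseIdentity(seqs[[id]],
                                    seqs[[red8$assignment[[id]]]]), 0.9)
    }
})

test_that("candidate ranking sorts by prediction with lexicographic ties", {
    set.seed(3)
    X <- matrix(rnorm(20), 10, 2,
                dimnames = list(c("c", "a", "b", sprintf("x%d", 1:7))))
    y <- setNames(c(3, 2, 1, rnorm(7)), rownames(X))
    m <- gridSearchTrain(X, y, regressorSpec("knn",
        grid = list(k = 1L, distance = "euclidean"), seed = 1))
    emb <- new("EmbeddingMatrix", X = X, layer = 0L)

    ranked <- rankCandidates(m, emb, rownames(X)[1:3])
    expect_equal(ranked$id, c("c", "a", "b"))
    expect_equal(ranked$rank, 1:3)

    # all-equal predictions: ids in lexicographic order
    Xe <- matrix(rep(X[1, ], 3), 3, 2, byrow = TRUE,
                 dimnames = list(c("zz", "aa", "mm")))
    rankedEq <- rankCandidates(m, new("EmbeddingMatrix", X = Xe,
                                      layer = 0L), c("zz", "aa", "mm"))
    expect_equal(rankedEq$id, c("aa", "mm", "zz"))

    # 100 candidates equal an independent sort of the prediction vector
    X100 <- matrix(rnorm(200), 100, 2,
                   dimnames = list(sprintf("p%03d", 1:100)))
    emb100 <- new("EmbeddingMatrix", X = X100, layer = 0L)
    r100 <- rankCandidates(m, emb100, rownames(X100))
    pred <- predictFitness(m, emb100)
    expect_identical(r100$id,
                     names(pred)[order(-pred, names(pred))])
    expect_true(all(diff(r100$predicted_value) <= 0))
    expect_identical(sort(r100$rank), 1:100)

    expect_error(rankCandidates(m, emb, c("a", "ghost")), "ghost")
})

test_that("identity-to-query diagnostics report extremes and degeneracy", {
    set.seed(9)
    q <- paste(sample(AA20, 40, TRUE), collapse = "")
    recs <- c(self = q)
    X <- matrix(rnorm(2), 1, 2, dimnames = list("self"))
    ranked <- data.frame(rank = 1L, id = "self", predicted_value = 1,
                         identity_to_query = NA)
    out <- identityVsPrediction(ranked,
                                q, Biostrings::AAStringSet(recs),
                                topK = 1)
    expect_equal(out$min, 1.0)
    expect_equal(out$max, 1.0)
    expect_true(is.na(out$rhoRankIdentity))  # undefined, reported not crashed

    # planted identity gradient: extremes match brute-force identities
    muts <- c(1, 5, 10, 20)
    panel <- vapply(muts, function(k) {
        s <- strsplit(q, "")[[1]]
        pos <- sample(40, k)
        s[pos] <- vapply(s[pos], function(r)
            sample(setdiff(AA20, r), 1), "")
        paste(s, collapse = "")
    }, "")
    names(panel) <- sprintf("v%d", muts)
    rankedP <- data.frame(rank = 1:4, id = names(panel),
                          predicted_value = c(4, 3, 2, 1),
                          identity_to_query = NA)
    outP <- identityVsPrediction(rankedP, q,
                                 Biostrings::AAStringSet(panel), topK = 4)
    brute <- vapply(panel, function(s) pairwiseIdentity(s, q), numeric(1))
    expect_equal(outP$min, min(brute))
    expect_equal(outP$max, max(brute))
    expect_equal(outP$identities$identity, unname(brute))

    expect_error(identityVsPrediction(rankedP, q,
        Biostrings::AAStringSet(panel), topK = 9), "exceeds")
})
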