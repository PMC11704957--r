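# Synthetic labelled datasets and homology fixtures with known ground
# truth.

#' Generate a synthetic fitness landscape
#'
#' Builds a mutant cloud around a random reference sequence, emulating the
#' statistical structure of an engineered training set (many variants of
#' one wild type at high identity): a library of `nSites` functional sites
#' is planted, each carrying one alternative residue, and every variant
#' includes each library substitution independently with probability
#' `mutationRate * length / nSites` — so the expected number of mutations
#' per variant is `mutationRate * length` and the expected identity to the
#' reference is `1 - mutationRate` (96.5% at the default rate). True
#' fitness is additive over the functional sites: the site coefficient
#' (drawn once from N(0, 1)) times the standardized hydropathy of the
#' residue present; labels add N(0, noiseSd^2) measurement noise.
#'
#' @param seed integer seed; all draws are derived from it and
#'   regeneration is bit-identical.
#' @param n number of variants (>= 10).
#' @param length sequence length (default 120).
#' @param nSites number of functional sites (default 16).
#' @param mutationRate expected per-position mutation rate (default 0.035).
#' @param noiseSd sd of the label noise (default 0.3).
#' @return a [SyntheticLandscape-class]; variant ids are `var0001`, ...
#' @examples
#' ls <- generateLandscape(seed = 1, n = 20)
#' landscapeDataset(ls)
#' @export
generateLandscape <- function(seed, n, length = 120L, nSites = 16L,
                              mutationRate = 0.035, noiseSd = 0.3) {
    n <- as.integer(n); length <- as.integer(length)
    nSites <- as.integer(nSites)
    if (n < 10L) stop("n must be >= 10", call. = FALSE)
    if (nSites < 1L || nSites >= length)
        stop("nSites must be in [1, length)", call. = FALSE)
    if (mutationRate <= 0 || mutationRate >= 1)
        stop("mutationRate must be in (0, 1)", call. = FALSE)
    if (noiseSd < 0) stop("noiseSd must be >= 0", call. = FALSE)
    q <- mutationRate * length / nSites
    if (q >= 1)
        stop("mutationRate * length / nSites must be < 1", call. = FALSE)
    .withSeed(.deriveSeed("landscape", seed), {
        ref <- sample(.AA20, length, replace = TRUE)
        sites <- sort(sample.int(length, nSites))
        alts <- vapply(sites,
                       function(p) sample(setdiff(.AA20, ref[p]), 1L), "")
        weights <- stats::rnorm(nSites)
        hydro <- .physTable[, "hydropathy"]
        seqs <- character(n)
        fitness <- numeric(n)
        for (i in seq_len(n)) {
            v <- ref
            inc <- stats::runif(nSites) < q
            v[sites[inc]] <- alts[inc]
            seqs[i] <- paste(v, collapse = "")
            fitness[i] <- sum(weights * hydro[v[sites]])
        }
        noise <- stats::rnorm(n, 0, noiseSd)
        ids <- sprintf("var%04d", seq_len(n))
        dataset <- FitnessDataset(stats::setNames(seqs, ids),
                                  fitness + noise,
                                  measureName = "synthetic_fitness",
                                  transform = "identity")
        new("SyntheticLandscape", dataset = dataset,
            reference = paste(ref, collapse = ""), sites = sites,
            siteWeights = weights, altResidues = alts,
            trueFitness = fitness, noise = noise, noiseSd = noiseSd,
            seed = as.integer(seed))
    })
}

#' Generate a toy m8 hit file with planted filter outcomes
#'
#' Writes `n` synthetic hits with known pass/fail labels against the
#' default thresholds of [filterHits()] (E-value < 1e-3, bidirectional
#' coverage >= 0.9): a fraction fails the E-value rule, a fraction fails
#' the coverage rule (on a random side), and the rest pass both.
#'
#' @param seed integer seed.
#' @param n number of hits.
#' @param fracFailEvalue,fracFailCov fractions in \[0, 1\], sum at most 1.
#' @param path optional path; when given the 14-column m8 content is
#'   written there.
#' @return list with `hits` (parsed data.frame), `content` (the m8 lines)
#'   and `expectedSurvivors` (ids of hits that pass both filters, in file
#'   order).
#' @export
generateToyHits <- function(seed, n, fracFailEvalue = 0,
                            fracFailCov = 0, path = NULL) {
    n <- as.integer(n)
    if (fracFailEvalue < 0 || fracFailCov < 0 ||
        fracFailEvalue + fracFailCov > 1)
        stop("fractions must be in [0, 1] with sum <= 1", call. = FALSE)
    .withSeed(.deriveSeed("toyhits", seed), {
        nE <- round(n * fracFailEvalue)
        nC <- round(n * fracFailCov)
        if (nE + nC > n) nC <- n - nE
        status <- sample(c(rep("failE", nE), rep("failC", nC),
                           rep("pass", n - nE - nC)))
        qlen <- sample(100:400, n, replace = TRUE)
        tlen <- sample(100:400, n, replace = TRUE)
        span <- function(len, cov) {
            # inclusive span covering at least (>=) or strictly less (<)
            # than cov of len
            need <- ceiling(cov * len)
            start <- sample.int(len - need + 1L, 1L)
            c(start, start + need - 1L)
        }
        shortSpan <- function(len, cov) {
            most <- ceiling(cov * len) - 1L  # span/len < cov guaranteed
            take <- sample.int(max(most, 1L), 1L)
            start <- sample.int(len - take + 1L, 1L)
            c(start, start + take - 1L)
        }
        rows <- character(n)
        for (i in seq_len(n)) {
            ev <- if (status[i] == "failE")
                10^stats::runif(1, -3, 1) else 10^stats::runif(1, -50, -4)
            if (status[i] == "failC") {
                side <- sample(c("q", "t"), 1L)
                qs <- if (side == "q") shortSpan(qlen[i], 0.9)
                      else span(qlen[i], 0.9)
                ts <- if (side == "t") shortSpan(tlen[i], 0.9)
                      else span(tlen[i], 0.9)
            } else {
                qs <- span(qlen[i], 0.9)
                ts <- span(tlen[i], 0.9)
            }
            al <- max(qs[2] - qs[1], ts[2] - ts[1]) + 1L
            pid <- round(stats::runif(1, 30, 100), 1)
            rows[i] <- paste(c("query", sprintf("hit%04d", i), pid, al,
                               round(al * (1 - pid / 100)), 0,
                               qs[1], qs[2], ts[1], ts[2],
                               sprintf("%.3e", ev), round(al * 2.1, 1),
                               qlen[i], tlen[i]), collapse = "\t")
        }
        tmp <- if (is.null(path)) tempfile(fileext = ".m8") else path
        writeLines(rows, tmp)
        hits <- readHitsM8(tmp)
        if (is.null(path)) unlink(tmp)
        list(hits = hits, content = rows,
             expectedSurvivors = hits$target_id[status == "pass"])
    })
}

#' Sample a fresh variant panel from an existing landscape
#'
#' Draws additional variants from the same reference, functional-site
#' library and fitness weights as `landscape`, using an independent seed —
#' e.g. a candidate panel to rank with a model trained on the original
#' cloud.
#'
#' @param landscape a [SyntheticLandscape-class].
#' @param n number of new variants.
#' @param seed integer seed for the new draws.
#' @param mutationRate expected per-position mutation rate (defaults to
#'   the landscape's implied rate via its inclusion probability).
#' @param prefix id prefix for the new variants.
#' @return a [SyntheticLandscape-class] sharing reference, sites and
#'   weights with `landscape`, holding the new variants.
#' @export
sampleVariants <- function(landscape, n, seed,
                           mutationRate = 0.035, prefix = "panel") {
    n <- as.integer(n)
    ref <- strsplit(landscape@reference, "", fixed = TRUE)[[1L]]
    sites <- landscape@sites
    q <- mutationRate * length(ref) / length(sites)
    hydro <- .physTable[, "hydropathy"]
    .withSeed(.deriveSeed("panel", seed), {
        seqs <- character(n)
        fitness <- numeric(n)
        for (i in seq_len(n)) {
            v <- ref
            inc <- stats::runif(length(sites)) < q
            v[sites[inc]] <- landscape@altResidues[inc]
            seqs[i] <- paste(v, collapse = "")
            fitness[i] <- sum(landscape@siteWeights * hydro[v[sites]])
        }
        noise <- stats::rnorm(n, 0, landscape@noiseSd)
        ids <- sprintf("%s%04d", prefix, seq_len(n))
        dataset <- FitnessDataset(stats::setNames(seqs, ids),
                                  fitness + noise,
                                  measureName = "synthetic_fitness",
                                  transform = "identity")
        new("SyntheticLandscape", dataset = dataset,
            reference = landscape@reference, sites = sites,
            siteWeights = landscape@siteWeights,
            altResidues = landscape@altResidues, trueFitness = fitness,
            noise = noise, noiseSd = landscape@noiseSd,
            seed = as.integer(seed))
    })
}
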