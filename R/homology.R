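# Homology-hit parsing and filtering, alignment identity, redundancy
# removal, and candidate ranking.

.M8_COLS <- c("query_id", "target_id", "percent_identity", "aln_len",
              "mismatches", "gap_opens", "q_start", "q_end", "t_start",
              "t_end", "evalue", "bit_score")
.M8_NUMERIC <- setdiff(.M8_COLS, c("query_id", "target_id"))

#' Parse a BLAST/MMseqs2 tabular (m8) hit file
#'
#' Accepts the standard 12-column outfmt-6 dialect, optionally extended
#' with `qlen` and `tlen` as columns 13-14. When the length columns are
#' absent they may be supplied from sequence sets; positions are 1-based
#' inclusive, as standard for the format.
#'
#' @param path tab-separated hit file.
#' @param querySeqs,targetSeqs optional named `AAStringSet`s (or anything
#'   [readFasta()] returns) used to fill in `q_len` / `t_len` when the file
#'   has only 12 columns.
#' @return data.frame with columns `query_id`, `target_id`,
#'   `percent_identity`, `aln_len`, `mismatches`, `gap_opens`, `q_start`,
#'   `q_end`, `t_start`, `t_end`, `evalue`, `bit_score`, `q_len`, `t_len`
#'   (the last two possibly NA).
#' @export
readHitsM8 <- function(path, querySeqs = NULL, targetSeqs = NULL) {
    if (!file.exists(path))
        stop(sprintf("file not found: %s", path), call. = FALSE)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L)
        return(.emptyHits())
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    bad <- which(!(nf %in% c(12L, 14L)))
    if (length(bad))
        stop(sprintf("line %d has %d columns (expected 12 or 14)",
                     bad[1L], nf[bad[1L]]), call. = FALSE)
    if (length(unique(nf)) != 1L)
        stop("mixed column counts in hit file", call. = FALSE)
    m <- do.call(rbind, parts)
    hits <- data.frame(query_id = m[, 1L], target_id = m[, 2L],
                       stringsAsFactors = FALSE)
    for (j in 3:12) {
        v <- suppressWarnings(as.numeric(m[, j]))
        if (any(is.na(v)))
            stop(sprintf("unparseable number '%s' at line %d, column %d",
                         m[which(is.na(v))[1L], j], which(is.na(v))[1L], j),
                 call. = FALSE)
        hits[[.M8_COLS[j]]] <- v
    }
    if (ncol(m) == 14L) {
        for (j in 13:14) {
            v <- suppressWarnings(as.numeric(m[, j]))
            if (any(is.na(v)))
                stop(sprintf("unparseable number '%s' at line %d, column %d",
                             m[which(is.na(v))[1L], j],
                             which(is.na(v))[1L], j), call. = FALSE)
            hits[[c("q_len", "t_len")[j - 12L]]] <- v
        }
    } else {
        hits$q_len <- .lookupLen(hits$query_id, querySeqs)
        hits$t_len <- .lookupLen(hits$target_id, targetSeqs)
    }
    hits
}

.lookupLen <- function(ids, seqs) {
    if (is.null(seqs)) return(rep(NA_real_, length(ids)))
    w <- stats::setNames(Biostrings::width(seqs), names(seqs))
    as.numeric(w[ids])
}

.emptyHits <- function() {
    out <- data.frame(query_id = character(), target_id = character(),
                      stringsAsFactors = FALSE)
    for (nm in .M8_NUMERIC) out[[nm]] <- numeric()
    out$q_len <- numeric(); out$t_len <- numeric()
    out
}

#' Write hits in m8 (14-column) format
#'
#' @param hits data.frame as returned by [readHitsM8()] (with `q_len`,
#'   `t_len`).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeHitsM8 <- function(hits, path) {
    cols <- c(.M8_COLS, "q_len", "t_len")
    out <- hits[, cols]
    out$evalue <- sprintf("%.3e", out$evalue)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Filter homology hits by E-value and bidirectional coverage
#'
#' Keeps hits whose E-value is strictly below `maxEvalue` and whose
#' alignment spans at least `minBidirCov` of BOTH the query and the target
#' length (bidirectional length overlap); coverage bounds are inclusive.
#' Input order is preserved and the operation is idempotent.
#'
#' @param hits data.frame from [readHitsM8()]; `q_len` and `t_len` must be
#'   known for every hit.
#' @param maxEvalue strict upper bound on the E-value (default `1e-3`).
#' @param minBidirCov minimum per-side coverage fraction (default 0.9).
#' @return the surviving subset of `hits`, original order.
#' @export
filterHits <- function(hits, maxEvalue = 1e-3, minBidirCov = 0.9) {
    if (nrow(hits) == 0L) return(hits)
    if (any(is.na(hits$q_len)) || any(is.na(hits$t_len))) {
        i <- which(is.na(hits$q_len) | is.na(hits$t_len))[1L]
        stop(sprintf("missing sequence length for hit %s -> %s",
                     hits$query_id[i], hits$target_id[i]), call. = FALSE)
    }
    qcov <- (hits$q_end - hits$q_start + 1) / hits$q_len
    tcov <- (hits$t_end - hits$t_start + 1) / hits$t_len
    keep <- hits$evalue < maxEvalue & qcov >= minBidirCov &
        tcov >= minBidirCov
    hits[keep, , drop = FALSE]
}

#' Global pairwise sequence identity
#'
#' Aligns two protein sequences end-to-end (Needleman-Wunsch, BLOSUM62,
#' affine gaps with opening 11 and extension 1) and returns the fraction of
#' alignment columns with identical residues; gap columns count in the
#' denominator. Symmetric, equals 1 exactly for identical sequences.
#'
#' @param a,b sequences (character, `AAString`, or length-one
#'   `AAStringSet`).
#' @return identity in \[0, 1\].
#' @examples
#' pairwiseIdentity("AAAAAAAAAA", "AAAAAAAAAC")  # 0.9
#' @export
pairwiseIdentity <- function(a, b) {
    a <- .asSequenceString(a); b <- .asSequenceString(b)
    if (!nzchar(a) || !nzchar(b))
        stop("sequences must be non-empty", call. = FALSE)
    if (a == b) return(1)
    aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
        substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    sum(p == s) / length(p)
}

#' Greedy identity-based redundancy removal
#'
#' Incremental clustering: records are visited sorted by length descending
#' then id ascending; each record joins the first existing representative
#' it matches with identity at least `threshold`, otherwise it founds a new
#' cluster. Every non-representative therefore maps to a representative
#' with identity >= threshold.
#'
#' @param records named `AAStringSet` (or [FitnessDataset-class]).
#' @param threshold identity threshold in (0, 1\], default 0.9.
#' @return list with `representatives` (an `AAStringSet` subset, in
#'   visiting order) and `assignment` (named character: every input id ->
#'   its representative id).
#' @export
redundancyFilter <- function(records, threshold = 0.9) {
    if (is(records, "FitnessDataset")) records <- sequenceSet(records)
    if (threshold <= 0 || threshold > 1)
        stop("threshold must be in (0, 1]", call. = FALSE)
    ids <- names(records)
    ord <- order(-Biostrings::width(records), ids)
    seqs <- as.character(records)
    repIds <- character()
    assignment <- stats::setNames(character(length(ids)), ids[ord])
    for (i in ord) {
        id <- ids[i]
        joined <- NA_character_
        for (r in repIds) {
            if (pairwiseIdentity(seqs[i], seqs[r]) >= threshold) {
                joined <- r
                break
            }
        }
        if (is.na(joined)) {
            repIds <- c(repIds, id)
            assignment[id] <- id
        } else {
            assignment[id] <- joined
        }
    }
    list(representatives = records[repIds], assignment = assignment)
}

#' Rank candidate sequences by predicted fitness
#'
#' Predicts every record's fitness from its embedding and sorts by
#' predicted value descending, ties by id ascending; ranks are dense and
#' 1-based.
#'
#' @param model a [TrainedRanker-class].
#' @param embeddings an [EmbeddingMatrix-class] covering all records.
#' @param records named `AAStringSet` or character vector of candidate ids.
#' @return data.frame with columns `rank`, `id`, `predicted_value`,
#'   `identity_to_query` (NA until computed).
#' @export
rankCandidates <- function(model, embeddings, records) {
    ids <- if (is.character(records) && is.null(names(records))) records
           else names(records)
    if (is.null(ids) || any(!nzchar(ids)))
        stop("records must be named", call. = FALSE)
    miss <- setdiff(ids, names(embeddings))
    if (length(miss))
        stop(sprintf("no embedding for record '%s'", miss[1L]),
             call. = FALSE)
    pred <- predictFitness(model, embeddings[ids])
    ord <- order(-pred, ids)
    data.frame(rank = seq_along(ids), id = ids[ord],
               predicted_value = as.numeric(pred[ord]),
               identity_to_query = NA_real_, stringsAsFactors = FALSE)
}

#' Identity-to-query diagnostic for a ranked panel
#'
#' Computes the global-alignment identity of the top `topK` ranked
#' candidates to the query sequence, and the Spearman correlation between
#' rank and identity as a diversity diagnostic (a weak correlation means
#' the ranker is not simply recapitulating sequence similarity).
#'
#' @param ranked data.frame from [rankCandidates()].
#' @param query the query sequence (character or `AAString`).
#' @param records named `AAStringSet` holding the candidate sequences.
#' @param topK number of top candidates to examine (default 50).
#' @return list with `identities` (data.frame of `rank`, `id`,
#'   `identity`), `min`, `max`, and `rhoRankIdentity` (NA when undefined,
#'   e.g. all identities equal).
#' @export
identityVsPrediction <- function(ranked, query, records, topK = 50L) {
    topK <- as.integer(topK)
    if (topK > nrow(ranked))
        stop("topK exceeds the number of ranked candidates", call. = FALSE)
    top <- ranked[seq_len(topK), ]
    q <- .asSequenceString(query)
    seqs <- as.character(records)
    idn <- vapply(top$id, function(id) pairwiseIdentity(seqs[[id]], q),
                  numeric(1L))
    rho <- tryCatch(spearmanRho(top$rank, idn),
                    error = function(e) NA_real_)
    list(identities = data.frame(rank = top$rank, id = top$id,
                                 identity = as.numeric(idn),
                                 stringsAsFactors = FALSE),
         min = min(idn), max = max(idn), rhoRankIdentity = rho)
}
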