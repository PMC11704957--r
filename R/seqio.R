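# Reading and writing protein sequences, labels, and ranked tables.

#' Read a protein FASTA file
#'
#' Reads a (possibly multi-line) FASTA file, uppercases residues, strips
#' terminal `*` stop characters, and validates that sequences contain only
#' the 20 standard amino acids plus `X`. The id is the first whitespace-
#' separated token of the header; the remainder is kept as the description.
#'
#' @param path path to a FASTA file.
#' @return an `AAStringSet` named by id, with the per-record description in
#'   `mcols(x)$description`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a first", "MKV", ">b", "GG"), f)
#' readFasta(f)
#' @export
readFasta <- function(path) {
    if (!file.exists(path))
        stop(sprintf("file not found: %s", path), call. = FALSE)
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L)
        stop("no sequences", call. = FALSE)
    headers <- names(raw)
    ids <- sub("\\s.*$", "", headers)
    desc <- ifelse(grepl("\\s", headers),
                   sub("^\\S+\\s+", "", headers), "")
    if (any(!nzchar(ids)))
        stop("FASTA header with empty id", call. = FALSE)
    if (anyDuplicated(ids))
        stop(sprintf("duplicate sequence id '%s'",
                     ids[duplicated(ids)][1L]), call. = FALSE)
    seqs <- toupper(gsub("\\s", "", as.character(raw)))
    seqs <- sub("\\*+$", "", seqs)
    if (any(!nzchar(seqs)))
        stop(sprintf("empty sequence for id '%s'",
                     ids[!nzchar(seqs)][1L]), call. = FALSE)
    for (k in seq_along(seqs)) .checkResidues(seqs[k], ids[k])
    out <- Biostrings::AAStringSet(seqs)
    names(out) <- ids
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
    out
}

#' Write sequences to FASTA
#'
#' @param x named `AAStringSet` or `FitnessDataset` (sequences only).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeFasta <- function(x, path) {
    if (is(x, "FitnessDataset")) x <- sequenceSet(x)
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' Read a labelled FASTA into a FitnessDataset
#'
#' Two dialects are accepted. In the header dialect the last
#' whitespace-separated token of each FASTA header is the measurement, e.g.
#' `">wt some text 4.2"`. In the sidecar dialect `labels` points to a
#' 2-column tab-separated file (header row `id<TAB>value`) paired with a
#' plain FASTA. Both produce identical datasets for the same content.
#'
#' @param path FASTA file.
#' @param labels optional path to a TSV of `id`, `value`.
#' @param measureName name of the measure.
#' @param transform `"log10"` (default, suited to kinetic parameters that
#'   span orders of magnitude; requires positive values) or `"identity"`.
#' @return a [FitnessDataset-class] with values aligned to records in file
#'   order; raw values are stored and the transform is applied lazily at
#'   training time.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">wt 4.2", "MKV"), f)
#' readFitnessFasta(f)
#' @export
readFitnessFasta <- function(path, labels = NULL, measureName = "fitness",
                             transform = c("log10", "identity")) {
    transform <- match.arg(transform)
    if (is.null(labels)) {
        if (!file.exists(path))
            stop(sprintf("file not found: %s", path), call. = FALSE)
        raw <- Biostrings::readBStringSet(path)
        if (length(raw) == 0L) stop("no sequences", call. = FALSE)
        headers <- names(raw)
        tokens <- sub("^.*\\s", "", headers)
        values <- suppressWarnings(as.numeric(tokens))
        bad <- !grepl("\\s", headers) | !is.finite(values)
        if (any(bad))
            stop(sprintf(
                "header without a parseable numeric measure: '>%s'",
                headers[bad][1L]), call. = FALSE)
        # Re-parse sequences through the validating reader semantics:
        ids <- sub("\\s.*$", "", headers)
        if (anyDuplicated(ids))
            stop(sprintf("duplicate sequence id '%s'",
                         ids[duplicated(ids)][1L]), call. = FALSE)
        seqs <- toupper(gsub("\\s", "", as.character(raw)))
        seqs <- sub("\\*+$", "", seqs)
        for (k in seq_along(seqs)) .checkResidues(seqs[k], ids[k])
        sset <- Biostrings::AAStringSet(seqs)
        names(sset) <- ids
    } else {
        sset <- readFasta(path)
        tab <- utils::read.delim(labels, header = TRUE, sep = "\t",
                                 colClasses = c("character", "numeric"))
        if (ncol(tab) < 2L)
            stop("label TSV must have columns id, value", call. = FALSE)
        miss <- setdiff(tab[[1L]], names(sset))
        if (length(miss))
            stop(sprintf("label id '%s' absent from FASTA", miss[1L]),
                 call. = FALSE)
        missing_lab <- setdiff(names(sset), tab[[1L]])
        if (length(missing_lab))
            stop(sprintf("no label for sequence '%s'", missing_lab[1L]),
                 call. = FALSE)
        values <- tab[[2L]][match(names(sset), tab[[1L]])]
        if (any(!is.finite(values)))
            stop("non-finite value in label TSV", call. = FALSE)
    }
    FitnessDataset(sset, values, measureName = measureName,
                   transform = transform)
}

#' Write a FitnessDataset as labelled FASTA
#'
#' Writes the header dialect read by [readFitnessFasta()]: the raw value is
#' appended as the last header token at full precision.
#'
#' @param dataset a [FitnessDataset-class].
#' @param path output FASTA path.
#' @return invisibly, `path`.
#' @export
writeFitnessFasta <- function(dataset, path) {
    ids <- names(dataset)
    vals <- sprintf("%.17g", fitnessValues(dataset))
    seqs <- as.character(sequenceSet(dataset))
    con <- file(path, "w")
    on.exit(close(con))
    for (k in seq_along(ids))
        writeLines(c(sprintf(">%s %s", ids[k], vals[k]), seqs[k]), con)
    invisible(path)
}

#' Write a ranked candidate table
#'
#' Writes a TSV with columns `rank`, `id`, `predicted_value`,
#' `identity_to_query` (empty where unknown). The input must already be
#' ranked (dense 1-based ranks, predicted values non-increasing), as
#' produced by [rankCandidates()].
#'
#' @param candidates data.frame with columns `rank`, `id`,
#'   `predicted_value`, and optionally `identity_to_query`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeRankedTable <- function(candidates, path) {
    req <- c("rank", "id", "predicted_value")
    if (!all(req %in% names(candidates)))
        stop("candidates must have columns rank, id, predicted_value",
             call. = FALSE)
    n <- nrow(candidates)
    if (n > 0L) {
        if (!identical(as.integer(candidates$rank), seq_len(n)))
            stop("candidates must be sorted with dense 1-based ranks; rank first",
                 call. = FALSE)
        if (is.unsorted(-candidates$predicted_value))
            stop("predicted values must be non-increasing with rank; rank first",
                 call. = FALSE)
    }
    idc <- if ("identity_to_query" %in% names(candidates))
        candidates$identity_to_query else rep(NA_real_, n)
    out <- data.frame(rank = candidates$rank, id = candidates$id,
                      predicted_value = sprintf("%.6f",
                                                candidates$predicted_value),
                      identity_to_query = ifelse(is.na(idc), "",
                                                 sprintf("%.6f", idc)),
                      stringsAsFactors = FALSE)
    if (n == 0L)
        out <- data.frame(rank = integer(), id = character(),
                          predicted_value = character(),
                          identity_to_query = character())
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a ranked candidate table written by [writeRankedTable()]
#'
#' @param path TSV path.
#' @return data.frame with columns `rank`, `id`, `predicted_value`,
#'   `identity_to_query` (NA where empty).
#' @export
readRankedTable <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = c("integer", "character",
                                            "numeric", "character"))
    tab$identity_to_query <- suppressWarnings(
        as.numeric(ifelse(nzchar(tab$identity_to_query),
                          tab$identity_to_query, NA)))
    tab
}
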