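# Internal helpers: amino-acid tables, deterministic hashing, scoped RNG.

# The 20 standard residues, plus X for unknown/ambiguous.
.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
.AA21 <- c(.AA20, "X")

# Physicochemical scales: Kyte-Doolittle hydropathy, residue volume (A^3),
# net charge at pH 7, polarity and aromaticity indicators. Hydropathy and
# volume are standardized over the 20 residues; X gets the column mean (0).
.physTable <- local({
    kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
            E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
            M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
            Y = -1.3, V = 4.2)
    vol <- c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
             Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
             L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
             S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)
    chg <- c(A = 0, R = 1, N = 0, D = -1, C = 0, Q = 0, E = -1, G = 0,
             H = 0.1, I = 0, L = 0, K = 1, M = 0, F = 0, P = 0, S = 0,
             T = 0, W = 0, Y = 0, V = 0)
    pol <- c(A = 0, R = 1, N = 1, D = 1, C = 0, Q = 1, E = 1, G = 0,
             H = 1, I = 0, L = 0, K = 1, M = 0, F = 0, P = 0, S = 1,
             T = 1, W = 0, Y = 1, V = 0)
    aro <- c(A = 0, R = 0, N = 0, D = 0, C = 0, Q = 0, E = 0, G = 0,
             H = 1, I = 0, L = 0, K = 0, M = 0, F = 1, P = 0, S = 0,
             T = 0, W = 1, Y = 1, V = 0)
    zs <- function(v) (v - mean(v)) / stats::sd(v)
    m <- cbind(hydropathy = zs(kd), volume = zs(vol), charge = chg,
               polarity = pol, aromaticity = aro)
    rbind(m[.AA20, ], X = rep(0, 5))
})

.MOD31 <- 2147483647  # 2^31 - 1, keeps every derived seed a valid R integer

# Polynomial rolling hash of a string, in [0, 2^31 - 1).
.strHash <- function(s) {
    h <- 0
    for (x in utf8ToInt(s)) h <- (h * 31 + x) %% .MOD31
    h
}

# Fold any mix of integers/strings into one reproducible seed.
.deriveSeed <- function(...) {
    parts <- list(...)
    h <- 7
    for (p in parts) {
        h <- (h * 131 + .strHash(paste0(p, ""))) %% .MOD31
    }
    as.integer(h %% (.MOD31 - 2L) + 1L)
}

# Evaluate expr under a given seed without disturbing the caller's RNG state.
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

.assertScalarNumber <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
        stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}

# Coerce a sequence argument (character, AAString, length-1 AAStringSet)
# to a plain upper-case character scalar.
.asSequenceString <- function(x) {
    if (is(x, "XStringSet")) {
        if (length(x) != 1L)
            stop("expected a single sequence", call. = FALSE)
        x <- as.character(x)
    } else if (is(x, "XString")) {
        x <- as.character(x)
    }
    if (!is.character(x) || length(x) != 1L || is.na(x))
        stop("sequence must be a single character string", call. = FALSE)
    toupper(x)
}

.checkResidues <- function(seq, id = NULL) {
    bad <- regexpr(sprintf("[^%s]", paste(.AA21, collapse = "")), seq)
    if (bad > 0L) {
        where <- if (is.null(id)) "" else sprintf(" in sequence '%s'", id)
        stop(sprintf("invalid residue '%s' at position %d%s",
                     substr(seq, bad, bad), bad, where), call. = FALSE)
    }
    invisible(TRUE)
}
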