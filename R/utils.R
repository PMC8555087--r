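# internal helpers shared across modules

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    expr
}

# derive a stream seed from a master seed; kept < 2^31
deriveSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

revComp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# TRUE per context string iff any of its 6-mers is in `hexamers`
# (set membership, so arbitrarily large signal sets stay cheap)
containsAnyHexamer <- function(ctx, hexamers) {
    vapply(ctx, function(s) {
        n <- nchar(s)
        if (n < 6L) return(FALSE)
        starts <- seq_len(n - 5L)
        any(substring(s, starts, starts + 5L) %in% hexamers)
    }, logical(1L), USE.NAMES = FALSE)
}

# first differences as sense-strand distance helper
stopifnotScalar <- function(x, what) {
    if (length(x) != 1L || is.na(x))
        stop(what, " must be a single non-missing value")
    invisible(x)
}
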