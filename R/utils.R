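# internal helpers: scoped RNG and derived seeds, light logging

# run expr under a fixed seed without disturbing the caller's RNG stream
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

# derive a per-stage seed from a master seed; stays inside 32-bit range
deriveSeed <- function(seed, stage, k = 0L) {
    h <- sum(utf8ToInt(stage)) %% 1000L
    (as.integer(seed) * 7919L + h * 131L + as.integer(k)) %% 2147483399L
}

dnMessage <- function(fmt, ..., verbose = TRUE) {
    if (isTRUE(verbose)) message(sprintf(fmt, ...))
    invisible(NULL)
}

# filename-safe version of a group label
slugify <- function(x) {
    x <- gsub("[^A-Za-z0-9]+", "_", x)
    gsub("^_+|_+$", "", x)
}
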