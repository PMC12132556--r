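# Internal helpers: scoped RNG, seed derivation, lightweight logging.

# Evaluate expr with a private Mersenne-Twister stream; the caller's
# .Random.seed is untouched.
withSeed <- function(seed, expr) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = env)
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister")
    expr
}

# Mix several non-negative integers into one seed < 2^31.
deriveSeed <- function(...) {
    parts <- as.numeric(c(...))
    h <- 0
    for (p in parts) h <- (h * 48271 + p + 1) %% 2147483647
    as.integer(h)
}

cfLog <- function(msg, ..., file = NULL, verbose = TRUE) {
    line <- sprintf(msg, ...)
    if (!is.null(file))
        cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), line, "\n",
            file = file, sep = "", append = TRUE)
    if (verbose) message(line)
    invisible(line)
}

# Encode alignment rows as an integer matrix (columns = sequences) for
# vectorised Hamming arithmetic.
msaCodeMatrix <- function(rows) {
    L <- nchar(rows[[1L]])
    vapply(rows, function(r) utf8ToInt(r), integer(L), USE.NAMES = FALSE)
}
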