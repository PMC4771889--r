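# Internal helpers: seeded evaluation that does not disturb the caller's RNG
# stream, and a deterministic integer hash for deriving per-subproblem seeds
# from a master seed.

.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(force(expr))
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (has_old) {
            assign(".Random.seed", old, envir = globalenv())
        } else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE)) {
            rm(".Random.seed", envir = globalenv())
        }
    })
    set.seed(seed)
    force(expr)
}

# Polynomial hash modulo 2^31 - 1; exact in double arithmetic because every
# intermediate stays below 2^53.
.seedHash <- function(...) {
    vals <- abs(as.numeric(unlist(list(...))))
    h <- 17
    for (v in vals) h <- (h * 1000003 + v) %% 2147483647
    as.integer(h)
}

# sample() that never interprets a length-1 vector as 1:n
.sampleVec <- function(x, size) {
    if (length(x) == 1L) return(rep(x, length.out = size))
    sample(x, size)
}
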