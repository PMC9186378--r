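# internal helpers shared across modules

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(seed)
    }
    force(expr)
}

stopIf <- function(cond, fmt, ...) if (cond) stop(sprintf(fmt, ...), call. = FALSE)

# mean of log2 expression per gene for a set of columns
.rowMeansCols <- function(m, cols) rowMeans(m[, cols, drop = FALSE])
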