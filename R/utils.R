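## Internal helpers.

## Evaluate `code` under a fixed RNG seed without disturbing the caller's
## RNG stream.
withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Derive a child seed from a base seed and a small stream offset, kept
## within 32-bit integer range.
childSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) * 1009 + offset) %% 2147483647)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
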