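## Internal helpers.

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG
## state afterwards so that library calls never perturb user RNG flow.
withSeed <- function(seed, code) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(as.integer(seed))
    force(code)
}

## Derive a child seed from a base seed and a stream index, staying
## within the 32-bit signed integer range.
childSeed <- function(seed, stream) {
    as.integer((as.numeric(seed) * 7919 + 104729 * stream) %% .Machine$integer.max)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

## Numerically stable softmax of a vector of log scores.
softmaxVec <- function(y) {
    e <- exp(y - max(y))
    e / sum(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
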