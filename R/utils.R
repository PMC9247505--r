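# Deterministic substream seeds: each (global seed, center, stream) pair gets
# its own RNG seed, so adding a center or changing one center's group sizes
# never perturbs another center's draws.
.streamSeed <- function(seed, ...) {
    key <- paste(c(...), collapse = "/")
    h <- 0
    for (cc in utf8ToInt(key)) h <- (h * 131 + cc) %% 2147483587
    as.integer((as.numeric(seed) * 48271 + h + 1) %% 2147483587)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE)) {
            rm(".Random.seed", envir = globalenv())
        }
    })
    set.seed(seed)
    force(expr)
}
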