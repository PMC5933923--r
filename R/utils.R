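# Evaluate expr with a temporary RNG seed; the caller's RNG state is
# untouched. seed = NULL uses (and advances) the current stream.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(eval.parent(substitute(expr)))
    hadSeed <- exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)
    if (hadSeed)
        oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (hadSeed)
            assign(".Random.seed", oldSeed, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}
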