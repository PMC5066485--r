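# Evaluate expr with a fixed RNG seed, leaving the caller's RNG state
# untouched. All generators route their randomness through this so a fixed
# seed gives bit-identical output regardless of surrounding code.
with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  expr
}
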