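# Run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards. Keeps all generator randomness behind one seed
# without clobbering user RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# squared Euclidean distances between matched rows
rowSqDist <- function(A, B) rowSums((A - B)^2)
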