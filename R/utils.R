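## Small shared helpers: scoped RNG state so seeded generators do not
## disturb the caller's random stream.

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

random_rna <- function(n, bases = RNA_BASES, prob = NULL) {
  paste(sample(bases, n, replace = TRUE, prob = prob), collapse = "")
}
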