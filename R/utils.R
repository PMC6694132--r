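# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Canonicalize an unordered pair table so that id_a < id_b lexicographically.
canonicalizePairs <- function(df, a = "id_a", b = "id_b") {
  swap <- as.character(df[[a]]) > as.character(df[[b]])
  if (any(swap)) {
    tmp <- df[[a]][swap]
    df[[a]][swap] <- df[[b]][swap]
    df[[b]][swap] <- tmp
  }
  df
}

# Key of a canonical unordered pair.
pairKey <- function(a, b) {
  paste(pmin(as.character(a), as.character(b)),
        pmax(as.character(a), as.character(b)), sep = "\r")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
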