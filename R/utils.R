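# Internal helpers.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so seeded pipeline stages do not perturb the global stream.
# A NULL seed uses (and advances) the current stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible sub-seed from a parent seed (kept within 32-bit range).
subSeed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

# Canonical taxon-name form: case-folded, whitespace-collapsed.
canonicalTaxon <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

stopIfNot01 <- function(x, what) {
  if (any(x < 0 | x > 1, na.rm = TRUE))
    stop(what, " must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}
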