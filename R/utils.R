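# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministically mix a master seed with integer tags into a new seed
# below 2^31. Multiplier kept small so products stay exact in doubles.
mix_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (v in c(...)) {
    h <- (h * 69069 + as.numeric(v) + 1) %% 2147483647
  }
  as.integer(h)
}

# hash an integer set order-independently-ish (sorted polynomial hash)
hash_index_set <- function(idx) {
  h <- 0
  for (v in sort(as.integer(idx))) h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
}
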