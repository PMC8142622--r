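# Internal helpers: deterministic string hashing and scoped RNG.

# Polynomial rolling hash mod 2^31 - 1 (Mersenne prime). All intermediate
# products stay below 2^53, so the arithmetic is exact in doubles and the
# result is identical on every platform. `mult` and `init` select the hash
# family; two families give the pair of base hashes used for double hashing.
.HASH_P <- 2147483647

.hash_string <- function(s, mult = 33, init = 5381) {
  h <- init
  for (c in utf8ToInt(s)) h <- (h * mult + c) %% .HASH_P
  h
}

.hash_strings <- function(xs, mult = 33, init = 5381) {
  vapply(xs, .hash_string, numeric(1), mult = mult, init = init,
         USE.NAMES = FALSE)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Mix a user seed with a stage tag so that distinct pipeline stages draw
# from distinct, reproducible streams. Result stays below 2^31.
.derive_seed <- function(seed, tag) {
  (.hash_string(tag, mult = 53, init = seed %% .HASH_P)) %% 2147483629
}

.is_missing_chr <- function(x) is.na(x) | x == ""

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
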