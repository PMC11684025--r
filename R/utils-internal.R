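# Internal helpers: platform-independent hashing and scoped RNG.

# 32-bit FNV-1a over a character string (UTF-8 bytes).
# Exact 32-bit wraparound multiplication is done on doubles by splitting the
# accumulator into 16-bit halves; all intermediates stay below 2^53.
.fnv1a32 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    # XOR of h (< 2^32) with a byte: only the low 8 bits change
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b))
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * prime) %% 65536) * 65536 + lo * prime
    h <- h %% 4294967296
  }
  h
}

# Vectorised convenience wrapper
.fnv1a32v <- function(x) vapply(x, .fnv1a32, numeric(1), USE.NAMES = FALSE)

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb user-level randomness.
.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  eval.parent(substitute(expr))
}

.msg <- function(...) message("kindock: ", ...)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
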