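# Internal helpers: validation, seeded initialisation, small numerics.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_binary_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x)) stopf("%s must be a matrix", what)
  if (nrow(x) < 1L) stopf("%s must have at least one row", what)
  if (any(!is.finite(x)) || any(x != 0 & x != 1))
    stopf("%s must contain only 0/1 entries", what)
  invisible(x)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("%s must be a single number in [0, 1], got %s", name, format(x))
  invisible(x)
}

# Run code under a temporary RNG state so library calls never perturb the
# caller's stream. `seed` below 2^31 always.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Deterministic 31-bit string hash, used to derive per-token seeds.
hash_string <- function(s) {
  v <- utf8ToInt(enc2utf8(s))
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  as.integer(h)
}

# Xavier/Glorot uniform initialisation for a fan_in x fan_out matrix.
xavier <- function(fan_in, fan_out, gain = 1) {
  a <- gain * sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -a, a), fan_in, fan_out)
}

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope = 0.2) ifelse(x > 0, 1, slope)

sigmoid <- function(x) 1 / (1 + exp(-x))

row_normalize <- function(m) {
  s <- rowSums(m)
  keep <- s > 0
  m[keep, ] <- m[keep, , drop = FALSE] / s[keep]
  m
}
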