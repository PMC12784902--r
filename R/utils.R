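# internal helpers: validation, seeding, raw MAD

# midpoint-of-middle-two median via partial sort; inputs are pre-validated
# (hot path inside the permutation and bootstrap loops)
median_fast <- function(v) {
  n <- length(v)
  h <- (n + 1L) %/% 2L
  if (n %% 2L == 1L) {
    sort(v, partial = h)[h]
  } else {
    s <- sort(v, partial = c(h, h + 1L))
    (s[h] + s[h + 1L]) / 2
  }
}

# raw (unscaled) MAD; no consistency constant
mad_raw <- function(x) {
  m <- median_fast(x)
  median_fast(abs(x - m))
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE,
                         integerish = FALSE) {
  if (length(x) != 1 || !is.numeric(x) || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", field))
  }
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf("`%s` = %g is outside its valid range.", field, x))
  }
  if (integerish && x != round(x)) {
    abort(sprintf("`%s` must be a whole number.", field))
  }
  invisible(x)
}

# derive a per-unit substream seed from a master seed and a counter, so that
# adding a fly at the end never perturbs earlier flies' draws
substream_seed <- function(seed, counter) {
  as.integer((as.double(seed) %% 65011 + 1) * 31357 + counter) %% 2147483629L
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a
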