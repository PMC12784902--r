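# shared fixtures and independent oracles

# direct-enumeration MAD oracle (independent of the package's mad path)
oracle_mad <- function(x) {
  xs <- sort(x)
  med <- function(v) {
    n <- length(v)
    if (n %% 2 == 1) sort(v)[(n + 1) / 2]
    else mean(sort(v)[c(n / 2, n / 2 + 1)])
  }
  med(abs(xs - med(xs)))
}

# exhaustive label-permutation p-value for the MAD difference
exhaustive_perm_p <- function(a, b, alternative = "two_sided") {
  pooled <- c(a, b)
  N <- length(pooled)
  idxs <- utils::combn(N, length(a), simplify = FALSE)
  obs <- oracle_mad(a) - oracle_mad(b)
  stats <- vapply(idxs, function(ix) {
    oracle_mad(pooled[ix]) - oracle_mad(pooled[-ix])
  }, numeric(1))
  switch(alternative,
         two_sided = mean(abs(stats) >= abs(obs)),
         less = mean(stats <= obs),
         greater = mean(stats >= obs))
}

tiny_events <- function() {
  tibble::tibble(
    fly_id = rep(c("f1", "f2"), c(4, 3)),
    treatment = rep(c("ctrl", "ctrl"), c(4, 3)),
    time_s = c(1, 2, 3, 4, 1, 2, 3),
    direction = c("R", "R", "L", "R", "L", "L", "R")
  )
}

two_group_flies <- function(n = 50, k_a = 60, k_b = 10, seed = 1) {
  tibble::tibble(
    fly_id = sprintf("f%03d", seq_len(2 * n)),
    treatment = rep(c("a", "b"), each = n),
    n_turns = 100L,
    prop_right = c(sample_bias(0.5, k_a, n, seed = seed),
                   sample_bias(0.5, k_b, n, seed = seed + 1)),
    choice_mad = 0,
    turns_per_min = 100 / 120
  )
}
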