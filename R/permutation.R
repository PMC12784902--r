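#' Label-permutation test for a difference in group MAD
#'
#' Tests whether two groups differ in inter-individual dispersion of a score
#' (here, per-fly turn bias) by permuting group labels. The observed
#' statistic is `MAD(a) - MAD(b)`; under the exchangeable null the pooled
#' values are reassigned uniformly at random to groups of the original sizes
#' `n_iter` times and the statistic recomputed. The reported p-value uses the
#' add-one estimator `(1 + #extreme) / (1 + n_iter)`, which is strictly
#' positive and gives valid type-I control.
#'
#' @param values_a,values_b Numeric vectors of per-fly scores (>= 2 each).
#' @param n_iter Number of permutations (default 10000).
#' @param alternative `"two_sided"` (default; extreme means
#'   `|stat*| >= |stat_obs|`), `"less"` or `"greater"`.
#' @param seed Seed for the permutation stream.
#' @param group_a,group_b Labels carried into the result.
#' @return An object of class `mad_perm_test`: observed MADs and difference,
#'   p-value, null-distribution quantiles, sizes, seed. Has [print()],
#'   [generics::tidy()] and [generics::glance()] methods.
#' @examples
#' a <- sample_bias(0.5, 60, 50, seed = 1)
#' b <- sample_bias(0.5, 10, 50, seed = 2)
#' perm_test_mad(a, b, n_iter = 500, seed = 3)
#' @export
perm_test_mad <- function(values_a, values_b, n_iter = 10000,
                          alternative = c("two_sided", "less", "greater"),
                          seed = 1L, group_a = "a", group_b = "b") {
  alternative <- match.arg(alternative)
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("both groups need at least 2 values to compare dispersions.")
  }
  if (!all(is.finite(values_a)) || !all(is.finite(values_b))) {
    abort("group values must be finite.")
  }
  check_number(n_iter, "n_iter", lower = 1, integerish = TRUE)

  n_a <- length(values_a)
  pooled <- c(values_a, values_b)
  N <- length(pooled)
  mad_a <- mad_raw(values_a)
  mad_b <- mad_raw(values_b)
  obs <- mad_a - mad_b

  set.seed(seed)
  idx_a <- seq_len(n_a)
  idx_b <- (n_a + 1L):N
  null_stats <- vapply(seq_len(n_iter), function(i) {
    perm <- pooled[sample.int(N)]
    mad_raw(perm[idx_a]) - mad_raw(perm[idx_b])
  }, numeric(1))

  n_extreme <- switch(alternative,
    two_sided = sum(abs(null_stats) >= abs(obs)),
    less = sum(null_stats <= obs),
    greater = sum(null_stats >= obs)
  )
  p <- (1 + n_extreme) / (1 + n_iter)

  structure(
    list(group_a = group_a, group_b = group_b,
         mad_a = mad_a, mad_b = mad_b,
         stat_observed = obs, p_value = p,
         n_iter = as.integer(n_iter), alternative = alternative,
         seed = as.integer(seed), n_a = n_a, n_b = length(values_b),
         null_quantiles = quantile(
           null_stats, c(0.025, 0.25, 0.5, 0.75, 0.975))),
    class = "mad_perm_test"
  )
}

#' @export
print.mad_perm_test <- function(x, ...) {
  cat("Label-permutation test for difference in group MAD\n")
  cat(sprintf("  %s (n=%d, MAD=%.4f)  vs  %s (n=%d, MAD=%.4f)\n",
              x$group_a, x$n_a, x$mad_a, x$group_b, x$n_b, x$mad_b))
  cat(sprintf("  observed difference: %+.4f\n", x$stat_observed))
  cat(sprintf("  p = %.4g  (%s, %d permutations, seed %d)\n",
              x$p_value, x$alternative, x$n_iter, x$seed))
  invisible(x)
}

#' Pairwise permutation tests of group MAD across all treatments
#'
#' Runs [perm_test_mad()] on every pair of treatment groups in a fly-summary
#' table and reports raw and Benjamini-Hochberg-adjusted p-values (the
#' pairwise comparisons form one family).
#'
#' @param flies Fly summaries from [summarize_flies()].
#' @param n_iter Permutations per pair (default 10000).
#' @param alternative Passed to [perm_test_mad()].
#' @param seed Master seed; each pair gets a counter-derived substream.
#' @param values_col Column holding the per-fly score (default
#'   `"prop_right"`).
#' @return Tibble: `group_a`, `group_b`, `n_a`, `n_b`, `mad_a`, `mad_b`,
#'   `stat_observed`, `p_value`, `p_adjusted`, `n_iter`, `alternative`,
#'   `seed`.
#' @export
pairwise_mad_tests <- function(flies, n_iter = 10000,
                               alternative = c("two_sided", "less", "greater"),
                               seed = 1L, values_col = "prop_right") {
  alternative <- match.arg(alternative)
  stopifnot(is.data.frame(flies))
  if (!all(c("treatment", values_col) %in% names(flies))) {
    abort(sprintf("`flies` needs columns `treatment` and `%s`.", values_col))
  }
  groups <- split(flies[[values_col]], flies$treatment)
  if (length(groups) < 2) abort("need at least 2 treatment groups.")
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    t <- perm_test_mad(groups[[pr[1]]], groups[[pr[2]]], n_iter = n_iter,
                       alternative = alternative,
                       seed = substream_seed(seed, i),
                       group_a = pr[1], group_b = pr[2])
    tibble(group_a = t$group_a, group_b = t$group_b,
           n_a = t$n_a, n_b = t$n_b, mad_a = t$mad_a, mad_b = t$mad_b,
           stat_observed = t$stat_observed, p_value = t$p_value,
           n_iter = t$n_iter, alternative = t$alternative, seed = t$seed)
  })
  out <- bind_rows(rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out[, c("group_a", "group_b", "n_a", "n_b", "mad_a", "mad_b",
          "stat_observed", "p_value", "p_adjusted", "n_iter",
          "alternative", "seed")]
}
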