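#' Raw median absolute deviation
#'
#' The dispersion statistic at the core of the predictability analysis:
#' `median(|x - median(x)|)`, with the even-length median taken as the
#' midpoint of the middle two order statistics. No consistency constant
#' (1.4826) is applied — the statistic is reported on the raw scale of the
#' data (here, turn-bias proportions), and no normality is assumed. A larger
#' group MAD of per-fly turn-bias scores means greater inter-individual
#' variability, i.e. lower behavioral predictability.
#'
#' @param values Numeric vector, at least one finite value.
#' @return Nonnegative scalar.
#' @examples
#' group_mad(c(0.2, 0.5, 0.5, 0.8, 0.9))  # 0.3
#' @export
group_mad <- function(values) {
  if (length(values) == 0) abort("`values` must contain at least one value.")
  if (!is.numeric(values) || !all(is.finite(values))) {
    abort("`values` must be finite and numeric.")
  }
  mad_raw(values)
}

#' Bootstrap standard error and percentile CI for a group MAD
#'
#' Resamples flies (values) with replacement `n_boot` times, recomputing the
#' raw MAD each time. The bootstrap SE is the standard deviation of the
#' resampled MADs; the interval is the 2.5/97.5 percentile interval (for the
#' default `conf = 0.95`). Degenerate input (all values identical) yields a
#' zero-width interval rather than an error.
#'
#' @param values Numeric vector of per-fly scores (>= 2 values).
#' @param n_boot Number of bootstrap resamples (>= 100; default 10000).
#' @param seed Seed for reproducibility.
#' @param conf Confidence level (default 0.95).
#' @return One-row tibble: `mad`, `boot_se`, `ci_low`, `ci_high`, `n_boot`,
#'   `seed`.
#' @export
bootstrap_mad <- function(values, n_boot = 10000, seed = 1L, conf = 0.95) {
  if (length(values) < 2) abort("`values` must contain at least 2 values.")
  if (!all(is.finite(values))) abort("`values` must be finite.")
  check_number(n_boot, "n_boot", lower = 100, integerish = TRUE)
  check_number(conf, "conf", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  obs <- mad_raw(values)
  n <- length(values)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    mad_raw(values[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  qs <- unname(quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        type = 7))
  tibble(mad = obs, boot_se = sd(boots), ci_low = qs[1], ci_high = qs[2],
         n_boot = as.integer(n_boot), seed = as.integer(seed))
}

#' Group-level variability of turn bias, with bootstrap uncertainty
#'
#' For each treatment group, the raw MAD of per-fly right-turn proportions
#' (the across-fly reading: the dispersion of individual biases), with
#' fly-level bootstrap SE and percentile CI. Setting `per_fly = TRUE`
#' instead aggregates each fly's own MAD of its 0/1 choice codes
#' (`choice_mad`); this alternative reading is exposed for completeness but
#' does not produce dispersion values on the scale of across-fly bias
#' variability and is not the recommended statistic.
#'
#' @param flies Fly summaries from [summarize_flies()].
#' @param n_boot Bootstrap resamples per group (default 10000).
#' @param seed Master seed; each group gets a counter-derived substream.
#' @param conf Confidence level for the percentile interval.
#' @param per_fly If `TRUE`, analyze `choice_mad` instead of `prop_right`.
#' @return Tibble: `treatment`, `n_flies`, `mad`, `boot_se`, `ci_low`,
#'   `ci_high`, `n_boot`, `seed`.
#' @export
group_variability <- function(flies, n_boot = 10000, seed = 1L, conf = 0.95,
                              per_fly = FALSE) {
  stopifnot(is.data.frame(flies))
  col <- if (per_fly) "choice_mad" else "prop_right"
  if (!all(c("treatment", col) %in% names(flies))) {
    abort(sprintf("`flies` needs columns `treatment` and `%s`.", col))
  }
  groups <- split(flies[[col]], flies$treatment)
  res <- lapply(seq_along(groups), function(i) {
    b <- bootstrap_mad(groups[[i]], n_boot = n_boot,
                       seed = substream_seed(seed, i), conf = conf)
    tibble(treatment = names(groups)[i], n_flies = length(groups[[i]])) %>%
      dplyr::bind_cols(b)
  })
  bind_rows(res)
}
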