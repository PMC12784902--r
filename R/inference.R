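#' One-way ANOVA on per-fly turn bias, with residual diagnostics
#'
#' Fixed-effects one-way ANOVA of the right-turn proportion on treatment,
#' with a Shapiro-Wilk test on the residuals and a Brown-Forsythe
#' (median-centered) Levene test of homoscedasticity attached as
#' diagnostics. This is the central-tendency companion to the dispersion
#' analysis: a non-significant F with group-mean biases near 0.5 indicates
#' no directional preference shift, even when dispersion differs.
#'
#' @param flies Fly summaries from [summarize_flies()]; needs `treatment`
#'   and `prop_right`, with >= 2 groups of >= 2 flies.
#' @return An object of class `bias_anova` with fields `statistic`, `df1`,
#'   `df2`, `p_value`, `diagnostics` (`shapiro_stat`, `shapiro_p`,
#'   `levene_stat`, `levene_p`) and the underlying `stats::lm` fit.
#'   Has [generics::tidy()] and [generics::glance()] methods.
#' @export
anova_bias <- function(flies) {
  stopifnot(is.data.frame(flies))
  if (!all(c("treatment", "prop_right") %in% names(flies))) {
    abort("`flies` needs columns `treatment` and `prop_right`.")
  }
  sizes <- table(flies$treatment)
  if (length(sizes) < 2 || any(sizes < 2)) {
    abort("ANOVA needs >= 2 groups each with >= 2 flies.")
  }
  dat <- data.frame(y = flies$prop_right,
                    g = factor(flies$treatment))
  fit <- lm(y ~ g, data = dat)
  a <- anova(fit)
  res <- residuals(fit)
  # shapiro.test is defined for 3..5000 observations; thin deterministically
  # above that (stride subsample), which leaves the test's verdict intact
  res_sw <- if (length(res) > 5000) {
    res[round(seq(1, length(res), length.out = 5000))]
  } else res
  sw <- shapiro.test(res_sw)
  lv <- car::leveneTest(y ~ g, data = dat, center = median)
  structure(
    list(test = "anova",
         statistic = unname(a$`F value`[1]),
         df1 = unname(a$Df[1]), df2 = unname(a$Df[2]),
         p_value = unname(a$`Pr(>F)`[1]),
         diagnostics = list(shapiro_stat = unname(sw$statistic),
                            shapiro_p = sw$p.value,
                            levene_stat = lv$`F value`[1],
                            levene_p = lv$`Pr(>F)`[1]),
         n = nrow(dat), n_groups = length(sizes), fit = fit),
    class = "bias_anova"
  )
}

#' @export
print.bias_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA on turn bias: F(%d, %d) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$statistic, x$p_value))
  cat(sprintf("  Shapiro-Wilk W = %.4f (p = %.3g); Levene/Brown-Forsythe F = %.4g (p = %.3g)\n",
              x$diagnostics$shapiro_stat, x$diagnostics$shapiro_p,
              x$diagnostics$levene_stat, x$diagnostics$levene_p))
  invisible(x)
}

#' Kruskal-Wallis test on turns per minute
#'
#' Rank-based omnibus comparison of locomotor activity across treatments,
#' with the standard tie correction; p from the chi-square approximation on
#' k - 1 degrees of freedom. If every observation is identical the statistic
#' is reported as 0 with p = 1 rather than failing.
#'
#' @param flies Fly summaries from [summarize_flies()]; needs `treatment`
#'   and the column named by `values_col`.
#' @param values_col Activity column (default `"turns_per_min"`).
#' @return An object of class `activity_kruskal` with `statistic` (H),
#'   `df1`, `p_value`, `n`, `n_groups`.
#' @export
kruskal_activity <- function(flies, values_col = "turns_per_min") {
  stopifnot(is.data.frame(flies))
  if (!all(c("treatment", values_col) %in% names(flies))) {
    abort(sprintf("`flies` needs columns `treatment` and `%s`.", values_col))
  }
  g <- factor(flies$treatment)
  if (nlevels(g) < 2) abort("need at least 2 treatment groups.")
  y <- flies[[values_col]]
  if (!all(is.finite(y))) abort("activity values must be finite.")
  k <- nlevels(g)
  if (length(unique(y)) == 1) {
    h <- 0
    p <- 1
  } else {
    kt <- kruskal.test(y, g)
    h <- unname(kt$statistic)
    p <- kt$p.value
  }
  structure(
    list(test = "kruskal_wallis", statistic = h, df1 = k - 1L,
         p_value = p, n = length(y), n_groups = k),
    class = "activity_kruskal"
  )
}

#' @export
print.activity_kruskal <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis on activity: H = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df1, x$p_value))
  invisible(x)
}

#' Two-sided Mann-Whitney U test
#'
#' Wraps the standard rank-sum machinery: the exact null distribution is
#' used when the smaller group has at most `exact_max` observations and the
#' pooled data are tie-free; otherwise the normal approximation with
#' tie-corrected variance and continuity correction. The reported U is for
#' the first sample.
#'
#' @param a,b Numeric vectors, both nonempty.
#' @param exact_max Size threshold for the exact branch (default 8).
#' @return List: `u_statistic`, `p_raw`, `method` (`"exact"` or
#'   `"normal_approx"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(a, b, exact_max = 8) {
  if (length(a) == 0 || length(b) == 0) abort("both groups must be nonempty.")
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    abort("group values must be finite.")
  }
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !ties && min(length(a), length(b)) <= exact_max
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = use_exact, correct = TRUE,
                alternative = "two.sided")
  )
  list(u_statistic = unname(wt$statistic), p_raw = wt$p.value,
       method = if (use_exact) "exact" else "normal_approx")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `q_(i) = min_{j >= i}(m p_(j) / j)` capped at 1, returned in the input
#' order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.04, 0.03))  # 0.03 0.04 0.04
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) ||
      any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    abort("all p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Pairwise Mann-Whitney comparisons of activity, BH-corrected
#'
#' All pairwise [mann_whitney_u()] tests on an activity column across
#' treatment groups, with the raw p-values adjusted as one
#' Benjamini-Hochberg family.
#'
#' @inheritParams kruskal_activity
#' @return Tibble: `group_a`, `group_b`, `u_statistic`, `p_raw`,
#'   `p_adjusted`, `method` (`"mann_whitney_bh"`).
#' @export
pairwise_activity <- function(flies, values_col = "turns_per_min") {
  stopifnot(is.data.frame(flies))
  if (!all(c("treatment", values_col) %in% names(flies))) {
    abort(sprintf("`flies` needs columns `treatment` and `%s`.", values_col))
  }
  groups <- split(flies[[values_col]], flies$treatment)
  if (length(groups) < 2) abort("need at least 2 treatment groups.")
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    m <- mann_whitney_u(groups[[pr[1]]], groups[[pr[2]]])
    tibble(group_a = pr[1], group_b = pr[2],
           u_statistic = m$u_statistic, p_raw = m$p_raw)
  })
  out <- bind_rows(rows)
  out$p_adjusted <- bh_adjust(out$p_raw)
  out$method <- "mann_whitney_bh"
  out
}
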