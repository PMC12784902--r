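#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a MAD permutation test
#'
#' @param x A `mad_perm_test`.
#' @param ... Unused.
#' @return Tibble with one row per group plus the null-distribution
#'   quantiles in attributes-free long columns.
#' @method tidy mad_perm_test
#' @export
tidy.mad_perm_test <- function(x, ...) {
  tibble(group = c(x$group_a, x$group_b),
         n = c(x$n_a, x$n_b),
         mad = c(x$mad_a, x$mad_b))
}

#' @rdname tidy.mad_perm_test
#' @return For `glance()`: a one-row tibble with the observed difference,
#'   p-value, iteration count, alternative and seed.
#' @method glance mad_perm_test
#' @export
glance.mad_perm_test <- function(x, ...) {
  tibble(group_a = x$group_a, group_b = x$group_b,
         stat_observed = x$stat_observed, p_value = x$p_value,
         n_iter = x$n_iter, alternative = x$alternative, seed = x$seed)
}

#' Tidy the turn-bias ANOVA
#'
#' @param x A `bias_anova`.
#' @param ... Unused.
#' @return `tidy()`: the standard per-term ANOVA table. `glance()`: one row
#'   with F, df, p and the Shapiro-Wilk / Levene diagnostics.
#' @method tidy bias_anova
#' @export
tidy.bias_anova <- function(x, ...) {
  a <- anova(x$fit)
  tibble(term = rownames(a), df = a$Df, sumsq = a$`Sum Sq`,
         meansq = a$`Mean Sq`, statistic = a$`F value`,
         p_value = a$`Pr(>F)`)
}

#' @rdname tidy.bias_anova
#' @method glance bias_anova
#' @export
glance.bias_anova <- function(x, ...) {
  tibble(test = "anova", statistic = x$statistic,
         df1 = x$df1, df2 = x$df2, p_value = x$p_value,
         shapiro_stat = x$diagnostics$shapiro_stat,
         shapiro_p = x$diagnostics$shapiro_p,
         levene_stat = x$diagnostics$levene_stat,
         levene_p = x$diagnostics$levene_p)
}

#' Tidy the activity Kruskal-Wallis test
#'
#' @param x An `activity_kruskal`.
#' @param ... Unused.
#' @method tidy activity_kruskal
#' @export
tidy.activity_kruskal <- function(x, ...) {
  glance.activity_kruskal(x)
}

#' @rdname tidy.activity_kruskal
#' @method glance activity_kruskal
#' @export
glance.activity_kruskal <- function(x, ...) {
  tibble(test = "kruskal_wallis", statistic = x$statistic,
         df1 = x$df1, df2 = NA_integer_, p_value = x$p_value,
         shapiro_stat = NA_real_, shapiro_p = NA_real_,
         levene_stat = NA_real_, levene_p = NA_real_)
}
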