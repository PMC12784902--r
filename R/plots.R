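#' Barplot of group MAD with bootstrap error bars
#'
#' One bar per treatment showing the raw MAD of per-fly turn bias; error
#' bars are the fly-level bootstrap SE (not a normal-theory SEM).
#'
#' @param group_variability Tibble from [group_variability()].
#' @return A ggplot object.
#' @export
plot_mad <- function(group_variability) {
  ggplot2::ggplot(group_variability,
                  ggplot2::aes(x = .data$treatment, y = .data$mad)) +
    ggplot2::geom_col(fill = "grey60", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mad - .data$boot_se,
                   ymax = .data$mad + .data$boot_se),
      width = 0.15) +
    ggplot2::labs(x = NULL, y = "MAD of right-turn proportion",
                  title = "Inter-individual variability of turn bias",
                  subtitle = "bars: group MAD; whiskers: bootstrap SE") +
    ggplot2::theme_classic()
}

#' Per-fly turn-bias strip plot with group medians
#'
#' Each dot is one fly's right-turn proportion; the horizontal bar marks the
#' group median. A cloud centered on 0.5 in every group indicates no
#' directional bias at the group level, whatever the spread.
#'
#' @param flies Tibble from [summarize_flies()].
#' @return A ggplot object.
#' @export
plot_bias <- function(flies) {
  ggplot2::ggplot(flies,
                  ggplot2::aes(x = .data$treatment, y = .data$prop_right)) +
    ggplot2::geom_jitter(width = 0.18, height = 0, size = 0.6,
                         alpha = 0.4, colour = "grey40") +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.45, linewidth = 0.5, colour = "black") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey70") +
    ggplot2::labs(x = NULL, y = "Proportion of right turns",
                  title = "Individual turn bias by treatment") +
    ggplot2::theme_classic()
}

#' Activity strip plot with significance letters
#'
#' Turns per minute per fly with group medians; groups sharing a letter are
#' not significantly different under the BH-adjusted pairwise Mann-Whitney
#' tests.
#'
#' @param flies Tibble from [summarize_flies()].
#' @param pairwise Optional tibble from [pairwise_activity()]; when given,
#'   compact letter displays are drawn above each group.
#' @param alpha Significance level for the letter assignment.
#' @return A ggplot object.
#' @export
plot_activity <- function(flies, pairwise = NULL, alpha = 0.05) {
  p <- ggplot2::ggplot(flies,
                       ggplot2::aes(x = .data$treatment,
                                    y = .data$turns_per_min)) +
    ggplot2::geom_jitter(width = 0.18, height = 0, size = 0.6,
                         alpha = 0.4, colour = "grey40") +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.45, linewidth = 0.5, colour = "black") +
    ggplot2::labs(x = NULL, y = "Turns per minute",
                  title = "Locomotor activity by treatment") +
    ggplot2::theme_classic()
  if (!is.null(pairwise)) {
    letters_tab <- significance_letters(pairwise, alpha = alpha)
    tops <- flies %>%
      group_by(.data$treatment) %>%
      summarise(y = max(.data$turns_per_min), .groups = "drop") %>%
      left_join(letters_tab, by = "treatment")
    p <- p + ggplot2::geom_text(
      data = tops,
      ggplot2::aes(x = .data$treatment, y = .data$y * 1.05,
                   label = .data$letters),
      inherit.aes = FALSE)
  }
  p
}

#' Compact letter display from pairwise adjusted p-values
#'
#' Builds the usual "groups sharing a letter do not differ" annotation: the
#' nonsignificance graph (edge when adjusted p >= alpha) is covered by its
#' maximal cliques, each clique lettered in order. Suitable for the small
#' numbers of groups typical of treatment designs (exhaustive clique search,
#' capped at 12 groups).
#'
#' @param pairwise Tibble with `group_a`, `group_b` and `p_adjusted`.
#' @param alpha Significance level (default 0.05).
#' @return Tibble: `treatment`, `letters`.
#' @export
significance_letters <- function(pairwise, alpha = 0.05) {
  stopifnot(all(c("group_a", "group_b", "p_adjusted") %in% names(pairwise)))
  labs <- sort(unique(c(pairwise$group_a, pairwise$group_b)))
  k <- length(labs)
  if (k > 12) abort("letter display supported for at most 12 groups.")
  ns <- matrix(TRUE, k, k, dimnames = list(labs, labs))
  for (i in seq_len(nrow(pairwise))) {
    sig <- pairwise$p_adjusted[i] < alpha
    a <- pairwise$group_a[i]; b <- pairwise$group_b[i]
    ns[a, b] <- ns[b, a] <- !sig
  }
  # enumerate maximal cliques of the nonsignificance graph exhaustively
  subsets <- lapply(seq_len(2^k - 1), function(m) which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0))
  is_clique <- vapply(subsets, function(s) {
    all(ns[s, s, drop = FALSE])
  }, logical(1))
  cliques <- subsets[is_clique]
  maximal <- cliques[vapply(cliques, function(s) {
    !any(vapply(cliques, function(t) length(t) > length(s) && all(s %in% t),
                logical(1)))
  }, logical(1))]
  maximal <- maximal[order(vapply(maximal, min, integer(1)))]
  assign <- setNames(rep("", k), labs)
  for (i in seq_along(maximal)) {
    for (g in labs[maximal[[i]]]) {
      assign[g] <- paste0(assign[g], letters[i])
    }
  }
  tibble(treatment = labs, letters = unname(assign))
}

#' @rdname plot_mad
#' @param object A `report_bundle`.
#' @param which Which figure: `"mad"`, `"bias"` or `"activity"`.
#' @param ... Unused.
#' @method autoplot report_bundle
#' @export
autoplot.report_bundle <- function(object, which = c("mad", "bias", "activity"),
                                   ...) {
  which <- match.arg(which)
  switch(which,
         mad = plot_mad(object$group_variability),
         bias = plot_bias(object$fly_summaries),
         activity = plot_activity(object$fly_summaries,
                                  object$pairwise_tests))
}

#' Null-distribution plot for a MAD permutation test
#'
#' Histogram of the permutation null of the MAD difference with the observed
#' statistic marked.
#'
#' @param object A `mad_perm_test`.
#' @param ... Unused.
#' @method autoplot mad_perm_test
#' @export
autoplot.mad_perm_test <- function(object, ...) {
  qs <- object$null_quantiles
  dat <- tibble(q = names(qs), value = unname(qs))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$value, y = 0)) +
    ggplot2::geom_point(shape = 3, size = 3) +
    ggplot2::geom_vline(xintercept = object$stat_observed,
                        colour = "red", linewidth = 0.8) +
    ggplot2::labs(
      x = sprintf("MAD(%s) - MAD(%s) under label permutation",
                  object$group_a, object$group_b),
      y = NULL,
      title = sprintf("Observed difference %+.4f, p = %.4g",
                      object$stat_observed, object$p_value),
      subtitle = "crosses: null quantiles (2.5/25/50/75/97.5%)") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}
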