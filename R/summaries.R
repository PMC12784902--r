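#' Summarize per-fly turn bias and activity
#'
#' Collapses a turn-event table to one row per fly: number of turns, the
#' right-turn proportion (turns coded 1 for right, 0 for left), a per-fly MAD
#' of those 0/1 choice codes, and turns per minute over the observation
#' window. Flies with fewer than `min_turns` events are excluded from the
#' returned summaries and reported, with a reason, in the `excluded`
#' attribute; an inclusion filter of this kind is required before the
#' right-turn proportion is a stable individual score.
#'
#' @param events Data frame with `fly_id`, `treatment`, `time_s`,
#'   `direction` (values exactly `"L"` or `"R"`).
#' @param observation_minutes Denominator for turns/min (default 120, the
#'   full session).
#' @param min_turns Minimum events for inclusion (default 10).
#' @param roster Optional data frame (`fly_id`, `treatment`) listing all
#'   tested flies, so zero-event flies appear in the exclusion report.
#' @return Tibble (`fly_id`, `treatment`, `n_turns`, `prop_right`,
#'   `choice_mad`, `turns_per_min`), one row per included fly, with attribute
#'   `excluded`: tibble (`fly_id`, `treatment`, `n_turns`, `reason`).
#' @examples
#' ev <- tibble::tibble(fly_id = "f1", treatment = "ctrl",
#'                      time_s = 1:4, direction = c("R", "R", "L", "R"))
#' summarize_flies(ev, observation_minutes = 120, min_turns = 1)
#' @export
summarize_flies <- function(events, observation_minutes = 120,
                            min_turns = 10, roster = NULL) {
  stopifnot(is.data.frame(events))
  need <- c("fly_id", "treatment", "time_s", "direction")
  miss <- setdiff(need, names(events))
  if (length(miss)) {
    abort(paste0("events is missing column(s): ", paste(miss, collapse = ", ")))
  }
  check_number(observation_minutes, "observation_minutes", lower = 0,
               open_lower = TRUE)
  check_number(min_turns, "min_turns", lower = 0, integerish = TRUE)
  bad_dir <- setdiff(unique(events$direction), c("L", "R"))
  if (length(bad_dir)) {
    abort(paste0("direction values outside {L, R}: ",
                 paste(unique(bad_dir), collapse = ", ")))
  }
  dup <- duplicated(events[, c("fly_id", "time_s")])
  if (any(dup)) {
    abort(paste0("duplicate (fly_id, time_s) rows at: ",
                 paste(head(which(dup), 10), collapse = ", ")))
  }

  per_fly <- events %>%
    group_by(.data$fly_id, .data$treatment) %>%
    summarise(
      n_turns = dplyr::n(),
      prop_right = mean(.data$direction == "R"),
      choice_mad = mad_raw(as.numeric(.data$direction == "R")),
      .groups = "drop"
    ) %>%
    mutate(turns_per_min = .data$n_turns / observation_minutes)

  if (!is.null(roster)) {
    stopifnot(all(c("fly_id", "treatment") %in% names(roster)))
    missing_ids <- setdiff(roster$fly_id, per_fly$fly_id)
    if (length(missing_ids)) {
      zero <- roster[roster$fly_id %in% missing_ids, c("fly_id", "treatment")]
      zero$n_turns <- 0L
      zero$prop_right <- NA_real_
      zero$choice_mad <- NA_real_
      zero$turns_per_min <- 0
      per_fly <- bind_rows(per_fly, as_tibble(zero))
    }
  }
  per_fly <- arrange(per_fly, .data$fly_id)

  keep <- per_fly$n_turns >= min_turns
  excluded <- per_fly[!keep, c("fly_id", "treatment", "n_turns")]
  excluded$reason <- "insufficient_turns"
  out <- per_fly[keep, ]
  attr(out, "excluded") <- as_tibble(excluded)
  out
}

#' Flies excluded by the inclusion filter
#'
#' @param flies Result of [summarize_flies()].
#' @return Tibble of excluded flies with reasons.
#' @export
excluded_flies <- function(flies) {
  attr(flies, "excluded") %||%
    tibble(fly_id = character(), treatment = character(),
           n_turns = integer(), reason = character())
}
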