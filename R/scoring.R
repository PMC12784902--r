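#' Score turn events from a single-fly centroid track
#'
#' Walks the track's zone-commitment sequence: a sample is committed to an
#' arm when it lies in that arm's sector at or beyond the commitment radius.
#' A turn event is emitted each time the committed arm changes; the event
#' time is the first committed sample in the new arm and the direction
#' follows [turn_direction()]. Dwell in the center zone or uncommitted
#' jitter between the two radii emits nothing, so boundary chatter cannot
#' double-count a decision.
#'
#' @param track Data frame with `time_s`, `x_mm`, `y_mm`, time-sorted,
#'   one fly.
#' @param geometry A [maze_geometry()].
#' @param convention Direction convention, see [turn_direction()].
#' @param max_out_fraction QC threshold: if more than this fraction of
#'   samples fall outside the maze the track is flagged (default 0.05).
#' @return Tibble of events (`time_s`, `arm_from`, `arm_to`, `direction`)
#'   with attributes `qc` (tibble: `n_samples`, `out_fraction`, `n_turns`,
#'   `flagged`).
#' @examples
#' tr <- simulate_trajectory(0.6, maze_geometry(), n_turns = 4, seed = 2)
#' score_turns(tr$track)
#' @export
score_turns <- function(track, geometry = maze_geometry(),
                        convention = c("cw-right", "ccw-right"),
                        max_out_fraction = 0.05) {
  convention <- match.arg(convention)
  stopifnot(is.data.frame(track))
  need <- c("time_s", "x_mm", "y_mm")
  miss <- setdiff(need, names(track))
  if (length(miss)) {
    abort(paste0("track is missing column(s): ", paste(miss, collapse = ", ")))
  }
  empty <- tibble(time_s = numeric(), arm_from = integer(),
                  arm_to = integer(), direction = character())
  if (nrow(track) < 2) {
    attr(empty, "qc") <- tibble(n_samples = nrow(track), out_fraction = 0,
                                n_turns = 0L, flagged = FALSE)
    return(empty)
  }
  if (is.unsorted(track$time_s)) abort("track must be sorted by `time_s`.")

  zone <- assign_zone(track$x_mm, track$y_mm, geometry)
  dx <- track$x_mm - geometry$center_xy[1]
  dy <- track$y_mm - geometry$center_xy[2]
  r <- sqrt(dx^2 + dy^2)
  arm_idx <- rep(NA_integer_, length(zone))
  is_arm <- startsWith(zone, "ARM")
  arm_idx[is_arm] <- as.integer(substring(zone[is_arm], 4))
  committed <- !is.na(arm_idx) & r >= geometry$commit_radius_mm

  out_fraction <- mean(zone == "OUT")
  idx <- which(committed)
  if (length(idx) == 0) {
    attr(empty, "qc") <- tibble(n_samples = nrow(track),
                                out_fraction = out_fraction,
                                n_turns = 0L,
                                flagged = out_fraction > max_out_fraction)
    return(empty)
  }
  arms <- arm_idx[idx]
  change <- c(FALSE, arms[-1] != arms[-length(arms)])
  ev_at <- idx[change]
  events <- if (length(ev_at)) {
    prev <- arms[which(change) - 1L]
    cur <- arms[change]
    tibble(time_s = track$time_s[ev_at],
           arm_from = as.integer(prev), arm_to = as.integer(cur),
           direction = turn_direction(prev, cur, convention))
  } else {
    empty
  }
  attr(events, "qc") <- tibble(n_samples = nrow(track),
                               out_fraction = out_fraction,
                               n_turns = nrow(events),
                               flagged = out_fraction > max_out_fraction)
  events
}

#' Score turn events for many flies at once
#'
#' Splits a multi-fly trajectory table by `fly_id`, scores each track with
#' [score_turns()], and returns one tidy event table in the shared dialect
#' plus a per-fly QC table.
#'
#' @param tracks Data frame with `fly_id`, `time_s`, `x_mm`, `y_mm` and
#'   optionally `treatment`.
#' @inheritParams score_turns
#' @return List with `events` (tibble: `fly_id`, `treatment` if supplied,
#'   `time_s`, `direction`, `arm_from`, `arm_to`) and `qc` (tibble:
#'   `fly_id`, `n_samples`, `out_fraction`, `n_turns`, `flagged`).
#' @export
score_trajectories <- function(tracks, geometry = maze_geometry(),
                               convention = c("cw-right", "ccw-right"),
                               max_out_fraction = 0.05) {
  convention <- match.arg(convention)
  stopifnot(is.data.frame(tracks))
  if (!"fly_id" %in% names(tracks)) abort("`tracks` needs a `fly_id` column.")
  has_trt <- "treatment" %in% names(tracks)
  split_tracks <- split(tracks, tracks$fly_id)
  pieces <- lapply(names(split_tracks), function(fid) {
    tr <- dplyr::arrange(split_tracks[[fid]], .data$time_s)
    ev <- score_turns(tr, geometry, convention, max_out_fraction)
    qc <- attr(ev, "qc")
    ev$fly_id <- rep(fid, nrow(ev))
    if (has_trt) ev$treatment <- rep(tr$treatment[1], nrow(ev))
    qc$fly_id <- fid
    list(events = ev, qc = qc)
  })
  events <- bind_rows(lapply(pieces, `[[`, "events"))
  cols <- c("fly_id", if (has_trt) "treatment",
            "time_s", "direction", "arm_from", "arm_to")
  if (nrow(events)) {
    events <- events[, cols]
  } else {
    events <- tibble(fly_id = character(), time_s = numeric(),
                     direction = character(), arm_from = integer(),
                     arm_to = integer())
    if (has_trt) events$treatment <- character()
    events <- events[, cols]
  }
  qc <- bind_rows(lapply(pieces, `[[`, "qc"))
  qc <- qc[, c("fly_id", "n_samples", "out_fraction", "n_turns", "flagged")]
  list(events = as_tibble(events), qc = as_tibble(qc))
}
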