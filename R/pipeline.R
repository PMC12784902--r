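#' Configure an analysis run
#'
#' Collects everything a reproducible run needs: the input mode (an events
#' table, raw trajectories to score, or simulation), the analysis
#' parameters, and the master seed. `n_iter` below 1000 triggers a warning —
#' permutation p-values from short runs are too granular for reporting.
#'
#' @param mode `"events"`, `"trajectories"` or `"simulate"`.
#' @param events_path,trajectories_path Input CSV paths (per mode).
#' @param synth A [synth_config()] (simulate mode; defaults to
#'   [study_config()] with the run seed).
#' @param geometry A [maze_geometry()] (trajectories mode).
#' @param col_map Optional column-name adapter passed to the readers.
#' @param roster Optional roster data frame (`fly_id`, `treatment`).
#' @param observation_minutes Session length used for turns/min
#'   (default 120).
#' @param min_turns Inclusion threshold on per-fly event count (default 10).
#' @param n_iter Permutations per pairwise MAD test (default 10000).
#' @param n_boot Bootstrap resamples per group (default 10000).
#' @param alpha Significance level for reporting (default 0.05).
#' @param alternative Permutation alternative (default `"two_sided"`).
#' @param convention Direction convention for scoring.
#' @param seed Master seed.
#' @param out_dir Optional output directory; when set, [run_pipeline()]
#'   writes the report there.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("events", "trajectories", "simulate"),
                       events_path = NULL, trajectories_path = NULL,
                       synth = NULL, geometry = maze_geometry(),
                       col_map = NULL, roster = NULL,
                       observation_minutes = 120, min_turns = 10,
                       n_iter = 10000, n_boot = 10000, alpha = 0.05,
                       alternative = "two_sided",
                       convention = c("cw-right", "ccw-right"),
                       seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  check_number(alpha, "alpha", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  check_number(n_iter, "n_iter", lower = 1, integerish = TRUE)
  check_number(n_boot, "n_boot", lower = 100, integerish = TRUE)
  check_number(seed, "seed", integerish = TRUE)
  if (n_iter < 1000) {
    warn("n_iter < 1000: permutation p-values will be coarse; use >= 1000 for reported runs.")
  }
  if (mode == "events" && is.null(events_path)) {
    abort("events mode needs `events_path`.")
  }
  if (mode == "trajectories" && is.null(trajectories_path)) {
    abort("trajectories mode needs `trajectories_path`.")
  }
  if (mode == "simulate" && is.null(synth)) synth <- study_config(seed = seed)
  structure(
    list(mode = mode, events_path = events_path,
         trajectories_path = trajectories_path, synth = synth,
         geometry = geometry, col_map = col_map, roster = roster,
         observation_minutes = observation_minutes, min_turns = min_turns,
         n_iter = n_iter, n_boot = n_boot, alpha = alpha,
         alternative = alternative, convention = convention,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Scalar keys mirror the [run_config()] arguments; a `synth` block mirrors
#' [synth_config()] with a `groups` list of [synth_group()] fields, and a
#' `geometry` block mirrors [maze_geometry()].
#'
#' @param path YAML file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$synth)) {
    groups <- lapply(vals$synth$groups, function(g) do.call(synth_group, g))
    vals$synth <- synth_config(groups,
                               session_minutes = vals$synth$session_minutes %||% 120,
                               seed = vals$synth$seed %||% vals$seed %||% 1L)
  }
  if (!is.null(vals$geometry)) {
    vals$geometry <- do.call(maze_geometry, vals$geometry)
  }
  if (!is.null(vals$col_map)) vals$col_map <- unlist(vals$col_map)
  do.call(run_config, vals)
}

#' Run the full analysis pipeline
#'
#' Executes the stage chain implied by the configured input mode —
#' simulate or read events (scoring trajectories first if needed), then
#' summarize flies, estimate group variability with bootstrap uncertainty,
#' run pairwise MAD permutation tests, the turn-bias ANOVA with diagnostics,
#' and the activity Kruskal-Wallis with BH-corrected pairwise Mann-Whitney
#' tests. Analysis outputs depend only on the events table and parameters,
#' never on which mode produced the events. All seeds and iteration counts
#' are echoed into the manifest so a run can be reproduced from it alone.
#'
#' @param config A [run_config()].
#' @return A `report_bundle`: tibbles `fly_summaries` (plus exclusions),
#'   `group_variability`, `permutation_tests`, `omnibus_tests`,
#'   `pairwise_tests`, optional `qc`, and `manifest`.
#' @examples
#' \donttest{
#' cfg <- run_config("simulate",
#'                   synth = synth_config(list(
#'                     synth_group("a", 40, bias_concentration = 30),
#'                     synth_group("b", 40, bias_concentration = 10)),
#'                     seed = 1),
#'                   n_iter = 1000, n_boot = 200, seed = 1)
#' bundle <- run_pipeline(cfg)
#' bundle$group_variability
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  qc <- NULL
  input_hashes <- list()
  if (config$mode == "simulate") {
    cohort <- simulate_cohort(config$synth)
    events <- cohort$events
    roster <- cohort$flies[, c("fly_id", "treatment")]
  } else if (config$mode == "events") {
    events <- read_events(config$events_path, config$col_map)
    roster <- config$roster
    input_hashes$events <- unname(tools::md5sum(config$events_path))
  } else {
    tracks <- read_trajectories(config$trajectories_path, config$col_map)
    input_hashes$trajectories <-
      unname(tools::md5sum(config$trajectories_path))
    scored <- score_trajectories(tracks, config$geometry, config$convention)
    events <- scored$events
    qc <- scored$qc
    roster <- config$roster
    if (is.null(roster) && "treatment" %in% names(tracks)) {
      roster <- dplyr::distinct(tracks[, c("fly_id", "treatment")])
    }
  }

  flies <- summarize_flies(events,
                           observation_minutes = config$observation_minutes,
                           min_turns = config$min_turns, roster = roster)
  gv <- group_variability(flies, n_boot = config$n_boot,
                          seed = substream_seed(config$seed, 1L))
  perms <- pairwise_mad_tests(flies, n_iter = config$n_iter,
                              alternative = config$alternative,
                              seed = substream_seed(config$seed, 2L))
  av <- anova_bias(flies)
  kw <- kruskal_activity(flies)
  omnibus <- bind_rows(glance(av), glance(kw))
  pw <- pairwise_activity(flies)

  manifest <- list(
    package_version = as.character(utils::packageVersion("turnvar")),
    r_version = as.character(getRversion()),
    mode = config$mode,
    seed = config$seed,
    n_iter = config$n_iter, n_boot = config$n_boot,
    min_turns = config$min_turns,
    observation_minutes = config$observation_minutes,
    alpha = config$alpha, alternative = config$alternative,
    convention = config$convention,
    input_hashes = input_hashes,
    n_flies_included = nrow(flies),
    n_flies_excluded = nrow(excluded_flies(flies)),
    synth = if (config$mode == "simulate") {
      list(session_minutes = config$synth$session_minutes,
           seed = config$synth$seed,
           groups = lapply(config$synth$groups, unclass))
    }
  )

  bundle <- structure(
    list(fly_summaries = flies,
         exclusions = excluded_flies(flies),
         group_variability = gv,
         permutation_tests = perms,
         omnibus_tests = omnibus,
         pairwise_tests = pw,
         qc = qc,
         manifest = manifest),
    class = "report_bundle"
  )
  if (!is.null(config$out_dir)) write_report(bundle, config$out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("turnvar report: %d flies in %d groups (%d excluded)\n",
              nrow(x$fly_summaries), nrow(x$group_variability),
              nrow(x$exclusions)))
  cat("\nGroup variability (raw MAD of per-fly turn bias):\n")
  print(x$group_variability, ...)
  cat("\nPairwise MAD permutation tests:\n")
  print(x$permutation_tests, ...)
  cat("\nOmnibus tests:\n")
  print(x$omnibus_tests, ...)
  cat("\nPairwise activity (Mann-Whitney, BH):\n")
  print(x$pairwise_tests, ...)
  invisible(x)
}

#' Recompute the headline statistics from a deposited events table
#'
#' Convenience wrapper for reproducing a published analysis from its
#' deposited per-turn event table: reads the events (optionally through a
#' column-name adapter), applies the inclusion filter, and returns the full
#' report bundle. Matching printed degrees of freedom exactly requires
#' matching the original study's inclusion filter via `min_turns`.
#'
#' @param events_path Path to the deposited events CSV.
#' @inheritParams run_config
#' @param ... Further arguments passed to [run_config()].
#' @return A `report_bundle`.
#' @export
reproduce_study <- function(events_path, col_map = NULL, min_turns = 10,
                            n_iter = 10000, n_boot = 10000, seed = 1L, ...) {
  run_pipeline(run_config("events", events_path = events_path,
                          col_map = col_map, min_turns = min_turns,
                          n_iter = n_iter, n_boot = n_boot, seed = seed, ...))
}
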