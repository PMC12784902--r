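#' Read a turn-event table
#'
#' Reads the shared CSV dialect (`fly_id`, `treatment`, `time_s`,
#' `direction`, optional `arm_from`, `arm_to`; UTF-8, header row,
#' comma-separated). Direction codes must be exactly `"L"` or `"R"` — longer
#' spellings such as `"left"` are an error, never silently coerced. A
#' header-only file yields an empty table with a warning.
#'
#' @param path CSV file path.
#' @param col_map Optional named character vector mapping standard column
#'   names to the file's column names, e.g.
#'   `c(fly_id = "animal", direction = "turn")` — a thin adapter for
#'   externally deposited tables.
#' @return Tibble of turn events.
#' @export
read_events <- function(path, col_map = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      src <- col_map[[std]]
      if (!src %in% names(tab)) {
        abort(sprintf("col_map column `%s` not present in %s", src, path))
      }
      names(tab)[names(tab) == src] <- std
    }
  }
  need <- c("fly_id", "treatment", "time_s", "direction")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    abort(sprintf("%s is missing column(s): %s", path,
                  paste(miss, collapse = ", ")))
  }
  if (nrow(tab) == 0) {
    warn(sprintf("%s contains a header but no events.", path))
    return(as_tibble(tab))
  }
  tab$fly_id <- as.character(tab$fly_id)
  tab$treatment <- as.character(tab$treatment)
  tab$direction <- as.character(tab$direction)
  bad <- setdiff(unique(tab$direction), c("L", "R"))
  if (length(bad)) {
    abort(sprintf("%s: direction values outside {L, R}: %s",
                  path, paste(bad, collapse = ", ")))
  }
  if (!is.numeric(tab$time_s) || any(!is.finite(tab$time_s))) {
    abort(sprintf("%s: time_s must be finite numeric seconds.", path))
  }
  as_tibble(tab)
}

#' Read a centroid-trajectory table
#'
#' Expects `fly_id`, `time_s`, `x_mm`, `y_mm` and optionally `treatment`,
#' in the shared CSV dialect.
#'
#' @inheritParams read_events
#' @return Tibble of centroid samples.
#' @export
read_trajectories <- function(path, col_map = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      src <- col_map[[std]]
      if (!src %in% names(tab)) {
        abort(sprintf("col_map column `%s` not present in %s", src, path))
      }
      names(tab)[names(tab) == src] <- std
    }
  }
  need <- c("fly_id", "time_s", "x_mm", "y_mm")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    abort(sprintf("%s is missing column(s): %s", path,
                  paste(miss, collapse = ", ")))
  }
  for (col in c("time_s", "x_mm", "y_mm")) {
    if (!is.numeric(tab[[col]]) || any(!is.finite(tab[[col]]))) {
      abort(sprintf("%s: `%s` must be finite numeric.", path, col))
    }
  }
  tab$fly_id <- as.character(tab$fly_id)
  as_tibble(tab)
}

#' Write a report bundle to disk
#'
#' Writes every table of a [run_pipeline()] result as CSV, the run manifest
#' as JSON, and (optionally) the standard figures as PNG.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @param figures Write PNG figures too (default TRUE).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(bundle, dir, figures = TRUE) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("fly_summaries", "group_variability", "permutation_tests",
              "omnibus_tests", "pairwise_tests", "qc")
  written <- character()
  for (nm in tables) {
    if (!is.null(bundle[[nm]])) {
      f <- file.path(dir, paste0(nm, ".csv"))
      readr::write_csv(bundle[[nm]], f)
      written <- c(written, f)
    }
  }
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(bundle$manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, mf)
  if (figures) {
    figs <- list(
      mad = plot_mad(bundle$group_variability),
      bias = plot_bias(bundle$fly_summaries),
      activity = plot_activity(bundle$fly_summaries, bundle$pairwise_tests)
    )
    for (nm in names(figs)) {
      f <- file.path(dir, paste0("fig_", nm, ".png"))
      ggplot2::ggsave(f, figs[[nm]], width = 5, height = 4, dpi = 150)
      written <- c(written, f)
    }
  }
  invisible(written)
}
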