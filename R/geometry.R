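#' Describe a symmetric three-armed (Y) maze
#'
#' Zone assignment uses two radii around the center: inside `center_radius_mm`
#' a point is in the CENTER zone; a point is *committed* to an arm only at
#' `commit_radius_mm` or beyond. The gap between the two radii is a hysteresis
#' band that absorbs tracking jitter so boundary chatter cannot create
#' spurious turn events.
#'
#' @param center_xy Numeric length-2, maze center in mm.
#' @param arm_angles_deg Bearings of the three arms in degrees (default 90,
#'   210, 330; pairwise distinct modulo 360).
#' @param arm_length_mm Arm length in mm (default 12).
#' @param center_radius_mm Radius of the central decision zone (default 2).
#' @param commit_radius_mm Commitment radius (default 4); must satisfy
#'   `0 < center_radius_mm < commit_radius_mm <= arm_length_mm`.
#' @return A `maze_geometry` object.
#' @export
maze_geometry <- function(center_xy = c(0, 0),
                          arm_angles_deg = c(90, 210, 330),
                          arm_length_mm = 12,
                          center_radius_mm = 2,
                          commit_radius_mm = 4) {
  if (length(center_xy) != 2 || !all(is.finite(center_xy))) {
    abort("`center_xy` must be two finite coordinates.")
  }
  if (length(arm_angles_deg) != 3 || !all(is.finite(arm_angles_deg))) {
    abort("`arm_angles_deg` must be three finite bearings.")
  }
  if (anyDuplicated(arm_angles_deg %% 360)) {
    abort("arm bearings must be pairwise distinct modulo 360.")
  }
  check_number(arm_length_mm, "arm_length_mm", lower = 0, open_lower = TRUE)
  check_number(center_radius_mm, "center_radius_mm", lower = 0,
               open_lower = TRUE)
  check_number(commit_radius_mm, "commit_radius_mm", lower = 0,
               open_lower = TRUE)
  if (!(center_radius_mm < commit_radius_mm &&
        commit_radius_mm <= arm_length_mm)) {
    abort("need 0 < center_radius_mm < commit_radius_mm <= arm_length_mm.")
  }
  structure(
    list(center_xy = as.numeric(center_xy),
         arm_angles_deg = as.numeric(arm_angles_deg),
         arm_length_mm = arm_length_mm,
         center_radius_mm = center_radius_mm,
         commit_radius_mm = commit_radius_mm),
    class = "maze_geometry"
  )
}

#' Read maze geometry from a YAML file
#'
#' @param path YAML file whose keys mirror the [maze_geometry()] arguments.
#' @return A `maze_geometry` object.
#' @export
read_geometry <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(maze_geometry, vals)
}

#' Assign maze zones to centroid points
#'
#' A point is `CENTER` when its distance from the maze center is below
#' `center_radius_mm`; otherwise it belongs to the arm whose bearing is
#' angularly nearest (ties broken deterministically toward the lowest arm
#' index), provided it lies within the maze extent; points beyond
#' `arm_length_mm` (plus `tolerance`) are flagged `OUT`.
#'
#' @param x,y Coordinates in mm (vectorized).
#' @param geometry A [maze_geometry()].
#' @param tolerance Radial slack in mm beyond the arm length before a point
#'   is declared OUT (default 0.5).
#' @return Character vector in
#'   `c("CENTER", "ARM0", "ARM1", "ARM2", "OUT")`.
#' @examples
#' assign_zone(c(0, 0), c(0, 6), maze_geometry())
#' @export
assign_zone <- function(x, y, geometry = maze_geometry(), tolerance = 0.5) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("non-finite coordinates in `x`/`y`; drop or repair these rows.")
  }
  dx <- x - geometry$center_xy[1]
  dy <- y - geometry$center_xy[2]
  r <- sqrt(dx^2 + dy^2)
  bearing <- (atan2(dy, dx) * 180 / pi) %% 360
  # absolute angular distance to each arm bearing, wrapped to [0, 180]
  dists <- vapply(geometry$arm_angles_deg, function(a) {
    d <- abs(bearing - a) %% 360
    pmin(d, 360 - d)
  }, numeric(length(x)))
  dists <- matrix(dists, ncol = 3)
  # deterministic tie-break at sector boundaries: lowest arm index wins,
  # with a small angular tolerance absorbing floating-point bearing error
  minv <- do.call(pmin, as.data.frame(dists))
  nearest <- max.col(-(dists > minv + 1e-9), ties.method = "first") - 1L
  zone <- paste0("ARM", nearest)
  zone[r > geometry$arm_length_mm + tolerance] <- "OUT"
  zone[r < geometry$center_radius_mm] <- "CENTER"
  zone
}

#' Turn direction implied by an arm-to-arm transition
#'
#' With arms indexed clockwise when viewed from above, moving to the
#' clockwise-adjacent arm (`arm_to = arm_from + 1 mod 3`) is a right turn
#' and moving to the counterclockwise neighbor is a left turn. The
#' `"ccw-right"` convention flips every label; at an unbiased mean turn
#' probability all dispersion statistics are invariant to this choice.
#'
#' @param arm_from,arm_to Integer arm indices in 0..2 (vectorized), unequal.
#' @param convention `"cw-right"` (default) or `"ccw-right"`.
#' @return Character vector of `"L"` / `"R"`.
#' @examples
#' turn_direction(0, 1)  # "R"
#' turn_direction(1, 0)  # "L"
#' @export
turn_direction <- function(arm_from, arm_to,
                           convention = c("cw-right", "ccw-right")) {
  convention <- match.arg(convention)
  if (length(arm_from) != length(arm_to)) {
    abort("`arm_from` and `arm_to` must have equal length.")
  }
  if (length(arm_from) == 0) return(character())
  if (!all(arm_from %in% 0:2) || !all(arm_to %in% 0:2)) {
    abort("arm indices must be integers in 0..2.")
  }
  if (any(arm_from == arm_to)) {
    abort("`arm_from` and `arm_to` must differ (no self-transition).")
  }
  right <- ((arm_to - arm_from) %% 3) == 1
  if (convention == "ccw-right") right <- !right
  ifelse(right, "R", "L")
}
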