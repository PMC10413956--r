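# Per-observation movement metrics: step lengths, path length, net
# displacement, straightness index, turn angles, proportion of intervals
# with movement, and the line-of-sight visibility index.
#
# Conventions:
#  * A "step" spans one 1-min interval between consecutive fixes.  Its
#    heading is measured in degrees counterclockwise from the +x axis;
#    all reported quantities (turn angles) are independent of this
#    convention.
#  * Intervals with no movement (length <= move_epsilon) are excluded
#    from the step-length and turn-angle series but kept in the
#    denominator of proportion_moving and contribute zero to path length.
#  * Whole-path metrics (path length, net displacement, straightness) are
#    reported only for complete 31-fix observations.

#' Decompose an observation into 1-min steps
#'
#' @param obs an `observation` with at least 2 fixes.
#' @param move_epsilon movement threshold in metres: a step is flagged as
#'   movement when its length strictly exceeds this.  Default 0: any
#'   nonzero recorded displacement counts as movement.
#' @return data frame of class `steps` with columns `from_t`, `to_t`,
#'   `length` (m), `heading` (degrees in (-180, 180], `NA` for
#'   non-moving steps) and `moved` (logical).
#' @export
compute_steps <- function(obs, move_epsilon = 0) {
  stopifnot(move_epsilon >= 0)
  f <- obs$fixes
  n <- nrow(f)
  if (n < 2L) stop("cannot compute steps: observation '",
                   obs$observation_id, "' has fewer than 2 fixes")
  dx <- diff(f$x)
  dy <- diff(f$y)
  len <- sqrt(dx^2 + dy^2)
  moved <- len > move_epsilon
  heading <- ifelse(moved, wrap_deg(atan2(dy, dx) * RAD2DEG), NA_real_)
  out <- data.frame(from_t = f$t[-n], to_t = f$t[-1L],
                    length = len, heading = heading, moved = moved)
  class(out) <- c("steps", "data.frame")
  out
}

#' Total path length of a complete observation
#'
#' Sum of all step lengths (non-moving intervals contribute zero).
#' Defined only for complete 31-fix observations; otherwise `NA`.
#'
#' @param steps a `steps` data frame from [compute_steps()].
#' @param complete is the parent observation complete?  Defaults to
#'   requiring the full 30 steps.
#' @return path length in metres, or `NA_real_` for incomplete paths.
#' @export
path_length <- function(steps, complete = nrow(steps) == MAX_FIXES - 1L) {
  if (!complete) return(NA_real_)
  sum(steps$length)
}

#' Net displacement of a complete observation
#'
#' Straight-line distance between the first and last fix; `NA` for
#' incomplete observations.
#'
#' @param obs an `observation`.
#' @return metres, or `NA_real_`.
#' @export
net_displacement <- function(obs) {
  if (!is_complete(obs)) return(NA_real_)
  f <- obs$fixes
  n <- nrow(f)
  sqrt((f$x[n] - f$x[1L])^2 + (f$y[n] - f$y[1L])^2)
}

#' Straightness index of a complete observation
#'
#' Net displacement divided by path length, clamped to \[0, 1\] against
#' rounding.  `NA` for incomplete observations and for paths of zero
#' length (a non-mover has no path shape).
#'
#' @param obs an `observation`.
#' @param move_epsilon movement threshold in metres (see
#'   [compute_steps()]).
#' @return unitless value in \[0, 1\], or `NA_real_`.
#' @export
straightness_index <- function(obs, move_epsilon = 0) {
  if (!is_complete(obs)) return(NA_real_)
  steps <- compute_steps(obs, move_epsilon)
  pl <- path_length(steps)
  if (is.na(pl) || pl == 0) return(NA_real_)
  min(max(net_displacement(obs) / pl, 0), 1)
}

#' Turn angles between consecutive movement steps
#'
#' Non-movement intervals are removed before differencing, so the heading
#' is carried across pauses by default: the turn after a pause compares
#' the new step's heading with the last moving step's heading.  With
#' `across_pauses = FALSE` only pairs of temporally adjacent moving steps
#' yield a turn.  The signed angle is the heading difference wrapped to
#' (-180, 180]; the absolute angle is its magnitude in \[0, 180\].
#'
#' @param steps a `steps` data frame from [compute_steps()].
#' @param across_pauses carry heading across non-movement intervals?
#' @return list with numeric vectors `signed` and `absolute` (degrees);
#'   both empty with fewer than 2 moving steps.
#' @export
turn_angles <- function(steps, across_pauses = TRUE) {
  mv <- steps[steps$moved, , drop = FALSE]
  if (nrow(mv) < 2L)
    return(list(signed = numeric(0), absolute = numeric(0)))
  signed <- wrap_deg(diff(mv$heading))
  if (!across_pauses) {
    adjacent <- mv$from_t[-1L] == mv$to_t[-nrow(mv)]
    signed <- signed[adjacent]
  }
  list(signed = signed, absolute = abs(signed))
}

#' Proportion of intervals with movement
#'
#' @param steps a `steps` data frame from [compute_steps()].
#' @return number of moving steps over the number of steps.
#' @export
proportion_moving <- function(steps) {
  stopifnot(nrow(steps) >= 1L)
  mean(steps$moved)
}

#' Visibility index of an observation
#'
#' The proportion of fix-to-fix transitions for which the destination was
#' visible (unobstructed at ground level) from the origin, taken from the
#' per-fix `visible_from_previous` flags.  If any non-initial fix lacks a
#' flag the index is undefined and `NA` is returned with a warning.
#'
#' @param obs an `observation`.
#' @return unitless value in \[0, 1\], or `NA_real_`.
#' @export
visibility_index <- function(obs) {
  flags <- obs$fixes$visible_from_previous[-1L]
  if (length(flags) == 0L) return(NA_real_)
  if (anyNA(flags)) {
    warning("observation '", obs$observation_id,
            "': visibility flags missing; visibility index undefined")
    return(NA_real_)
  }
  mean(flags)
}

#' Summarise one observation into its path metrics
#'
#' Computes the full metric set: moving-step lengths, whole-path metrics
#' (complete observations only), signed and folded turn angles,
#' proportion of intervals with movement, and the visibility index.
#'
#' @param obs an `observation`.
#' @param move_epsilon movement threshold in metres.
#' @param across_pauses carry heading across pauses for turn angles?
#' @return list of class `path_summary` with fields `observation_id`,
#'   `lizard_id`, `species`, `sex`, `svl_mm`, `n_fixes`, `n_intervals`,
#'   `complete`, `step_lengths` (moving steps only), `path_length`,
#'   `net_displacement`, `straightness_index`, `turn_angles_signed`,
#'   `turn_angles_abs`, `proportion_moving`, `visibility_index`.
#' @export
summarize_observation <- function(obs, move_epsilon = 0,
                                  across_pauses = TRUE) {
  steps <- compute_steps(obs, move_epsilon)
  ta <- turn_angles(steps, across_pauses)
  complete <- is_complete(obs)
  pl <- path_length(steps, complete)
  nd <- net_displacement(obs)
  si <- if (!complete || is.na(pl) || pl == 0) NA_real_ else
    min(max(nd / pl, 0), 1)
  structure(list(
    observation_id = obs$observation_id,
    lizard_id = obs$lizard_id,
    species = obs$species,
    sex = obs$sex,
    svl_mm = obs$svl_mm,
    n_fixes = n_fixes(obs),
    n_intervals = nrow(steps),
    complete = complete,
    step_lengths = steps$length[steps$moved],
    path_length = pl,
    net_displacement = nd,
    straightness_index = si,
    turn_angles_signed = ta$signed,
    turn_angles_abs = ta$absolute,
    proportion_moving = proportion_moving(steps),
    visibility_index = suppressWarnings(visibility_index(obs))),
    class = "path_summary")
}

#' Summarise every observation of a dataset
#'
#' @param dataset a `fix_dataset`.
#' @param move_epsilon movement threshold in metres.
#' @param across_pauses carry heading across pauses for turn angles?
#' @return data frame with one row per observation and the scalar fields
#'   of [summarize_observation()] (medians in place of the per-step
#'   vectors: `median_step_length`, `median_turn_angle_abs`,
#'   `n_moving_steps`, `n_turns`).
#' @export
summarize_dataset <- function(dataset, move_epsilon = 0,
                              across_pauses = TRUE) {
  rows <- lapply(dataset$observations, function(o) {
    s <- summarize_observation(o, move_epsilon, across_pauses)
    data.frame(observation_id = s$observation_id,
               lizard_id = s$lizard_id,
               species = s$species,
               sex = s$sex,
               svl_mm = s$svl_mm,
               n_fixes = s$n_fixes,
               n_intervals = s$n_intervals,
               complete = s$complete,
               n_moving_steps = length(s$step_lengths),
               median_step_length = if (length(s$step_lengths)) {
                 stats::median(s$step_lengths)
               } else NA_real_,
               path_length = s$path_length,
               net_displacement = s$net_displacement,
               straightness_index = s$straightness_index,
               n_turns = length(s$turn_angles_abs),
               median_turn_angle_abs = if (length(s$turn_angles_abs)) {
                 stats::median(s$turn_angles_abs)
               } else NA_real_,
               proportion_moving = s$proportion_moving,
               visibility_index = s$visibility_index,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Pool moving-step lengths across a dataset
#' @param dataset a `fix_dataset`.
#' @param move_epsilon movement threshold in metres.
#' @return numeric vector of all moving-step lengths, in observation order.
#' @export
pooled_step_lengths <- function(dataset, move_epsilon = 0) {
  unlist(lapply(dataset$observations, function(o) {
    s <- compute_steps(o, move_epsilon)
    s$length[s$moved]
  }), use.names = FALSE)
}

#' Pool turn angles across a dataset
#' @param dataset a `fix_dataset`.
#' @param move_epsilon movement threshold in metres.
#' @param folded return absolute angles in \[0, 180\] instead of signed?
#' @param across_pauses carry heading across pauses?
#' @return numeric vector of turn angles in degrees.
#' @export
pooled_turn_angles <- function(dataset, move_epsilon = 0, folded = FALSE,
                               across_pauses = TRUE) {
  ang <- unlist(lapply(dataset$observations, function(o) {
    turn_angles(compute_steps(o, move_epsilon), across_pauses)$signed
  }), use.names = FALSE)
  if (folded) abs(ang) else ang
}
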