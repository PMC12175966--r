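#' Open-field kinematics from a point trajectory
#'
#' Computes the movement metrics used to quantify a mouse's freedom of
#' movement: total walking distance, total (absolute) turning angle, and
#' per-frame linear and angular speed. Heading is taken from frame-to-frame
#' displacement vectors; displacements shorter than `min_displacement`
#' contribute no heading change, which suppresses tracking jitter when the
#' animal is stationary. Heading increments are wrapped into (-pi, pi] before
#' absolute summation, so the turning angle is total rotation regardless of
#' direction.
#'
#' @param traj Tibble with columns `time_s`, `x_cm`, `y_cm`, uniformly
#'   sampled.
#' @param min_displacement Minimum displacement (cm) for a frame to qualify
#'   for heading estimation (default 0.2).
#' @return An object of class `"kinematics"`. Use [glance()] for the scalar
#'   summary (walking distance in m, turning angle in rad) and [tidy()] for
#'   the per-frame series (speed in cm/s, angular speed in rad/s).
#' @export
compute_kinematics <- function(traj, min_displacement = 0.2) {
  required <- c("time_s", "x_cm", "y_cm")
  if (!all(required %in% names(traj))) {
    stop_config("`traj` must have columns time_s, x_cm, y_cm.")
  }
  if (nrow(traj) < 3L) stop_config("trajectory needs at least 3 samples.")
  if (any(!is.finite(traj$x_cm)) || any(!is.finite(traj$y_cm))) {
    stop_config("trajectory coordinates must be finite.")
  }
  check_number(min_displacement, "min_displacement", non_negative = TRUE)
  dt <- check_uniform_time(traj$time_s)
  frame_rate <- 1 / dt
  n <- nrow(traj)

  dx <- diff(traj$x_cm)
  dy <- diff(traj$y_cm)
  disp <- sqrt(dx^2 + dy^2)                     # cm per frame interval
  walking_distance_m <- sum(disp) / 100

  # linear speed: central differences, one-sided at the ends
  cs <- numeric(n)
  if (n > 2) {
    cs[2:(n - 1)] <- sqrt((traj$x_cm[3:n] - traj$x_cm[1:(n - 2)])^2 +
                          (traj$y_cm[3:n] - traj$y_cm[1:(n - 2)])^2) / (2 * dt)
  }
  cs[1] <- disp[1] / dt
  cs[n] <- disp[n - 1] / dt

  heading <- ifelse(disp >= min_displacement & disp > 0, atan2(dy, dx), NA_real_)
  qual <- which(!is.na(heading))
  ang_speed <- numeric(n)     # rad/s, attributed to the later displacement's frame
  turning_angle <- 0
  if (length(qual) >= 2L) {
    dh <- abs(wrap_angle(diff(heading[qual])))
    turning_angle <- sum(dh)
    ang_speed[qual[-1] + 1L] <- dh * frame_rate
  }

  structure(
    list(frames = tibble(frame = seq_len(n), time_s = traj$time_s,
                         x_cm = traj$x_cm, y_cm = traj$y_cm,
                         speed_cm_s = cs, ang_speed_rad_s = ang_speed),
         walking_distance_m = walking_distance_m,
         turning_angle_rad = turning_angle,
         frame_rate = frame_rate, min_displacement = min_displacement),
    class = "kinematics")
}

#' @export
print.kinematics <- function(x, ...) {
  cat(sprintf("<kinematics: %d frames at %.3g fps; distance %.2f m; turning %.2f rad>\n",
              nrow(x$frames), x$frame_rate, x$walking_distance_m,
              x$turning_angle_rad))
  invisible(x)
}

#' @rdname compute_kinematics
#' @param x A `"kinematics"` object.
#' @param ... Unused.
#' @method tidy kinematics
#' @export
tidy.kinematics <- function(x, ...) x$frames

#' @rdname compute_kinematics
#' @method glance kinematics
#' @export
glance.kinematics <- function(x, ...) {
  tibble(walking_distance_m = x$walking_distance_m,
         turning_angle_rad = x$turning_angle_rad,
         mean_speed_cm_s = mean(x$frames$speed_cm_s),
         n_frames = nrow(x$frames),
         duration_s = nrow(x$frames) / x$frame_rate)
}

#' Segment locomotion and rest by a velocity threshold
#'
#' A frame is locomotion iff its speed is at or above `threshold`
#' (1 cm/s by default, the value used to distinguish locomotion from resting
#' periods). Runs of either state shorter than `min_bout` seconds are
#' absorbed into the surrounding state, shortest run first (ties: earlier run
#' first), so brief threshold crossings do not fragment bouts.
#'
#' @param data Tibble with columns `time_s` and `speed_cm_s` (as produced by
#'   `tidy(compute_kinematics(...))`), or a numeric speed vector (then
#'   `frame_rate` is required).
#' @param threshold Speed threshold in cm/s (default 1).
#' @param min_bout Minimum run duration in seconds (default 1); runs strictly
#'   shorter are merged away. Use 0 to disable smoothing.
#' @param frame_rate Frames per second; taken from `time_s` when `data` is a
#'   tibble.
#' @param speed_col Name of the speed column (default `"speed_cm_s"`).
#' @return An object of class `"locomotion_mask"` with elements `mask`
#'   (logical per frame), `bouts` (tibble of half-open `[start_frame,
#'   end_frame)` locomotion intervals), `frame_rate`, `threshold`. [tidy()]
#'   returns the per-frame tibble.
#' @export
segment_locomotion <- function(data, threshold = 1, min_bout = 1,
                               frame_rate = NULL, speed_col = "speed_cm_s") {
  check_number(threshold, "threshold", positive = TRUE)
  check_number(min_bout, "min_bout", non_negative = TRUE)
  if (is.data.frame(data)) {
    if (!speed_col %in% names(data)) {
      stop_config("`data` must contain a `%s` column.", speed_col)
    }
    speed <- data[[speed_col]]
    if (is.null(frame_rate)) {
      if (!"time_s" %in% names(data)) {
        stop_config("supply `frame_rate` or a time_s column.")
      }
      frame_rate <- 1 / check_uniform_time(data$time_s)
    }
  } else {
    speed <- as.numeric(data)
    if (is.null(frame_rate)) stop_config("`frame_rate` is required for vector input.")
  }
  check_number(frame_rate, "frame_rate", positive = TRUE)
  if (length(speed) == 0L) stop_config("empty speed series.")

  mask <- speed >= threshold
  mask <- merge_short_runs(mask, min_frames = min_bout * frame_rate)

  structure(
    list(mask = mask, bouts = runs_to_bouts(mask, frame_rate),
         frame_rate = frame_rate, threshold = threshold),
    class = "locomotion_mask")
}

# Absorb runs (of either state) strictly shorter than min_frames into their
# surroundings: repeatedly flip the shortest short run (ties: earliest).
merge_short_runs <- function(mask, min_frames) {
  repeat {
    r <- rle(mask)
    if (length(r$lengths) <= 1L) return(mask)
    short <- which(r$lengths < min_frames)
    if (!length(short)) return(mask)
    k <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    mask[starts[k]:ends[k]] <- !r$values[k]
  }
}

runs_to_bouts <- function(mask, frame_rate) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  tibble(start_frame = starts[keep], end_frame = ends[keep] + 1L,
         start_s = (starts[keep] - 1L) / frame_rate,
         end_s = ends[keep] / frame_rate)
}

#' @export
print.locomotion_mask <- function(x, ...) {
  cat(sprintf("<locomotion_mask: %d/%d locomotion frames in %d bouts (threshold %.3g)>\n",
              sum(x$mask), length(x$mask), nrow(x$bouts), x$threshold))
  invisible(x)
}

#' @rdname segment_locomotion
#' @param x A `"locomotion_mask"` object.
#' @param ... Unused.
#' @method tidy locomotion_mask
#' @export
tidy.locomotion_mask <- function(x, ...) {
  tibble(frame = seq_along(x$mask),
         time_s = (seq_along(x$mask) - 1L) / x$frame_rate,
         locomotion = x$mask)
}

#' Locomotion segmentation for the head-fixed platter
#'
#' For head-fixed sessions locomotion is inferred from the platter's angular
#' velocity: the linear speed threshold (1 cm/s by default) is converted to
#' an angular threshold `omega_th = linear_threshold / effective_radius`, and
#' `|omega|` is segmented exactly as arena speed is.
#'
#' @param platter Tibble with columns `time_s` and `omega_rad_s`.
#' @param linear_threshold Linear-equivalent speed threshold, cm/s (default 1).
#' @param effective_radius Distance (cm) of the animal's paws from the
#'   platter rotation axis (default 10); sets the angular/linear conversion.
#' @param min_bout Minimum run duration in seconds (default 1).
#' @return A `"locomotion_mask"` (see [segment_locomotion()]).
#' @export
platter_locomotion <- function(platter, linear_threshold = 1,
                               effective_radius = 10, min_bout = 1) {
  if (!all(c("time_s", "omega_rad_s") %in% names(platter))) {
    stop_config("`platter` must have columns time_s and omega_rad_s.")
  }
  check_number(effective_radius, "effective_radius", positive = TRUE)
  check_number(linear_threshold, "linear_threshold", positive = TRUE)
  frame_rate <- 1 / check_uniform_time(platter$time_s)
  segment_locomotion(abs(platter$omega_rad_s),
                     threshold = linear_threshold / effective_radius,
                     min_bout = min_bout, frame_rate = frame_rate)
}

#' Per-condition movement summary and percent changes
#'
#' Summarises per-session walking distance and turning angle by condition and
#' computes percent changes between named condition pairs,
#' `(mean_A - mean_B) / mean_B * 100`, truncated to integer percent.
#'
#' @param sessions Tibble with one row per session: columns `condition`,
#'   `walking_distance_m`, `turning_angle_rad`, optionally `mouse`.
#' @param pairs List of 2-vectors `c(A, B)`; the change of A relative to B is
#'   reported. Default compares "on" vs "off" and "on" vs "free".
#' @return A list of class `"session_summary"` with tibbles
#'   `condition_means` and `percent_change`. A zero reference mean yields
#'   `NA` with `undefined = TRUE`, flagged with a warning.
#' @export
session_summary_table <- function(sessions,
                                  pairs = list(c("on", "off"), c("on", "free"))) {
  needed <- c("condition", "walking_distance_m", "turning_angle_rad")
  if (!all(needed %in% names(sessions))) {
    stop_config("`sessions` must have columns %s.", paste(needed, collapse = ", "))
  }
  means <- sessions |>
    group_by(.data$condition) |>
    summarise(walking_distance_m = mean(.data$walking_distance_m),
              turning_angle_rad = mean(.data$turning_angle_rad),
              n_sessions = dplyr::n(), .groups = "drop")

  pc_rows <- purrr::map_dfr(pairs, function(p) {
    a <- means[means$condition == p[1], ]
    b <- means[means$condition == p[2], ]
    if (nrow(a) == 0L || nrow(b) == 0L) {
      stop_config("condition pair (%s, %s) not present in `sessions`.", p[1], p[2])
    }
    purrr::map_dfr(c("walking_distance_m", "turning_angle_rad"), function(m) {
      undefined <- b[[m]] == 0
      if (undefined) {
        warn(sprintf("zero reference mean for %s in %s vs %s; percent change undefined.",
                     m, p[1], p[2]))
      }
      tibble(metric = m, condition_a = p[1], condition_b = p[2],
             mean_a = a[[m]], mean_b = b[[m]],
             percent_change = if (undefined) NA_real_ else
               trunc((a[[m]] - b[[m]]) / b[[m]] * 100),
             undefined = undefined)
    })
  })

  structure(list(condition_means = means, percent_change = pc_rows),
            class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat("Condition means:\n"); print(x$condition_means)
  cat("\nPercent changes (truncated to integer %):\n"); print(x$percent_change)
  invisible(x)
}

#' @rdname session_summary_table
#' @param x A `"session_summary"` object.
#' @param ... Unused.
#' @method tidy session_summary
#' @export
tidy.session_summary <- function(x, ...) x$percent_change

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)`, elementwise; a thin validated wrapper matching
#' `stats::p.adjust(p, "bonferroni", n = m)`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m Number of comparisons (default `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_config("p-values must lie in [0, 1].")
  }
  check_number(m, "m", positive = TRUE)
  pmin(1, m * p)
}
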