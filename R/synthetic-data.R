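#' Session specification
#'
#' Describes one imaging/behavior session: the experimental condition, frame
#' count and rate, and arena geometry. Defaults mirror the study design:
#' 1000-frame sessions recorded at 3 frames/s (333 s) in a 10-inch
#' (25.4 cm) square arena.
#'
#' @param condition One of `"free"`, `"on"`, `"off"`, `"fixed"`. `"on"`/`"off"`
#'   refer to the commutator's torque compensation being enabled or disabled;
#'   `"fixed"` is the head-fixed platter condition.
#' @param n_frames Number of imaging frames (default 1000).
#' @param frame_rate Acquisition rate in Hz (default 3).
#' @param arena_side Side of the square arena in cm (default 25.4).
#' @param session_id Free-form session label.
#' @return A list of class `"session_spec"`.
#' @export
session_spec <- function(condition = c("free", "on", "off", "fixed"),
                         n_frames = 1000L, frame_rate = 3, arena_side = 25.4,
                         session_id = "s1") {
  condition <- match.arg(condition)
  check_number(n_frames, "n_frames", positive = TRUE)
  check_number(frame_rate, "frame_rate", positive = TRUE)
  check_number(arena_side, "arena_side", positive = TRUE)
  structure(
    list(condition = condition, n_frames = as.integer(n_frames),
         frame_rate = frame_rate, duration_s = n_frames / frame_rate,
         arena_side = arena_side, session_id = session_id),
    class = "session_spec")
}

#' Per-neuron ground truth for the synthetic cohort
#'
#' One row per neuron: the baseline event rate under the compensation-"on"
#' condition and the condition gains applied under "off" and head-"fixed".
#' A gain > 1 marks a neuron whose firing activity truly increases under that
#' condition (ground-truth label `"increased"`), < 1 `"decreased"`, and == 1
#' `"other"`. The gain scales both the Poisson event rate and the transient
#' amplitude, so the per-event fluorescence rate r shifts with it.
#'
#' @param n_neurons Number of neurons.
#' @param base_event_rate Events/min under the "on" condition (default 6).
#' @param multiplier_off,multiplier_fixed Condition gains; recycled to
#'   `n_neurons`.
#' @param amplitude Peak transient amplitude in dF/F units (default 1).
#' @return A tibble with one row per neuron, including the ground-truth
#'   labels `true_label_off_vs_on` and `true_label_fixed_vs_on`.
#' @export
neuron_ground_truth <- function(n_neurons, base_event_rate = 6,
                                multiplier_off = 1, multiplier_fixed = 1,
                                amplitude = 1) {
  check_number(n_neurons, "n_neurons", positive = TRUE)
  if (any(base_event_rate <= 0)) stop_config("`base_event_rate` must be > 0.")
  if (any(multiplier_off <= 0) || any(multiplier_fixed <= 0)) {
    stop_config("condition multipliers must be > 0.")
  }
  label_of <- function(m) {
    dplyr::case_when(m > 1 ~ "increased", m < 1 ~ "decreased", TRUE ~ "other")
  }
  tibble(
    neuron_id = seq_len(n_neurons),
    base_event_rate = rep_len(base_event_rate, n_neurons),
    rate_multiplier_off = rep_len(multiplier_off, n_neurons),
    rate_multiplier_fixed = rep_len(multiplier_fixed, n_neurons),
    amplitude = rep_len(amplitude, n_neurons),
    true_label_off_vs_on = label_of(.data$rate_multiplier_off),
    true_label_fixed_vs_on = label_of(.data$rate_multiplier_fixed))
}

condition_multiplier <- function(gt_row, condition) {
  switch(condition,
         off = gt_row$rate_multiplier_off,
         fixed = gt_row$rate_multiplier_fixed,
         1)
}

# Double-exponential calcium impulse response, normalised to unit peak.
calcium_kernel <- function(t, rise, decay) {
  if (rise >= decay) stop_config("`kernel_rise` must be < `kernel_decay`.")
  h <- exp(-t / decay) - exp(-t / rise)
  t_peak <- rise * decay / (decay - rise) * log(decay / rise)
  h_peak <- exp(-t_peak / decay) - exp(-t_peak / rise)
  h / h_peak
}

#' Generate synthetic dF/F traces
#'
#' Draws event times for each neuron as a homogeneous Poisson process at
#' `base_event_rate` times the condition gain, convolves them with a
#' double-exponential GCaMP6m-like kernel (unit peak), scales by the neuron's
#' amplitude times the condition gain, and adds i.i.d. Gaussian noise. When a
#' locomotion mask is supplied (and `placement = "locomotion"`), events are
#' placed only inside locomotion frames, matching an analysis that scores
#' firing during locomotion periods.
#'
#' @param ground_truth Tibble from [neuron_ground_truth()].
#' @param spec A [session_spec()].
#' @param noise_sigma Gaussian noise sd in dF/F units (default 0.05).
#' @param kernel_rise,kernel_decay Kernel time constants in seconds
#'   (defaults 0.1 and 0.6).
#' @param locomotion Optional logical vector of length `n_frames` marking
#'   locomotion frames.
#' @param placement `"locomotion"` (events restricted to locomotion frames
#'   when a mask is given) or `"uniform"`.
#' @param seed Integer seed; every stochastic generator in the package takes
#'   an explicit seed rather than using global RNG state.
#' @return A long tibble (`neuron_id`, `frame`, `time_s`, `dff`, `condition`,
#'   `session_id`) carrying the ground-truth event table as attribute
#'   `"ground_truth_events"` (see [ground_truth_events()]).
#' @export
generate_dff <- function(ground_truth, spec, noise_sigma = 0.05,
                         kernel_rise = 0.1, kernel_decay = 0.6,
                         locomotion = NULL, placement = c("locomotion", "uniform"),
                         seed = 1L) {
  placement <- match.arg(placement)
  if (!inherits(spec, "session_spec")) stop_config("`spec` must be a session_spec().")
  check_number(noise_sigma, "noise_sigma", non_negative = TRUE)
  check_number(kernel_rise, "kernel_rise", positive = TRUE)
  check_number(kernel_decay, "kernel_decay", positive = TRUE)
  if (kernel_rise >= kernel_decay) stop_config("`kernel_rise` must be < `kernel_decay`.")
  n <- spec$n_frames
  dt <- 1 / spec$frame_rate
  t_frames <- (seq_len(n) - 1L) * dt
  if (!is.null(locomotion) && length(locomotion) != n) {
    stop_config("`locomotion` mask must have length n_frames.")
  }

  withr::with_seed(seed, {
    traces <- purrr::map(seq_len(nrow(ground_truth)), function(i) {
      gt <- ground_truth[i, ]
      mult <- condition_multiplier(gt, spec$condition)
      rate_hz <- gt$base_event_rate / 60 * mult
      amp <- gt$amplitude * mult
      if (!is.null(locomotion) && placement == "locomotion") {
        loco_frames <- which(locomotion)
        t_avail <- length(loco_frames) * dt
        n_ev <- rpois(1L, rate_hz * t_avail)
        ev_t <- if (n_ev > 0 && length(loco_frames) > 0) {
          sort((sample(loco_frames, n_ev, replace = TRUE) - 1L) * dt +
                 runif(n_ev, 0, dt))
        } else numeric(0)
      } else {
        n_ev <- rpois(1L, rate_hz * spec$duration_s)
        ev_t <- sort(runif(n_ev, 0, spec$duration_s))
      }
      dff <- numeric(n)
      for (te in ev_t) {
        idx <- which(t_frames >= te)
        if (length(idx)) {
          dff[idx] <- dff[idx] + amp * calcium_kernel(t_frames[idx] - te,
                                                      kernel_rise, kernel_decay)
        }
      }
      if (noise_sigma > 0) dff <- dff + rnorm(n, 0, noise_sigma)
      list(
        trace = tibble(neuron_id = gt$neuron_id, frame = seq_len(n),
                       time_s = t_frames, dff = dff,
                       condition = spec$condition, session_id = spec$session_id),
        events = tibble(neuron_id = gt$neuron_id, event_time_s = ev_t,
                        amplitude = amp, condition = spec$condition,
                        session_id = spec$session_id))
    })
    out <- dplyr::bind_rows(purrr::map(traces, "trace"))
    attr(out, "ground_truth_events") <- dplyr::bind_rows(purrr::map(traces, "events"))
    out
  })
}

#' Ground-truth event times attached to a synthetic trace table
#'
#' @param x A tibble returned by [generate_dff()].
#' @return Tibble of true event times (`neuron_id`, `event_time_s`,
#'   `amplitude`, `condition`, `session_id`).
#' @export
ground_truth_events <- function(x) {
  ev <- attr(x, "ground_truth_events", exact = TRUE)
  if (is.null(ev)) stop_config("no ground-truth events attached to this object.")
  ev
}

#' Generate a correlated-random-walk arena trajectory
#'
#' Per-frame step lengths are exponential with mean `step_speed_mean / frame_rate`;
#' heading increments are wrapped-normal with sd `1/sqrt(turn_concentration)`.
#' Walls of the square arena reflect both the position and the heading: a
#' step crossing a wall is folded back inside and the walker's heading
#' bounces with it, so every position lies in `[0, arena_side]^2` and the
#' walker does not dwell pushing against a wall.
#'
#' @param spec A [session_spec()].
#' @param step_speed_mean Mean speed in cm/s (default 3).
#' @param turn_concentration Concentration of the heading-increment
#'   distribution; larger values give straighter paths (default 4).
#' @param seed Integer seed.
#' @return Tibble (`frame`, `time_s`, `x_cm`, `y_cm`).
#' @export
generate_trajectory <- function(spec, step_speed_mean = 3,
                                turn_concentration = 4, seed = 1L) {
  if (!inherits(spec, "session_spec")) stop_config("`spec` must be a session_spec().")
  check_number(step_speed_mean, "step_speed_mean", non_negative = TRUE)
  check_number(turn_concentration, "turn_concentration", positive = TRUE)
  n <- spec$n_frames
  dt <- 1 / spec$frame_rate
  side <- spec$arena_side
  withr::with_seed(seed, {
    x <- numeric(n); y <- numeric(n)
    x[1] <- side / 2; y[1] <- side / 2
    heading <- runif(1, -pi, pi)
    turn_sd <- 1 / sqrt(turn_concentration)
    if (n > 1) {
      steps <- if (step_speed_mean > 0) rexp(n - 1, 1 / (step_speed_mean * dt)) else numeric(n - 1)
      turns <- rnorm(n - 1, 0, turn_sd)
      for (i in 2:n) {
        heading <- wrap_angle(heading + turns[i - 1])
        xi <- x[i - 1] + steps[i - 1] * cos(heading)
        yi <- y[i - 1] + steps[i - 1] * sin(heading)
        x[i] <- reflect_into(xi, side)
        y[i] <- reflect_into(yi, side)
        sx <- if (reflect_flips(xi, side)) -1 else 1
        sy <- if (reflect_flips(yi, side)) -1 else 1
        if (sx < 0 || sy < 0) {
          heading <- atan2(sy * sin(heading), sx * cos(heading))
        }
      }
    }
    tibble(frame = seq_len(n), time_s = (seq_len(n) - 1L) * dt,
           x_cm = x, y_cm = y)
  })
}

# Fold a coordinate back into [0, side] by repeated reflection at the walls.
reflect_into <- function(z, side) {
  period <- 2 * side
  z <- z %% period
  ifelse(z > side, period - z, z)
}

# TRUE when folding z reverses the direction of travel along that axis
# (odd number of wall reflections).
reflect_flips <- function(z, side) (z %% (2 * side)) > side

wrap_angle <- function(a) {
  # wrap into (-pi, pi]
  w <- (a + pi) %% (2 * pi) - pi
  ifelse(w == -pi, pi, w)
}

#' Generate a head-fixed platter angular-velocity trace
#'
#' Alternates rest (omega near 0) and locomotion bouts (omega near
#' `omega_locomotion`) according to a bout schedule, with additive Gaussian
#' noise. Bout boundaries are retained as ground truth for testing the
#' platter locomotion segmentation.
#'
#' @param spec A [session_spec()] with `condition = "fixed"`.
#' @param bouts Tibble with columns `start_s`, `end_s` giving locomotion bout
#'   intervals (half-open, in seconds from session start).
#' @param omega_locomotion Platter angular velocity during bouts, rad/s.
#' @param noise_sd Gaussian noise sd on omega, rad/s (default 0).
#' @param seed Integer seed.
#' @return Tibble (`frame`, `time_s`, `omega_rad_s`) with attribute
#'   `"ground_truth_bouts"`.
#' @export
generate_platter <- function(spec, bouts, omega_locomotion, noise_sd = 0,
                             seed = 1L) {
  if (!inherits(spec, "session_spec")) stop_config("`spec` must be a session_spec().")
  if (spec$condition != "fixed") {
    stop_config("platter traces exist only for the head-fixed condition.")
  }
  check_number(omega_locomotion, "omega_locomotion")
  check_number(noise_sd, "noise_sd", non_negative = TRUE)
  if (!all(c("start_s", "end_s") %in% names(bouts))) {
    stop_config("`bouts` must have columns start_s and end_s.")
  }
  n <- spec$n_frames
  dt <- 1 / spec$frame_rate
  t_frames <- (seq_len(n) - 1L) * dt
  omega <- numeric(n)
  for (j in seq_len(nrow(bouts))) {
    inside <- t_frames >= bouts$start_s[j] & t_frames < bouts$end_s[j]
    omega[inside] <- omega_locomotion
  }
  if (noise_sd > 0) {
    omega <- withr::with_seed(seed, omega + rnorm(n, 0, noise_sd))
  }
  out <- tibble(frame = seq_len(n), time_s = t_frames, omega_rad_s = omega)
  attr(out, "ground_truth_bouts") <- as_tibble(bouts)
  out
}

#' Draw per-neuron fluorescence-rate sets directly
#'
#' Event-level shortcut used for statistical calibration experiments: instead
#' of synthesising full traces and re-detecting events, draw each neuron's
#' per-event fluorescence rates r directly from a log-normal distribution
#' whose scale is multiplied by the condition gain. Useful for type-I-error
#' and power studies at large cohort sizes.
#'
#' @param ground_truth Tibble from [neuron_ground_truth()].
#' @param conditions Conditions to draw (default `c("on", "off", "fixed")`).
#' @param n_events Events per neuron per condition (default 30).
#' @param sdlog Log-scale sd of the rate distribution (default 0.5).
#' @param seed Integer seed.
#' @return A rate-set tibble (`neuron_id`, `condition`, `rates` list-column,
#'   `n_events`) as produced by [build_rate_sets()].
#' @export
generate_rate_sets <- function(ground_truth, conditions = c("on", "off", "fixed"),
                               n_events = 30L, sdlog = 0.5, seed = 1L) {
  check_number(n_events, "n_events", positive = TRUE)
  check_number(sdlog, "sdlog", positive = TRUE)
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(i = seq_len(nrow(ground_truth)),
                               condition = conditions)
    rates <- purrr::map2(grid$i, grid$condition, function(i, cond) {
      gt <- ground_truth[i, ]
      mult <- condition_multiplier(gt, cond)
      rlnorm(n_events, meanlog = log(gt$amplitude * mult), sdlog = sdlog)
    })
    tibble(neuron_id = ground_truth$neuron_id[grid$i],
           condition = grid$condition, rates = rates,
           n_events = lengths(rates), insufficient = lengths(rates) == 0L)
  })
}
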