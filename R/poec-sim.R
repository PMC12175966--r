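#' Configuration for the torque-compensation commutator simulator
#'
#' Parameters of the closed loop: a torsional-spring tether whose torque is
#' sensed each tick; when the sensed magnitude reaches `torque_threshold`
#' (0.8 mN·m by default) the stepper rotates the commutator in microsteps of
#' `step_angle` (0.225 deg) until the recomputed torque falls back below the
#' threshold (or the per-tick step budget `max_step_rate * sim_dt` is
#' exhausted). The stepper driver's microsecond-scale response time is far
#' below any sensible tick length and is modelled as zero latency within a
#' tick.
#'
#' @param torque_threshold Activation threshold, mN·m (default 0.8).
#' @param step_angle Microstep size, degrees (default 0.225).
#' @param max_step_rate Maximum stepping rate, steps/s (default 20000).
#' @param controller_latency Driver response time, s (default 1.2e-6); must
#'   not exceed `sim_dt`.
#' @param tether_stiffness Torsional stiffness, mN·m/rad (default 2: a few
#'   degrees of twist reach the threshold).
#' @param sim_dt Simulation tick, s (default 1e-3).
#' @param sensor_noise_sd Gaussian noise sd on the sensed torque, mN·m
#'   (default 0).
#' @return A list of class `"poec_config"`.
#' @export
poec_config <- function(torque_threshold = 0.8, step_angle = 0.225,
                        max_step_rate = 20000, controller_latency = 1.2e-6,
                        tether_stiffness = 2, sim_dt = 1e-3,
                        sensor_noise_sd = 0) {
  check_number(torque_threshold, "torque_threshold", positive = TRUE)
  check_number(step_angle, "step_angle", positive = TRUE)
  check_number(max_step_rate, "max_step_rate", positive = TRUE)
  check_number(controller_latency, "controller_latency", positive = TRUE)
  check_number(tether_stiffness, "tether_stiffness", positive = TRUE)
  check_number(sim_dt, "sim_dt", positive = TRUE)
  check_number(sensor_noise_sd, "sensor_noise_sd", non_negative = TRUE)
  if (controller_latency > sim_dt) {
    stop_config("`controller_latency` must be <= `sim_dt` (latency is subsumed in one tick).")
  }
  structure(list(torque_threshold = torque_threshold, step_angle = step_angle,
                 max_step_rate = max_step_rate,
                 controller_latency = controller_latency,
                 tether_stiffness = tether_stiffness, sim_dt = sim_dt,
                 sensor_noise_sd = sensor_noise_sd),
            class = "poec_config")
}

#' Simulate the closed-loop torque-compensating commutator
#'
#' Discrete-time simulation of the feedback loop. Each tick: the tether
#' twist is `phi = heading - commutator_angle` and the spring torque
#' `tau = stiffness * phi`; the sensed torque (plus optional sensor noise)
#' is compared with the threshold and, with compensation enabled, the
#' stepper unwinds the twist in microsteps until the recomputed torque
#' magnitude drops below the threshold. With compensation off the commutator
#' never moves and the spring law `tau = stiffness * twist` holds exactly.
#'
#' @param heading Animal heading in rad: a numeric vector sampled at
#'   `cfg$sim_dt`, or a tibble with columns `time_s` and `heading_rad`.
#' @param cfg A [poec_config()].
#' @param compensation Logical; simulate with the feedback loop enabled?
#' @param seed Integer seed (used only when `sensor_noise_sd > 0`).
#' @return Object of class `"poec_sim"`: `ticks` tibble (`tick`, `time_s`,
#'   `heading_rad`, `commutator_rad`, `torque_mNm` — the post-compensation
#'   torque the animal sustains over the tick), `total_steps`,
#'   `max_abs_torque` (mN·m), `rotational_work_uJ` (integral of torque over
#'   animal heading change, in microjoules). [tidy()] returns the tick
#'   table, [glance()] the scalar summary.
#' @export
simulate_poec <- function(heading, cfg = poec_config(), compensation = TRUE,
                          seed = 1L) {
  if (!inherits(cfg, "poec_config")) stop_config("`cfg` must be a poec_config().")
  if (is.data.frame(heading)) {
    if (!all(c("time_s", "heading_rad") %in% names(heading))) {
      stop_config("`heading` tibble must have columns time_s and heading_rad.")
    }
    dt <- check_uniform_time(heading$time_s)
    if (abs(dt - cfg$sim_dt) > 1e-9 * max(cfg$sim_dt, 1)) {
      stop_config("heading sampling interval (%.3g s) differs from cfg$sim_dt (%.3g s).",
                  dt, cfg$sim_dt)
    }
    heading <- heading$heading_rad
  }
  heading <- as.numeric(heading)
  if (length(heading) < 1L || any(!is.finite(heading))) {
    stop_config("`heading` must be a nonempty finite series.")
  }

  n <- length(heading)
  k <- cfg$tether_stiffness
  thr <- cfg$torque_threshold
  step_rad <- cfg$step_angle * pi / 180
  max_steps_tick <- max(1L, floor(cfg$max_step_rate * cfg$sim_dt))
  noise <- if (cfg$sensor_noise_sd > 0) {
    withr::with_seed(seed, rnorm(n, 0, cfg$sensor_noise_sd))
  } else numeric(n)

  comm <- 0
  total_steps <- 0L
  comm_trace <- numeric(n)
  torque <- numeric(n)
  for (i in seq_len(n)) {
    tau <- k * (heading[i] - comm)
    if (compensation && abs(tau + noise[i]) >= thr) {
      dir <- sign(tau + noise[i])
      s <- 0L
      while (s < max_steps_tick && abs(k * (heading[i] - comm)) >= thr) {
        comm <- comm + dir * step_rad
        s <- s + 1L
      }
      total_steps <- total_steps + s
    }
    comm_trace[i] <- comm
    torque[i] <- k * (heading[i] - comm)
  }

  work_mJ <- sum(torque * c(0, diff(heading)))   # mN·m x rad = mJ
  structure(
    list(ticks = tibble(tick = seq_len(n), time_s = (seq_len(n) - 1L) * cfg$sim_dt,
                        heading_rad = heading, commutator_rad = comm_trace,
                        torque_mNm = torque),
         total_steps = total_steps,
         max_abs_torque = max(abs(torque)),
         rotational_work_uJ = work_mJ * 1000,
         compensation = compensation, config = cfg),
    class = "poec_sim")
}

#' @export
print.poec_sim <- function(x, ...) {
  cat(sprintf(
    "<poec_sim: compensation %s; %d ticks; steps %d; max |torque| %.3g mN·m; work %.3g uJ>\n",
    if (x$compensation) "on" else "off", nrow(x$ticks), x$total_steps,
    x$max_abs_torque, x$rotational_work_uJ))
  invisible(x)
}

#' @rdname simulate_poec
#' @param x A `"poec_sim"` object.
#' @param ... Unused.
#' @method tidy poec_sim
#' @export
tidy.poec_sim <- function(x, ...) x$ticks

#' @rdname simulate_poec
#' @method glance poec_sim
#' @export
glance.poec_sim <- function(x, ...) {
  tibble(compensation = x$compensation, total_steps = x$total_steps,
         max_abs_torque_mNm = x$max_abs_torque,
         rotational_work_uJ = x$rotational_work_uJ,
         final_twist_rad = x$ticks$heading_rad[nrow(x$ticks)] -
           x$ticks$commutator_rad[nrow(x$ticks)],
         n_ticks = nrow(x$ticks))
}

#' Convert a limb force into tether torque
#'
#' `tau = (force_gram * 1e-3 kg * 9.81 m/s^2) * (lever_arm * 1e-3 m)`,
#' reported in mN·m. Useful for relating the activation threshold to the
#' force an animal must exert.
#'
#' @param force_gram Force in grams-force.
#' @param lever_arm_mm Lever arm in mm.
#' @return Torque in mN·m.
#' @export
torque_from_force <- function(force_gram, lever_arm_mm) {
  if (any(force_gram < 0) || any(lever_arm_mm < 0)) {
    stop_config("force and lever arm must be non-negative.")
  }
  force_gram * 1e-3 * 9.81 * lever_arm_mm * 1e-3 * 1e3
}

#' Run the simulator with compensation on and off on the same heading
#'
#' @param heading As in [simulate_poec()].
#' @param cfg A [poec_config()].
#' @param seed Seed shared by both runs.
#' @return List with elements `on`, `off` (the two `"poec_sim"` results) and
#'   `summary`, a tibble of per-mode max torque, rotational work and step
#'   count plus the on/off work ratio.
#' @export
compare_modes <- function(heading, cfg = poec_config(), seed = 1L) {
  on <- simulate_poec(heading, cfg, compensation = TRUE, seed = seed)
  off <- simulate_poec(heading, cfg, compensation = FALSE, seed = seed)
  summary <- dplyr::bind_rows(glance(on), glance(off)) |>
    mutate(mode = c("on", "off"), .before = 1) |>
    select(-"compensation")
  list(on = on, off = off, summary = summary,
       work_ratio = on$rotational_work_uJ / off$rotational_work_uJ)
}

#' Default multi-turn heading scenario
#'
#' A constant-rate heading ramp: `n_turns` full revolutions at `turn_rate`
#' turns/s, sampled at the configuration tick. This is the default scenario
#' used to contrast compensation on/off.
#'
#' @param n_turns Number of full revolutions (default 5).
#' @param turn_rate Turns per second (default 0.5).
#' @param sim_dt Tick length in s (default 1e-3).
#' @return Tibble (`time_s`, `heading_rad`).
#' @export
heading_ramp <- function(n_turns = 5, turn_rate = 0.5, sim_dt = 1e-3) {
  check_number(n_turns, "n_turns", positive = TRUE)
  check_number(turn_rate, "turn_rate", positive = TRUE)
  duration <- n_turns / turn_rate
  t <- seq(0, duration, by = sim_dt)
  tibble(time_s = t, heading_rad = 2 * pi * turn_rate * t)
}
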