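#' Pipeline run configuration
#'
#' Assembles and validates the configuration for an end-to-end synthetic run:
#' cohort composition, session geometry, generator noise, segmentation and
#' detection parameters, classification settings, and the commutator
#' scenario. Unknown keys are rejected, so typos cannot silently fall back
#' to defaults.
#'
#' @param seed Master seed; each stage derives its own seed from it by a
#'   fixed offset scheme (trajectory, platter, traces, rate draws), so reruns
#'   with the same configuration are bit-identical.
#' @param n_neurons Cohort size (default 60).
#' @param frac_increased,frac_decreased Fractions of neurons whose activity
#'   truly increases/decreases under both "off" and "fixed" (defaults 0.15).
#' @param multiplier_up,multiplier_down Condition gains of the affected
#'   subsets (defaults 2 and 0.5).
#' @param base_event_rate Events/min under "on" (default 6).
#' @param n_frames,frame_rate Session geometry (defaults 1000 frames at 3 Hz).
#' @param arena_side Arena side, cm (default 25.4).
#' @param noise_sigma Trace noise sd (default 0.05).
#' @param step_speed_mean Named numeric: mean arena speed (cm/s) per
#'   freely-behaving condition (defaults `c(on = 3, off = 1.5)`).
#' @param omega_locomotion Platter angular speed during bouts, rad/s
#'   (default 0.5).
#' @param effective_radius Platter effective radius, cm (default 10).
#' @param speed_threshold Locomotion threshold, cm/s (default 1).
#' @param min_bout Minimum locomotion/rest run, s (default 1).
#' @param k_on,k_off,min_duration Event-detection parameters.
#' @param alpha,min_events Classification parameters.
#' @param include_poec Also run the commutator on/off comparison on the
#'   default heading ramp (default TRUE).
#' @param out_dir Optional output directory for CSV/JSON artefacts.
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, n_neurons = 60L, frac_increased = 0.15,
                       frac_decreased = 0.15, multiplier_up = 2,
                       multiplier_down = 0.5, base_event_rate = 6,
                       n_frames = 1000L, frame_rate = 3, arena_side = 25.4,
                       noise_sigma = 0.05,
                       step_speed_mean = c(on = 3, off = 1.5),
                       omega_locomotion = 0.5, effective_radius = 10,
                       speed_threshold = 1, min_bout = 1,
                       k_on = 2.5, k_off = 0.5, min_duration = 2L,
                       alpha = 0.05, min_events = 3L,
                       include_poec = TRUE, out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), n_neurons = as.integer(n_neurons),
              frac_increased = frac_increased, frac_decreased = frac_decreased,
              multiplier_up = multiplier_up, multiplier_down = multiplier_down,
              base_event_rate = base_event_rate, n_frames = as.integer(n_frames),
              frame_rate = frame_rate, arena_side = arena_side,
              noise_sigma = noise_sigma, step_speed_mean = step_speed_mean,
              omega_locomotion = omega_locomotion,
              effective_radius = effective_radius,
              speed_threshold = speed_threshold, min_bout = min_bout,
              k_on = k_on, k_off = k_off, min_duration = as.integer(min_duration),
              alpha = alpha, min_events = as.integer(min_events),
              include_poec = isTRUE(include_poec), out_dir = out_dir)
  validate_run_config(cfg)
}

run_config_keys <- function() {
  c("seed", "n_neurons", "frac_increased", "frac_decreased", "multiplier_up",
    "multiplier_down", "base_event_rate", "n_frames", "frame_rate",
    "arena_side", "noise_sigma", "step_speed_mean", "omega_locomotion",
    "effective_radius", "speed_threshold", "min_bout", "k_on", "k_off",
    "min_duration", "alpha", "min_events", "include_poec", "out_dir")
}

validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), run_config_keys())
  if (length(unknown)) {
    stop_config("unknown configuration keys: %s.", paste(unknown, collapse = ", "))
  }
  check_number(cfg$n_neurons, "n_neurons", positive = TRUE)
  if (cfg$frac_increased < 0 || cfg$frac_decreased < 0 ||
      cfg$frac_increased + cfg$frac_decreased > 1) {
    stop_config("affected fractions must be >= 0 and sum to <= 1.")
  }
  cfg$step_speed_mean <- unlist(cfg$step_speed_mean)   # JSON reads as a list
  if (!all(c("on", "off") %in% names(cfg$step_speed_mean))) {
    stop_config("`step_speed_mean` must name at least the 'on' and 'off' conditions.")
  }
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as JSON
#'
#' The JSON round-trip is the persistence contract: `read_run_config()`
#' validates the keys (unknown keys rejected) and re-applies the schema, so
#' write-read-write is the identity.
#'
#' @param cfg A `"run_config"`.
#' @param path JSON file path.
#' @return `read_run_config()` returns a validated `"run_config"`.
#' @export
write_run_config <- function(cfg, path) {
  lst <- unclass(cfg)
  lst$step_speed_mean <- as.list(lst$step_speed_mean)  # keep the names in JSON
  lst <- lst[!vapply(lst, is.null, logical(1))]
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$out_dir <- raw$out_dir %||% NULL
  validate_run_config(raw)
}

stage_seed <- function(cfg, offset) (cfg$seed + offset) %% .Machine$integer.max

#' Run the full synthetic analysis pipeline
#'
#' Generates a synthetic cohort under the "on", "off" and head-"fixed"
#' conditions, runs behavior segmentation, event detection, locomotion
#' gating, rate-set building, per-neuron classification, trend analysis and
#' proportion summaries, and (optionally) the commutator on/off comparison.
#' All stage outputs are returned; when `cfg$out_dir` is set they are also
#' written as CSV plus a `summary.json`.
#'
#' @param cfg A [run_config()].
#' @return A list of class `"untether_report"` with elements `ground_truth`,
#'   `kinematics` (per-condition glance rows), `masks`, `events`,
#'   `rate_sets`, `classifications`, `trend`, `proportions`, `poec`
#'   (or NULL), and `summary` (the JSON-serialisable digest).
#' @export
run_pipeline <- function(cfg = run_config()) {
  if (!inherits(cfg, "run_config")) stop_config("`cfg` must be a run_config().")
  n_up <- round(cfg$n_neurons * cfg$frac_increased)
  n_dn <- round(cfg$n_neurons * cfg$frac_decreased)
  mult <- rep(1, cfg$n_neurons)
  if (n_up > 0) mult[seq_len(n_up)] <- cfg$multiplier_up
  if (n_dn > 0) mult[n_up + seq_len(n_dn)] <- cfg$multiplier_down
  gt <- neuron_ground_truth(cfg$n_neurons, base_event_rate = cfg$base_event_rate,
                            multiplier_off = mult, multiplier_fixed = mult)

  conditions <- c("on", "off", "fixed")
  masks <- list(); kin_rows <- list(); traces <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    spec <- session_spec(cond, n_frames = cfg$n_frames,
                         frame_rate = cfg$frame_rate,
                         arena_side = cfg$arena_side,
                         session_id = paste0("sim_", cond))
    if (cond == "fixed") {
      bouts <- alternating_bouts(spec$duration_s, rest_s = 20, bout_s = 30)
      platter <- generate_platter(spec, bouts,
                                  omega_locomotion = cfg$omega_locomotion,
                                  noise_sd = 0.01,
                                  seed = stage_seed(cfg, 100 + ci))
      mask <- platter_locomotion(platter, linear_threshold = cfg$speed_threshold,
                                 effective_radius = cfg$effective_radius,
                                 min_bout = cfg$min_bout)
      kin_rows[[cond]] <- tibble(condition = cond, walking_distance_m = NA_real_,
                                 turning_angle_rad = NA_real_)
    } else {
      traj <- generate_trajectory(spec,
                                  step_speed_mean = cfg$step_speed_mean[[cond]],
                                  seed = stage_seed(cfg, 100 + ci))
      kin <- compute_kinematics(traj)
      mask <- segment_locomotion(tidy(kin), threshold = cfg$speed_threshold,
                                 min_bout = cfg$min_bout)
      kin_rows[[cond]] <- tibble(condition = cond,
                                 walking_distance_m = kin$walking_distance_m,
                                 turning_angle_rad = kin$turning_angle_rad)
    }
    masks[[cond]] <- mask
    traces[[cond]] <- generate_dff(gt, spec, noise_sigma = cfg$noise_sigma,
                                   locomotion = mask$mask,
                                   seed = stage_seed(cfg, 200 + ci))
  }

  events <- purrr::imap_dfr(traces, function(tr, cond) {
    detect_events(tr, k_on = cfg$k_on, k_off = cfg$k_off,
                  min_duration = cfg$min_duration) |>
      gate_by_locomotion(masks[[cond]])
  })
  rate_sets <- build_rate_sets(events, neurons = gt$neuron_id,
                               conditions = conditions)
  cls <- classify_neurons(rate_sets, alpha = cfg$alpha,
                          min_events = cfg$min_events)
  trend <- trend_analysis(cls)
  props <- proportion_summary(cls)

  poec <- if (cfg$include_poec) {
    compare_modes(heading_ramp(), poec_config(), seed = stage_seed(cfg, 300))
  } else NULL

  summary <- list(
    seed = cfg$seed, n_neurons = cfg$n_neurons,
    kinematics = dplyr::bind_rows(kin_rows),
    proportions = props,
    n_consistent_up = sum(trend$trend == "consistent_up"),
    n_consistent_down = sum(trend$trend == "consistent_down"),
    poec = if (!is.null(poec)) poec$summary else NULL)

  report <- structure(
    list(ground_truth = gt, kinematics = dplyr::bind_rows(kin_rows),
         masks = masks, events = events, rate_sets = rate_sets,
         classifications = cls, trend = trend, proportions = props,
         poec = poec, summary = summary),
    class = "untether_report")

  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

alternating_bouts <- function(duration_s, rest_s, bout_s) {
  starts <- seq(rest_s, duration_s, by = rest_s + bout_s)
  tibble(start_s = starts, end_s = pmin(starts + bout_s, duration_s))
}

#' @export
print.untether_report <- function(x, ...) {
  cat(sprintf("<untether_report: %d neurons; %d events; %d/%d consistent up/down>\n",
              nrow(x$ground_truth), nrow(x$events),
              x$summary$n_consistent_up, x$summary$n_consistent_down))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$events, file.path(out_dir, "events.csv"))
  readr::write_csv(report$classifications, file.path(out_dir, "classifications.csv"))
  readr::write_csv(report$trend, file.path(out_dir, "trend.csv"))
  readr::write_csv(report$proportions, file.path(out_dir, "proportions.csv"))
  readr::write_csv(report$kinematics, file.path(out_dir, "kinematics.csv"))
  jsonlite::write_json(report$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, dataframe = "rows",
                       null = "null", pretty = TRUE)
  invisible(out_dir)
}
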