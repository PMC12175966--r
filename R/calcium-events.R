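#' Rolling-percentile baseline and robust noise estimate
#'
#' Estimates a per-frame baseline for each dF/F trace as a rolling low
#' percentile (default the 8th) over a centred window, then a robust noise sd
#' as `1.4826 * MAD(dff - baseline)`. Because the low percentile of pure
#' noise sits below its mean, the baseline is bias-corrected by
#' `sigma * qnorm(prob)` so that on transient-free Gaussian noise it is
#' centred on the true baseline. Traces shorter than the window fall back to
#' a single global percentile (with a warning).
#'
#' @param traces Long tibble of dF/F traces (`neuron_id`, `time_s`, `dff`,
#'   and optionally `condition`, `session_id`); processed per trace group.
#' @param window_s Window length in seconds (default 30; must be >= 10).
#' @param prob Baseline percentile in (0, 0.5) (default 0.08).
#' @return The input tibble with `baseline` and `sigma` columns added
#'   (`sigma` constant within each trace).
#' @export
estimate_baseline_noise <- function(traces, window_s = 30, prob = 0.08) {
  if (!all(c("dff", "time_s") %in% names(traces))) {
    stop_config("`traces` must contain dff and time_s columns.")
  }
  check_number(window_s, "window_s", positive = TRUE)
  if (window_s < 10) stop_config("`window_s` must be >= 10 s.")
  if (prob <= 0 || prob >= 0.5) stop_config("`prob` must be in (0, 0.5).")

  traces |>
    group_by(dplyr::across(dplyr::any_of(c("neuron_id", "condition", "session_id")))) |>
    group_modify(function(df, key) {
      dt <- check_uniform_time(df$time_s)
      w <- max(3L, round(window_s / dt))
      n <- nrow(df)
      if (w >= n) {
        warn("trace shorter than the baseline window; using a single global baseline.")
        b0 <- rep(quantile(df$dff, prob, names = FALSE), n)
      } else {
        b0 <- rolling_quantile(df$dff, w, prob)
      }
      resid <- df$dff - b0
      sigma <- mad(resid)           # 1.4826 * median absolute deviation
      df$baseline <- b0 - sigma * qnorm(prob)
      df$sigma <- sigma
      df
    }) |>
    ungroup()
}

rolling_quantile <- function(x, w, prob) {
  n <- length(x)
  h <- w %/% 2L
  vapply(seq_len(n), function(i) {
    quantile(x[max(1L, i - h):min(n, i + h)], prob, names = FALSE)
  }, numeric(1))
}

#' Detect calcium firing events and score r = dS/dt
#'
#' Threshold-crossing event detection on baseline-subtracted dF/F: an event
#' opens when `dff - baseline >= k_on * sigma` and closes when it falls below
#' `k_off * sigma`. Events closer than `merge_gap` frames are merged; events
#' shorter than `min_duration` frames are discarded. Each event is scored by
#' its area `dS` (per-frame rectangle quadrature of the baseline-subtracted
#' trace, clipped at 0 so noise dips cannot contribute negative area), its
#' duration `dt` in seconds, and the fluorescence rate `r = dS / dt` — the
#' mean baseline-subtracted dF/F over the event. A rectangular pulse of
#' height h therefore has r = h exactly, independent of frame rate.
#'
#' When `sigma` is 0 for a non-constant trace (noiseless synthetic data) the
#' thresholds fall back to the absolute level `abs_threshold` (opening) and
#' `abs_threshold * k_off / k_on` (closing), with a warning.
#'
#' @param traces Tibble with `dff`, `time_s` and (from
#'   [estimate_baseline_noise()]) `baseline`, `sigma`; baselines are computed
#'   on the fly when absent.
#' @param k_on,k_off Opening/closing thresholds in noise-sd units (defaults
#'   2.5 and 0.5).
#' @param min_duration Minimum event length in frames (default 2).
#' @param merge_gap Events separated by fewer than this many frames are
#'   merged before scoring (default 1, i.e. only back-to-back events merge).
#' @param abs_threshold Absolute dF/F opening threshold used when sigma is 0
#'   (default 0.1).
#' @param ... Passed to [estimate_baseline_noise()] when baselines are
#'   computed here.
#' @return Tibble of events: id columns plus `onset_frame`,
#'   `offset_frame` (half-open, 1-based), `onset_s`, `duration_s`, `area`,
#'   `rate`, `peak`.
#' @export
detect_events <- function(traces, k_on = 2.5, k_off = 0.5, min_duration = 2L,
                          merge_gap = 1L, abs_threshold = 0.1, ...) {
  check_number(k_on, "k_on", positive = TRUE)
  check_number(k_off, "k_off", non_negative = TRUE)
  if (k_off > k_on) stop_config("`k_off` must be <= `k_on`.")
  check_number(min_duration, "min_duration", positive = TRUE)
  check_number(abs_threshold, "abs_threshold", positive = TRUE)
  if (!all(c("baseline", "sigma") %in% names(traces))) {
    traces <- estimate_baseline_noise(traces, ...)
  }

  traces |>
    group_by(dplyr::across(dplyr::any_of(c("neuron_id", "condition", "session_id")))) |>
    group_modify(function(df, key) {
      dt <- check_uniform_time(df$time_s)
      z <- df$dff - df$baseline
      sigma <- df$sigma[1]
      if (sigma < 0) stop_config("`sigma` must be >= 0.")
      if (sigma == 0 && length(unique(df$dff)) > 1L) {
        warn("sigma is 0 for a non-constant trace; using the absolute threshold.")
        on_thr <- abs_threshold
        off_thr <- abs_threshold * k_off / k_on
      } else {
        on_thr <- k_on * sigma
        off_thr <- k_off * sigma
      }
      if (on_thr <= 0) return(empty_events())
      ev <- extract_events(z, on_thr, off_thr)
      if (nrow(ev) == 0L) return(empty_events())
      ev <- merge_close_events(ev, merge_gap)
      ev <- ev[ev$offset - ev$onset >= min_duration, , drop = FALSE]
      if (nrow(ev) == 0L) return(empty_events())
      purrr::map_dfr(seq_len(nrow(ev)), function(i) {
        idx <- ev$onset[i]:(ev$offset[i] - 1L)
        area <- sum(pmax(z[idx], 0)) * dt
        dur <- length(idx) * dt
        tibble(onset_frame = ev$onset[i], offset_frame = ev$offset[i],
               onset_s = df$time_s[ev$onset[i]], duration_s = dur,
               area = area, rate = area / dur, peak = max(z[idx]))
      })
    }) |>
    ungroup()
}

empty_events <- function() {
  tibble(onset_frame = integer(0), offset_frame = integer(0),
         onset_s = numeric(0), duration_s = numeric(0),
         area = numeric(0), rate = numeric(0), peak = numeric(0))
}

# State machine: open at >= on_thr, close at < off_thr. Returns half-open
# [onset, offset) frame intervals (1-based).
extract_events <- function(z, on_thr, off_thr) {
  onsets <- integer(0); offsets <- integer(0)
  active <- FALSE; start <- 0L
  for (i in seq_along(z)) {
    if (!active && z[i] >= on_thr) {
      active <- TRUE; start <- i
    } else if (active && z[i] < off_thr) {
      onsets <- c(onsets, start); offsets <- c(offsets, i)
      active <- FALSE
    }
  }
  if (active) { onsets <- c(onsets, start); offsets <- c(offsets, length(z) + 1L) }
  tibble(onset = onsets, offset = offsets)
}

merge_close_events <- function(ev, merge_gap) {
  if (nrow(ev) <= 1L) return(ev)
  keep_on <- ev$onset[1]; out_on <- integer(0); out_off <- integer(0)
  cur_off <- ev$offset[1]
  for (i in 2:nrow(ev)) {
    if (ev$onset[i] - cur_off < merge_gap) {
      cur_off <- ev$offset[i]
    } else {
      out_on <- c(out_on, keep_on); out_off <- c(out_off, cur_off)
      keep_on <- ev$onset[i]; cur_off <- ev$offset[i]
    }
  }
  tibble(onset = c(out_on, keep_on), offset = c(out_off, cur_off))
}

#' Restrict events to locomotion periods
#'
#' Keeps the events that belong to locomotion, since the fluorescence-rate
#' statistic is scored during locomotion periods only. Default rule: an event
#' belongs to locomotion iff its onset frame lies in a locomotion bout;
#' `"majority"` instead requires more than half of the event's frames to be
#' locomotion.
#'
#' @param events Event tibble from [detect_events()].
#' @param mask A `"locomotion_mask"` covering the trace frames, or a logical
#'   vector.
#' @param rule `"onset"` (default) or `"majority"`.
#' @return The filtered event tibble.
#' @export
gate_by_locomotion <- function(events, mask, rule = c("onset", "majority")) {
  rule <- match.arg(rule)
  m <- if (inherits(mask, "locomotion_mask")) mask$mask else as.logical(mask)
  if (nrow(events) == 0L) return(events)
  if (max(events$offset_frame) - 1L > length(m)) {
    stop_config("locomotion mask does not cover the event frames.")
  }
  keep <- if (rule == "onset") {
    m[events$onset_frame]
  } else {
    purrr::map2_lgl(events$onset_frame, events$offset_frame, function(a, b) {
      mean(m[a:(b - 1L)]) > 0.5
    })
  }
  events[keep, , drop = FALSE]
}

#' Collect per-neuron, per-condition fluorescence-rate sets
#'
#' Groups (gated) events into the rate sets R_on, R_off, R_fixed compared by
#' the condition classification: one row per neuron x condition holding the
#' multiset of per-event rates. Neuron/condition combinations with no events
#' are retained (empty set, flagged `insufficient`) so that downstream
#' classification can report them rather than silently drop them.
#'
#' @param events Event tibble with `neuron_id`, `condition`, `rate` (sessions
#'   of the same condition are pooled).
#' @param neurons,conditions Optional universes used to complete the grid;
#'   defaults to the values present in `events`.
#' @return Tibble (`neuron_id`, `condition`, `rates` list-column, `n_events`,
#'   `insufficient`).
#' @export
build_rate_sets <- function(events, neurons = NULL, conditions = NULL) {
  if (!all(c("neuron_id", "condition", "rate") %in% names(events))) {
    stop_config("`events` must have neuron_id, condition and rate columns.")
  }
  neurons <- neurons %||% sort(unique(events$neuron_id))
  conditions <- conditions %||% unique(events$condition)
  events |>
    group_by(.data$neuron_id, .data$condition) |>
    summarise(rates = list(.data$rate), .groups = "drop") |>
    tidyr::complete(neuron_id = neurons, condition = conditions,
                    fill = list(rates = list(numeric(0)))) |>
    mutate(n_events = lengths(.data$rates),
           insufficient = .data$n_events == 0L) |>
    arrange(.data$neuron_id, .data$condition)
}
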