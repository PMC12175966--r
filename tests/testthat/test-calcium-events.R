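trace_of <- function(dff, fps = 3, baseline = NULL, sigma = NULL) {
  tr <- tibble::tibble(time_s = (seq_along(dff) - 1) / fps, dff = dff)
  if (!is.null(baseline)) tr$baseline <- baseline
  if (!is.null(sigma)) tr$sigma <- sigma
  tr
}

test_that("constant traces get a flat baseline and zero noise estimate", {
  tr <- estimate_baseline_noise(trace_of(rep(0.7, 400)))
  expect_equal(tr$baseline, rep(0.7, 400))
  expect_equal(tr$sigma[1], 0)
})

test_that("noise sd is recovered within 15% on pure Gaussian traces", {
  sigmas <- vapply(1:60, function(s) {
    dff <- withr::with_seed(s, rnorm(600, 0, 0.05))
    estimate_baseline_noise(trace_of(dff))$sigma[1]
  }, numeric(1))
  expect_true(all(abs(sigmas - 0.05) / 0.05 < 0.15))
  expect_lt(abs(mean(sigmas) - 0.05) / 0.05, 0.05)
})

test_that("baseline tracks zero within one sigma under sparse transients", {
  gt <- neuron_ground_truth(1, base_event_rate = 4)
  tr <- generate_dff(gt, session_spec("on"), noise_sigma = 0.05, seed = 2)
  est <- estimate_baseline_noise(tr)
  frac_close <- mean(abs(est$baseline) <= est$sigma)
  expect_gte(frac_close, 0.95)
})

test_that("short traces fall back to a global baseline with a warning", {
  dff <- withr::with_seed(1, rnorm(20, 0, 0.05))
  expect_warning(est <- estimate_baseline_noise(trace_of(dff)), "global")
  expect_equal(length(unique(round(est$baseline, 12))), 1L)
})

test_that("a rectangular pulse of height h scores r = h exactly", {
  for (h in c(1, 0.37)) {
    dff <- rep(0, 100); dff[11:19] <- h
    ev <- suppressWarnings(detect_events(trace_of(dff, baseline = 0, sigma = 0)))
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$rate, h)
    expect_equal(ev$area, h * 3)       # 9 frames at 3 fps
    expect_equal(ev$duration_s, 3)
  }
})

test_that("a zero trace yields zero events", {
  ev <- detect_events(trace_of(rep(0, 100), baseline = 0, sigma = 0))
  expect_equal(nrow(ev), 0L)
})

test_that("a triangular pulse scores r = peak/2 within discretisation", {
  fps <- 3
  tt <- (0:99) / fps
  for (p in c(1, 2)) {
    tri <- pmax(0, p * (1 - abs(tt - 10) / 2))   # base 4 s, peak p at t = 10
    ev <- suppressWarnings(detect_events(trace_of(tri, baseline = 0, sigma = 0)))
    expect_equal(nrow(ev), 1L)
    expect_lt(abs(ev$rate - p / 2), 0.06 * p)
  }
})

test_that("r of a rectangle is invariant under frame-rate doubling", {
  h <- 0.8
  r_at <- function(fps) {
    n <- 40 * fps
    dff <- rep(0, n)
    dff[(5 * fps):(8 * fps)] <- h
    ev <- suppressWarnings(detect_events(trace_of(dff, fps = fps,
                                                  baseline = 0, sigma = 0)))
    ev$rate
  }
  expect_lt(abs(r_at(6) - r_at(3)) / r_at(3), 0.01)
})

test_that("event count is monotone non-increasing in the opening threshold", {
  gt <- neuron_ground_truth(1, base_event_rate = 8)
  tr <- generate_dff(gt, session_spec("on"), noise_sigma = 0.08, seed = 5)
  est <- estimate_baseline_noise(tr)
  counts <- vapply(c(1.5, 2.5, 3.5, 5), function(k) {
    nrow(detect_events(est, k_on = k))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("noiseless well-separated transients are recovered near ground truth", {
  # sampled fast enough (12 fps) that quadrature error is not the limit
  gt <- neuron_ground_truth(1, base_event_rate = 2, amplitude = 1)
  sp <- session_spec("on", frame_rate = 12, n_frames = 2400)
  found <- FALSE
  for (s in 1:60) {   # first seed whose events are all well separated
    tr <- generate_dff(gt, sp, noise_sigma = 0, seed = s)
    evt <- ground_truth_events(tr)
    if (nrow(evt) >= 5 && all(diff(evt$event_time_s) > 5)) { found <- TRUE; break }
  }
  expect_true(found)
  ev <- suppressWarnings(
    detect_events(trace_of(tr$dff, fps = 12, baseline = 0, sigma = 0),
                  min_duration = 1))
  expect_equal(nrow(ev), nrow(evt))
  # onsets within (one frame + threshold-crossing delay) of the true times
  expect_true(all(ev$onset_s - evt$event_time_s <= 1.5 / 12))
  expect_true(all(ev$onset_s - evt$event_time_s > -1e-9))
  # areas within 5% of the analytic kernel integral (decay - rise) / peak,
  # excluding events whose tail runs into the session end
  tp <- 0.1 * 0.6 / 0.5 * log(6)                  # kernel peak time
  kern_area <- 0.5 / (exp(-tp / 0.6) - exp(-tp / 0.1))
  whole <- evt$event_time_s < sp$duration_s - 5
  expect_true(all((abs(ev$area - kern_area) / kern_area)[whole] < 0.05))
})

test_that("locomotion gating follows the onset rule and its edge cases", {
  dff <- rep(0, 60); dff[11:15] <- 1; dff[41:45] <- 1
  ev <- suppressWarnings(detect_events(trace_of(dff, baseline = 0, sigma = 0)))
  expect_equal(nrow(ev), 2L)

  expect_equal(gate_by_locomotion(ev, rep(TRUE, 60)), ev)
  expect_equal(nrow(gate_by_locomotion(ev, rep(FALSE, 60))), 0L)

  mask <- rep(FALSE, 60); mask[1:12] <- TRUE     # first onset in, second out
  kept <- gate_by_locomotion(ev, mask)
  expect_equal(kept$onset_frame, 11L)

  # majority rule: first event has 2/5 locomotion frames -> dropped
  expect_equal(nrow(gate_by_locomotion(ev, mask, rule = "majority")), 0L)
  mask2 <- rep(FALSE, 60); mask2[11:14] <- TRUE  # 4/5 frames -> kept
  expect_equal(nrow(gate_by_locomotion(ev, mask2, rule = "majority")), 1L)

  expect_error(gate_by_locomotion(ev, rep(TRUE, 30)),
               class = "untether_config_error")
})

test_that("gating on a mixed mask equals direct enumeration of the onset rule", {
  gt <- neuron_ground_truth(1, base_event_rate = 10)
  tr <- generate_dff(gt, session_spec("on", n_frames = 600),
                     noise_sigma = 0.05, seed = 3)
  ev <- detect_events(estimate_baseline_noise(tr))
  mask <- withr::with_seed(13, rep(runif(60) > 0.5, each = 10))
  kept <- gate_by_locomotion(ev, mask)
  expect_equal(kept, ev[mask[ev$onset_frame], , drop = FALSE])
})

test_that("rate sets collect per-neuron, per-condition multisets", {
  ev <- tibble::tibble(neuron_id = c(1, 1, 1, 2), condition = c("on", "on", "off", "on"),
                       rate = c(0.2, 0.4, 0.9, 0.5))
  rs <- build_rate_sets(ev, conditions = c("on", "off"))
  expect_equal(nrow(rs), 4L)
  on1 <- rs$rates[rs$neuron_id == 1 & rs$condition == "on"][[1]]
  expect_equal(sort(on1), c(0.2, 0.4))
  off2 <- rs[rs$neuron_id == 2 & rs$condition == "off", ]
  expect_equal(off2$n_events, 0L)
  expect_true(off2$insufficient)
})

test_that("detection recovers ground-truth event counts on clean traces", {
  gt <- neuron_ground_truth(1, base_event_rate = 2)
  sp <- session_spec("on")
  for (s in 1:60) {
    tr <- generate_dff(gt, sp, noise_sigma = 0, seed = s)
    evt <- ground_truth_events(tr)
    if (nrow(evt) >= 5 && all(diff(evt$event_time_s) > 5)) break
  }
  ev <- suppressWarnings(
    detect_events(trace_of(tr$dff, baseline = 0, sigma = 0), min_duration = 1))
  rs <- build_rate_sets(ev |> dplyr::mutate(neuron_id = 1, condition = "on"))
  expect_equal(rs$n_events, nrow(evt))
})
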