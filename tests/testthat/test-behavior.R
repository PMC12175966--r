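make_traj <- function(x, y, fps = 3) {
  tibble::tibble(time_s = (seq_along(x) - 1) / fps, x_cm = x, y_cm = y)
}

test_that("a straight path has its length as distance and zero turning", {
  n <- 21
  traj <- make_traj(seq(0, 100, length.out = n), rep(2, n))
  k <- compute_kinematics(traj, min_displacement = 0)
  expect_equal(k$walking_distance_m, 1)
  expect_equal(k$turning_angle_rad, 0)
})

test_that("one lap of a closed convex polygon turns exactly 2*pi, any n", {
  for (n in c(3, 5, 8)) {
    th <- 2 * pi * (0:(n - 1)) / n
    v <- cbind(10 + 5 * cos(th), 10 + 5 * sin(th))
    pts <- rbind(v, v[1, ], v[2, ])  # close the loop and wrap the heading
    k <- compute_kinematics(make_traj(pts[, 1], pts[, 2]), min_displacement = 0)
    expect_equal(k$turning_angle_rad, 2 * pi, tolerance = 1e-10)
  }
})

test_that("distance and turning are invariant under rigid transforms", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      x <- cumsum(rnorm(100)); y <- cumsum(rnorm(100))
      k0 <- compute_kinematics(make_traj(x, y), min_displacement = 0)
      phi <- runif(1, 0, 2 * pi); dx <- runif(1, -50, 50); dy <- runif(1, -50, 50)
      xr <- cos(phi) * x - sin(phi) * y + dx
      yr <- sin(phi) * x + cos(phi) * y + dy
      k1 <- compute_kinematics(make_traj(xr, yr), min_displacement = 0)
      expect_equal(k1$walking_distance_m, k0$walking_distance_m)
      expect_equal(k1$turning_angle_rad, k0$turning_angle_rad)
    }
  })
})

test_that("turning angle equals the direct-summation oracle on jittered paths", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      x <- cumsum(rnorm(100, sd = 0.5))
      y <- cumsum(rnorm(100, sd = 0.5))
      for (md in c(0, 0.2, 0.5)) {
        k <- compute_kinematics(make_traj(x, y), min_displacement = md)
        expect_equal(k$turning_angle_rad, oracle_turning_angle(x, y, md),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("linear speed uses central differences with one-sided ends", {
  traj <- make_traj(seq(0, 10, by = 1), rep(0, 11), fps = 2) # 2 cm/s
  k <- compute_kinematics(traj, min_displacement = 0)
  expect_equal(tidy(k)$speed_cm_s, rep(2, 11))
})

test_that("kinematics rejects malformed trajectories", {
  expect_error(compute_kinematics(make_traj(1:2, 1:2)),
               class = "untether_config_error")
  bad <- tibble::tibble(time_s = c(0, 1, 3, 3.5), x_cm = 1:4, y_cm = 1:4)
  expect_error(compute_kinematics(bad), class = "untether_config_error")
  expect_error(compute_kinematics(make_traj(c(1, NA, 3), c(1, 2, 3))),
               class = "untether_config_error")
})

test_that("velocity-threshold segmentation handles the edge regimes", {
  expect_error(segment_locomotion(numeric(0), frame_rate = 3),
               class = "untether_config_error")
  none <- segment_locomotion(rep(0, 30), frame_rate = 3)
  expect_equal(sum(none$mask), 0L)
  expect_equal(nrow(none$bouts), 0L)
  all_go <- segment_locomotion(rep(2, 30), frame_rate = 3)
  expect_true(all(all_go$mask))
  expect_equal(nrow(all_go$bouts), 1L)
  expect_equal(unname(unlist(all_go$bouts[1, c("start_frame", "end_frame")])),
               c(1L, 31L))
})

test_that("bout smoothing matches the run-length post-processing oracle", {
  fps <- 3
  cases <- list(
    rep(c(0, 2), 15),                                   # alternating frames
    c(rep(2, 9), rep(0, 2), rep(2, 4), rep(0, 9)),      # short rest gap
    c(rep(0, 2), rep(2, 2), rep(0, 2), rep(2, 7)),      # leading fragments
    rep(2, 5), rep(0, 5))
  for (speed in cases) {
    got <- segment_locomotion(speed, threshold = 1, min_bout = 1, frame_rate = fps)
    want <- oracle_merge_runs(speed >= 1, min_frames = 1 * fps)
    expect_equal(got$mask, want)
  }
})

test_that("raising the threshold never adds locomotion frames (no smoothing)", {
  withr::with_seed(3, {
    speed <- abs(rnorm(200, 1, 1))
    frames <- vapply(c(0.5, 1, 1.5, 2, 3), function(th) {
      sum(segment_locomotion(speed, threshold = th, min_bout = 0,
                             frame_rate = 3)$mask)
    }, numeric(1))
    expect_true(all(diff(frames) <= 0))
  })
})

test_that("locomotion and rest partition the session into sorted bouts", {
  withr::with_seed(11, {
    speed <- abs(rnorm(300, 1, 0.8))
    m <- segment_locomotion(speed, frame_rate = 3, min_bout = 1)
    b <- m$bouts
    if (nrow(b) > 1) {
      expect_true(all(diff(b$start_frame) > 0))
      expect_true(all(b$start_frame[-1] >= b$end_frame[-nrow(b)]))
    }
    in_bouts <- rep(FALSE, length(speed))
    for (i in seq_len(nrow(b))) in_bouts[b$start_frame[i]:(b$end_frame[i] - 1)] <- TRUE
    expect_equal(in_bouts, m$mask)
  })
})

test_that("platter segmentation converts the linear threshold to angular", {
  # radius 10 cm, 1 cm/s -> omega threshold 0.1 rad/s
  t <- (0:29) / 3
  platter <- tibble::tibble(time_s = t, omega_rad_s = rep(c(0.099, 0.101), 15))
  m <- platter_locomotion(platter, linear_threshold = 1, effective_radius = 10,
                          min_bout = 0)
  expect_equal(m$mask, rep(c(FALSE, TRUE), 15))
  expect_error(platter_locomotion(platter, effective_radius = 0),
               class = "untether_config_error")

  still <- tibble::tibble(time_s = t, omega_rad_s = rep(0, 30))
  expect_equal(sum(platter_locomotion(still)$mask), 0L)
})

test_that("platter bout boundaries are recovered from the generator schedule", {
  spf <- session_spec("fixed")
  # linear-equivalent speed 2x the 1 cm/s threshold at radius 10 cm
  tr <- generate_platter(spf, tibble::tibble(start_s = 100, end_s = 130),
                         omega_locomotion = 0.2, noise_sd = 0.005, seed = 4)
  m <- platter_locomotion(tr, linear_threshold = 1, effective_radius = 10)
  expect_equal(nrow(m$bouts), 1L)
  truth_start <- min(which(tr$time_s >= 100))
  truth_end <- min(which(tr$time_s >= 130))
  expect_lte(abs(m$bouts$start_frame[1] - truth_start), 1)
  expect_lte(abs(m$bouts$end_frame[1] - truth_end), 1)
})

test_that("noise well below the angular threshold yields no locomotion", {
  spf <- session_spec("fixed")
  tr <- generate_platter(spf, tibble::tibble(start_s = numeric(0),
                                             end_s = numeric(0)),
                         omega_locomotion = 0.2, noise_sd = 0.01, seed = 8)
  m <- platter_locomotion(tr, linear_threshold = 1, effective_radius = 10)
  expect_equal(sum(m$mask), 0L)
})

test_that("condition summary reproduces the printed percent increases", {
  sessions <- tibble::tibble(
    condition = c("on", "off"),
    walking_distance_m = c(9.51, 4.67),
    turning_angle_rad = c(287.15, 160.20))
  ss <- session_summary_table(sessions, pairs = list(c("on", "off")))
  pc <- ss$percent_change
  expect_equal(pc$percent_change[pc$metric == "walking_distance_m"], 103)
  expect_equal(pc$percent_change[pc$metric == "turning_angle_rad"], 79)

  equal <- tibble::tibble(condition = c("a", "b"),
                          walking_distance_m = c(5, 5),
                          turning_angle_rad = c(2, 2))
  pc0 <- session_summary_table(equal, pairs = list(c("a", "b")))$percent_change
  expect_equal(pc0$percent_change, c(0, 0))

  zero <- tibble::tibble(condition = c("a", "b"),
                         walking_distance_m = c(5, 0),
                         turning_angle_rad = c(2, 1))
  expect_warning(ssz <- session_summary_table(zero, pairs = list(c("a", "b"))),
                 "undefined")
  expect_true(any(ssz$percent_change$undefined))
  expect_true(is.na(ssz$percent_change$percent_change[
    ssz$percent_change$metric == "walking_distance_m"]))
})

test_that("bonferroni adjustment caps at one and matches stats::p.adjust", {
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(0.01, 3), 0.03)
  p <- c(0.001, 0.02, 0.2, 0.9)
  expect_equal(bonferroni(p, 4), stats::p.adjust(p, "bonferroni"))
  expect_equal(bonferroni(p, 10), pmin(1, 10 * p))
  expect_error(bonferroni(1.2, 3), class = "untether_config_error")
  expect_error(bonferroni(-0.1, 3), class = "untether_config_error")
})
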