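# Independent brute-force oracles used to pin down expected values.

# Exact two-sided Mann-Whitney p by explicit enumeration of all C(N, n_a)
# group assignments (midranks; deviation-from-mean two-sided rule).
oracle_mw_exact <- function(x, y) {
  n_a <- length(x); n_b <- length(y)
  r <- rank(c(x, y))
  N <- n_a + n_b
  subsets <- utils::combn(N, n_a)
  u_all <- colSums(matrix(r[subsets], nrow = n_a)) - n_a * (n_a + 1) / 2
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Monte-Carlo permutation p-value for the same two-sided statistic.
oracle_mw_permutation <- function(x, y, B = 1e5, seed = 1) {
  n_a <- length(x)
  r <- rank(c(x, y))
  mu <- n_a * length(y) / 2
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  withr::with_seed(seed, {
    u_perm <- vapply(seq_len(B), function(b) {
      sum(sample(r, n_a)) - n_a * (n_a + 1) / 2
    }, numeric(1))
  })
  mean(abs(u_perm - mu) >= abs(u_obs - mu) - 1e-9)
}

# Direct-summation turning angle: headings of displacement vectors, explicit
# wrapping of increments into (-pi, pi], absolute sum over qualifying steps.
oracle_turning_angle <- function(x, y, min_disp = 0) {
  headings <- c()
  for (i in 2:length(x)) {
    dx <- x[i] - x[i - 1]; dy <- y[i] - y[i - 1]
    if (sqrt(dx^2 + dy^2) >= min_disp && (dx != 0 || dy != 0)) {
      headings <- c(headings, atan2(dy, dx))
    }
  }
  if (length(headings) < 2) return(0)
  total <- 0
  for (i in 2:length(headings)) {
    d <- headings[i] - headings[i - 1]
    while (d <= -pi) d <- d + 2 * pi
    while (d > pi) d <- d - 2 * pi
    total <- total + abs(d)
  }
  total
}

# Run-length post-processing oracle for bout smoothing: scan for runs
# shorter than min_frames, flip the shortest (earliest on ties), repeat.
oracle_merge_runs <- function(mask, min_frames) {
  repeat {
    runs <- list(); i <- 1
    while (i <= length(mask)) {
      j <- i
      while (j < length(mask) && mask[j + 1] == mask[i]) j <- j + 1
      runs[[length(runs) + 1]] <- c(start = i, end = j, len = j - i + 1)
      i <- j + 1
    }
    if (length(runs) <= 1) return(mask)
    lens <- vapply(runs, function(r) r[["len"]], numeric(1))
    short <- which(lens < min_frames)
    if (!length(short)) return(mask)
    k <- short[which.min(lens[short])]
    idx <- runs[[k]][["start"]]:runs[[k]][["end"]]
    mask[idx] <- !mask[idx]
  }
}

# Small helper: rate-set tibble from a named list of numeric vectors per
# condition, single neuron.
rate_sets_of <- function(..., neuron_id = 1L) {
  sets <- list(...)
  tibble::tibble(neuron_id = neuron_id, condition = names(sets),
                 rates = unname(sets), n_events = lengths(sets),
                 insufficient = lengths(sets) == 0L)
}
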