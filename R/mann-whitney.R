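#' Mann-Whitney U test (exact and normal-approximation modes)
#'
#' Two-sided rank-sum test used for the per-neuron comparison of
#' fluorescence-rate sets across conditions. `U` is computed from rank sums
#' with midranks for ties, so `U_a + U_b = n_a * n_b` always holds. In exact
#' mode the full permutation distribution of U is computed with a
#' shift-algorithm dynamic programme over the (doubled, hence integer)
#' midranks — correct under ties, unlike the classical no-tie tables — and
#' the two-sided p-value is `P(|U - n_a n_b / 2| >= |U_obs - n_a n_b / 2|)`.
#' In normal mode the tie-corrected variance and a 0.5 continuity correction
#' are used. `mode = "auto"` (default) picks exact when both samples have at
#' most 8 observations.
#'
#' @param x,y Numeric vectors of per-event rates (each nonempty).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return A list with elements `statistic` (U for `x`), `p_value`,
#'   `n_a`, `n_b` and `method`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) {
    abort("both rate sets must be nonempty; use the insufficient-data path.",
          class = "untether_insufficient_data")
  }
  if (anyNA(x) || anyNA(y)) stop_config("rate sets must not contain NA.")
  n_a <- length(x); n_b <- length(y)
  r <- rank(c(x, y))
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  exact <- mode == "exact" || (mode == "auto" && n_a <= 8L && n_b <= 8L)
  p <- if (exact) mw_exact_p(r, n_a, u_a) else mw_normal_p(r, n_a, n_b, u_a)
  list(statistic = u_a, p_value = p, n_a = n_a, n_b = n_b,
       method = if (exact) "exact" else "normal_approx")
}

# Exact two-sided p: DP over subsets of the doubled midranks (integer
# scores). dp[k + 1, s + 1] counts k-subsets with doubled rank sum s.
mw_exact_p <- function(r, n_a, u_a) {
  s <- as.integer(round(2 * r))
  N <- length(s)
  max_sum <- sum(sort(s, decreasing = TRUE)[seq_len(n_a)])
  dp <- matrix(0, nrow = n_a + 1L, ncol = max_sum + 1L)
  dp[1L, 1L] <- 1
  for (v in s) {
    for (k in seq(min(n_a, N), 1L)) {
      cols <- (v + 1L):(max_sum + 1L)
      dp[k + 1L, cols] <- dp[k + 1L, cols] + dp[k, seq_len(max_sum + 1L - v)]
    }
  }
  counts <- dp[n_a + 1L, ]
  sums2 <- 0:max_sum                       # doubled rank sums
  u_vals <- sums2 / 2 - n_a * (n_a + 1) / 2
  mu <- n_a * (N - n_a) / 2
  dev <- abs(u_a - mu)
  sum(counts[abs(u_vals - mu) >= dev - 1e-9]) / sum(counts)
}

mw_normal_p <- function(r, n_a, n_b, u_a) {
  N <- n_a + n_b
  mu <- n_a * n_b / 2
  tie_counts <- table(r)
  tie_term <- sum(tie_counts^3 - tie_counts)
  sigma2 <- n_a * n_b / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- max(0, (abs(u_a - mu) - 0.5)) / sqrt(sigma2)
  min(1, 2 * pnorm(-z))
}
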