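#' Classify neurons by condition-wise rate comparison
#'
#' For each neuron and each comparison (by default "off" vs "on" and "fixed"
#' vs "on"), tests whether the distribution of per-event fluorescence rates
#' differs between the test condition and the baseline condition with a
#' two-sided Mann-Whitney U test at level `alpha`. Significant neurons are
#' labelled `"increased"` when the direction statistic favours the test
#' condition (U above its null mean `n_a n_b / 2`; ties broken by median
#' comparison) and `"decreased"` when it favours the baseline; all others —
#' including neurons with fewer than `min_events` events in either condition
#' — are `"other"`.
#'
#' @param rate_sets Rate-set tibble from [build_rate_sets()] or
#'   [generate_rate_sets()].
#' @param comparisons Named character vector mapping comparison name to the
#'   test condition (default `c(off_vs_on = "off", fixed_vs_on = "fixed")`).
#' @param baseline Baseline condition (default `"on"`).
#' @param alpha Significance level (default 0.05).
#' @param min_events Minimum events required in each condition (default 3).
#' @param mode Test mode passed to [mann_whitney_u()].
#' @param p_adjust `"none"` (default; per-neuron tests at `alpha` without
#'   correction) or `"BH"` for a Benjamini-Hochberg option across neurons
#'   within each comparison.
#' @return Tibble with one row per neuron x comparison: `label`, `p_value`,
#'   `u`, `median_a` (test), `median_b` (baseline), `n_a`, `n_b`, `reason`
#'   (`"tested"` or `"insufficient"`).
#' @export
classify_neurons <- function(rate_sets,
                             comparisons = c(off_vs_on = "off",
                                             fixed_vs_on = "fixed"),
                             baseline = "on", alpha = 0.05, min_events = 3L,
                             mode = c("auto", "exact", "normal"),
                             p_adjust = c("none", "BH")) {
  mode <- match.arg(mode)
  p_adjust <- match.arg(p_adjust)
  if (alpha <= 0 || alpha >= 1) stop_config("`alpha` must be in (0, 1).")
  check_number(min_events, "min_events", positive = TRUE)
  present <- unique(rate_sets$condition)
  if (!baseline %in% present) {
    stop_config("baseline condition '%s' absent from `rate_sets`.", baseline)
  }
  comparisons <- comparisons[comparisons %in% present]
  if (!length(comparisons)) stop_config("no comparison condition present in `rate_sets`.")

  wide <- rate_sets |>
    select("neuron_id", "condition", "rates") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "rates")

  out <- purrr::imap_dfr(comparisons, function(test_cond, comp_name) {
    purrr::map_dfr(seq_len(nrow(wide)), function(i) {
      ra <- wide[[test_cond]][[i]] %||% numeric(0)
      rb <- wide[[baseline]][[i]] %||% numeric(0)
      row <- tibble(neuron_id = wide$neuron_id[i], comparison = comp_name,
                    label = "other", p_value = NA_real_, u = NA_real_,
                    median_a = if (length(ra)) median(ra) else NA_real_,
                    median_b = if (length(rb)) median(rb) else NA_real_,
                    n_a = length(ra), n_b = length(rb), reason = "insufficient")
      if (length(ra) < min_events || length(rb) < min_events) return(row)
      tst <- mann_whitney_u(ra, rb, mode = mode)
      row$p_value <- tst$p_value
      row$u <- tst$statistic
      row$reason <- "tested"
      row
    })
  })

  if (p_adjust == "BH") {
    out <- out |>
      group_by(.data$comparison) |>
      mutate(p_value = ifelse(.data$reason == "tested",
                              p.adjust(.data$p_value, "BH"), .data$p_value)) |>
      ungroup()
  }

  out |>
    mutate(label = dplyr::case_when(
      .data$reason != "tested" | .data$p_value >= alpha ~ "other",
      direction_up(.data$u, .data$n_a, .data$n_b,
                   .data$median_a, .data$median_b) ~ "increased",
      TRUE ~ "decreased"))
}

# TRUE when the direction statistic favours the test condition: U above its
# null mean, with median comparison as the tie-break at U == n_a n_b / 2.
direction_up <- function(u, n_a, n_b, median_a, median_b) {
  mu <- n_a * n_b / 2
  ifelse(u != mu, u > mu, median_a > median_b)
}

#' Consistent-trend identification across both comparisons
#'
#' Flags neurons whose firing-rate statistic shifts the same way in both the
#' off-vs-on and fixed-vs-on comparisons: `"consistent_up"` when increased in
#' both (R_off > R_on and R_fixed > R_on), `"consistent_down"` when
#' decreased in both, `"none"` otherwise. With
#' `require = "median_order"` significance is not required and the trend is
#' read from the median ordering alone.
#'
#' @param classifications Output of [classify_neurons()] containing both
#'   comparisons.
#' @param require `"significance"` (default) or `"median_order"`.
#' @return Tibble per neuron: `trend`, and the condition medians
#'   `median_on`, `median_off`, `median_fixed` (as available).
#' @export
trend_analysis <- function(classifications,
                           require = c("significance", "median_order")) {
  require <- match.arg(require)
  comps <- unique(classifications$comparison)
  if (length(comps) < 2L) {
    stop_config("trend analysis needs classifications from both comparisons.")
  }

  c1 <- comps[1]; c2 <- comps[2]
  wide <- classifications |>
    select("neuron_id", "comparison", "label", "median_a", "median_b") |>
    tidyr::pivot_wider(names_from = "comparison",
                       values_from = c("label", "median_a", "median_b"))
  col <- function(prefix, comp) wide[[paste0(prefix, comp)]]

  is_dir <- function(comp, dir) {
    if (require == "significance") col("label_", comp) == dir
    else if (dir == "increased") col("median_a_", comp) > col("median_b_", comp)
    else col("median_a_", comp) < col("median_b_", comp)
  }

  tibble(neuron_id = wide$neuron_id,
         trend = dplyr::case_when(
           is_dir(c1, "increased") & is_dir(c2, "increased") ~ "consistent_up",
           is_dir(c1, "decreased") & is_dir(c2, "decreased") ~ "consistent_down",
           TRUE ~ "none"),
         median_on = col("median_b_", c1),
         median_off = col("median_a_", c1),
         median_fixed = col("median_a_", c2))
}

#' Stacked proportions of classification labels
#'
#' Per-comparison percentages of increased / decreased / other neurons, the
#' quantities shown as stacked percentage bars. Percentages are exact (not
#' pre-rounded) and sum to 100 within floating-point error.
#'
#' @param classifications Output of [classify_neurons()].
#' @return Tibble (`comparison`, `label`, `n`, `percent`).
#' @export
proportion_summary <- function(classifications) {
  if (nrow(classifications) == 0L) stop_config("no classified neurons.")
  classifications |>
    mutate(label = factor(.data$label,
                          levels = c("increased", "decreased", "other"))) |>
    group_by(.data$comparison, .data$label, .drop = FALSE) |>
    summarise(n = dplyr::n(), .groups = "drop_last") |>
    mutate(percent = .data$n / sum(.data$n) * 100) |>
    ungroup()
}
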