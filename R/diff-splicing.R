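#' Per-intron paired differential-splicing tests within cohorts
#'
#' For every intron with at least `min_pairs` complete tumor-normal pairs in a
#' cohort, tests the paired dPSI values (normal - tumor) with the Wilcoxon
#' signed-rank test, adjusts p-values by Benjamini-Hochberg within the cohort,
#' and classifies direction: `up_in_tumor` when q < alpha and mean dPSI > 0
#' (PSI dropped in tumor, i.e. splicing increased), `down_in_tumor` when
#' q < alpha and mean dPSI < 0, `ns` otherwise.
#'
#' @param paired Paired PSI tibble from [build_paired_psi()].
#' @param alpha Significance threshold on q (default 0.05).
#' @param min_pairs Minimum complete pairs per intron (default 3).
#' @return Tibble with `cohort`, `intron_id`, `n_pairs`, `mean_dpsi`,
#'   `statistic`, `p`, `q`, `direction`.
#' @export
test_cohort_introns <- function(paired, alpha = 0.05, min_pairs = 3L) {
  testable <- filter_testable_introns(paired, min_pairs)
  if (nrow(testable) == 0L) {
    warning("no testable introns")
    return(tibble(
      cohort = character(), intron_id = character(), n_pairs = integer(),
      mean_dpsi = numeric(), statistic = numeric(), p = numeric(),
      q = numeric(), direction = character()
    ))
  }
  res <- paired %>%
    semi_join(testable, by = c("cohort", "intron_id")) %>%
    group_by(.data$cohort, .data$intron_id) %>%
    summarise(
      n_pairs = dplyr::n(),
      mean_dpsi = mean(.data$dpsi),
      test = list(paired_wilcoxon(.data$dpsi)),
      .groups = "drop"
    ) %>%
    mutate(
      statistic = vapply(.data$test, `[[`, numeric(1), "statistic"),
      p = vapply(.data$test, `[[`, numeric(1), "p")
    ) %>%
    select(-"test") %>%
    group_by(.data$cohort) %>%
    mutate(q = bh_fdr(.data$p)) %>%
    ungroup() %>%
    mutate(direction = dplyr::case_when(
      .data$q < alpha & .data$mean_dpsi > 0 ~ "up_in_tumor",
      .data$q < alpha & .data$mean_dpsi < 0 ~ "down_in_tumor",
      TRUE ~ "ns"
    )) %>%
    arrange(.data$cohort, .data$intron_id)
  res
}

#' Cohort-level splicing summary: minor-splicing score and skew test
#'
#' Counts significantly up- and down-spliced introns per cohort, computes the
#' minor-splicing score (n_up - n_down), runs the two-sided binomial skew
#' test on (n_up, n_down), and adjusts the skew p-values by BH across all
#' cohorts in the run. `skew_class` is `increased` (splicing up in tumor)
#' when skew_q < alpha and n_up > n_down, `decreased` when skew_q < alpha and
#' n_down > n_up, `none` otherwise (including cohorts with no significant
#' introns, which carry no test).
#'
#' @param results Per-intron results from [test_cohort_introns()] (one or
#'   more cohorts).
#' @param alpha Threshold on skew_q (default 0.05).
#' @return Tibble with `cohort`, `n_up`, `n_down`, `n_ns`, `score`,
#'   `skew_p`, `skew_q`, `skew_class`, sorted by score descending.
#' @export
summarize_cohorts <- function(results, alpha = 0.05) {
  summ <- results %>%
    group_by(.data$cohort) %>%
    summarise(
      n_up = sum(.data$direction == "up_in_tumor"),
      n_down = sum(.data$direction == "down_in_tumor"),
      n_ns = sum(.data$direction == "ns"),
      .groups = "drop"
    ) %>%
    mutate(score = .data$n_up - .data$n_down)
  summ$skew_p <- vapply(seq_len(nrow(summ)), function(i) {
    if (summ$n_up[i] + summ$n_down[i] >= 1) {
      binomial_skew_test(summ$n_up[i], summ$n_down[i])
    } else {
      NA_real_
    }
  }, numeric(1))
  summ$skew_q <- NA_real_
  tested <- !is.na(summ$skew_p)
  if (any(tested)) summ$skew_q[tested] <- bh_fdr(summ$skew_p[tested])
  summ <- summ %>%
    mutate(skew_class = dplyr::case_when(
      !is.na(.data$skew_q) & .data$skew_q < alpha & .data$n_up > .data$n_down ~ "increased",
      !is.na(.data$skew_q) & .data$skew_q < alpha & .data$n_down > .data$n_up ~ "decreased",
      TRUE ~ "none"
    )) %>%
    arrange(dplyr::desc(.data$score), .data$cohort)
  summ
}
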