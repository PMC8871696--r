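#' Correlate minor-splicing scores with gene expression change across cohorts
#'
#' For each gene present in at least `min_cohorts` cohorts, a Spearman
#' correlation of the per-cohort minor-splicing score against the gene's
#' per-cohort mean log2 fold change (tumor/normal), BH-adjusted across all
#' genes tested. Rank-based, so any order-preserving transform of the scores
#' leaves the result unchanged; ties receive average ranks. Genes with zero
#' variance in fold change (or a constant score vector) are reported absent.
#'
#' @param scores Tibble with `cohort`, `score` (from [summarize_cohorts()]).
#' @param mean_lfc Tibble with `cohort`, `gene_id`, `mean_log2fc` (the `mean`
#'   element of [paired_log2fc()]).
#' @param min_cohorts Minimum cohorts per gene (default 3).
#' @return Tibble with `gene_id`, `n_cohorts`, `rho`, `p`, `q`, sorted by `q`.
#' @export
score_expression_correlation <- function(scores, mean_lfc, min_cohorts = 3L) {
  stopifnot(min_cohorts >= 3)
  kept <- mean_lfc %>%
    inner_join(scores[, c("cohort", "score")], by = "cohort") %>%
    group_by(.data$gene_id) %>%
    filter(dplyr::n() >= min_cohorts)
  n_skipped <- dplyr::n_distinct(mean_lfc$gene_id) -
    dplyr::n_distinct(kept$gene_id)
  if (n_skipped > 0) {
    message(n_skipped, " gene(s) present in fewer than ", min_cohorts,
            " cohorts; skipped")
  }
  if (nrow(kept) == 0L) {
    return(tibble(gene_id = character(), n_cohorts = numeric(),
                  rho = numeric(), p = numeric(), q = numeric()))
  }
  tab <- kept %>%
    summarise(res = list(spearman_test(.data$score, .data$mean_log2fc)),
              .groups = "drop")
  res <- tab %>%
    mutate(
      n_cohorts = vapply(.data$res, `[[`, numeric(1), "n"),
      rho = vapply(.data$res, `[[`, numeric(1), "rho"),
      p = vapply(.data$res, `[[`, numeric(1), "p")
    ) %>%
    select(-"res") %>%
    filter(!is.na(.data$rho))
  res$q <- bh_fdr(res$p)
  res %>% arrange(.data$q, .data$gene_id)
}
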