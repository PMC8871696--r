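#' Normal-tissue PSI reference statistics per intron
#'
#' Mean and standard deviation (n - 1 denominator) of each intron's PSI
#' across all normal samples of the cohort — all normals with a defined PSI,
#' not only those belonging to matched pairs. A usable sigma needs at least
#' two normals.
#'
#' @param psi PSI table from [compute_psi()].
#' @return Tibble with `cohort`, `intron_id`, `mu`, `sigma`, `n_normals`
#'   (`sigma` is `NA` when fewer than two normals).
#' @export
normal_psi_stats <- function(psi) {
  psi %>%
    filter(.data$tissue == "normal") %>%
    group_by(.data$cohort, .data$intron_id) %>%
    summarise(
      mu = mean(.data$psi),
      sigma = if (dplyr::n() >= 2) sd(.data$psi) else NA_real_,
      n_normals = dplyr::n(),
      .groups = "drop"
    )
}

#' Standardized splicing-activity coefficient for one intron in one tumor
#'
#' beta = (mu - T) / sigma: how many normal-tissue standard deviations the
#' tumor's PSI lies below the normal mean. Positive beta means less retention
#' in the tumor, i.e. higher minor-splicing activity. Returns `NA` (intron to
#' be excluded) when sigma is zero or missing.
#'
#' @param t_psi Tumor PSI.
#' @param mu,sigma Normal-tissue mean and standard deviation of the intron's
#'   PSI.
#' @return Numeric beta, vectorized.
#' @export
beta_coefficient <- function(t_psi, mu, sigma) {
  beta <- (mu - t_psi) / sigma
  beta[is.na(sigma) | sigma <= 0] <- NA_real_
  beta
}

#' Per-tumor minor-splicing activity (summed beta)
#'
#' Sums beta over every intron where the tumor sample has a defined PSI and
#' the cohort's normal reference has a positive sigma. Tumors with no usable
#' intron are absent from the result.
#'
#' @param psi PSI table from [compute_psi()].
#' @param stats Normal reference from [normal_psi_stats()].
#' @return Tibble with `cohort`, `sample_id`, `patient_id`, `sum_beta`,
#'   `n_introns_used`.
#' @export
tumor_activity <- function(psi, stats) {
  usable <- stats %>% filter(!is.na(.data$sigma), .data$sigma > 0)
  scores <- psi %>%
    filter(.data$tissue == "tumor") %>%
    inner_join(usable, by = c("cohort", "intron_id")) %>%
    mutate(beta = beta_coefficient(.data$psi, .data$mu, .data$sigma)) %>%
    group_by(.data$cohort, .data$sample_id, .data$patient_id) %>%
    summarise(sum_beta = sum(.data$beta),
              n_introns_used = dplyr::n(), .groups = "drop")
  scores
}

#' Per-patient change in minor-splicing activity (summed dPSI)
#'
#' Sums dPSI (normal - tumor) over all introns with PSI defined in both
#' tissues of the patient; positive values mean the patient's tumor splices
#' minor introns more efficiently overall.
#'
#' @param paired Paired PSI tibble from [build_paired_psi()].
#' @return Tibble with `cohort`, `patient_id`, `sum_dpsi`, `n_introns_used`.
#' @export
patient_activity_change <- function(paired) {
  paired %>%
    group_by(.data$cohort, .data$patient_id) %>%
    summarise(sum_dpsi = sum(.data$dpsi),
              n_introns_used = dplyr::n(), .groups = "drop")
}

empty_correlation <- function(scope = c("cohort", "gene_id")) {
  out <- tibble(n = numeric(), rho = numeric(), p = numeric(), q = numeric())
  for (s in rev(scope)) out <- dplyr::bind_cols(tibble(!!s := character()), out)
  out
}

correlate_by_cohort <- function(tab, value_x, value_y, min_n = 3L) {
  tab <- tab %>%
    group_by(.data$cohort, .data$gene_id) %>%
    filter(dplyr::n() >= min_n)
  if (nrow(tab) == 0L) return(empty_correlation())
  tab %>%
    summarise(res = list(spearman_test(.data[[value_x]], .data[[value_y]])),
              .groups = "drop") %>%
    mutate(
      n = vapply(.data$res, `[[`, numeric(1), "n"),
      rho = vapply(.data$res, `[[`, numeric(1), "rho"),
      p = vapply(.data$res, `[[`, numeric(1), "p")
    ) %>%
    select(-"res") %>%
    filter(!is.na(.data$rho)) %>%
    group_by(.data$cohort) %>%
    mutate(q = bh_fdr(.data$p)) %>%
    ungroup()
}

#' Correlate tumor activity with component expression within cohorts
#'
#' Spearman correlation, per cohort, between each spliceosome component's
#' normalized expression in tumor samples and those tumors' summed-beta
#' activity, with BH adjustment across components within the cohort.
#' Components measured in fewer than 3 tumors, or with zero variance, are
#' reported absent.
#'
#' @param activity Tumor activity scores from [tumor_activity()].
#' @param norm_counts Normalized genes-by-samples matrix.
#' @param component_genes Character vector of component gene ids.
#' @return Tibble with `cohort`, `gene_id`, `n`, `rho`, `p`, `q`.
#' @export
component_activity_correlation <- function(activity, norm_counts,
                                           component_genes) {
  component_genes <- intersect(component_genes, rownames(norm_counts))
  act <- activity %>% filter(.data$sample_id %in% colnames(norm_counts))
  if (nrow(act) == 0L || length(component_genes) == 0L) {
    return(tibble(cohort = character(), gene_id = character(), n = numeric(),
                  rho = numeric(), p = numeric(), q = numeric()))
  }
  expr <- norm_counts[component_genes, act$sample_id, drop = FALSE]
  tab <- tibble(
    cohort = rep(act$cohort, each = length(component_genes)),
    gene_id = rep(component_genes, times = nrow(act)),
    sum_beta = rep(act$sum_beta, each = length(component_genes)),
    expression = as.vector(expr)
  )
  correlate_by_cohort(tab, "expression", "sum_beta")
}

#' Correlate per-patient activity change with component expression change
#'
#' Spearman correlation, per cohort, between each component's per-patient
#' log2 fold change (tumor/normal) and the patient's summed-dPSI activity
#' change, BH-adjusted across components within the cohort.
#'
#' @param changes Patient activity changes from [patient_activity_change()].
#' @param per_patient_lfc Per-patient fold changes (`per_patient` element of
#'   [paired_log2fc()]), restricted to or filtered for component genes.
#' @param component_genes Character vector of component gene ids.
#' @return Tibble with `cohort`, `gene_id`, `n`, `rho`, `p`, `q`.
#' @export
change_correlation <- function(changes, per_patient_lfc, component_genes) {
  tab <- per_patient_lfc %>%
    filter(.data$gene_id %in% component_genes) %>%
    inner_join(changes, by = c("cohort", "patient_id"))
  if (nrow(tab) == 0L) {
    return(tibble(cohort = character(), gene_id = character(), n = numeric(),
                  rho = numeric(), p = numeric(), q = numeric()))
  }
  correlate_by_cohort(tab, "log2fc", "sum_dpsi")
}
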