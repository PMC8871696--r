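#' Median-of-ratios size factors
#'
#' Per-sample scaling constants: the reference is the per-gene geometric mean
#' over samples, restricted to genes with strictly positive counts in every
#' sample; a sample's factor is the median over those genes of
#' count / reference.
#'
#' @param counts Genes-by-samples numeric matrix of raw counts (>= 2 samples).
#' @return Named numeric vector of positive size factors.
#' @export
median_of_ratios <- function(counts) {
  if (ncol(counts) < 2) stop("need at least 2 samples")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("no gene has positive counts in every sample; size factors cannot ",
         "be estimated (filter samples or supply deeper counts)")
  }
  logc <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(logc)
  sf <- apply(logc, 2, function(col) exp(median(col - ref)))
  sf
}

#' Divide counts by per-sample size factors
#'
#' @param counts Genes-by-samples matrix.
#' @param size_factors Named vector from [median_of_ratios()]; names must
#'   cover the matrix columns.
#' @return Normalized matrix of the same shape.
#' @export
normalize_counts <- function(counts, size_factors) {
  if (!all(colnames(counts) %in% names(size_factors))) {
    stop("size factors missing for some samples")
  }
  sweep(counts, 2, size_factors[colnames(counts)], "/")
}

#' Per-patient and mean log2 fold change (tumor/normal)
#'
#' For each gene and matched pair: log2((tumor + pseudocount) /
#' (normal + pseudocount)) on normalized counts, then the mean over patients.
#'
#' @param norm_counts Normalized genes-by-samples matrix.
#' @param pairs Matched pairs tibble ([select_matched_pairs()]); eligible
#'   cohorts only are used.
#' @param genes Optional character vector restricting the genes.
#' @param pseudocount Added to both terms (default 1).
#' @return List with `per_patient` (tibble: cohort, gene_id, patient_id,
#'   log2fc) and `mean` (tibble: cohort, gene_id, n_pairs, mean_log2fc).
#' @export
paired_log2fc <- function(norm_counts, pairs, genes = NULL, pseudocount = 1) {
  pairs <- pairs[pairs$eligible, ]
  if (is.null(genes)) genes <- rownames(norm_counts)
  genes <- intersect(genes, rownames(norm_counts))
  keep <- pairs$tumor_sample %in% colnames(norm_counts) &
    pairs$normal_sample %in% colnames(norm_counts)
  pairs <- pairs[keep, ]
  tum <- norm_counts[genes, pairs$tumor_sample, drop = FALSE]
  nor <- norm_counts[genes, pairs$normal_sample, drop = FALSE]
  lfc <- log2((tum + pseudocount) / (nor + pseudocount))
  per_patient <- tibble(
    cohort = rep(pairs$cohort, each = length(genes)),
    gene_id = rep(genes, times = nrow(pairs)),
    patient_id = rep(pairs$patient_id, each = length(genes)),
    log2fc = as.vector(lfc)
  )
  mean_tab <- per_patient %>%
    group_by(.data$cohort, .data$gene_id) %>%
    summarise(n_pairs = dplyr::n(), mean_log2fc = mean(.data$log2fc),
              .groups = "drop")
  list(per_patient = per_patient, mean = mean_tab)
}

#' Paired differential expression for a gene set
#'
#' Per cohort and per gene in the set, a paired Wilcoxon signed-rank test on
#' normalized tumor-vs-normal counts across matched pairs, with BH adjustment
#' within (cohort, gene set). Direction is `up`/`down` at q < alpha by the
#' sign of the mean log2 fold change, `ns` otherwise.
#'
#' @param norm_counts Normalized genes-by-samples matrix.
#' @param pairs Matched pairs tibble; eligible cohorts only.
#' @param gene_sets Tibble with `gene_id`, `gene_set` (a gene may appear under
#'   several labels; each label is tested and adjusted separately). Genes
#'   absent from the matrix are skipped with a message.
#' @param alpha Significance threshold on q (default 0.05).
#' @param pseudocount Pseudocount for the fold changes (default 1).
#' @param min_pairs Minimum matched pairs per cohort (default 3).
#' @return Tibble with `cohort`, `gene_set`, `gene_id`, `n_pairs`,
#'   `mean_log2fc`, `statistic`, `p`, `q`, `direction`.
#' @export
test_gene_set_de <- function(norm_counts, pairs, gene_sets, alpha = 0.05,
                             pseudocount = 1, min_pairs = 3L) {
  pairs <- pairs[pairs$eligible, ]
  missing <- setdiff(unique(gene_sets$gene_id), rownames(norm_counts))
  if (length(missing)) {
    message(length(missing), " gene(s) absent from the count table; skipped")
    gene_sets <- gene_sets[!gene_sets$gene_id %in% missing, ]
  }
  if (nrow(gene_sets) == 0L) {
    return(tibble(
      cohort = character(), gene_set = character(), gene_id = character(),
      n_pairs = integer(), mean_log2fc = numeric(), statistic = numeric(),
      p = numeric(), q = numeric(), direction = character()
    ))
  }
  out <- list()
  for (coh in sort(unique(pairs$cohort))) {
    cp <- pairs[pairs$cohort == coh, ]
    cp <- cp[cp$tumor_sample %in% colnames(norm_counts) &
               cp$normal_sample %in% colnames(norm_counts), ]
    if (nrow(cp) < min_pairs) next
    genes <- unique(gene_sets$gene_id)
    tum <- norm_counts[genes, cp$tumor_sample, drop = FALSE]
    nor <- norm_counts[genes, cp$normal_sample, drop = FALSE]
    diffs <- tum - nor
    lfc_mean <- rowMeans(log2((tum + pseudocount) / (nor + pseudocount)))
    tests <- apply(diffs, 1, paired_wilcoxon)
    per_gene <- tibble(
      gene_id = genes,
      n_pairs = nrow(cp),
      mean_log2fc = unname(lfc_mean),
      statistic = unname(vapply(tests, `[[`, numeric(1), "statistic")),
      p = unname(vapply(tests, `[[`, numeric(1), "p"))
    )
    res <- gene_sets %>%
      inner_join(per_gene, by = "gene_id") %>%
      group_by(.data$gene_set) %>%
      mutate(q = bh_fdr(.data$p)) %>%
      ungroup() %>%
      mutate(
        cohort = coh,
        direction = dplyr::case_when(
          .data$q < alpha & .data$mean_log2fc > 0 ~ "up",
          .data$q < alpha & .data$mean_log2fc < 0 ~ "down",
          TRUE ~ "ns"
        )
      )
    out[[coh]] <- res
  }
  bind_rows(out) %>%
    select("cohort", "gene_set", "gene_id", "n_pairs", "mean_log2fc",
           "statistic", "p", "q", "direction") %>%
    arrange(.data$cohort, .data$gene_set, .data$gene_id)
}

#' MIG up-regulation enrichment against the protein-coding background
#'
#' Per cohort, a one-sided exact binomial test asking whether more MIGs are
#' significantly up-regulated than expected from the protein-coding
#' background, with BH adjustment across cohorts. Two contrasts are
#' available: `"background"` (default) takes the background proportion as
#' (significantly up protein-coding genes) / (protein-coding genes tested)
#' and the successes as MIGs significantly up among all MIGs tested;
#' `"significant_only"` restricts both to significant genes, i.e.
#' up / (up + down).
#'
#' @param de Differential-expression results from [test_gene_set_de()]
#'   containing gene sets `"MIG"` and `"protein_coding"`.
#' @param contrast `"background"` or `"significant_only"`.
#' @return Tibble with `cohort`, `n_mig_tested`, `n_mig_up`,
#'   `background_prop`, `p`, `q`.
#' @export
mig_enrichment <- function(de, contrast = c("background", "significant_only")) {
  contrast <- match.arg(contrast)
  per_cohort <- de %>%
    filter(.data$gene_set %in% c("MIG", "protein_coding")) %>%
    group_by(.data$cohort, .data$gene_set) %>%
    summarise(
      n_tested = dplyr::n(),
      n_up = sum(.data$direction == "up"),
      n_down = sum(.data$direction == "down"),
      .groups = "drop"
    ) %>%
    tidyr::pivot_wider(names_from = "gene_set",
                       values_from = c("n_tested", "n_up", "n_down"))
  if (contrast == "background") {
    res <- per_cohort %>%
      mutate(
        n_mig_tested = .data$n_tested_MIG,
        n_mig_up = .data$n_up_MIG,
        background_prop = .data$n_up_protein_coding / .data$n_tested_protein_coding
      )
  } else {
    res <- per_cohort %>%
      mutate(
        n_mig_tested = .data$n_up_MIG + .data$n_down_MIG,
        n_mig_up = .data$n_up_MIG,
        background_prop = .data$n_up_protein_coding /
          pmax(.data$n_up_protein_coding + .data$n_down_protein_coding, 1L)
      ) %>%
      filter(.data$n_mig_tested > 0)
  }
  res <- res %>%
    mutate(p = mapply(binomial_enrichment_test, .data$n_mig_up,
                      .data$n_mig_tested, .data$background_prop)) %>%
    select("cohort", "n_mig_tested", "n_mig_up", "background_prop", "p")
  res$q <- bh_fdr(res$p)
  res
}
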