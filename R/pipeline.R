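#' Run configuration for the end-to-end pipeline
#'
#' @param annotation,coverage,gene_counts,samples,gene_sets Input paths
#'   (gene_counts/gene_sets may be `NULL` to skip the expression layer).
#' @param out_dir Output directory.
#' @param coverage_dialect `"tsv_long"` or `"hdf5"`.
#' @param alpha Significance threshold used throughout (default 0.05).
#' @param min_patients Matched pairs required for cohort eligibility
#'   (default 5).
#' @param min_pairs Complete pairs required per intron/gene test (default 3).
#' @param pseudocount Pseudocount for fold changes (default 1).
#' @param enrichment_contrast `"background"` or `"significant_only"` (see
#'   [mig_enrichment()]).
#' @return A `minorsplice_run_config` list.
#' @export
run_config <- function(annotation, coverage, samples, gene_counts = NULL,
                       gene_sets = NULL, out_dir = "minorsplice_out",
                       coverage_dialect = "tsv_long", alpha = 0.05,
                       min_patients = 5L, min_pairs = 3L, pseudocount = 1,
                       enrichment_contrast = "background") {
  stopifnot(alpha > 0, alpha < 1, min_patients >= 1, min_pairs >= 1)
  cfg <- list(
    annotation = annotation, coverage = coverage, samples = samples,
    gene_counts = gene_counts, gene_sets = gene_sets, out_dir = out_dir,
    coverage_dialect = coverage_dialect, alpha = alpha,
    min_patients = as.integer(min_patients), min_pairs = as.integer(min_pairs),
    pseudocount = pseudocount, enrichment_contrast = enrichment_contrast
  )
  class(cfg) <- "minorsplice_run_config"
  cfg
}

write_out <- function(tab, dir, name) {
  readr::write_tsv(tab, file.path(dir, name))
}

#' Run the full minor-splicing analysis and write all result tables
#'
#' Reads the inputs, computes PSI and paired dPSI, tests per-intron
#' differential splicing and summarises cohorts by their minor-splicing
#' score, runs the expression layer (size factors, per-set differential
#' expression, MIG enrichment), estimates per-tumor activity and per-patient
#' activity change with their component correlations, and screens genes for
#' cross-cohort correlation between splicing score and expression change.
#' Every table is written as TSV under `config$out_dir`, together with a JSON
#' run manifest (package version, parameters, input digests). The run is
#' deterministic given inputs and configuration.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of all result tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "minorsplice_run_config"))
  for (p in c(config$annotation, config$coverage, config$samples)) {
    if (!file.exists(p)) stop("input not found: ", p)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  annotation <- read_intron_annotation(config$annotation)
  cov <- read_coverage(config$coverage, config$coverage_dialect)
  coverage <- cov$records
  if (!is.null(cov$events)) {
    mapping <- match_events_to_minor_introns(cov$events, annotation)
    coverage <- coverage %>%
      inner_join(mapping, by = c(intron_id = "event_id")) %>%
      mutate(intron_id = .data$intron_id.y) %>%
      select(-"intron_id.y")
  }
  samples <- read_sample_sheet(config$samples)

  pairs <- select_matched_pairs(samples, config$min_patients)
  psi <- compute_psi(coverage, annotation, samples)
  paired <- build_paired_psi(psi, pairs)
  intron_tests <- test_cohort_introns(paired, config$alpha, config$min_pairs)
  cohort_summary <- summarize_cohorts(intron_tests, config$alpha)

  stats <- normal_psi_stats(psi)
  activity <- tumor_activity(psi, stats)
  changes <- patient_activity_change(paired)

  results <- list(
    pairs = pairs, psi = psi, paired_psi = paired,
    intron_tests = intron_tests, cohort_summary = cohort_summary,
    activity = activity, activity_change = changes
  )

  if (!is.null(config$gene_counts)) {
    counts <- read_gene_counts(config$gene_counts)
    gene_sets <- read_gene_sets(config$gene_sets)
    sf <- median_of_ratios(counts)
    norm <- normalize_counts(counts, sf)
    de <- test_gene_set_de(norm, pairs, gene_sets, config$alpha,
                           config$pseudocount, config$min_pairs)
    enr <- mig_enrichment(de, config$enrichment_contrast)
    lfc <- paired_log2fc(norm, pairs, pseudocount = config$pseudocount)
    comp_genes <- gene_sets$gene_id[gene_sets$gene_set == "component"]
    comp_corr <- component_activity_correlation(activity, norm, comp_genes)
    chg_corr <- change_correlation(changes, lfc$per_patient, comp_genes)
    cross <- score_expression_correlation(cohort_summary, lfc$mean)
    results <- c(results, list(
      size_factors = tibble(sample_id = names(sf), size_factor = sf),
      gene_de = de, mig_enrichment = enr,
      component_activity_correlation = comp_corr,
      change_correlation = chg_corr,
      cross_cohort_correlation = cross
    ))
  }

  for (nm in names(results)) {
    write_out(results[[nm]], config$out_dir, paste0(nm, ".tsv"))
  }
  summary_tab <- render_summary(results)
  write_out(summary_tab, config$out_dir, "summary.tsv")
  results$summary <- summary_tab

  inputs <- c(annotation = config$annotation, coverage = config$coverage,
              samples = config$samples)
  if (!is.null(config$gene_counts)) {
    inputs <- c(inputs, gene_counts = config$gene_counts,
                gene_sets = config$gene_sets)
  }
  manifest <- list(
    package = "minorsplice",
    version = as.character(utils::packageVersion("minorsplice")),
    parameters = config[c("alpha", "min_patients", "min_pairs", "pseudocount",
                          "enrichment_contrast", "coverage_dialect")],
    input_md5 = as.list(tools::md5sum(inputs))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

#' Cohort-level report table
#'
#' One row per cohort, ordered by minor-splicing score (descending): counts
#' of significantly up/down/ns introns, the score and skew class, and — when
#' the expression layer ran — the MIG up/down/ns gene counts.
#'
#' @param results Result list from [run_pipeline()].
#' @return Tibble, one row per cohort.
#' @export
render_summary <- function(results) {
  summ <- results$cohort_summary %>%
    select("cohort", introns_up = "n_up", introns_down = "n_down",
           introns_ns = "n_ns", "score", "skew_class")
  if (!is.null(results$gene_de) && nrow(results$gene_de)) {
    genes <- results$gene_de %>%
      filter(.data$gene_set == "MIG") %>%
      group_by(.data$cohort) %>%
      summarise(
        mig_up = sum(.data$direction == "up"),
        mig_down = sum(.data$direction == "down"),
        mig_ns = sum(.data$direction == "ns"),
        .groups = "drop"
      )
    summ <- left_join(summ, genes, by = "cohort")
  }
  arrange(summ, dplyr::desc(.data$score), .data$cohort)
}
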