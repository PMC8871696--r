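#' Percent-spliced-in from intron and junction counts
#'
#' PSI = 100 * COV_INT / (COV_INT + COV_EJ), where COV_INT is the mean
#' per-base coverage of the intron (total alignments to the intron divided by
#' intron length) and COV_EJ the number of spliced alignments spanning it.
#' High PSI means high retention, i.e. low splicing. A sample yields a PSI
#' for an intron only when it has at least one read supporting either the
#' retained or the spliced form; otherwise the value is `NA`.
#'
#' @param intron_alignment_count Total alignments overlapping the intron.
#' @param intron_length Intron length in bp (> 0).
#' @param junction_count Spliced alignments spanning the intron.
#' @return Numeric PSI in \[0, 100\], `NA` where both counts are zero.
#' @export
psi_value <- function(intron_alignment_count, intron_length, junction_count) {
  if (any(intron_length <= 0)) stop("intron_length must be > 0")
  if (any(intron_alignment_count < 0) || any(junction_count < 0)) {
    stop("counts must be non-negative")
  }
  cov_int <- intron_alignment_count / intron_length
  psi <- 100 * cov_int / (cov_int + junction_count)
  psi[intron_alignment_count + junction_count < 1] <- NA_real_
  psi
}

#' Build the per-sample PSI table
#'
#' Joins coverage records to the minor-intron annotation (for lengths) and the
#' sample sheet (for patient/tissue/cohort), computes PSI via [psi_value()],
#' and applies the >= 1 supporting read filter per (intron, sample). Records
#' for samples absent from the sheet or introns absent from the annotation
#' are dropped.
#'
#' @param coverage Coverage tibble (see [read_coverage()]), with `intron_id`
#'   already mapped to annotation ids.
#' @param annotation Tibble from [read_intron_annotation()]; only minor
#'   introns are used.
#' @param samples Sample sheet tibble.
#' @return Tibble with `cohort`, `intron_id`, `sample_id`, `patient_id`,
#'   `tissue`, `cov_int`, `cov_ej`, `psi`.
#' @export
compute_psi <- function(coverage, annotation, samples) {
  minor <- annotation[annotation$is_minor, c("intron_id", "length")]
  tab <- coverage %>%
    inner_join(minor, by = "intron_id") %>%
    inner_join(samples, by = "sample_id") %>%
    mutate(
      cov_int = .data$intron_alignment_count / .data$length,
      cov_ej = .data$junction_count,
      psi = psi_value(.data$intron_alignment_count, .data$length,
                      .data$junction_count)
    ) %>%
    filter(!is.na(.data$psi)) %>%
    select("cohort", "intron_id", "sample_id", "patient_id", "tissue",
           "cov_int", "cov_ej", "psi")
  tab
}

#' Pair tumor and normal PSI per patient
#'
#' One row per (intron, patient) where both the tumor and the matched normal
#' sample have a defined PSI; dPSI = PSI_normal - PSI_tumor, so positive dPSI
#' means the intron is spliced more efficiently in the tumor.
#'
#' @param psi PSI table from [compute_psi()].
#' @param pairs Matched pairs from [select_matched_pairs()]; only eligible
#'   cohorts' pairs are used.
#' @return Tibble with `cohort`, `intron_id`, `patient_id`, `psi_normal`,
#'   `psi_tumor`, `dpsi`.
#' @export
build_paired_psi <- function(psi, pairs) {
  pairs <- pairs[pairs$eligible, ]
  tum <- psi %>%
    inner_join(pairs, by = c(sample_id = "tumor_sample", cohort = "cohort",
                             patient_id = "patient_id")) %>%
    select("cohort", "intron_id", "patient_id", psi_tumor = "psi")
  nor <- psi %>%
    inner_join(pairs, by = c(sample_id = "normal_sample", cohort = "cohort",
                             patient_id = "patient_id")) %>%
    select("cohort", "intron_id", "patient_id", psi_normal = "psi")
  inner_join(nor, tum, by = c("cohort", "intron_id", "patient_id")) %>%
    mutate(dpsi = .data$psi_normal - .data$psi_tumor) %>%
    arrange(.data$cohort, .data$intron_id, .data$patient_id)
}

#' Introns testable within each cohort
#'
#' An intron is testable in a cohort when at least `min_pairs` patients there
#' have PSI defined in both tissues.
#'
#' @param paired Paired PSI tibble from [build_paired_psi()].
#' @param min_pairs Minimum complete pairs (default 3).
#' @return Tibble with `cohort`, `intron_id`, `n_pairs` for testable introns.
#' @export
filter_testable_introns <- function(paired, min_pairs = 3L) {
  stopifnot(min_pairs >= 1)
  paired %>%
    count(.data$cohort, .data$intron_id, name = "n_pairs") %>%
    filter(.data$n_pairs >= min_pairs)
}
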