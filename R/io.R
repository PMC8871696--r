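#' Read a minor/major intron annotation from a BED6+2 file
#'
#' Expects whitespace- or tab-delimited BED with at least 8 columns:
#' chrom, start, end, name, score, strand, gene_id, minor|major.
#' Coordinates are taken as BED convention (0-based, half-open) and kept that
#' way internally; intron length is computed as `end - start`, never read from
#' the file.
#'
#' @param path Path to the BED-like annotation file.
#' @return A tibble with columns `intron_id`, `chrom`, `start`, `end`,
#'   `strand`, `length`, `gene_id`, `is_minor`.
#' @export
read_intron_annotation <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) {
    warning("empty intron annotation: ", path)
    return(tibble(
      intron_id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), length = integer(),
      gene_id = character(), is_minor = logical()
    ))
  }
  fields <- strsplit(lines, "[ \t]+")
  bad <- which(vapply(fields, length, 1L) < 8L)
  if (length(bad)) {
    stop("annotation line ", bad[1], " has fewer than 8 columns: ", lines[bad[1]])
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  if (anyNA(start) || anyNA(end)) {
    stop("annotation line ", which(is.na(start) | is.na(end))[1],
         ": non-integer coordinates")
  }
  bad <- which(end <= start)
  if (length(bad)) {
    stop("annotation line ", bad[1], ": end <= start (", lines[bad[1]], ")")
  }
  if (any(start < 0L)) stop("negative start coordinate in annotation")
  if (!all(m[, 6] %in% c("+", "-"))) stop("strand must be '+' or '-'")
  minor_lab <- tolower(m[, 8])
  if (!all(minor_lab %in% c("minor", "major"))) {
    stop("column 8 must be 'minor' or 'major'")
  }
  ann <- tibble(
    intron_id = m[, 4], chrom = m[, 1], start = start, end = end,
    strand = m[, 6], length = end - start, gene_id = m[, 7],
    is_minor = minor_lab == "minor"
  )
  if (anyDuplicated(ann$intron_id)) {
    stop("duplicate intron_id in annotation: ",
         ann$intron_id[duplicated(ann$intron_id)][1])
  }
  ann
}

#' Read intron-retention coverage records
#'
#' Two dialects are supported. `tsv_long` is the portable interchange: a
#' four-column table (`intron_id`, `sample_id`, `intron_alignment_count`,
#' `junction_count`), one row per observed (event, sample). `hdf5` is an
#' events-by-samples hierarchical container with datasets `events`
#' (event_id, chrom, start, end, strand), `samples` (sample-id vector),
#' `intron_counts` and `junction_counts` (events x samples matrices); it
#' requires the rhdf5 package.
#'
#' @param path Path to the container.
#' @param dialect `"tsv_long"` or `"hdf5"`.
#' @return A list with `records` (tibble of coverage records) and `events`
#'   (tibble of event coordinates, or `NULL` for the TSV dialect, whose
#'   events are keyed by id).
#' @export
read_coverage <- function(path, dialect = c("tsv_long", "hdf5")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  if (dialect == "tsv_long") {
    rec <- readr::read_tsv(path, col_types = readr::cols(
      intron_id = readr::col_character(),
      sample_id = readr::col_character(),
      intron_alignment_count = readr::col_double(),
      junction_count = readr::col_double()
    ))
    validate_coverage(rec)
    return(list(records = rec, events = NULL))
  }
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("the 'hdf5' dialect requires the rhdf5 package")
  }
  ev <- as_tibble(rhdf5::h5read(path, "events"))
  ev$start <- as.integer(ev$start)
  ev$end <- as.integer(ev$end)
  samples <- as.character(rhdf5::h5read(path, "samples"))
  ic <- rhdf5::h5read(path, "intron_counts")
  jc <- rhdf5::h5read(path, "junction_counts")
  if (ncol(ic) != length(samples) || ncol(jc) != length(samples)) {
    stop("sample-id vector length does not match count matrix columns")
  }
  if (nrow(ic) != nrow(ev) || nrow(jc) != nrow(ev)) {
    stop("event table and count matrices disagree on the number of events")
  }
  rec <- tibble(
    intron_id = rep(ev$event_id, times = length(samples)),
    sample_id = rep(samples, each = nrow(ev)),
    intron_alignment_count = as.vector(ic),
    junction_count = as.vector(jc)
  )
  validate_coverage(rec)
  list(records = rec, events = ev)
}

validate_coverage <- function(rec) {
  need <- c("intron_id", "sample_id", "intron_alignment_count", "junction_count")
  if (!all(need %in% names(rec))) {
    stop("coverage table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyNA(rec$intron_alignment_count) || anyNA(rec$junction_count)) {
    stop("missing counts in coverage table")
  }
  if (any(rec$intron_alignment_count < 0) || any(rec$junction_count < 0)) {
    stop("negative counts in coverage table")
  }
  invisible(rec)
}

#' Write coverage records
#'
#' Inverse of [read_coverage()]; both dialects round-trip exactly.
#'
#' @param records Coverage tibble (see [read_coverage()]).
#' @param path Output path.
#' @param dialect `"tsv_long"` or `"hdf5"`.
#' @param events Event coordinate tibble; required for the hdf5 dialect.
#' @export
write_coverage <- function(records, path, dialect = c("tsv_long", "hdf5"),
                           events = NULL) {
  dialect <- match.arg(dialect)
  validate_coverage(records)
  if (dialect == "tsv_long") {
    readr::write_tsv(records, path)
    return(invisible(path))
  }
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("the 'hdf5' dialect requires the rhdf5 package")
  }
  if (is.null(events)) stop("hdf5 dialect needs an event coordinate table")
  samples <- sort(unique(records$sample_id))
  key <- match(records$intron_id, events$event_id)
  if (anyNA(key)) stop("records reference events absent from the event table")
  ic <- matrix(0, nrow(events), length(samples))
  jc <- matrix(0, nrow(events), length(samples))
  idx <- cbind(key, match(records$sample_id, samples))
  ic[idx] <- records$intron_alignment_count
  jc[idx] <- records$junction_count
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(as.data.frame(events), path, "events")
  rhdf5::h5write(samples, path, "samples")
  rhdf5::h5write(ic, path, "intron_counts")
  rhdf5::h5write(jc, path, "junction_counts")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Parse TCGA-style sample barcodes into patient and tissue
#'
#' Characters 1-12 are the patient id; characters 14-15 are the sample-type
#' code: 01-09 tumor, 10-19 normal. Other codes (e.g. 20+ controls) and
#' malformed barcodes yield `NA` tissue and are meant to be excluded by the
#' caller.
#'
#' @param barcode Character vector of barcodes (>= 15 characters each).
#' @return A tibble with `sample_id`, `patient_id`, `tissue` (`NA` where the
#'   barcode could not be parsed or the code is out of range).
#' @export
parse_sample_barcode <- function(barcode) {
  patient <- ifelse(nchar(barcode) >= 15, substr(barcode, 1, 12), NA_character_)
  code <- suppressWarnings(as.integer(substr(barcode, 14, 15)))
  tissue <- rep(NA_character_, length(barcode))
  ok <- !is.na(patient) & !is.na(code)
  tissue[ok & code >= 1 & code <= 9] <- "tumor"
  tissue[ok & code >= 10 & code <= 19] <- "normal"
  patient[is.na(tissue)] <- NA_character_
  tibble(sample_id = barcode, patient_id = patient, tissue = tissue)
}

#' Read a sample sheet
#'
#' Either a full sheet with columns `sample_id`, `patient_id`, `tissue`,
#' `cohort`, or a barcode sheet with columns `sample_id`, `cohort` whose
#' sample ids are TCGA-style barcodes to be parsed with
#' [parse_sample_barcode()]. Unparseable barcodes are dropped with a message.
#'
#' @param path Path to the TSV sample sheet.
#' @return Tibble with `sample_id`, `patient_id`, `tissue`, `cohort`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (all(c("sample_id", "patient_id", "tissue", "cohort") %in% names(sheet))) {
    if (!all(sheet$tissue %in% c("tumor", "normal"))) {
      stop("tissue must be 'tumor' or 'normal'")
    }
    return(sheet[, c("sample_id", "patient_id", "tissue", "cohort")])
  }
  if (!all(c("sample_id", "cohort") %in% names(sheet))) {
    stop("sample sheet needs sample_id/patient_id/tissue/cohort or sample_id/cohort")
  }
  parsed <- parse_sample_barcode(sheet$sample_id)
  bad <- is.na(parsed$tissue)
  if (any(bad)) {
    message(sum(bad), " sample(s) excluded: unparseable or out-of-range barcode")
  }
  dplyr::bind_cols(parsed, cohort = sheet$cohort)[!bad, ]
}

#' Match detected retention events to annotated minor introns
#'
#' An event maps to an intron iff chrom, start, end and strand all match
#' exactly (both sides 0-based, half-open). Only minor introns are matched;
#' unmatched events are dropped with their count reported via `message()`.
#'
#' @param events Tibble with `event_id`, `chrom`, `start`, `end`, `strand`.
#' @param annotation Tibble from [read_intron_annotation()].
#' @return Tibble mapping `event_id` to `intron_id`.
#' @export
match_events_to_minor_introns <- function(events, annotation) {
  minor <- annotation[annotation$is_minor, ]
  key <- paste(minor$chrom, minor$start, minor$end, minor$strand)
  if (anyDuplicated(key)) {
    stop("duplicate coordinates in minor-intron annotation: ambiguous join")
  }
  ekey <- paste(events$chrom, events$start, events$end, events$strand)
  hit <- match(ekey, key)
  n_unmatched <- sum(is.na(hit))
  if (n_unmatched > 0) {
    message(n_unmatched, " retention event(s) did not match a minor intron and were dropped")
  }
  tibble(
    event_id = events$event_id[!is.na(hit)],
    intron_id = minor$intron_id[hit[!is.na(hit)]]
  )
}

#' Select matched tumor-normal pairs per cohort
#'
#' A patient contributes a pair when it has at least one usable tumor and one
#' usable normal sample; multiple aliquots of the same tissue are collapsed to
#' the lexicographically smallest sample id (a deterministic convention).
#' Cohorts with fewer than `min_patients` pairs are flagged ineligible.
#'
#' @param samples Tibble with `sample_id`, `patient_id`, `tissue`, `cohort`.
#' @param min_patients Minimum matched pairs for cohort eligibility (default 5).
#' @return Tibble with `cohort`, `patient_id`, `tumor_sample`,
#'   `normal_sample`, `eligible` (cohort-level flag repeated per row).
#' @export
select_matched_pairs <- function(samples, min_patients = 5L) {
  stopifnot(min_patients >= 1)
  dedup <- samples %>%
    filter(.data$tissue %in% c("tumor", "normal")) %>%
    group_by(.data$cohort, .data$patient_id, .data$tissue) %>%
    slice_min(.data$sample_id, n = 1, with_ties = FALSE) %>%
    ungroup()
  pairs <- dedup %>%
    tidyr::pivot_wider(
      id_cols = c("cohort", "patient_id"),
      names_from = "tissue", values_from = "sample_id"
    )
  if (!all(c("tumor", "normal") %in% names(pairs))) {
    pairs$tumor <- if ("tumor" %in% names(pairs)) pairs$tumor else NA_character_
    pairs$normal <- if ("normal" %in% names(pairs)) pairs$normal else NA_character_
  }
  pairs <- pairs %>%
    filter(!is.na(.data$tumor), !is.na(.data$normal)) %>%
    rename(tumor_sample = "tumor", normal_sample = "normal") %>%
    group_by(.data$cohort) %>%
    mutate(eligible = dplyr::n() >= min_patients) %>%
    ungroup() %>%
    arrange(.data$cohort, .data$patient_id)
  pairs
}

#' Read a genes-by-samples raw count table
#'
#' @param path TSV with a `gene_id` column followed by one column per sample.
#' @return Integer-valued numeric matrix, genes in rows.
#' @export
read_gene_counts <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ))
  if (anyDuplicated(tab$gene_id)) stop("duplicate gene_id in counts table")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene_id
  if (any(m < 0)) stop("negative entries in gene counts")
  m
}

#' Read a gene-set labelling table
#'
#' Default curated lists ship with the package and can be combined with a
#' user table: `system.file("extdata", "component_genes.tsv", package =
#' "minorsplice")` holds 15 minor-spliceosome components (snRNAs and
#' minor-specific proteins), and `stem_signature_genes.tsv` holds 48
#' placeholder identifiers for an adult stem-cell signature, meant to be
#' overridden with the user's own list.
#'
#' @param path TSV with columns `gene_id`, `gene_set` (a gene may carry
#'   several labels, one row per label).
#' @return Tibble with `gene_id`, `gene_set`.
#' @export
read_gene_sets <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), gene_set = readr::col_character()
  ))
}
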