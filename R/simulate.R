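#' Configuration for the synthetic matched-cohort generator
#'
#' Defines the study conditions a simulated run emulates: matched
#' tumor/normal pairs in several cohorts, per-intron baseline retention drawn
#' from a Beta distribution, negative-binomial read depth per (intron,
#' sample), optional injected tumor PSI shifts, negative-binomial gene counts
#' with sample-specific library factors and injected fold changes, and
#' optional coupling of spliceosome-component expression to a latent
#' per-tumor activity. The default shape (14 cohorts, 110 minor introns,
#' 623 MIGs among 5000 genes, 15 components, 48 stem-signature genes) mirrors
#' the dimensions of a pan-cancer matched-cohort study at desk scale.
#'
#' @param seed Integer seed; it fully determines the generator's output.
#' @param cohorts Character vector of cohort names.
#' @param n_patients Matched pairs per cohort (scalar or one per cohort).
#' @param n_introns Number of minor introns.
#' @param intron_length_range Uniform integer bounds for intron lengths (bp).
#' @param psi_beta_shape Beta shape pair for baseline PSI (on 0-1, then x100).
#' @param depth_mean,depth_size Negative-binomial mean and size for the total
#'   informative reads per (intron, sample).
#' @param psi_effects Tibble (`intron` index, `psi_shift` in PSI points) added
#'   to the tumor's true PSI; negative shifts mean more splicing in the tumor
#'   (positive expected dPSI).
#' @param dropout Probability that an (intron, sample) observation is missing.
#' @param activity_sd PSI points of per-tumor latent-activity jitter: a tumor
#'   with latent z has all intron PSIs shifted by `-activity_sd * z`.
#' @param n_genes Total genes (0 disables the expression layer).
#' @param mig_fraction Fraction of genes labelled MIG.
#' @param n_components,n_stem Sizes of the spliceosome-component and
#'   stem-signature gene sets (disjoint from MIGs).
#' @param gene_log_mu,gene_log_sd Log-normal parameters for per-gene baseline
#'   mean counts.
#' @param gene_dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param libsize_log_sd Log-normal sd of per-sample library factors.
#' @param de_effects Tibble (`gene` index, `log2fc`) applied to tumor means.
#' @param component_coupling Tibble (`component` index, `slope`, `noise_sd`):
#'   a tumor's component mean is multiplied by
#'   `2^(slope * z + N(0, noise_sd))` with z the tumor's latent activity.
#' @return A `minorsplice_sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              cohorts = sprintf("CH%02d", 1:14),
                              n_patients = 20L,
                              n_introns = 110L,
                              intron_length_range = c(80L, 2000L),
                              psi_beta_shape = c(2, 8),
                              depth_mean = 200,
                              depth_size = 10,
                              psi_effects = NULL,
                              dropout = 0,
                              activity_sd = 0,
                              n_genes = 5000L,
                              mig_fraction = 623 / 5000,
                              n_components = 15L,
                              n_stem = 48L,
                              gene_log_mu = log(100),
                              gene_log_sd = 1,
                              gene_dispersion = 0.1,
                              libsize_log_sd = 0.2,
                              de_effects = NULL,
                              component_coupling = NULL) {
  if (length(n_patients) == 1L) n_patients <- rep(n_patients, length(cohorts))
  stopifnot(
    length(n_patients) == length(cohorts),
    all(n_patients >= 1), n_introns >= 1,
    intron_length_range[1] >= 1,
    intron_length_range[2] >= intron_length_range[1],
    all(psi_beta_shape > 0), depth_mean > 0, depth_size > 0,
    dropout >= 0, dropout <= 1, activity_sd >= 0,
    n_genes >= 0, mig_fraction >= 0, mig_fraction <= 1,
    gene_dispersion > 0, libsize_log_sd >= 0
  )
  if (!is.null(psi_effects)) {
    stopifnot(all(psi_effects$intron >= 1), all(psi_effects$intron <= n_introns),
              !anyDuplicated(psi_effects$intron))
  }
  if (!is.null(de_effects) && n_genes > 0) {
    stopifnot(all(de_effects$gene >= 1), all(de_effects$gene <= n_genes),
              !anyDuplicated(de_effects$gene))
  }
  cfg <- list(
    seed = as.integer(seed), cohorts = cohorts, n_patients = n_patients,
    n_introns = as.integer(n_introns),
    intron_length_range = as.integer(intron_length_range),
    psi_beta_shape = psi_beta_shape, depth_mean = depth_mean,
    depth_size = depth_size, psi_effects = psi_effects, dropout = dropout,
    activity_sd = activity_sd, n_genes = as.integer(n_genes),
    mig_fraction = mig_fraction, n_components = as.integer(n_components),
    n_stem = as.integer(n_stem), gene_log_mu = gene_log_mu,
    gene_log_sd = gene_log_sd, gene_dispersion = gene_dispersion,
    libsize_log_sd = libsize_log_sd, de_effects = de_effects,
    component_coupling = component_coupling
  )
  class(cfg) <- "minorsplice_sim_config"
  cfg
}

clip_psi <- function(x) pmin(pmax(x, 0), 100)

#' Simulate a matched tumor/normal study with ground truth
#'
#' Generates, under one seed, an intron annotation, per-(intron, sample)
#' coverage records, gene counts, a sample sheet with TCGA-style barcodes,
#' gene-set labels, and the ground truth behind all of them. For each
#' (intron, sample) the total informative read count N is negative-binomial;
#' the junction count is Binomial(N, 1 - PSI_true/100); the intron alignment
#' count is emitted as (N - junction) * intron_length so that the mean
#' per-base coverage equals the retained-read count exactly and the PSI
#' estimator's sampling distribution is purely binomial.
#'
#' @param config A [simulation_config()].
#' @return List with `annotation`, `coverage`, `events`, `gene_counts`,
#'   `samples`, `gene_sets`, and `truth` (tibbles `introns`, `genes`,
#'   `samples`, `cohorts`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "minorsplice_sim_config"))
  set.seed(config$seed)
  ni <- config$n_introns

  intron_id <- sprintf("MI%04d", seq_len(ni))
  len <- sample(seq(config$intron_length_range[1],
                    config$intron_length_range[2]), ni, replace = TRUE)
  start <- sample.int(1e7, ni, replace = TRUE)
  host <- sprintf("GENE%05d", seq_len(max(config$n_genes, ni)))
  annotation <- tibble(
    intron_id = intron_id,
    chrom = paste0("chr", sample(1:22, ni, replace = TRUE)),
    start = start, end = start + len,
    strand = sample(c("+", "-"), ni, replace = TRUE),
    length = len,
    gene_id = head(rep_len(host, ni), ni),
    is_minor = TRUE
  )
  events <- annotation %>%
    mutate(event_id = .data$intron_id) %>%
    select("event_id", "chrom", "start", "end", "strand")

  baseline <- 100 * rbeta(ni, config$psi_beta_shape[1], config$psi_beta_shape[2])
  shift <- numeric(ni)
  if (!is.null(config$psi_effects)) {
    shift[config$psi_effects$intron] <- config$psi_effects$psi_shift
  }

  samples_list <- list()
  coverage_list <- list()
  truth_samples <- list()
  for (ci in seq_along(config$cohorts)) {
    coh <- config$cohorts[ci]
    np <- config$n_patients[ci]
    pid <- sprintf("TCGA-%02d-%04d", ci, seq_len(np))
    tum <- paste0(pid, "-01A")
    nor <- paste0(pid, "-11A")
    samples_list[[coh]] <- tibble(
      sample_id = c(tum, nor),
      patient_id = rep(pid, 2),
      tissue = rep(c("tumor", "normal"), each = np),
      cohort = coh
    )
    z <- rnorm(np)
    truth_samples[[coh]] <- tibble(
      sample_id = c(tum, nor), cohort = coh,
      tissue = rep(c("tumor", "normal"), each = np),
      activity_z = c(z, rep(0, np))
    )
    # columns: np tumor samples then np normals; rows: introns
    psi_true <- cbind(
      clip_psi(outer(baseline + shift, rep(1, np)) -
                 config$activity_sd * matrix(z, ni, np, byrow = TRUE)),
      matrix(baseline, ni, np)
    )
    sample_ids <- c(tum, nor)
    n_cells <- ni * length(sample_ids)
    n_total <- rnbinom(n_cells, mu = config$depth_mean, size = config$depth_size)
    p_spliced <- 1 - as.vector(psi_true) / 100
    junction <- rbinom(n_cells, n_total, p_spliced)
    retained <- n_total - junction
    rec <- tibble(
      intron_id = rep(intron_id, times = length(sample_ids)),
      sample_id = rep(sample_ids, each = ni),
      intron_alignment_count = retained * rep(len, times = length(sample_ids)),
      junction_count = junction
    )
    if (config$dropout > 0) {
      rec <- rec[runif(nrow(rec)) >= config$dropout, ]
    }
    coverage_list[[coh]] <- rec
  }
  samples <- bind_rows(samples_list)
  coverage <- bind_rows(coverage_list)
  truth_samples <- bind_rows(truth_samples)

  # expression layer
  gene_counts <- NULL
  gene_sets <- tibble(gene_id = character(), gene_set = character())
  truth_genes <- tibble(gene_id = character(), log2fc = numeric())
  if (config$n_genes > 0) {
    ng <- config$n_genes
    gene_id <- sprintf("GENE%05d", seq_len(ng))
    n_mig <- round(config$mig_fraction * ng)
    mig <- gene_id[seq_len(n_mig)]
    rest <- setdiff(gene_id, mig)
    comp <- head(rest, config$n_components)
    stem <- head(setdiff(rest, comp), config$n_stem)
    gene_sets <- bind_rows(
      tibble(gene_id = gene_id, gene_set = "protein_coding"),
      tibble(gene_id = mig, gene_set = "MIG"),
      tibble(gene_id = comp, gene_set = "component"),
      tibble(gene_id = stem, gene_set = "stem_signature")
    )
    base_mu <- rlnorm(ng, config$gene_log_mu, config$gene_log_sd)
    lfc <- numeric(ng)
    if (!is.null(config$de_effects)) {
      lfc[config$de_effects$gene] <- config$de_effects$log2fc
    }
    libf <- rlnorm(nrow(samples), 0, config$libsize_log_sd)
    is_tumor <- samples$tissue == "tumor"
    mu <- outer(base_mu, libf)
    mu[, is_tumor] <- mu[, is_tumor] * 2^lfc
    if (!is.null(config$component_coupling)) {
      cc <- config$component_coupling
      zvec <- truth_samples$activity_z[match(samples$sample_id,
                                             truth_samples$sample_id)]
      for (k in seq_len(nrow(cc))) {
        g <- comp[cc$component[k]]
        gi <- match(g, gene_id)
        noise <- rnorm(sum(is_tumor), 0, cc$noise_sd[k])
        mu[gi, is_tumor] <- mu[gi, is_tumor] *
          2^(cc$slope[k] * zvec[is_tumor] + noise)
      }
    }
    cnt <- matrix(
      rnbinom(length(mu), mu = as.vector(mu), size = 1 / config$gene_dispersion),
      nrow = ng
    )
    rownames(cnt) <- gene_id
    colnames(cnt) <- samples$sample_id
    gene_counts <- cnt
    truth_genes <- tibble(gene_id = gene_id, log2fc = lfc,
                          is_mig = gene_id %in% mig,
                          is_component = gene_id %in% comp,
                          is_stem = gene_id %in% stem)
  }

  truth <- list(
    introns = tibble(intron_id = intron_id, baseline_psi = baseline,
                     psi_shift = shift),
    genes = truth_genes,
    samples = truth_samples,
    cohorts = tibble(
      cohort = config$cohorts,
      true_score_sign = sign(sum(shift < 0) - sum(shift > 0))
    )
  )
  list(annotation = annotation, coverage = coverage, events = events,
       gene_counts = gene_counts, samples = samples, gene_sets = gene_sets,
       truth = truth)
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Emits exactly what the ingestion layer reads: `annotation.bed` (BED6+2),
#' `coverage.tsv` or `coverage.h5`, `gene_counts.tsv`, `samples.tsv`,
#' `gene_sets.tsv`, plus ground-truth TSVs under `truth_*.tsv`.
#'
#' @param sim Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @param dialect Coverage dialect, `"tsv_long"` or `"hdf5"`.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, dialect = c("tsv_long", "hdf5")) {
  dialect <- match.arg(dialect)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- sim$annotation
  bed <- sprintf("%s\t%d\t%d\t%s\t.\t%s\t%s\t%s", ann$chrom, ann$start,
                 ann$end, ann$intron_id, ann$strand, ann$gene_id,
                 ifelse(ann$is_minor, "minor", "major"))
  writeLines(bed, file.path(dir, "annotation.bed"))
  if (dialect == "tsv_long") {
    write_coverage(sim$coverage, file.path(dir, "coverage.tsv"), "tsv_long")
  } else {
    write_coverage(sim$coverage, file.path(dir, "coverage.h5"), "hdf5",
                   events = sim$events)
  }
  readr::write_tsv(sim$samples, file.path(dir, "samples.tsv"))
  if (!is.null(sim$gene_counts)) {
    gc <- tibble::as_tibble(sim$gene_counts, rownames = "gene_id")
    readr::write_tsv(gc, file.path(dir, "gene_counts.tsv"))
    readr::write_tsv(sim$gene_sets, file.path(dir, "gene_sets.tsv"))
  }
  readr::write_tsv(sim$truth$introns, file.path(dir, "truth_introns.tsv"))
  readr::write_tsv(sim$truth$samples, file.path(dir, "truth_samples.tsv"))
  if (nrow(sim$truth$genes)) {
    readr::write_tsv(sim$truth$genes, file.path(dir, "truth_genes.tsv"))
  }
  invisible(dir)
}

#' Null-simulation study of the intron test's type-I error
#'
#' Repeatedly simulates cohorts with no injected splicing effect, runs the
#' PSI quantification and per-intron paired tests, and reports per replicate
#' the fraction of raw p-values below `alpha` and the number of introns
#' passing the FDR threshold.
#'
#' @param config A [simulation_config()] whose `psi_effects` is empty.
#' @param n_reps Number of replicates (0 gives an empty table).
#' @param alpha Nominal level (default 0.05).
#' @return Tibble with `rep`, `n_tests`, `frac_p_sig`, `n_q_sig`.
#' @export
simulate_null_pvalue_study <- function(config, n_reps, alpha = 0.05) {
  stopifnot(inherits(config, "minorsplice_sim_config"))
  if (!is.null(config$psi_effects) && nrow(config$psi_effects) > 0) {
    stop("null study requires an empty psi_effects specification")
  }
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    sim <- simulate_study(cfg)
    psi <- compute_psi(sim$coverage, sim$annotation, sim$samples)
    pairs <- select_matched_pairs(sim$samples)
    paired <- build_paired_psi(psi, pairs)
    res <- test_cohort_introns(paired, alpha = alpha)
    out[[r]] <- tibble(
      rep = r, n_tests = nrow(res),
      frac_p_sig = mean(res$p < alpha),
      n_q_sig = sum(res$q < alpha)
    )
  }
  if (n_reps == 0) {
    return(tibble(rep = integer(), n_tests = integer(),
                  frac_p_sig = numeric(), n_q_sig = integer()))
  }
  bind_rows(out)
}
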