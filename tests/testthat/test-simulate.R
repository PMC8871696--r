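test_that("the generator is deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 555, cohorts = c("A", "B"), n_patients = 6,
                           n_introns = 15, n_genes = 120, mig_fraction = 0.25,
                           n_components = 4, n_stem = 6)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_study(simulation_config(seed = 556, cohorts = c("A", "B"),
                                         n_patients = 6, n_introns = 15,
                                         n_genes = 120))
  expect_false(identical(s1$coverage, s3$coverage))
})

test_that("emitted files match the ingestion formats and round-trip", {
  cfg <- simulation_config(seed = 321, cohorts = "A", n_patients = 6,
                           n_introns = 10, n_genes = 50, mig_fraction = 0.2,
                           n_components = 3, n_stem = 4)
  sim <- simulate_study(cfg)
  d <- tempfile()
  write_simulation(sim, d)
  ann <- read_intron_annotation(file.path(d, "annotation.bed"))
  expect_equal(ann$length, sim$annotation$length)
  cov <- read_coverage(file.path(d, "coverage.tsv"))
  expect_equal(nrow(cov$records), nrow(sim$coverage))
  counts <- read_gene_counts(file.path(d, "gene_counts.tsv"))
  expect_identical(unname(counts), unname(sim$gene_counts))
  sheet <- read_sample_sheet(file.path(d, "samples.tsv"))
  expect_equal(nrow(sheet), 2 * 6)
  # barcodes in the sheet parse back to the sheet's own patient/tissue
  parsed <- parse_sample_barcode(sheet$sample_id)
  expect_equal(parsed$patient_id, sheet$patient_id)
  expect_equal(parsed$tissue, sheet$tissue)
})

test_that("PSI recovered from simulated counts is unbiased at depth", {
  cfg <- simulation_config(seed = 42, cohorts = "A", n_patients = 50,
                           n_introns = 50, n_genes = 0, depth_mean = 150)
  sim <- simulate_study(cfg)
  psi <- compute_psi(sim$coverage, sim$annotation, sim$samples)
  truth <- sim$truth$introns
  by_intron <- psi %>%
    dplyr::group_by(intron_id) %>%
    dplyr::summarise(mean_psi = mean(psi)) %>%
    dplyr::inner_join(truth, by = "intron_id")
  bias <- by_intron$mean_psi - by_intron$baseline_psi
  expect_lt(mean(abs(bias)), 0.5)  # < 0.5 PSI points at depth >= 100
})

test_that("null construction yields no systematic tumor-normal PSI difference", {
  cfg <- simulation_config(seed = 7, cohorts = "A", n_patients = 40,
                           n_introns = 30, n_genes = 0)
  sim <- simulate_study(cfg)
  psi <- compute_psi(sim$coverage, sim$annotation, sim$samples)
  paired <- build_paired_psi(psi, select_matched_pairs(sim$samples))
  per_intron <- paired %>%
    dplyr::group_by(intron_id) %>%
    dplyr::summarise(m = mean(dpsi), se = sd(dpsi) / sqrt(dplyr::n()))
  expect_gt(mean(abs(per_intron$m) <= 3 * per_intron$se), 0.95)
})

test_that("an injected shift is recovered with the dPSI sign convention", {
  # mid-range baselines: a -20 shift is only realizable when baseline PSI
  # stays clear of the 0 boundary
  cfg <- simulation_config(
    seed = 11, cohorts = "A", n_patients = 50, n_introns = 10, n_genes = 0,
    depth_mean = 200, psi_beta_shape = c(10, 10),
    psi_effects = tibble::tibble(intron = 1, psi_shift = -20)
  )
  sim <- simulate_study(cfg)
  psi <- compute_psi(sim$coverage, sim$annotation, sim$samples)
  paired <- build_paired_psi(psi, select_matched_pairs(sim$samples))
  shifted_id <- sim$truth$introns$intron_id[1]
  rec <- mean(paired$dpsi[paired$intron_id == shifted_id])
  expect_lt(abs(rec - 20), 2)  # tumor PSI down 20 -> dPSI approx +20
})

test_that("ground-truth dPSI shifts are recovered in rank order", {
  shifts <- seq(-25, 25, length.out = 11)
  cfg <- simulation_config(
    seed = 101, cohorts = "A", n_patients = 50, n_introns = 40, n_genes = 0,
    psi_beta_shape = c(10, 10),
    psi_effects = tibble::tibble(intron = 1:11, psi_shift = shifts)
  )
  sim <- simulate_study(cfg)
  psi <- compute_psi(sim$coverage, sim$annotation, sim$samples)
  paired <- build_paired_psi(psi, select_matched_pairs(sim$samples))
  est <- paired %>%
    dplyr::group_by(intron_id) %>%
    dplyr::summarise(mean_dpsi = mean(dpsi)) %>%
    dplyr::inner_join(sim$truth$introns, by = "intron_id") %>%
    dplyr::filter(abs(psi_shift) >= 10)  # rank recovery is claimed for clear effects
  rho <- spearman_test(-est$psi_shift, est$mean_dpsi)$rho
  expect_gt(rho, 0.9)
})

test_that("dropout thins observations and the null study table is well-formed", {
  cfg <- simulation_config(seed = 5, cohorts = "A", n_patients = 10,
                           n_introns = 50, n_genes = 0, dropout = 0.4)
  sim <- simulate_study(cfg)
  expect_lt(nrow(sim$coverage), 50 * 20 * 0.75)
  expect_gt(nrow(sim$coverage), 50 * 20 * 0.45)

  cfg0 <- simulation_config(seed = 5, cohorts = "A", n_patients = 5,
                            n_introns = 20, n_genes = 0)
  empty <- simulate_null_pvalue_study(cfg0, 0)
  expect_equal(nrow(empty), 0L)
  bad <- simulation_config(seed = 5, cohorts = "A", n_patients = 5,
                           n_introns = 20, n_genes = 0,
                           psi_effects = tibble::tibble(intron = 1, psi_shift = 5))
  expect_error(simulate_null_pvalue_study(bad, 1), "empty psi_effects")
})

test_that("component coupling drives expression with latent tumor activity", {
  cfg <- simulation_config(
    seed = 31, cohorts = "A", n_patients = 40, n_introns = 30,
    n_genes = 200, mig_fraction = 0.2, n_components = 3, n_stem = 3,
    activity_sd = 6, gene_dispersion = 0.02,
    component_coupling = tibble::tibble(component = 1, slope = 1.5,
                                        noise_sd = 0.05)
  )
  sim <- simulate_study(cfg)
  psi <- compute_psi(sim$coverage, sim$annotation, sim$samples)
  act <- tumor_activity(psi, normal_psi_stats(psi))
  norm <- normalize_counts(sim$gene_counts, median_of_ratios(sim$gene_counts))
  comp <- sim$gene_sets$gene_id[sim$gene_sets$gene_set == "component"]
  cc <- component_activity_correlation(act, norm, comp)
  coupled <- cc[cc$gene_id == comp[1], ]
  expect_gt(coupled$rho, 0.5)
  expect_lt(coupled$q, 0.05)
})
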