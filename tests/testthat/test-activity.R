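psi_row <- function(cohort, intron, sample, patient, tissue, psi) {
  tibble::tibble(cohort = cohort, intron_id = intron, sample_id = sample,
                 patient_id = patient, tissue = tissue,
                 cov_int = 1, cov_ej = 1, psi = psi)
}

test_that("beta is the standardized PSI deviation with degenerate sigma excluded", {
  expect_equal(beta_coefficient(40, 60, 10), 2.0)
  expect_equal(beta_coefficient(60, 60, 3), 0.0)
  expect_true(is.na(beta_coefficient(40, 60, 0)))
  expect_true(is.na(beta_coefficient(40, 60, NA)))
  # location equivariance: shifting the tumor PSI by -delta adds delta/sigma
  expect_equal(beta_coefficient(40 - 7, 60, 10) - beta_coefficient(40, 60, 10),
               7 / 10)
})

test_that("normal stats pool all normals and tumor activity sums usable betas", {
  psi <- dplyr::bind_rows(
    # three normals for i1 (psi 50, 60, 70), two for i2 (both 30: sigma 0)
    psi_row("C", "i1", "N1", "P1", "normal", 50),
    psi_row("C", "i1", "N2", "P2", "normal", 60),
    psi_row("C", "i1", "N3", "P3", "normal", 70),
    psi_row("C", "i2", "N1", "P1", "normal", 30),
    psi_row("C", "i2", "N2", "P2", "normal", 30),
    psi_row("C", "i3", "N1", "P1", "normal", 10),
    # tumor T1 sees all three introns, T2 only i1
    psi_row("C", "i1", "T1", "P1", "tumor", 40),
    psi_row("C", "i2", "T1", "P1", "tumor", 10),
    psi_row("C", "i3", "T1", "P1", "tumor", 10),
    psi_row("C", "i1", "T2", "P2", "tumor", 60)
  )
  st <- normal_psi_stats(psi)
  i1 <- st[st$intron_id == "i1", ]
  expect_equal(i1$mu, 60)
  expect_equal(i1$sigma, 10)  # sample sd, n-1 denominator
  expect_equal(i1$n_normals, 3L)
  expect_true(is.na(st$sigma[st$intron_id == "i3"]))  # single normal

  act <- tumor_activity(psi, st)
  t1 <- act[act$sample_id == "T1", ]
  # i2 (sigma 0) and i3 (sigma NA) are excluded; only i1 contributes
  expect_equal(t1$n_introns_used, 1L)
  expect_equal(t1$sum_beta, (60 - 40) / 10)
  t2 <- act[act$sample_id == "T2", ]
  expect_equal(t2$sum_beta, 0)  # tumor at the normal mean
})

test_that("patient activity change sums dPSI over shared introns", {
  paired <- tibble::tibble(
    cohort = "C", intron_id = c("i1", "i2"), patient_id = "P1",
    psi_normal = c(50, 30), psi_tumor = c(40, 35),
    dpsi = c(10, -5)
  )
  chg <- patient_activity_change(paired)
  expect_equal(chg$sum_dpsi, 5)
  expect_equal(chg$n_introns_used, 2L)
})

test_that("held-out normals score near zero; a global splicing gain scores positive", {
  cfg <- simulation_config(seed = 88, cohorts = "H", n_patients = 25,
                           n_introns = 40, n_genes = 0)
  sim <- simulate_study(cfg)
  psi <- compute_psi(sim$coverage, sim$annotation, sim$samples)
  normals <- unique(psi$sample_id[psi$tissue == "normal"])
  held <- normals[1:10]
  scores <- vapply(held, function(s) {
    ref <- normal_psi_stats(psi[!(psi$sample_id == s), ])
    pseudo_tumor <- dplyr::mutate(psi[psi$sample_id == s, ], tissue = "tumor")
    tumor_activity(pseudo_tumor, ref)$sum_beta
  }, numeric(1))
  se <- stats::sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores)), 3 * se + 1e-9)

  # all introns shifted -10 in tumors: activity should be clearly positive
  cfg2 <- simulation_config(
    seed = 99, cohorts = "S", n_patients = 25, n_introns = 40, n_genes = 0,
    psi_effects = tibble::tibble(intron = 1:40, psi_shift = -10)
  )
  sim2 <- simulate_study(cfg2)
  psi2 <- compute_psi(sim2$coverage, sim2$annotation, sim2$samples)
  act2 <- tumor_activity(psi2, normal_psi_stats(psi2))
  expect_gte(mean(act2$sum_beta > 0), 0.95)
})

test_that("component-activity correlations hit the monotone constructions", {
  act <- tibble::tibble(
    cohort = "C", sample_id = paste0("T", 1:8),
    patient_id = paste0("P", 1:8),
    sum_beta = c(3, -1, 5, 0, 2, -4, 7, 1), n_introns_used = 10L
  )
  expr <- rbind(
    cmpA = 10 + act$sum_beta,        # monotone in activity
    cmpB = c(9, 9, 9, 9, 9, 9, 9, 9) # zero variance: reported absent
  )
  colnames(expr) <- act$sample_id
  cc <- component_activity_correlation(act, expr, c("cmpA", "cmpB"))
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$rho[cc$gene_id == "cmpA"], 1)
  # fewer than 3 tumors: skipped entirely
  cc2 <- component_activity_correlation(act[1:2, ], expr[, 1:2], "cmpA")
  expect_equal(nrow(cc2), 0L)
})

test_that("change correlations follow monotone and antitone constructions", {
  chg <- tibble::tibble(
    cohort = "C", patient_id = paste0("P", 1:6),
    sum_dpsi = c(12, -4, 6, 0, -9, 3), n_introns_used = 5L
  )
  lfc <- dplyr::bind_rows(
    tibble::tibble(cohort = "C", gene_id = "up", patient_id = chg$patient_id,
                   log2fc = chg$sum_dpsi / 10),
    tibble::tibble(cohort = "C", gene_id = "dn", patient_id = chg$patient_id,
                   log2fc = -chg$sum_dpsi / 10),
    tibble::tibble(cohort = "C", gene_id = "flat", patient_id = chg$patient_id,
                   log2fc = 0.5)
  )
  cc <- change_correlation(chg, lfc, c("up", "dn", "flat"))
  expect_equal(cc$rho[cc$gene_id == "up"], 1)
  expect_equal(cc$rho[cc$gene_id == "dn"], -1)
  expect_false("flat" %in% cc$gene_id)  # zero variance
})
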