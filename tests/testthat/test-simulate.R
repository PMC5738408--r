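test_that("cohort structure matches the configuration", {
  sc <- small_cohort()
  sim <- sc$sim
  expect_equal(ncol(sim$counts), 16 * 2 * 2)   # donors x lines x cell types
  expect_equal(nrow(sim$counts), 600)
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == round(sim$counts)))
  expect_setequal(unique(sim$metadata$cell_type), c("NPC", "neuron"))
  expect_equal(sum(sim$metadata$diagnosis == "case"), 8 * 2 * 2)
  # mixing proportions are a simplex per sample
  expect_true(all(sim$truth$mixing_profiles >= 0))
  expect_equal(unname(rowSums(sim$truth$mixing_profiles)),
               rep(1, ncol(sim$counts)), tolerance = 1e-12)
  expect_equal(unname(rowSums(sim$truth$mixing_cell_types)),
               rep(1, ncol(sim$counts)), tolerance = 1e-12)
})

test_that("the same seed reproduces the cohort exactly", {
  sc <- small_cohort()
  again <- simulate_cohort(sc$cfg)
  expect_identical(sc$sim$counts, again$counts)
  expect_identical(sc$sim$metadata, again$metadata)
})

test_that("noise-free limit recovers the signature profile", {
  # one cell type locked onto a single profile, no donor effect, no DE,
  # Poisson limit with huge libraries: counts proportional to the signature
  panel <- simulate_signature_panel(n_genes = 300, profiles = c("P1", "P2"),
                                    cell_type_map = c(P1 = "a", P2 = "b"),
                                    seed = 3)
  mix <- list(pure = c(1e6, 1e-6))
  cfg <- simulation_config(n_genes = 300, n_donors_case = 2,
                           n_donors_control = 2, lines_per_donor = 2,
                           cell_types = "pure", icc_donor = 0,
                           frac_de_genes = 0, frac_eqtl = 0, sigma_res = 0,
                           nb_dispersion = 0, mixing_concentration = mix,
                           libsize_log_mean = log(5e7), signature = panel,
                           seed = 4)
  sim <- simulate_cohort(cfg)
  expected <- panel$profiles[, "P1"] + 1    # mix floor
  obs <- rowMeans(sim$counts)
  expect_gt(cor(obs, expected), 0.9999)
})

test_that("simulated donor fraction is recovered by variance partitioning", {
  # tight mixing and near-Poisson counts isolate the documented calibration
  # sigma2_d = icc * sigma2_res / (1 - icc)
  panel <- simulate_signature_panel(n_genes = 400, seed = 2)
  mix <- lapply(ipscvar:::default_mixing(panel, "NPC"), function(a) a * 200)
  cfg <- simulation_config(n_genes = 400, icc_donor = 0.488,
                           n_donors_case = 10, n_donors_control = 10,
                           lines_per_donor = 3, cell_types = "NPC",
                           mixing_concentration = mix, nb_dispersion = 0.005,
                           frac_de_genes = 0, frac_eqtl = 0, seed = 7,
                           signature = panel)
  sim <- simulate_cohort(cfg)
  vp <- partition_matrix(tmm_normalize(sim$counts), sim$metadata,
                         categorical = "donor")
  expect_lt(abs(vp$medians[["donor"]] - 0.488), 0.08)
})

test_that("zeroed variance components leave only residual variation", {
  panel <- simulate_signature_panel(n_genes = 200, n_markers = 20, seed = 5)
  mix <- lapply(ipscvar:::default_mixing(panel, "NPC"), function(a) a * 500)
  cfg <- simulation_config(n_genes = 200, icc_donor = 0, frac_de_genes = 0,
                           frac_eqtl = 0, n_donors_case = 6,
                           n_donors_control = 6, cell_types = "NPC",
                           mixing_concentration = mix, nb_dispersion = 0.005,
                           signature = panel, seed = 6)
  sim <- simulate_cohort(cfg)
  vp <- partition_matrix(tmm_normalize(sim$counts), sim$metadata,
                         categorical = "donor")
  expect_gt(vp$medians[["residual"]], 0.9)
})

test_that("paired cohorts hit the requested effect correlation", {
  cfg <- simulation_config(n_genes = 2000, n_donors_case = 3,
                           n_donors_control = 3, cell_types = "NPC",
                           frac_de_genes = 0.3, seed = 11)
  pr1 <- simulate_paired_cohorts(cfg, 1)
  expect_equal(pr1$cohort_a$truth$lfc, pr1$cohort_b$truth$lfc)
  pr0 <- simulate_paired_cohorts(cfg, 0)
  expect_lt(abs(cor(pr0$cohort_a$truth$lfc, pr0$cohort_b$truth$lfc)), 0.1)
  pr5 <- simulate_paired_cohorts(cfg, 0.5)
  expect_lt(abs(cor(pr5$cohort_a$truth$lfc, pr5$cohort_b$truth$lfc) - 0.5),
            0.12)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(icc_donor = 1), "icc_donor")
  expect_error(simulation_config(n_genes = 100,
                                 signature = simulate_signature_panel(300)),
               "disagree")
  panel <- simulate_signature_panel(n_genes = 300, seed = 1)
  expect_error(simulation_config(n_genes = 300, signature = panel,
                                 mixing_concentration = list(NPC = c(-1, 1)),
                                 cell_types = "NPC"),
               "positive")
})
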