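test_that("blood repertoire conserves molecules and is seed-deterministic", {
  cfg <- tiny_config()
  rep <- simulate_blood_repertoire(cfg, 1)
  expect_identical(rep$total_molecules, cfg$molecules_per_sample)
  expect_equal(sum(clonotype_frequencies(rep)), 1, tolerance = 1e-9)
  expect_identical(rep, simulate_blood_repertoire(cfg, 1))
  expect_false(identical(rep$clonotypes,
                         simulate_blood_repertoire(cfg, 2)$clonotypes))

  one <- simulate_blood_repertoire(tiny_config(n_background_clones = 1L), 1)
  expect_identical(nrow(one$clonotypes), 1L)
  expect_equal(clonotype_frequencies(one), 1)
})

test_that("power-law clone-size law is accepted and invalid laws are not", {
  cfg <- tiny_config(clone_size_law = list(family = "power_law", alpha = 2))
  rep <- simulate_blood_repertoire(cfg, 1)
  expect_identical(rep$total_molecules, cfg$molecules_per_sample)
  expect_error(tiny_config(clone_size_law = list(family = "lognormal",
                                                 mu = 0, sigma = -1)),
               "sigma")
  expect_error(tiny_config(clone_size_law = list(family = "zipf")),
               "unknown")
})

test_that("sharing boundaries flag every or no planted clone as systemic", {
  all_sys <- simulate_patient(tiny_config(sharing_theta = 1,
                                          tcell_infiltration_link = 0), 1)
  expect_true(all(all_sys$truth$planted$flag == "systemic"))
  none <- simulate_patient(tiny_config(sharing_theta = 0,
                                       tcell_infiltration_link = 0), 1)
  expect_false(any(none$truth$planted$flag == "systemic"))
})

test_that("systemic fraction matches the sharing probability", {
  cfg <- tiny_config(n_patients = 200L, n_background_clones = 50L,
                     n_planted_per_joint = 20L, sharing_theta = 0.5,
                     tcell_infiltration_link = 0)
  flags <- unlist(lapply(1:200, function(i)
    simulate_patient(cfg, i)$truth$planted$flag))
  expect_gte(mean(flags == "systemic"), 0.4)
  expect_lte(mean(flags == "systemic"), 0.6)
})

test_that("joint repertoires carry the planted clones near the target frequency", {
  cfg <- tiny_config(sharing_theta = 1, tcell_infiltration_link = 0)
  sim <- simulate_patient(cfg, 1)
  for (jt in list(sim$joint_small, sim$joint_large)) {
    key <- paste(jt$clonotypes$v_call, jt$clonotypes$junction)
    pk <- paste(sim$truth$planted$v_call, sim$truth$planted$junction)
    idx <- match(pk, key)
    expect_false(anyNA(idx))
    freqs <- clonotype_frequencies(jt)[idx]
    expect_true(all(abs(freqs - cfg$planted_tissue_freq) < 0.005))
  }
})

test_that("read emission respects UMIs and the miscall rate", {
  cfg <- tiny_config(clonotype_miscall_rate = 0)
  rep1 <- make_repertoire(1L)
  reads <- emit_reads(rep1, cfg, seed = 5)
  expect_identical(length(unique(reads$umi)), 1L)
  expect_true(all(reads$junction == rep1$clonotypes$junction))

  cfg2 <- tiny_config(clonotype_miscall_rate = 0.1,
                      reads_per_molecule_mean = 1)
  big <- make_repertoire(rep(1000L, 10))
  reads2 <- emit_reads(big, cfg2, seed = 6)
  expect_identical(length(unique(reads2$umi)), 10000L)
  truth <- rep(big$clonotypes$junction, big$clonotypes$count)
  # reads_per_molecule_mean = 1 gives exactly one read per molecule, in
  # molecule order, so the observed miscall fraction is a direct binomial
  miscall <- mean(reads2$junction != truth)
  expect_gte(miscall, 0.08)
  expect_lte(miscall, 0.12)
})

test_that("expression generator recovers the planted pathway effect", {
  cfg <- tiny_config(n_patients = 1L,
                     pathway_sizes = c(TCR_SIGNALING = 50L),
                     delta_pathway = c(TCR_SIGNALING = 2),
                     sigma_patient = 0, sigma_resid = 0.1,
                     tcell_infiltration_link = 0)
  sim <- simulate_patient(cfg, 1)
  ex <- simulate_expression(cfg, list(sim$truth), n_oa = 4)
  sel <- ex$gene_sets$TCR_SIGNALING
  oa <- ex$sample_sheet$sample_id[ex$sample_sheet$disease == "OA"]
  ra <- ex$sample_sheet$sample_id[ex$sample_sheet$disease == "RA"]
  d <- mean(ex$matrix[sel, ra[1]] - rowMeans(ex$matrix[sel, oa]))
  expect_equal(d, 2, tolerance = 0.1)
  expect_identical(ex$matrix, simulate_expression(cfg, list(sim$truth), 4)$matrix)
})

test_that("null expression makes RA and OA columns exchangeable", {
  cfg <- tiny_config(n_patients = 10L, pathway_sizes = c(TCR_SIGNALING = 20L),
                     delta_pathway = c(TCR_SIGNALING = 0),
                     sigma_patient = 0, tcell_infiltration_link = 0)
  sims <- lapply(1:10, function(i) simulate_patient(cfg, i)$truth)
  ex <- simulate_expression(cfg, sims, n_oa = 10)
  ra <- ex$sample_sheet$disease == "RA"
  expect_lt(abs(mean(ex$matrix[, ra]) - mean(ex$matrix[, !ra])), 0.05)
})

test_that("histology scores are ordinal 0-3 with the planted pair correlation", {
  ident <- simulate_histology(tiny_config(histology_pair_rho = 1))
  expect_true(all(ident$score %in% 0:3))
  wide <- reshape(ident, idvar = c("patient_id", "marker"),
                  timevar = "joint", direction = "wide")
  expect_identical(wide$score.small, wide$score.large)

  null <- simulate_histology(tiny_config(n_patients = 500L,
                                         histology_pair_rho = 0))
  sm <- null[null$joint == "small" & null$marker == "CD3", ]
  lg <- null[null$joint == "large" & null$marker == "CD3", ]
  r <- suppressWarnings(cor(sm$score[match(lg$patient_id, sm$patient_id)],
                            lg$score, method = "spearman"))
  expect_lt(abs(r), 0.1)
})

test_that("configuration invariants are enforced", {
  expect_error(tiny_config(planted_tissue_freq = 1.2), "planted_tissue_freq")
  expect_error(tiny_config(n_planted_per_joint = 150L,
                           planted_tissue_freq = 0.01), ">= 1")
  expect_error(tiny_config(molecules_per_sample = 5000L), "20,000")
  expect_error(tiny_config(pathway_sizes = c(TCR_SIGNALING = 500L),
                           delta_pathway = c(TCR_SIGNALING = 1)),
               "exceed")
  expect_error(tiny_config(sharing_theta = 1.5), "sharing_theta")
})
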