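make_matrix <- function(values, probes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- probes %||% sprintf("p%03d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("gene score is the median fold change against the OA mean", {
  m <- make_matrix(cbind(c(5, 6, 7), c(5, 6, 7), c(5, 6, 7)),
                   samples = c("ra1", "oa1", "oa2"))
  expect_equal(gene_score(m, rownames(m), "ra1", c("oa1", "oa2")), 0)

  m2 <- make_matrix(cbind(c(6, 8, 17), c(5, 6, 7), c(5, 6, 7)),
                    samples = c("ra1", "oa1", "oa2"))
  expect_equal(gene_score(m2, rownames(m2), "ra1", c("oa1", "oa2")), 2)
  # probe order is irrelevant; adding a constant to a probe across all
  # samples leaves the log2 difference unchanged
  expect_equal(gene_score(m2, rev(rownames(m2)), "ra1", c("oa1", "oa2")), 2)
  m3 <- m2; m3[2, ] <- m3[2, ] + 5
  expect_equal(gene_score(m3, rownames(m3), "ra1", c("oa1", "oa2")), 2)

  expect_equal(gene_score(m2, rownames(m2), "ra1", c("oa1", "oa2"),
                          scale = "linear"), 4)
  expect_error(gene_score(m2, rownames(m2), "ra1", "oa1"), "2 OA")
  expect_error(gene_score(m2, c("absent1", "absent2"), "ra1",
                          c("oa1", "oa2")), "unresolvable")
  expect_warning(gene_score(m2, c(rownames(m2), "absent"), "ra1",
                            c("oa1", "oa2")), "not in matrix")
})

test_that("gene scores recover the planted pathway effect across samples", {
  cfg <- tiny_config(n_patients = 6L,
                     pathway_sizes = c(TCR_SIGNALING = 50L),
                     delta_pathway = c(TCR_SIGNALING = 2),
                     sigma_patient = 0, sigma_resid = 0.1,
                     tcell_infiltration_link = 0)
  truths <- lapply(1:6, function(i) simulate_patient(cfg, i)$truth)
  ex <- simulate_expression(cfg, truths, n_oa = 4)
  gs <- gene_score_table(ex$matrix, ex$gene_sets, ex$sample_sheet)
  expect_identical(nrow(gs), 12L)
  expect_true(all(abs(gs$TCR_SIGNALING - 2) < 0.15))
})

test_that("paired differential expression of identical groups is flagged null", {
  m <- make_matrix(matrix(rnorm(40), 10))
  de <- differential_expression(m, colnames(m)[1:2], colnames(m)[1:2],
                                paired = TRUE)
  expect_true(all(de$effect == 0))
  expect_true(all(de$p_value == 1))
  expect_true(all(de$zero_variance))
  expect_error(differential_expression(m, colnames(m)[1:3],
                                       colnames(m)[1:2], paired = TRUE),
               "aligned")
})

test_that("differential expression detects planted effects and keeps BH monotone", {
  set.seed(42)
  null_part <- matrix(rnorm(450 * 20), 450)
  sig_part <- cbind(matrix(rnorm(50 * 10, mean = 2, sd = 0.5), 50),
                    matrix(rnorm(50 * 10, sd = 0.5), 50))
  m <- make_matrix(rbind(sig_part, null_part))
  de <- differential_expression(m, colnames(m)[1:10], colnames(m)[11:20])
  planted <- sprintf("p%03d", 1:50)
  expect_gte(mean(de$fdr[match(planted, de$probe_id)] < 0.05), 0.9)
  expect_true(all(diff(de$fdr[order(de$p_value)]) >= -1e-12))
  expect_true(all(de$fdr >= de$p_value, na.rm = TRUE))
})

test_that("T-cell stratification recovers planted blocks deterministically", {
  set.seed(7)
  base <- matrix(rnorm(30 * 12), 30)
  shifted <- base
  shifted[1:20, 1:6] <- shifted[1:20, 1:6] + 3
  m <- make_matrix(shifted)
  labels <- tcell_stratify(m, rownames(m)[1:20], colnames(m))
  expect_identical(unname(labels[1:6]), rep("T-cell-rich", 6))
  expect_identical(unname(labels[7:12]), rep("T-cell-poor", 6))
  expect_identical(labels, tcell_stratify(m, rownames(m)[1:20], colnames(m)))
  expect_setequal(names(labels), colnames(m))

  # duplicated columns (both joints identical) get identical labels
  dup <- make_matrix(shifted[, rep(1:6, each = 2)],
                     samples = sprintf("s%02d", 1:12))
  lab2 <- tcell_stratify(dup, rownames(dup)[1:20], colnames(dup))
  expect_identical(unname(lab2[seq(1, 11, 2)]), unname(lab2[seq(2, 12, 2)]))

  expect_error(tcell_stratify(m, rownames(m)[1:20], colnames(m)[1:3]),
               "at least 4")
})

test_that("correlation matrix reflects shared latent structure", {
  set.seed(11)
  f <- rnorm(30)
  a <- make_matrix(t(sapply(1:5, function(i) f + rnorm(30, sd = 0.2))),
                   probes = sprintf("a%d", 1:5))
  b <- t(sapply(1:4, function(i) f + rnorm(30, sd = 0.2)))
  anti <- -f + rnorm(30, sd = 0.2)
  m <- make_matrix(rbind(a, b, anti, rep(1, 30)),
                   probes = c(sprintf("a%d", 1:5), sprintf("b%d", 1:4),
                              "anti", "flat"))
  r <- correlation_matrix(m, sprintf("a%d", 1:5), sprintf("b%d", 1:4),
                          colnames(m))
  expect_gt(mean(r), 0.8)
  expect_equal(unname(correlation_matrix(m, "a1", "a1", colnames(m))[1, 1]), 1)
  expect_lt(correlation_matrix(m, "a1", "anti", colnames(m))[1, 1], 0)
  expect_true(is.na(correlation_matrix(m, "a1", "flat", colnames(m))[1, 1]))
  expect_error(correlation_matrix(m, "a1", "b1", colnames(m)[1:2]),
               "3 samples")
})
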