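test_that("UMI collapse takes the majority clonotype with deterministic ties", {
  reads <- make_reads(umi = "AAAA",
                      v = c("TRBV1", "TRBV1", "TRBV1", "TRBV1", "TRBV2"),
                      j = "TRBJ1-1",
                      junction = c(rep("ACGTACGT", 4), "ACGTACGA"))
  mol <- collapse_umis(reads)
  expect_identical(nrow(mol), 1L)
  expect_identical(mol$v_call, "TRBV1")
  expect_identical(mol$read_support, 5L)

  three <- make_reads(umi = c("AAAA", "CCCC", "GGGG"), v = "TRBV1",
                      j = "TRBJ1-1", junction = "ACGTACGT")
  expect_identical(nrow(collapse_umis(three)), 3L)

  # 1-1 tie: lexicographically smaller (v, j, junction) wins
  tie <- make_reads(umi = "AAAA", v = c("TRBV2", "TRBV1"), j = "TRBJ1-1",
                    junction = c("ACGTACGA", "ACGTACGT"))
  expect_identical(collapse_umis(tie)$v_call, "TRBV1")

  expect_identical(nrow(collapse_umis(three, min_reads = 2L)), 0L)
  expect_error(collapse_umis(make_reads(umi = "AAAA", v = "TRBV1",
                                        j = "TRBJ1-1",
                                        junction = "ACGT",
                                        sample_id = c("S1", "S2"))),
               "multiple samples")
})

test_that("UMI collapse absorbs read miscalls and matches an exhaustive tally", {
  cfg <- tiny_config(clonotype_miscall_rate = 0.05,
                     reads_per_molecule_mean = 5)
  rep0 <- make_repertoire(rep(500L, 10))  # 5,000 molecules
  reads <- emit_reads(rep0, cfg, seed = 9)
  mol <- collapse_umis(reads)
  truth_set <- paste(rep0$clonotypes$v_call, rep0$clonotypes$junction)
  recovered <- mean(paste(mol$v_call, mol$junction) %in% truth_set)
  expect_gte(recovered, 0.99)

  # independent oracle: per-UMI exhaustive tally
  idx <- split(seq_len(nrow(reads)), reads$umi)
  oracle <- vapply(idx, function(ii) {
    keys <- paste(reads$v_call[ii], reads$j_call[ii], reads$junction[ii])
    tab <- sort(table(keys), decreasing = TRUE)
    winners <- names(tab)[tab == max(tab)]
    sort(winners)[1]
  }, character(1))
  got <- paste(mol$v_call, mol$j_call, mol$junction)[match(names(idx), mol$umi)]
  expect_identical(unname(oracle), got)
})

test_that("repertoire construction filters non-productive molecules", {
  mol <- data.frame(sample_id = "S1", umi = sprintf("U%02d", 1:10),
                    v_call = "TRBV1", j_call = "TRBJ1-1",
                    junction = "ACGTACGT",
                    productive = rep(c(TRUE, FALSE), each = 5),
                    read_support = 1L, stringsAsFactors = FALSE)
  rep1 <- build_repertoire(mol, "S1", "P1", "synovium", "small")
  expect_identical(rep1$total_molecules, 5L)
  expect_identical(rep1$clonotypes$count, 5L)

  expect_error(build_repertoire(mol[mol$productive == FALSE, ],
                                "S1", "P1", "synovium", "small"),
               "productive")
  expect_error(build_repertoire(mol, "OTHER", "P1", "synovium", "small"),
               "metadata mismatch")
})

test_that("blood subsampling conserves totals and reduces to a full draw", {
  blood <- make_repertoire(c(15000L, 5000L), tissue = "blood", joint = "none")
  full <- subsample_blood(blood, 20000L, seed = 1)
  expect_identical(full$count, blood$clonotypes$count)

  deep <- make_repertoire(c(20000L, 60000L), tissue = "blood", joint = "none")
  sub <- subsample_blood(deep, 20000L, seed = 1)
  expect_identical(sum(sub$count), 20000L)
  # clone at blood frequency 0.25: exact hypergeometric quantiles bound the
  # subsample count around the expectation of 5,000
  lo <- qhyper(1e-7, 20000, 60000, 20000)
  hi <- qhyper(1 - 1e-7, 20000, 60000, 20000)
  for (s in 1:10) {
    cnt <- subsample_blood(deep, 20000L, seed = s)$count[1]
    expect_gte(cnt, lo); expect_lte(cnt, hi)
  }
  expect_identical(subsample_blood(deep, 20000L, seed = 3),
                   subsample_blood(deep, 20000L, seed = 3))
  expect_error(subsample_blood(blood, 30000L, seed = 1), "short by 10000")
})

test_that("blood frequency estimates are scale-consistent and censored at the floor", {
  est <- estimate_blood_frequency(40L, 20000L)
  expect_equal(est$est_frequency, 0.002)
  expect_false(est$censored)

  absent <- estimate_blood_frequency(0L, 20000L)
  expect_equal(absent$est_frequency, 1 / 20000)
  expect_true(absent$censored)

  expect_equal(estimate_blood_frequency(20000L, 20000L)$est_frequency, 1)
  expect_error(estimate_blood_frequency(-1L, 100L), "lie in")
})

test_that("enrichment p-value equals the exact binomial tail", {
  expect_equal(enrichment_pvalue(0L, 10L, 0.5), 1)
  # brute-force oracle: direct summation of the binomial mass over k = 3..10
  oracle <- sum(dbinom(3:10, 10, 0.2))
  expect_equal(enrichment_pvalue(3L, 10L, 0.2), oracle, tolerance = 1e-12)
  expect_error(enrichment_pvalue(11L, 10L, 0.2), "syn_count")
  expect_error(enrichment_pvalue(1L, 10L, 0), "blood_freq")
})

test_that("enrichment p-value is monotone in count and blood frequency", {
  for (n in c(50L, 500L)) {
    p_by_count <- enrichment_pvalue(0:n, n, 0.01)
    expect_true(all(diff(p_by_count) <= 1e-15))
    freqs <- c(1e-4, 1e-3, 1e-2, 0.1, 0.5)
    p_by_freq <- enrichment_pvalue(5L, n, freqs)
    expect_true(all(diff(p_by_freq) >= -1e-15))
  }
})

test_that("ETC detection applies all three criteria and matches brute force", {
  joint <- make_repertoire(c(200L, 9L, 50L, 1741L))
  sub <- data.frame(v_call = "TRBV3", j_call = "TRBJ1-1",
                    junction = make_repertoire(c(1L, 1L, 1L))$clonotypes$junction[3],
                    count = 1000L, stringsAsFactors = FALSE)
  # pad subsample to exactly 20,000 with an unrelated clone
  sub <- rbind(sub, data.frame(v_call = "TRBVX", j_call = "TRBJ1-1",
                               junction = "AAAACCCCGGGGTTTT", count = 19000L))
  etc <- detect_etc(joint, sub)
  # clone 1 (200 molecules, blood-absent): passes; clone 2 fails the count
  # criterion; clone 3 is at 5% blood frequency (fold ~ 0.5); clone 4 passes
  expect_identical(etc$v_call, c("TRBV4", "TRBV1"))
  expect_true(all(etc$synovial_count >= 10L,
                  etc$fold >= 100, etc$p_value < 1e-6))
  expect_identical(etc$synovial_freq, sort(etc$synovial_freq,
                                           decreasing = TRUE))
  expect_setequal(paste(etc$v_call, etc$j_call, etc$junction),
                  brute_force_etc(joint, sub, etc_thresholds()))

  stricter <- detect_etc(joint, sub, etc_thresholds(min_fold = 1000))
  expect_true(all(paste(stricter$v_call, stricter$junction) %in%
                    paste(etc$v_call, etc$junction)))

  expect_error(detect_etc(joint, sub[1, ]), "subsample totals")
  blood_rep <- make_repertoire(20000L, tissue = "blood", joint = "none")
  expect_error(detect_etc(blood_rep, sub), "synovial repertoire")
})

test_that("Fisher alternative agrees with the binomial test on clear calls", {
  joint <- make_repertoire(c(300L, 19700L))
  sub <- data.frame(v_call = "TRBVX", j_call = "TRBJ1-1",
                    junction = "AAAACCCCGGGGTTTT", count = 20000L,
                    stringsAsFactors = FALSE)
  bino <- detect_etc(joint, sub)
  fish <- detect_etc(joint, sub, test = "fisher")
  expect_identical(paste(bino$v_call, bino$junction),
                   paste(fish$v_call, fish$junction))
})

test_that("shared-ETC summary counts rearrangements detected in the other joint", {
  rep_s <- make_repertoire(c(100L, 100L, 19800L), sample_id = "S1")
  rep_l <- make_repertoire(c(100L, 100L, 19800L), sample_id = "S2",
                           joint = "large")
  sub <- data.frame(v_call = "TRBVX", j_call = "TRBJ1-1",
                    junction = "AAAACCCCGGGGTTTT", count = 20000L,
                    stringsAsFactors = FALSE)
  etc_s <- detect_etc(rep_s, sub)
  etc_l <- detect_etc(rep_l, sub)
  same <- shared_etc(etc_s, etc_l, rep_s, rep_l)
  expect_equal(same$fraction_shared, 1)

  rep_l2 <- make_repertoire(c(50L, 19950L), sample_id = "S2", joint = "large")
  etc_l2 <- detect_etc(rep_l2, sub)
  # large-joint repertoire contains the small joint's ETC keys, so they
  # still count as shared; restrict to disjoint key spaces for the zero case
  rep_l3 <- repertoire(data.frame(v_call = "TRBV9", j_call = "TRBJ2-1",
                                  junction = "TTTTGGGGCCCCAAAA",
                                  productive = TRUE, count = 20000L),
                       "S2", "P1", "synovium", "large")
  etc_l3 <- detect_etc(rep_l3, sub)
  none <- shared_etc(etc_s, etc_l3, rep_s, rep_l3)
  expect_equal(none$fraction_shared, 0)

  other <- make_repertoire(c(10L, 10L), sample_id = "S9", patient_id = "P2")
  expect_error(shared_etc(etc_s, etc_l, rep_s, other), "patient mismatch")
})

test_that("fully systemic simulations share every detected clonotype", {
  cfg <- tiny_config(sharing_theta = 1, tcell_infiltration_link = 0,
                     n_patients = 5L)
  for (i in 1:5) {
    sim <- simulate_patient(cfg, i)
    sub <- subsample_blood(sim$blood, 20000L, seed = i)
    sh <- shared_etc(detect_etc(sim$joint_small, sub),
                     detect_etc(sim$joint_large, sub),
                     sim$joint_small, sim$joint_large)
    expect_equal(sh$fraction_shared, 1)
  }
})

test_that("detected ETC recover the planted expansions of the joint", {
  cfg <- tiny_config(n_patients = 4L)
  for (i in 1:4) {
    sim <- simulate_patient(cfg, i)
    sub <- subsample_blood(sim$blood, 20000L, seed = i)
    tr <- sim$truth$planted
    for (jt in c("small", "large")) {
      jr <- if (jt == "small") sim$joint_small else sim$joint_large
      expected <- tr[tr$flag %in% c("systemic", paste0("private-", jt)), ]
      etc <- detect_etc(jr, sub)
      expect_true(all(paste(expected$v_call, expected$junction) %in%
                        paste(etc$v_call, etc$junction)))
    }
  }
})
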