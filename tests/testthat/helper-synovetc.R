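# Shared fixtures and independent oracles used across the suite.

# Small read table: one row per read.
make_reads <- function(umi, v, j, junction, sample_id = "S1",
                       productive = TRUE) {
  n <- max(length(umi), length(v), length(j), length(junction))
  data.frame(read_id = sprintf("r%03d", seq_len(n)), sample_id = sample_id,
             umi = rep_len(umi, n), v_call = rep_len(v, n),
             j_call = rep_len(j, n), junction = rep_len(junction, n),
             productive = rep_len(productive, n), stringsAsFactors = FALSE)
}

# Encode an integer as a short A/C/G/T string (distinct per integer).
nt_encode <- function(i) {
  s <- ""
  repeat {
    s <- paste0(c("A", "C", "G", "T")[(i %% 4) + 1], s)
    i <- i %/% 4
    if (i == 0) break
  }
  s
}

# Repertoire from a count vector; clonotype i gets a distinct junction.
make_repertoire <- function(counts, sample_id = "S1", patient_id = "P1",
                            tissue = "synovium", joint = "small") {
  n <- length(counts)
  tab <- data.frame(v_call = sprintf("TRBV%d", seq_len(n)),
                    j_call = "TRBJ1-1",
                    junction = vapply(seq_len(n), function(i)
                      paste0("ACGTACGTACGT", nt_encode(i)), character(1)),
                    productive = TRUE, count = as.integer(counts),
                    stringsAsFactors = FALSE)
  repertoire(tab, sample_id, patient_id, tissue, joint)
}

# Brute-force ETC oracle: evaluate the three defining criteria clone by
# clone with a direct binomial tail summation.
brute_force_etc <- function(joint, subsample, thr) {
  n <- sum(subsample$count)
  sub_key <- paste(subsample$v_call, subsample$j_call, subsample$junction)
  tab <- joint$clonotypes
  hits <- character(0)
  for (i in seq_len(nrow(tab))) {
    key <- paste(tab$v_call[i], tab$j_call[i], tab$junction[i])
    bc <- subsample$count[match(key, sub_key)]
    if (is.na(bc)) bc <- 0L
    freq_blood <- if (bc == 0L) 1 / n else bc / n
    freq_syn <- tab$count[i] / joint$total_molecules
    p <- sum(dbinom(tab$count[i]:joint$total_molecules,
                    joint$total_molecules, freq_blood))
    if (tab$count[i] >= thr$min_synovial_molecules &&
        freq_syn / freq_blood >= thr$min_fold && p < thr$alpha)
      hits <- c(hits, key)
  }
  sort(hits)
}

# Direct ANOVA-based one-way ICC oracle via aov().
icc_aov_oracle <- function(x) {
  df <- data.frame(y = c(x[, 1], x[, 2]),
                   g = factor(rep(seq_len(nrow(x)), 2)))
  ms <- summary(aov(y ~ g, data = df))[[1]]$`Mean Sq`
  (ms[1] - ms[2]) / (ms[1] + ms[2])
}

# Small default-ish config kept cheap for unit tests; overrides win.
tiny_config <- function(...) {
  args <- list(n_patients = 3L, n_background_clones = 300L,
               n_probes = 200L,
               pathway_sizes = c(TCR_SIGNALING = 20L,
                                 RESPONSE_TO_TNF = 15L),
               delta_pathway = c(TCR_SIGNALING = 2,
                                 RESPONSE_TO_TNF = 1.5),
               seed = 101L)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_config, args)
}
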