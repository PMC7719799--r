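# Clonotype repertoires: UMI collapse, construction, blood subsampling,
# and detection of synovium-enriched T cell clonotypes (ETC).

#' Construct a clonotype repertoire
#'
#' A repertoire is the absolute UMI-based quantification of a sample's TCRB
#' clonotypes: one row per unique productive rearrangement (V gene, J gene,
#' CDR3 junction nucleotides) with its molecule count.
#'
#' @param clonotypes data.frame with columns `v_call`, `j_call`, `junction`,
#'   `productive`, `count` (positive integer molecule counts).
#' @param sample_id,patient_id sample metadata.
#' @param tissue `"blood"` or `"synovium"`.
#' @param joint `"small"`, `"large"`, or `"none"` (blood).
#' @return an object of class `repertoire`: a list with the clonotype table,
#'   metadata, and `total_molecules`.
#' @export
repertoire <- function(clonotypes, sample_id, patient_id,
                       tissue = c("blood", "synovium"),
                       joint = c("none", "small", "large")) {
  tissue <- match.arg(tissue)
  joint <- match.arg(joint)
  need <- c("v_call", "j_call", "junction", "productive", "count")
  if (!all(need %in% names(clonotypes)))
    stop("clonotype table must have columns: ", paste(need, collapse = ", "))
  clonotypes <- clonotypes[clonotypes$count > 0, need, drop = FALSE]
  if (!nrow(clonotypes))
    stop("empty repertoire: no clonotypes with positive counts for sample ",
         sample_id)
  if (!all(clonotypes$productive))
    stop("repertoire may only contain productive clonotypes")
  id <- clone_id(clonotypes$v_call, clonotypes$j_call, clonotypes$junction)
  if (anyDuplicated(id)) {
    agg <- rowsum(clonotypes$count, id)
    keep <- !duplicated(id)
    clonotypes <- clonotypes[keep, , drop = FALSE]
    clonotypes$count <- as.integer(agg[id[keep], 1L])
  }
  o <- order(clonotypes$v_call, clonotypes$j_call, clonotypes$junction,
             method = "radix")
  clonotypes <- clonotypes[o, , drop = FALSE]
  rownames(clonotypes) <- NULL
  structure(list(sample_id = sample_id,
                 patient_id = patient_id,
                 tissue = tissue,
                 joint = joint,
                 clonotypes = clonotypes,
                 total_molecules = sum(clonotypes$count)),
            class = "repertoire")
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("TCRB repertoire: sample %s (patient %s, %s%s)\n",
              x$sample_id, x$patient_id, x$tissue,
              if (x$joint == "none") "" else paste0(", ", x$joint, " joint")))
  cat(sprintf("  %d clonotypes, %d UMI molecules\n",
              nrow(x$clonotypes), x$total_molecules))
  top <- head(x$clonotypes[order(-x$clonotypes$count), ], 3L)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %s %s %s: %d (%.3g)\n", top$v_call[i], top$j_call[i],
                top$junction[i], top$count[i],
                top$count[i] / x$total_molecules))
  invisible(x)
}

#' Clonotype frequencies of a repertoire
#' @param rep a `repertoire`.
#' @return numeric vector of frequencies aligned with `rep$clonotypes`,
#'   summing to 1.
#' @export
clonotype_frequencies <- function(rep) {
  rep$clonotypes$count / rep$total_molecules
}

#' Collapse UMI-tagged reads into molecules
#'
#' Groups reads of one sample by their UMI barcode and assigns each UMI a
#' single consensus molecule: the clonotype called by the majority of the
#' UMI's reads, ties broken by lexicographic order of
#' (v_call, j_call, junction). This is the step that absorbs amplification
#' bias (many reads, one molecule) and sporadic per-read sequencing error.
#'
#' @param reads data.frame of annotated reads with columns `sample_id`,
#'   `umi`, `v_call`, `j_call`, `junction`, `productive` (and optionally
#'   `read_id`). All reads must come from one sample.
#' @param min_reads minimum read support per UMI; molecules with fewer
#'   supporting reads are dropped.
#' @return data.frame of molecules: `sample_id`, `umi`, `v_call`, `j_call`,
#'   `junction`, `productive`, `read_support`.
#' @export
collapse_umis <- function(reads, min_reads = 1L) {
  cols <- c("sample_id", "umi", "v_call", "j_call", "junction", "productive")
  if (!nrow(reads)) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    out$productive <- logical(0)
    out$read_support <- integer(0)
    return(out)
  }
  if (!all(cols %in% names(reads)))
    stop("reads must have columns: ", paste(cols, collapse = ", "))
  if (length(unique(reads$sample_id)) > 1L)
    stop("reads from multiple samples passed to collapse_umis; ",
         "collapse one sample at a time")
  clid <- paste(reads$v_call, reads$j_call, reads$junction, reads$productive,
                sep = "\r")
  key <- paste(reads$umi, clid, sep = "\n")
  votes <- table(key)
  support <- table(reads$umi)
  first <- !duplicated(key)
  cand <- reads[first, cols]
  cand$n_votes <- as.integer(votes[key[first]])
  o <- order(cand$umi, -cand$n_votes, cand$v_call, cand$j_call,
             cand$junction, method = "radix")
  cand <- cand[o, , drop = FALSE]
  win <- cand[!duplicated(cand$umi), , drop = FALSE]
  win$read_support <- as.integer(support[win$umi])
  win <- win[win$read_support >= min_reads, c(cols, "read_support")]
  rownames(win) <- NULL
  win
}

#' Build a repertoire from consensus molecules
#'
#' Discards non-productive rearrangements and aggregates molecule counts per
#' unique clonotype.
#'
#' @param molecules data.frame as returned by [collapse_umis()].
#' @param sample_id,patient_id,tissue,joint sample metadata; `sample_id`
#'   must match the molecules' own sample id.
#' @return a `repertoire`.
#' @export
build_repertoire <- function(molecules, sample_id, patient_id,
                             tissue = c("blood", "synovium"),
                             joint = c("none", "small", "large")) {
  if (nrow(molecules) && "sample_id" %in% names(molecules) &&
      any(molecules$sample_id != sample_id))
    stop("metadata mismatch: molecules carry sample id(s) ",
         paste(setdiff(unique(molecules$sample_id), sample_id), collapse = ", "),
         " but repertoire is being built for ", sample_id)
  prod <- molecules[as.logical(molecules$productive), , drop = FALSE]
  if (!nrow(prod))
    stop("empty repertoire: no productive molecules for sample ", sample_id)
  id <- clone_id(prod$v_call, prod$j_call, prod$junction)
  agg <- rowsum(rep.int(1L, nrow(prod)), id)
  keep <- !duplicated(id)
  tab <- prod[keep, c("v_call", "j_call", "junction", "productive")]
  tab$count <- as.integer(agg[id[keep], 1L])
  repertoire(tab, sample_id, patient_id, tissue, joint)
}

#' Random fixed-size subsample of a blood repertoire
#'
#' Draws exactly `n` molecules without replacement from the blood sample
#' (a multivariate hypergeometric draw over clonotypes), emulating the
#' fixed 20,000-molecule blood reference against which synovial enrichment
#' is judged.
#'
#' @param blood a blood `repertoire` with at least `n` molecules.
#' @param n subsample size (default 20,000).
#' @param seed integer seed making the draw reproducible.
#' @return data.frame `v_call`, `j_call`, `junction`, `count` restricted to
#'   clonotypes with positive subsample counts; counts sum to `n`.
#' @export
subsample_blood <- function(blood, n = 20000L, seed = 1L) {
  stopifnot(inherits(blood, "repertoire"))
  n <- as.integer(n)
  if (blood$total_molecules < n)
    stop(sprintf(
      "insufficient blood depth: %d molecules available, %d requested (short by %d)",
      blood$total_molecules, n, n - blood$total_molecules))
  tab <- blood$clonotypes
  if (blood$total_molecules == n) {
    counts <- tab$count
  } else {
    idx <- rep.int(seq_len(nrow(tab)), tab$count)
    counts <- with_seed(seed, tabulate(sample(idx, n), nbins = nrow(tab)))
  }
  out <- data.frame(v_call = tab$v_call, j_call = tab$j_call,
                    junction = tab$junction, count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[out$count > 0L, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "subsample_size") <- n
  out
}

#' Estimate a clonotype's blood frequency from the fixed subsample
#'
#' A clonotype present in the subsample is estimated at `count / n`; a
#' clonotype absent from the subsample is censored at the detection floor
#' `1 / n` (its true blood frequency is at most that).
#'
#' @param count subsample molecule count(s) of the clonotype(s); 0 if absent.
#' @param n subsample size.
#' @return data.frame `subsample_count`, `est_frequency`, `censored`.
#' @export
estimate_blood_frequency <- function(count, n = 20000L) {
  count <- as.integer(count)
  if (n <= 0L) stop("subsample size must be positive")
  if (any(count < 0L) || any(count > n)) stop("counts must lie in [0, n]")
  censored <- count == 0L
  data.frame(subsample_count = count,
             est_frequency = ifelse(censored, 1 / n, count / n),
             censored = censored)
}

#' Exact binomial enrichment p-value
#'
#' One-sided upper-tail probability of observing at least `syn_count`
#' molecules of a clonotype among `syn_total` synovial molecules if its true
#' frequency were the (possibly censored) blood estimate:
#' P(X >= syn_count), X ~ Binomial(syn_total, blood_freq).
#'
#' @param syn_count synovial molecule count(s) of the clonotype.
#' @param syn_total total synovial molecules in the sample.
#' @param blood_freq estimated blood frequency in (0, 1].
#' @return p-value(s) in (0, 1]; vectorised.
#' @export
enrichment_pvalue <- function(syn_count, syn_total, blood_freq) {
  if (any(syn_count < 0) || any(syn_count > syn_total))
    stop("syn_count must lie in [0, syn_total]")
  if (any(blood_freq <= 0) || any(blood_freq > 1))
    stop("blood_freq must lie in (0, 1]")
  stats::pbinom(syn_count - 1, syn_total, blood_freq, lower.tail = FALSE)
}

#' ETC detection thresholds
#'
#' The three defining criteria of a synovium-enriched T cell clonotype:
#' at least `min_synovial_molecules` UMI molecules in the synovial sample,
#' synovial frequency at least `min_fold` times the estimated blood
#' frequency, and enrichment p-value below `alpha`.
#'
#' @param min_synovial_molecules minimum synovial molecule count (default 10).
#' @param min_fold minimum synovium/blood frequency ratio (default 100).
#' @param alpha significance threshold (default 1e-6).
#' @param blood_subsample_size size of the blood subsample the frequencies
#'   are estimated from (default 20,000).
#' @return a list of class `etc_thresholds`.
#' @export
etc_thresholds <- function(min_synovial_molecules = 10L, min_fold = 100,
                           alpha = 1e-6, blood_subsample_size = 20000L) {
  if (min_synovial_molecules <= 0 || min_fold <= 0 || alpha <= 0 ||
      blood_subsample_size <= 0)
    stop("all ETC thresholds must be strictly positive")
  if (alpha >= 1) stop("alpha must be below 1")
  structure(list(min_synovial_molecules = as.integer(min_synovial_molecules),
                 min_fold = min_fold, alpha = alpha,
                 blood_subsample_size = as.integer(blood_subsample_size)),
            class = "etc_thresholds")
}

#' Detect synovium-enriched T cell clonotypes (ETC)
#'
#' Applies the three ETC criteria (molecule count, fold enrichment over the
#' censored blood frequency estimate, enrichment p-value) to every clonotype
#' of a synovial repertoire.
#'
#' @param joint a synovial `repertoire`.
#' @param blood_subsample subsample table from [subsample_blood()]; its
#'   total must equal `thresholds$blood_subsample_size`.
#' @param thresholds an [etc_thresholds()] object.
#' @param test `"binomial"` (exact one-sided binomial, default) or
#'   `"fisher"` (one-sided Fisher exact test of the 2x2 synovium/blood
#'   count table).
#' @return data.frame of class `etc_table`, one row per ETC, sorted by
#'   decreasing synovial frequency, with columns `v_call`, `j_call`,
#'   `junction`, `synovial_count`, `synovial_freq`, `blood_count`,
#'   `blood_est_frequency`, `blood_censored`, `fold`, `p_value`.
#' @export
detect_etc <- function(joint, blood_subsample,
                       thresholds = etc_thresholds(),
                       test = c("binomial", "fisher")) {
  test <- match.arg(test)
  stopifnot(inherits(joint, "repertoire"))
  if (joint$tissue != "synovium")
    stop("detect_etc expects a synovial repertoire, got tissue '",
         joint$tissue, "'")
  n <- sum(blood_subsample$count)
  if (n != thresholds$blood_subsample_size)
    stop(sprintf(
      "blood subsample totals %d molecules but thresholds expect %d",
      n, thresholds$blood_subsample_size))
  tab <- joint$clonotypes
  syn_total <- joint$total_molecules
  bid <- clone_id(blood_subsample$v_call, blood_subsample$j_call,
                  blood_subsample$junction)
  jid <- clone_id(tab$v_call, tab$j_call, tab$junction)
  bc <- blood_subsample$count[match(jid, bid)]
  bc[is.na(bc)] <- 0L
  est <- estimate_blood_frequency(bc, n)
  syn_freq <- tab$count / syn_total
  fold <- syn_freq / est$est_frequency
  # cheap criteria first; the p-value only decides among count+fold passers
  cand <- tab$count >= thresholds$min_synovial_molecules &
    fold >= thresholds$min_fold
  p <- rep(NA_real_, nrow(tab))
  if (any(cand)) {
    if (test == "binomial") {
      p[cand] <- enrichment_pvalue(tab$count[cand], syn_total,
                                   est$est_frequency[cand])
    } else {
      bc_eff <- ifelse(est$censored, 1L, est$subsample_count)
      idx <- which(cand)
      p[idx] <- vapply(idx, function(i) {
        m <- matrix(c(tab$count[i], syn_total - tab$count[i],
                      bc_eff[i], n - bc_eff[i]), nrow = 2, byrow = TRUE)
        stats::fisher.test(m, alternative = "greater")$p.value
      }, numeric(1))
    }
  }
  keep <- cand & !is.na(p) & p < thresholds$alpha
  out <- data.frame(v_call = tab$v_call[keep], j_call = tab$j_call[keep],
                    junction = tab$junction[keep],
                    synovial_count = tab$count[keep],
                    synovial_freq = syn_freq[keep],
                    blood_count = as.integer(bc[keep]),
                    blood_est_frequency = est$est_frequency[keep],
                    blood_censored = est$censored[keep],
                    fold = fold[keep], p_value = p[keep],
                    stringsAsFactors = FALSE)
  o <- order(-out$synovial_freq, out$v_call, out$j_call, out$junction,
             method = "radix")
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("etc_table", "data.frame"),
            sample_id = joint$sample_id, patient_id = joint$patient_id,
            joint = joint$joint, syn_total = syn_total,
            thresholds = thresholds)
}

#' Shared-ETC summary for one patient's pair of joints
#'
#' An ETC of one joint counts as shared when the same TCRB rearrangement is
#' detected (at least one molecule) in the patient's other joint. The
#' headline fraction uses the union of distinct ETC keys across both joints
#' as denominator; per-joint fractions are also reported.
#'
#' @param etc_small,etc_large `etc_table`s of the small and large joint.
#' @param rep_small,rep_large the corresponding synovial `repertoire`s.
#' @return list of class `shared_etc_summary` with `patient_id`,
#'   `n_etc_small`, `n_etc_large`, `n_etc_union`, `n_shared`,
#'   `fraction_shared`, `fraction_shared_small`, `fraction_shared_large`.
#' @export
shared_etc <- function(etc_small, etc_large, rep_small, rep_large) {
  pats <- c(attr(etc_small, "patient_id"), attr(etc_large, "patient_id"),
            rep_small$patient_id, rep_large$patient_id)
  if (length(unique(pats)) != 1L)
    stop("patient mismatch across shared_etc inputs: ",
         paste(unique(pats), collapse = ", "))
  key_s <- clone_id(etc_small$v_call, etc_small$j_call, etc_small$junction)
  key_l <- clone_id(etc_large$v_call, etc_large$j_call, etc_large$junction)
  in_s <- clone_id(rep_small$clonotypes$v_call, rep_small$clonotypes$j_call,
                   rep_small$clonotypes$junction)
  in_l <- clone_id(rep_large$clonotypes$v_call, rep_large$clonotypes$j_call,
                   rep_large$clonotypes$junction)
  shared_s <- key_s[key_s %in% in_l]
  shared_l <- key_l[key_l %in% in_s]
  union_keys <- unique(c(key_s, key_l))
  shared_keys <- unique(c(shared_s, shared_l))
  frac <- function(num, den) if (den == 0L) NA_real_ else num / den
  structure(list(patient_id = pats[1],
                 n_etc_small = length(key_s),
                 n_etc_large = length(key_l),
                 n_etc_union = length(union_keys),
                 n_shared = length(shared_keys),
                 fraction_shared = frac(length(shared_keys), length(union_keys)),
                 fraction_shared_small = frac(length(shared_s), length(key_s)),
                 fraction_shared_large = frac(length(shared_l), length(key_l))),
            class = "shared_etc_summary")
}

#' @export
print.shared_etc_summary <- function(x, ...) {
  cat(sprintf("Shared-ETC summary, patient %s\n", x$patient_id))
  cat(sprintf("  ETC small joint: %d, large joint: %d (union %d)\n",
              x$n_etc_small, x$n_etc_large, x$n_etc_union))
  cat(sprintf("  shared: %d (%s of union)\n", x$n_shared,
              if (is.na(x$fraction_shared)) "NA"
              else sprintf("%.0f%%", 100 * x$fraction_shared)))
  invisible(x)
}
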