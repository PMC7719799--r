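# Expression analyses: pathway gene scores vs the OA reference,
# differential expression, T-cell-rich/poor stratification, and cross-set
# correlation structure.

check_matrix <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("expression matrix must be a numeric matrix (probes x samples)")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("expression matrix needs probe rownames and sample colnames")
  if (anyDuplicated(rownames(matrix)) || anyDuplicated(colnames(matrix)))
    stop("probe and sample ids must be unique")
  invisible(matrix)
}

#' Resolve a gene set against the matrix probes
#'
#' @param probe_ids character vector of requested probe ids.
#' @param matrix expression matrix.
#' @param set_name name used in messages.
#' @return the resolved probe ids; unresolved ids are attached as attribute
#'   `missing` and reported with a warning, an empty resolution is an error.
#' @export
resolve_gene_set <- function(probe_ids, matrix, set_name = "gene set") {
  probe_ids <- unique(probe_ids)
  hit <- probe_ids %in% rownames(matrix)
  if (!any(hit))
    stop("unresolvable pathway: no probe of '", set_name,
         "' is present in the matrix")
  if (any(!hit))
    warning(sprintf("%s: %d of %d probes not in matrix (%s)", set_name,
                    sum(!hit), length(probe_ids),
                    paste(utils::head(probe_ids[!hit], 5), collapse = ", ")))
  structure(probe_ids[hit], missing = probe_ids[!hit])
}

#' Pathway gene score of one RA sample against the OA reference
#'
#' Per probe of the set, the fold change is the log2 expression in the RA
#' sample minus the mean log2 expression across the OA reference samples;
#' the gene score is the median of these fold changes over the set.
#'
#' @param matrix probes x samples log2 expression matrix.
#' @param probe_ids probes of the pathway (resolved against the matrix).
#' @param ra_sample one RA sample id.
#' @param oa_samples at least two OA reference sample ids.
#' @param scale `"log2"` (default; fold change as log2 difference) or
#'   `"linear"` (fold change as ratio of linear intensities,
#'   2^RA / mean(2^OA), score reported on that linear scale).
#' @return the score (numeric scalar).
#' @export
gene_score <- function(matrix, probe_ids, ra_sample, oa_samples,
                       scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  check_matrix(matrix)
  if (length(oa_samples) < 2L)
    stop("at least 2 OA reference samples are required")
  probe_ids <- resolve_gene_set(probe_ids, matrix)
  stopifnot(ra_sample %in% colnames(matrix),
            all(oa_samples %in% colnames(matrix)))
  ra <- matrix[probe_ids, ra_sample]
  oa <- matrix[probe_ids, oa_samples, drop = FALSE]
  if (scale == "log2") {
    stats::median(ra - rowMeans(oa))
  } else {
    stats::median(2^ra / rowMeans(2^oa))
  }
}

#' Gene scores for every RA sample and pathway
#'
#' @param matrix probes x samples log2 expression matrix.
#' @param gene_sets named list of probe-id vectors.
#' @param sample_sheet data.frame with `sample_id` and `disease` columns;
#'   RA samples are scored against the OA samples.
#' @inheritParams gene_score
#' @return data.frame sample_id x pathway of scores (RA samples as rows).
#' @export
gene_score_table <- function(matrix, gene_sets, sample_sheet,
                             scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  ra <- sample_sheet$sample_id[sample_sheet$disease == "RA"]
  oa <- sample_sheet$sample_id[sample_sheet$disease == "OA"]
  ra <- intersect(ra, colnames(matrix))
  oa <- intersect(oa, colnames(matrix))
  if (length(oa) < 2L) stop("at least 2 OA samples are required")
  out <- data.frame(sample_id = ra, stringsAsFactors = FALSE)
  for (nm in names(gene_sets))
    out[[nm]] <- vapply(ra, function(s)
      gene_score(matrix, gene_sets[[nm]], s, oa, scale), numeric(1))
  out
}

#' Per-probe differential expression with BH correction
#'
#' Two-sided t-tests per probe (paired when `paired = TRUE`, with groups
#' aligned by position, e.g. by patient; otherwise a pooled-variance
#' two-sample test), followed by Benjamini-Hochberg FDR across probes.
#' Zero-variance probes are flagged rather than dropped: a probe with zero
#' variance and zero effect gets p = 1, one with zero variance but non-zero
#' effect gets p = NA.
#'
#' @param matrix probes x samples log2 expression matrix.
#' @param group_a,group_b sample id vectors; under `paired = TRUE` they must
#'   have equal length >= 2 and aligned order.
#' @param paired logical.
#' @return data.frame sorted by p-value: `probe_id`, `effect` (mean log2
#'   difference, A minus B), `statistic`, `p_value`, `fdr`,
#'   `zero_variance`.
#' @export
differential_expression <- function(matrix, group_a, group_b,
                                    paired = FALSE) {
  check_matrix(matrix)
  miss <- setdiff(c(group_a, group_b), colnames(matrix))
  if (length(miss))
    stop("samples not in matrix: ", paste(miss, collapse = ", "))
  a <- matrix[, group_a, drop = FALSE]
  b <- matrix[, group_b, drop = FALSE]
  if (paired) {
    if (length(group_a) != length(group_b) || length(group_a) < 2L)
      stop("paired groups must be aligned and of equal length >= 2")
    d <- a - b
    n <- ncol(d)
    effect <- rowMeans(d)
    sd_d <- sqrt(rowSums((d - effect)^2) / (n - 1))
    tstat <- effect / (sd_d / sqrt(n))
    df <- n - 1
  } else {
    if (ncol(a) < 2L || ncol(b) < 2L)
      stop("each group needs at least 2 samples")
    na <- ncol(a); nb <- ncol(b)
    ma <- rowMeans(a); mb <- rowMeans(b)
    effect <- ma - mb
    ssa <- rowSums((a - ma)^2)
    ssb <- rowSums((b - mb)^2)
    sp2 <- (ssa + ssb) / (na + nb - 2)
    tstat <- effect / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  zero_var <- !is.finite(tstat)
  p <- 2 * stats::pt(-abs(tstat), df)
  p[zero_var] <- ifelse(abs(effect[zero_var]) < .Machine$double.eps^0.5,
                        1, NA_real_)
  tstat[zero_var] <- NA_real_
  out <- data.frame(probe_id = rownames(matrix), effect = effect,
                    statistic = tstat, p_value = p,
                    fdr = stats::p.adjust(p, method = "BH"),
                    zero_variance = zero_var,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_value, out$probe_id, method = "radix"), , drop = FALSE]
}

#' Stratify RA samples into T-cell-rich and T-cell-poor groups
#'
#' Agglomerative hierarchical clustering (Euclidean distance, Ward linkage,
#' cut at two clusters) of the RA samples on the mean-centred log2 values of
#' the TCR-signaling probe set; the cluster with the higher mean centred
#' TCR-set expression is labelled `T-cell-rich`. Deterministic: no random
#' initialisation is involved.
#'
#' @param matrix probes x samples log2 expression matrix.
#' @param tcr_probes probe ids of the TCR-signaling set.
#' @param ra_samples at least 4 RA sample ids.
#' @return named character vector sample_id -> `"T-cell-rich"` /
#'   `"T-cell-poor"`.
#' @export
tcell_stratify <- function(matrix, tcr_probes, ra_samples) {
  check_matrix(matrix)
  if (length(ra_samples) < 4L)
    stop("at least 4 RA samples are required for stratification")
  tcr_probes <- resolve_gene_set(tcr_probes, matrix, "TCR set")
  sub <- matrix[tcr_probes, ra_samples, drop = FALSE]
  centred <- sub - rowMeans(sub)
  cl <- stats::cutree(stats::hclust(stats::dist(t(centred)), "ward.D2"), 2L)
  means <- tapply(colMeans(centred), cl, mean)
  rich <- as.integer(names(means)[which.max(means)])
  setNames(ifelse(cl == rich, "T-cell-rich", "T-cell-poor"),
           ra_samples)
}

#' Pairwise Pearson correlations between two probe sets
#'
#' Correlates each probe of set A with each probe of set B across the given
#' samples. Probes with zero variance yield `NA` entries (recorded, not an
#' error).
#'
#' @param matrix probes x samples log2 expression matrix.
#' @param probes_a,probes_b probe id vectors.
#' @param samples at least 3 sample ids.
#' @return matrix of Pearson r (rows = set A, columns = set B).
#' @export
correlation_matrix <- function(matrix, probes_a, probes_b, samples) {
  check_matrix(matrix)
  if (length(samples) < 3L) stop("at least 3 samples are required")
  probes_a <- resolve_gene_set(probes_a, matrix, "set A")
  probes_b <- resolve_gene_set(probes_b, matrix, "set B")
  a <- t(matrix[probes_a, samples, drop = FALSE])
  b <- t(matrix[probes_b, samples, drop = FALSE])
  suppressWarnings(stats::cor(a, b, method = "pearson"))
}
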