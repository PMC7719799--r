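# Within-patient concordance: one-way ICC of expression in real versus
# random joint pairings, Spearman concordance of ordinal histology scores,
# and correlations of per-pair statistics.

#' One-way single-rater intra-class correlation, ICC(1,1)
#'
#' From the one-way random-effects ANOVA decomposition of `n` pairs of
#' measurements: ICC = (MSB - MSW) / (MSB + (k - 1) MSW) with k = 2, where
#' MSB and MSW are the between-pair and within-pair mean squares. May be
#' negative; a constant input (zero total variance) returns `NA`.
#'
#' @param x numeric matrix with one row per pair and two columns (the pair
#'   members), or a 2-column data.frame.
#' @return the ICC (scalar in [-1, 1], or `NA` for constant input).
#' @export
icc_oneway <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 2L || nrow(x) < 2L)
    stop("icc_oneway needs >= 2 pairs of size 2")
  drop(icc_oneway_rows(t(x[, 1]), t(x[, 2])))
}

# Vectorised ICC(1,1) across probes: S and L are probes x n_pairs matrices.
icc_oneway_rows <- function(S, L) {
  n <- ncol(S)
  pm <- (S + L) / 2
  grand <- rowMeans(pm)
  msb <- 2 * rowSums((pm - grand)^2) / (n - 1)
  msw <- rowSums((S - pm)^2 + (L - pm)^2) / n
  icc <- (msb - msw) / (msb + msw)
  icc[msb + msw == 0] <- NA_real_
  icc
}

#' Compare per-probe ICC under the real pairing against random pairings
#'
#' Computes the per-probe one-way ICC(1,1) of the small/large expression
#' pairs under the real patient pairing, then under `n_random` random
#' re-matchings of small to large samples. By default the random
#' re-matchings are derangements (no re-matched pair equals a real pair),
#' keeping the null strictly non-informative. Significance is the fraction
#' of random pairings whose median per-probe ICC is at least the real
#' median, with add-one correction.
#'
#' @param matrix probes x samples log2 expression matrix.
#' @param pairing data.frame with columns `patient_id`, `small_sample_id`,
#'   `large_sample_id`.
#' @param probes probe ids to use (default: all probes of the matrix).
#' @param n_random number of random pairings (>= 100).
#' @param seed integer seed.
#' @param exclude_true_pairs if `FALSE`, random pairings are unconstrained
#'   permutations (true pairs may reappear).
#' @return list of class `icc_report`: `icc_real` (per-probe), `median_real`,
#'   `random_medians` (one per random pairing), `median_random`
#'   (median of the per-pairing medians), `median_random_pooled` (median of
#'   all random per-probe ICCs), `p_value`, `n_random`.
#' @export
compare_real_vs_random <- function(matrix, pairing, probes = NULL,
                                   n_random = 1000L, seed = 1L,
                                   exclude_true_pairs = TRUE) {
  check_matrix(matrix)
  if (n_random < 100L) stop("n_random must be >= 100")
  npat <- nrow(pairing)
  if (npat < 2L) stop("at least 2 patients are needed to re-match pairs")
  probes <- if (is.null(probes)) rownames(matrix)
            else resolve_gene_set(probes, matrix, "ICC probe set")
  S <- matrix[probes, pairing$small_sample_id, drop = FALSE]
  L <- matrix[probes, pairing$large_sample_id, drop = FALSE]
  icc_real <- icc_oneway_rows(S, L)
  median_real <- stats::median(icc_real, na.rm = TRUE)
  random_perm <- function() {
    repeat {
      perm <- sample.int(npat)
      if (!exclude_true_pairs || !any(perm == seq_len(npat))) return(perm)
    }
  }
  res <- with_seed(seed, {
    meds <- numeric(n_random)
    pooled <- numeric(0)
    acc <- vector("list", n_random)
    for (r in seq_len(n_random)) {
      perm <- random_perm()
      icc_r <- icc_oneway_rows(S, L[, perm, drop = FALSE])
      meds[r] <- stats::median(icc_r, na.rm = TRUE)
      acc[[r]] <- icc_r
    }
    list(meds = meds,
         pooled_median = stats::median(unlist(acc), na.rm = TRUE))
  })
  structure(list(icc_real = setNames(icc_real, probes),
                 median_real = median_real,
                 random_medians = res$meds,
                 median_random = stats::median(res$meds),
                 median_random_pooled = res$pooled_median,
                 p_value = (1 + sum(res$meds >= median_real)) /
                   (n_random + 1),
                 n_random = as.integer(n_random)),
            class = "icc_report")
}

#' @export
print.icc_report <- function(x, ...) {
  cat("One-way ICC, real versus random joint pairings\n")
  cat(sprintf("  probes: %d, random pairings: %d\n",
              length(x$icc_real), x$n_random))
  cat(sprintf("  median ICC real: %.3f, random: %.3f (pooled %.3f)\n",
              x$median_real, x$median_random, x$median_random_pooled))
  cat(sprintf("  permutation p (random median >= real): %.4g\n", x$p_value))
  invisible(x)
}

#' Spearman concordance of paired ordinal histology scores
#'
#' For each marker, the Spearman rank correlation (midrank ties) between
#' small-joint and large-joint scores across patients, with a two-sided
#' p-value. Markers constant in either joint are flagged with `NA`.
#'
#' @param scores long data.frame with columns `sample_id`, `marker`,
#'   `score`.
#' @param pairing data.frame with `patient_id`, `small_sample_id`,
#'   `large_sample_id`.
#' @return data.frame `marker`, `n`, `rho`, `p_value`, `undefined`.
#' @export
histology_concordance <- function(scores, pairing) {
  need <- c("sample_id", "marker", "score")
  if (!all(need %in% names(scores)))
    stop("scores must have columns: ", paste(need, collapse = ", "))
  markers <- unique(scores$marker)
  rows <- lapply(markers, function(mk) {
    sub <- scores[scores$marker == mk, ]
    s <- sub$score[match(pairing$small_sample_id, sub$sample_id)]
    l <- sub$score[match(pairing$large_sample_id, sub$sample_id)]
    ok <- stats::complete.cases(s, l)
    s <- s[ok]; l <- l[ok]
    if (length(s) < 3L)
      stop("marker '", mk, "' has fewer than 3 complete pairs")
    if (stats::sd(s) == 0 || stats::sd(l) == 0)
      return(data.frame(marker = mk, n = length(s), rho = NA_real_,
                        p_value = NA_real_, undefined = TRUE))
    ct <- suppressWarnings(
      stats::cor.test(s, l, method = "spearman", exact = FALSE))
    data.frame(marker = mk, n = length(s), rho = unname(ct$estimate),
               p_value = ct$p.value, undefined = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation between two per-pair statistics
#'
#' Correlates two per-pair summaries (e.g. the mean TCR-signaling gene score
#' of a pair against its shared-ETC fraction, or small- against large-joint
#' gene scores).
#'
#' @param x,y numeric vectors of equal length >= 3 (one value per pair).
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r`, `p_value`, `n`, `method`.
#' @export
pair_score_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y))
    stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("at least 3 complete pairs are required")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       method = method)
}
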