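# End-to-end pipeline: UMI collapse -> repertoires -> blood subsample ->
# ETC -> shared ETC -> gene scores -> stratification -> ICC -> histology
# concordance -> pair correlations, with a provenance block and optional
# on-disk report.

#' Pipeline configuration
#'
#' Collects the input file paths, thresholds and toggles of a full
#' paired-joint analysis run. Referenced files are checked for existence at
#' validation time.
#'
#' @param reads path to an AIRR-style per-read TSV (UMI-tagged), or `NULL`.
#' @param clonotypes path to a pre-collapsed clonotype TSV, or `NULL`.
#'   Exactly one of `reads` / `clonotypes` is needed for the repertoire
#'   stage.
#' @param expression path to the probes x samples expression TSV.
#' @param sample_sheet path to the sample sheet CSV (required).
#' @param gene_sets path to a GMT file of pathways.
#' @param histology path to the histology scores CSV.
#' @param pairing path to the patient pairing CSV.
#' @param thresholds an [etc_thresholds()] object.
#' @param tcell_set name of the TCR-signaling gene set used for
#'   stratification and the score-vs-shared-fraction correlation.
#' @param stages character subset of
#'   `c("repertoire", "expression", "icc", "histology", "correlations")`.
#' @param min_reads minimum read support per UMI when collapsing reads.
#' @param n_random_pairings random pairings for the ICC comparison.
#' @param seed master seed for subsampling and random pairings.
#' @param out_dir output directory for the report, or `NULL` to skip
#'   writing.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(reads = NULL, clonotypes = NULL,
                            expression = NULL, sample_sheet,
                            gene_sets = NULL, histology = NULL,
                            pairing = NULL,
                            thresholds = etc_thresholds(),
                            tcell_set = "TCR_SIGNALING",
                            stages = c("repertoire", "expression", "icc",
                                       "histology", "correlations"),
                            min_reads = 1L, n_random_pairings = 1000L,
                            seed = 1L, out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  cfg <- list(reads = reads, clonotypes = clonotypes,
              expression = expression, sample_sheet = sample_sheet,
              gene_sets = gene_sets, histology = histology,
              pairing = pairing, thresholds = thresholds,
              tcell_set = tcell_set, stages = stages,
              min_reads = as.integer(min_reads),
              n_random_pairings = as.integer(n_random_pairings),
              seed = as.integer(seed), out_dir = out_dir)
  for (f in c("reads", "clonotypes", "expression", "sample_sheet",
              "gene_sets", "histology", "pairing")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("pipeline input '", f, "' does not exist: ", cfg[[f]])
  }
  if ("repertoire" %in% stages && is.null(reads) && is.null(clonotypes))
    stop("repertoire stage enabled but neither reads nor clonotypes given")
  structure(cfg, class = "pipeline_config")
}

# Hash of the analysis-relevant configuration (out_dir excluded so two runs
# writing to different places share provenance).
config_hash <- function(config) {
  key <- config[setdiff(names(config), "out_dir")]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(key, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

build_repertoires_from_config <- function(config, sheet) {
  if (!is.null(config$reads)) {
    reads <- read_airr_reads(config$reads)
    by_sample <- split(reads, reads$sample_id)
    mols <- lapply(by_sample, collapse_umis, min_reads = config$min_reads)
  } else {
    clon <- read_airr_clonotypes(config$clonotypes)
    by_sample <- split(clon, clon$sample_id)
    mols <- NULL
  }
  ids <- names(by_sample)
  meta <- sheet[match(ids, sheet$sample_id), ]
  if (any(is.na(meta$sample_id)))
    stop("repertoire sample(s) missing from sample sheet: ",
         paste(ids[is.na(meta$sample_id)], collapse = ", "))
  reps <- lapply(seq_along(ids), function(i) {
    if (!is.null(mols)) {
      build_repertoire(mols[[i]], ids[i], meta$patient_id[i],
                       meta$tissue[i], meta$joint[i])
    } else {
      tab <- by_sample[[i]]
      tab <- tab[tab$productive, , drop = FALSE]
      if (!nrow(tab)) stop("empty repertoire for sample ", ids[i])
      repertoire(data.frame(tab[c("v_call", "j_call", "junction",
                                  "productive")],
                            count = tab$duplicate_count,
                            stringsAsFactors = FALSE),
                 ids[i], meta$patient_id[i], meta$tissue[i], meta$joint[i])
    }
  })
  names(reps) <- ids
  reps
}

repertoire_stage <- function(config, sheet, log) {
  reps <- build_repertoires_from_config(config, sheet)
  log(sprintf("repertoire: built %d repertoires (%d molecules total)",
              length(reps),
              sum(vapply(reps, `[[`, numeric(1), "total_molecules"))))
  by_patient <- split(reps, vapply(reps, `[[`, character(1), "patient_id"))
  etc_rows <- list(); shared_rows <- list(); etc_tables <- list()
  for (pid in names(by_patient)) {
    pr <- by_patient[[pid]]
    tissue <- vapply(pr, `[[`, character(1), "tissue")
    joint <- vapply(pr, `[[`, character(1), "joint")
    blood <- pr[tissue == "blood"]
    small <- pr[joint == "small" & tissue == "synovium"]
    large <- pr[joint == "large" & tissue == "synovium"]
    if (length(blood) != 1L || length(small) != 1L || length(large) != 1L) {
      log(sprintf("repertoire: patient %s lacks a complete blood/small/large trio, skipped", pid))
      next
    }
    sub <- subsample_blood(blood[[1]], config$thresholds$blood_subsample_size,
                           sub_seed(config$seed, "subsample",
                                    match(pid, names(by_patient))))
    etc_s <- detect_etc(small[[1]], sub, config$thresholds)
    etc_l <- detect_etc(large[[1]], sub, config$thresholds)
    etc_tables[[small[[1]]$sample_id]] <- etc_s
    etc_tables[[large[[1]]$sample_id]] <- etc_l
    etc_rows[[pid]] <- data.frame(
      sample_id = c(small[[1]]$sample_id, large[[1]]$sample_id),
      patient_id = pid, joint = c("small", "large"),
      n_etc = c(nrow(etc_s), nrow(etc_l)),
      total_molecules = c(small[[1]]$total_molecules,
                          large[[1]]$total_molecules),
      stringsAsFactors = FALSE)
    sh <- shared_etc(etc_s, etc_l, small[[1]], large[[1]])
    shared_rows[[pid]] <- data.frame(
      patient_id = pid, n_etc_small = sh$n_etc_small,
      n_etc_large = sh$n_etc_large, n_etc_union = sh$n_etc_union,
      n_shared = sh$n_shared, fraction_shared = sh$fraction_shared,
      fraction_shared_small = sh$fraction_shared_small,
      fraction_shared_large = sh$fraction_shared_large,
      stringsAsFactors = FALSE)
  }
  etc_counts <- do.call(rbind, etc_rows)
  shared <- do.call(rbind, shared_rows)
  if (!is.null(etc_counts)) rownames(etc_counts) <- NULL
  if (!is.null(shared)) rownames(shared) <- NULL
  log(sprintf("repertoire: %d ETC across %d synovial samples",
              sum(etc_counts$n_etc %||% 0), nrow(etc_counts %||% data.frame())))
  list(etc_counts = etc_counts, shared = shared, etc_tables = etc_tables)
}

#' Run the full paired-joint analysis pipeline
#'
#' Executes the enabled stages in order and assembles a run report. All
#' randomness (blood subsampling, random pairings) derives from the config
#' seed through named substreams, so identical config + seed yields an
#' identical report.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage logging.
#' @return list of class `run_report` with one element per enabled stage
#'   plus a `provenance` block (config hash, seed, package version). If
#'   `config$out_dir` is set, the report is also written there as
#'   `report.json` plus TSV tables.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- if (quiet) function(...) invisible() else
    function(msg) message("[synovetc] ", msg)
  report <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  sheet <- stage("inputs", read_sample_sheet(config$sample_sheet))
  matrix <- NULL; sets <- NULL; pairing <- NULL
  if (!is.null(config$expression))
    matrix <- stage("inputs", read_expression_matrix(config$expression))
  if (!is.null(config$gene_sets))
    sets <- stage("inputs", read_gmt(config$gene_sets))
  if (!is.null(config$pairing))
    pairing <- stage("inputs", read_pairing(config$pairing))

  if ("repertoire" %in% config$stages)
    report$repertoire <- stage("repertoire",
                               repertoire_stage(config, sheet, log))

  if ("expression" %in% config$stages && !is.null(matrix) &&
      !is.null(sets)) {
    report$expression <- stage("expression", {
      scores <- gene_score_table(matrix, sets, sheet)
      strat <- NULL
      ra <- sheet$sample_id[sheet$disease == "RA" &
                              sheet$sample_id %in% colnames(matrix)]
      if (config$tcell_set %in% names(sets) && length(ra) >= 4L)
        strat <- tcell_stratify(matrix, sets[[config$tcell_set]], ra)
      log(sprintf("expression: scored %d RA samples on %d pathways",
                  nrow(scores), length(sets)))
      list(gene_scores = scores, stratification = strat)
    })
  }

  if ("icc" %in% config$stages && !is.null(matrix) && !is.null(pairing)) {
    report$icc <- stage("icc", {
      rep_icc <- compare_real_vs_random(
        matrix, pairing, n_random = config$n_random_pairings,
        seed = sub_seed(config$seed, "icc"))
      log(sprintf("icc: median real %.3f vs random %.3f (p = %.4g)",
                  rep_icc$median_real, rep_icc$median_random,
                  rep_icc$p_value))
      rep_icc
    })
  }

  if ("histology" %in% config$stages && !is.null(config$histology) &&
      !is.null(pairing)) {
    report$histology <- stage("histology", {
      hc <- histology_concordance(read_histology_scores(config$histology),
                                  pairing)
      log(sprintf("histology: %d markers", nrow(hc)))
      hc
    })
  }

  if ("correlations" %in% config$stages && !is.null(report$expression) &&
      !is.null(pairing)) {
    report$correlations <- stage("correlations", {
      scores <- report$expression$gene_scores
      res <- list()
      for (nm in setdiff(names(scores), "sample_id")) {
        s <- scores[match(pairing$small_sample_id, scores$sample_id), nm]
        l <- scores[match(pairing$large_sample_id, scores$sample_id), nm]
        if (sum(stats::complete.cases(s, l)) >= 3L)
          res[[paste0("small_vs_large_", nm)]] <-
            pair_score_correlation(s, l, "pearson")
      }
      sh <- report$repertoire$shared
      if (!is.null(sh) && config$tcell_set %in% names(scores)) {
        ts <- scores[[config$tcell_set]]
        ms <- (ts[match(pairing$small_sample_id, scores$sample_id)] +
                 ts[match(pairing$large_sample_id, scores$sample_id)]) / 2
        fr <- sh$fraction_shared[match(pairing$patient_id, sh$patient_id)]
        if (sum(stats::complete.cases(ms, fr)) >= 3L)
          res$tcell_score_vs_shared_fraction <-
            pair_score_correlation(ms, fr, "pearson")
      }
      log(sprintf("correlations: %d computed", length(res)))
      res
    })
  }

  report$provenance <- list(config_hash = config_hash(config),
                            seed = config$seed,
                            package = "synovetc",
                            version = as.character(
                              utils::packageVersion("synovetc")))
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Paired-joint analysis run report\n")
  cat("  sections:", paste(setdiff(names(x), "provenance"),
                           collapse = ", "), "\n")
  if (!is.null(x$repertoire$shared)) {
    fr <- x$repertoire$shared$fraction_shared
    cat(sprintf("  shared-ETC fraction: %s\n",
                paste(sprintf("%.0f%%", 100 * range(fr, na.rm = TRUE)),
                      collapse = " - ")))
  }
  if (!is.null(x$icc))
    cat(sprintf("  median ICC real %.3f vs random %.3f (p = %.4g)\n",
                x$icc$median_real, x$icc$median_random, x$icc$p_value))
  cat(sprintf("  provenance: config %s, seed %d\n",
              x$provenance$config_hash, x$provenance$seed))
  invisible(x)
}

# Serialisable view of a report (per-probe ICC vector and ETC tables go to
# TSV, not JSON).
report_json_body <- function(report) {
  body <- report
  if (!is.null(body$icc))
    body$icc <- body$icc[c("median_real", "median_random",
                           "median_random_pooled", "p_value", "n_random")]
  if (!is.null(body$repertoire))
    body$repertoire$etc_tables <- NULL
  if (!is.null(body$expression$stratification))
    body$expression$stratification <-
      as.list(body$expression$stratification)
  unclass(body)
}

#' Write a run report to disk
#'
#' Writes `report.json` plus TSV tables (ETC per sample, shared-ETC
#' summaries, gene scores, per-probe ICC, histology concordance). Every
#' table carries the config hash in a header comment line.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stamp <- sprintf("# synovetc config %s seed %d",
                   report$provenance$config_hash, report$provenance$seed)
  write_tsv <- function(df, name) {
    path <- file.path(dir, name)
    con <- file(path, "w")
    writeLines(stamp, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    written <<- c(written, path)
  }
  jpath <- file.path(dir, "report.json")
  jsonlite::write_json(report_json_body(report), jpath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  written <- c(written, jpath)
  if (!is.null(report$repertoire$etc_counts))
    write_tsv(report$repertoire$etc_counts, "etc_counts.tsv")
  if (!is.null(report$repertoire$shared))
    write_tsv(report$repertoire$shared, "shared_etc.tsv")
  if (length(report$repertoire$etc_tables)) {
    all_etc <- do.call(rbind, lapply(names(report$repertoire$etc_tables),
                                     function(s) {
      t <- report$repertoire$etc_tables[[s]]
      if (!nrow(t)) return(NULL)
      data.frame(sample_id = s, as.data.frame(t), stringsAsFactors = FALSE)
    }))
    if (!is.null(all_etc)) write_tsv(all_etc, "etc_tables.tsv")
  }
  if (!is.null(report$expression$gene_scores))
    write_tsv(report$expression$gene_scores, "gene_scores.tsv")
  if (!is.null(report$expression$stratification))
    write_tsv(data.frame(sample_id = names(report$expression$stratification),
                         label = unname(report$expression$stratification),
                         stringsAsFactors = FALSE),
              "stratification.tsv")
  if (!is.null(report$icc))
    write_tsv(data.frame(probe_id = names(report$icc$icc_real),
                         icc = unname(report$icc$icc_real),
                         stringsAsFactors = FALSE),
              "icc_probes.tsv")
  if (!is.null(report$histology))
    write_tsv(report$histology, "histology_concordance.tsv")
  invisible(written)
}
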