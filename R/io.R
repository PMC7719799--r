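# Readers and writers for the pipeline's plain-text formats: AIRR-style
# per-read and clonotype TSVs, GMT gene sets, expression matrix TSV, and
# CSV metadata tables.

read_table_checked <- function(path, sep, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("schema error in ", what, " ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  df
}

parse_productive <- function(x) {
  out <- rep(NA, length(x))
  out[tolower(as.character(x)) %in% c("t", "true", "1", "yes")] <- TRUE
  out[tolower(as.character(x)) %in% c("f", "false", "0", "no")] <- FALSE
  out
}

#' Read AIRR-style per-read TSV
#'
#' Expects one row per sequencing read with columns `sample_id`, `umi`,
#' `v_call`, `j_call`, `junction`, `productive` (an optional `read_id` is
#' kept). Rows with malformed nucleotide strings (characters outside ACGT
#' in `umi` or `junction`) or an unparseable `productive` flag are rejected
#' with a warning listing their line numbers.
#'
#' @param path TSV file path.
#' @return data.frame of annotated reads.
#' @export
read_airr_reads <- function(path) {
  req <- c("sample_id", "umi", "v_call", "j_call", "junction", "productive")
  df <- read_table_checked(path, "\t", req, "AIRR reads")
  if (!nrow(df)) stop("empty input: no reads in ", path)
  df$productive <- parse_productive(df$productive)
  bad <- !is_nt_string(df$umi) | !is_nt_string(df$junction) |
    is.na(df$productive) | is.na(df$sample_id) | !nzchar(df$v_call) |
    !nzchar(df$j_call)
  if (any(bad)) {
    # +1 for the header line
    warning(sprintf("rejected %d malformed read row(s) at line(s) %s",
                    sum(bad),
                    paste(utils::head(which(bad) + 1L, 20), collapse = ", ")))
    df <- df[!bad, , drop = FALSE]
  }
  if (!nrow(df)) stop("empty input: all rows of ", path, " were malformed")
  if (!"read_id" %in% names(df))
    df$read_id <- sprintf("read_%07d", seq_len(nrow(df)))
  rownames(df) <- NULL
  df[, c("read_id", req)]
}

#' Write AIRR-style per-read TSV
#' @param reads data.frame of annotated reads.
#' @param path output TSV path.
#' @export
write_airr_reads <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read pre-collapsed AIRR-style clonotype TSV
#'
#' Expects one row per clonotype and sample with columns `sample_id`,
#' `v_call`, `j_call`, `junction`, `productive`, `duplicate_count` (UMI
#' molecule count).
#'
#' @param path TSV file path.
#' @return data.frame of clonotype rows.
#' @export
read_airr_clonotypes <- function(path) {
  req <- c("sample_id", "v_call", "j_call", "junction", "productive",
           "duplicate_count")
  df <- read_table_checked(path, "\t", req, "AIRR clonotypes")
  if (!nrow(df)) stop("empty input: no clonotypes in ", path)
  df$productive <- parse_productive(df$productive)
  df$duplicate_count <- as.integer(df$duplicate_count)
  bad <- !is_nt_string(df$junction) | is.na(df$productive) |
    is.na(df$duplicate_count) | df$duplicate_count < 1L
  if (any(bad)) {
    warning(sprintf("rejected %d malformed clonotype row(s) at line(s) %s",
                    sum(bad),
                    paste(utils::head(which(bad) + 1L, 20), collapse = ", ")))
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df[, req]
}

#' Write repertoires as a clonotype-level AIRR-style TSV
#' @param reps list of `repertoire` objects.
#' @param path output TSV path.
#' @export
write_airr_clonotypes <- function(reps, path) {
  rows <- do.call(rbind, lapply(reps, function(r) {
    data.frame(sample_id = r$sample_id, r$clonotypes[
      c("v_call", "j_call", "junction", "productive")],
      duplicate_count = r$clonotypes$count, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per non-empty line: name, description, then member ids,
#' tab-separated. Duplicate members within a line are removed with a
#' warning.
#'
#' @param path GMT file path.
#' @return named list of character vectors (set name -> member ids); an
#'   empty file yields an empty list.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("GMT format error at line ", i,
           ": expected at least 3 tab-separated fields")
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("GMT line %d ('%s'): %d duplicated member id(s) removed",
                      i, fields[1], sum(duplicated(members))))
      members <- unique(members)
    }
    sets[[fields[1]]] <- members
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of member-id vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a probes x samples expression matrix TSV
#'
#' First column = probe id, header = sample ids.
#' @param path TSV file path.
#' @return numeric matrix with probe rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("expression matrix file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, quote = "",
                          comment.char = "")
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("expression matrix contains non-finite values")
  check_matrix(m)
}

#' Write a probes x samples expression matrix TSV
#' @param matrix numeric matrix with probe rownames and sample colnames.
#' @param path output path.
#' @export
write_expression_matrix <- function(matrix, path) {
  df <- data.frame(probe_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the sample sheet CSV
#'
#' Columns `sample_id`, `patient_id`, `disease` (RA/OA), `joint`
#' (small/large/none) and optionally `tissue` (blood/synovium; defaults to
#' synovium).
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- read_table_checked(path, ",",
                           c("sample_id", "patient_id", "disease", "joint"),
                           "sample sheet")
  if (!"tissue" %in% names(df)) df$tissue <- "synovium"
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in sample sheet")
  if (!all(df$disease %in% c("RA", "OA")))
    stop("disease must be RA or OA")
  if (!all(df$joint %in% c("small", "large", "none")))
    stop("joint must be small, large or none")
  df
}

#' Read the histology scores CSV
#'
#' Long format with columns `sample_id`, `marker`, `score` (ordinal 0-3).
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_histology_scores <- function(path) {
  df <- read_table_checked(path, ",", c("sample_id", "marker", "score"),
                           "histology scores")
  df$score <- as.numeric(df$score)
  if (any(!is.finite(df$score) | df$score < 0 | df$score > 3))
    stop("histology scores must lie in [0, 3]")
  df
}

#' Read the patient pairing CSV
#'
#' Columns `patient_id`, `small_sample_id`, `large_sample_id`; sample ids
#' must be distinct and each used once.
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_pairing <- function(path) {
  df <- read_table_checked(path, ",",
                           c("patient_id", "small_sample_id",
                             "large_sample_id"),
                           "pairing")
  ids <- c(df$small_sample_id, df$large_sample_id)
  if (anyDuplicated(ids)) stop("pairing sample ids must be distinct")
  df
}

#' Write a simulated bundle to plain-text files
#'
#' Writes the repertoires (per-read TSV when reads were emitted, otherwise
#' clonotype-level TSV), expression matrix, sample sheet, gene sets,
#' histology scores, pairing and the planted truth.
#'
#' @param bundle a `sim_bundle` from [simulate_bundle()].
#' @param dir output directory (created if needed).
#' @return named list of written file paths, suitable for
#'   [pipeline_config()].
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  all_reps <- unlist(bundle$repertoires, recursive = FALSE)
  if (!is.null(bundle$reads)) {
    paths$reads <- file.path(dir, "reads.tsv")
    write_airr_reads(bundle$reads, paths$reads)
  } else {
    paths$clonotypes <- file.path(dir, "clonotypes.tsv")
    write_airr_clonotypes(all_reps, paths$clonotypes)
  }
  paths$expression <- file.path(dir, "expression.tsv")
  write_expression_matrix(bundle$expression$matrix, paths$expression)
  paths$sample_sheet <- file.path(dir, "sample_sheet.csv")
  utils::write.csv(bundle$sample_sheet, paths$sample_sheet,
                   row.names = FALSE, quote = FALSE)
  paths$gene_sets <- file.path(dir, "gene_sets.gmt")
  write_gmt(bundle$expression$gene_sets, paths$gene_sets)
  paths$histology <- file.path(dir, "histology.csv")
  utils::write.csv(bundle$histology[, c("sample_id", "marker", "score")],
                   paths$histology, row.names = FALSE, quote = FALSE)
  paths$pairing <- file.path(dir, "pairing.csv")
  utils::write.csv(bundle$pairing, paths$pairing, row.names = FALSE,
                   quote = FALSE)
  paths$truth <- file.path(dir, "truth.json")
  truth <- lapply(bundle$truths, function(t)
    list(patient_id = t$patient_id, infiltration = t$infiltration,
         theta = t$theta, planted = t$planted))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  paths
}
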