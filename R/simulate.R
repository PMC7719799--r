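# Synthetic-data generator: paired-joint TCRB repertoires with planted
# clonal expansions, UMI-tagged reads, expression matrices with planted
# pathway effects and patient random intercepts, and ordinal histology
# scores. Every output is reproducible from the config seed via named
# substreams, and ground truth is recorded for recovery testing.

TRBV_POOL <- sprintf("TRBV%d", 1:30)
TRBJ_POOL <- c(sprintf("TRBJ1-%d", 1:6), sprintf("TRBJ2-%d", 1:7))
JUNCTION_LEN <- 36L
HISTOLOGY_MARKERS <- c("hyperplasia", "infiltrates", "vascularity",
                       "fibrinoid_necrosis", "CD3", "CD20", "CD68")

patient_id_of <- function(i) sprintf("P%02d", i)

# Draw a set of n distinct abstract clonotype keys.
draw_clonotypes <- function(n) {
  if (n == 0L)
    return(data.frame(v_call = character(0), j_call = character(0),
                      junction = character(0), stringsAsFactors = FALSE))
  repeat {
    df <- data.frame(v_call = sample(TRBV_POOL, n, replace = TRUE),
                     j_call = sample(TRBJ_POOL, n, replace = TRUE),
                     junction = random_nt(n, JUNCTION_LEN),
                     stringsAsFactors = FALSE)
    if (!anyDuplicated(clone_id(df$v_call, df$j_call, df$junction))) return(df)
  }
}

clone_size_weights <- function(law, n) {
  switch(law$family,
         lognormal = stats::rlnorm(n, law$mu, law$sigma),
         power_law = seq_len(n)^(-law$alpha),
         stop("unknown clone size law"))
}

# Fixed per-patient world: background clone pool with frequencies, planted
# expansions with systemic/private flags, latent infiltration level.
patient_world <- function(config, patient_index) {
  with_seed(sub_seed(config$seed, "patient", patient_index), {
    bg <- draw_clonotypes(config$n_background_clones)
    w <- clone_size_weights(config$clone_size_law, config$n_background_clones)
    p_bg <- w / sum(w)
    u <- stats::runif(1)
    link <- config$tcell_infiltration_link
    theta_p <- if (link == 0) config$sharing_theta else
      min(max(config$sharing_theta + link * (u - 0.5), 0), 1)
    n_pl <- config$n_planted_per_joint
    planted <- draw_clonotypes(n_pl)
    systemic <- stats::runif(n_pl) < theta_p
    side <- ifelse(systemic, "both",
                   ifelse(stats::runif(n_pl) < 0.5, "small", "large"))
    planted$flag <- ifelse(side == "both", "systemic",
                           paste0("private-", side))
    planted$tissue_freq <- rep(config$planted_tissue_freq, n_pl)
    list(patient_id = patient_id_of(patient_index),
         background = bg, p_background = p_bg,
         planted = planted, planted_side = side,
         infiltration = u, theta = theta_p)
  })
}

multinomial_repertoire <- function(clones, probs, n_molecules, seed,
                                   sample_id, patient_id, tissue, joint) {
  counts <- with_seed(seed,
                      as.integer(stats::rmultinom(1, n_molecules, probs)))
  tab <- data.frame(v_call = clones$v_call, j_call = clones$j_call,
                    junction = clones$junction, productive = TRUE,
                    count = counts, stringsAsFactors = FALSE)
  repertoire(tab, sample_id, patient_id, tissue, joint)
}

#' Simulate a patient's blood TCRB repertoire
#'
#' Draws `molecules_per_sample` UMI molecules multinomially from the
#' patient's heavy-tailed background clone-size distribution. Planted
#' synovial expansions are absent from blood, mimicking tissue-expanded
#' clones below the blood detection floor.
#'
#' @param config a [simulation_config()].
#' @param patient patient index (1-based).
#' @return a blood `repertoire`.
#' @export
simulate_blood_repertoire <- function(config, patient) {
  validate_sim_config(config)
  world <- patient_world(config, patient)
  multinomial_repertoire(world$background, world$p_background,
                         config$molecules_per_sample,
                         sub_seed(config$seed, "blood", patient),
                         paste0(world$patient_id, "_B"), world$patient_id,
                         "blood", "none")
}

#' Simulate one patient: blood plus paired synovial joints with ground truth
#'
#' Both joints share the patient's blood background clone pool at blood
#' frequencies. Each planted expansion is raised to `planted_tissue_freq`
#' in both joints (systemic) with the patient's sharing probability, else in
#' exactly one joint (private); background frequencies are rescaled so the
#' joint frequency vector sums to one.
#'
#' @param config a [simulation_config()].
#' @param patient patient index (1-based).
#' @return list with elements `blood`, `joint_small`, `joint_large`
#'   (repertoires) and `truth` (class `planted_truth`: the planted clonotype
#'   table with systemic/private flags and tissue frequencies, plus the
#'   patient's latent infiltration level and realised sharing probability).
#' @export
simulate_patient <- function(config, patient) {
  validate_sim_config(config)
  world <- patient_world(config, patient)
  pid <- world$patient_id
  blood <- multinomial_repertoire(world$background, world$p_background,
                                  config$molecules_per_sample,
                                  sub_seed(config$seed, "blood", patient),
                                  paste0(pid, "_B"), pid, "blood", "none")
  joint_rep <- function(joint_name, suffix) {
    in_joint <- world$planted_side %in% c("both", joint_name)
    planted <- world$planted[in_joint, , drop = FALSE]
    f_planted <- sum(planted$tissue_freq)
    if (f_planted >= 1)
      stop("planted frequencies sum to >= 1 in the ", joint_name, " joint")
    clones <- rbind(world$background[, c("v_call", "j_call", "junction")],
                    planted[, c("v_call", "j_call", "junction")])
    probs <- c(world$p_background * (1 - f_planted), planted$tissue_freq)
    multinomial_repertoire(clones, probs, config$molecules_per_sample,
                           sub_seed(config$seed,
                                    paste0("joint_", joint_name), patient),
                           paste0(pid, suffix), pid, "synovium", joint_name)
  }
  truth <- structure(list(patient_id = pid,
                          planted = world$planted,
                          infiltration = world$infiltration,
                          theta = world$theta),
                     class = "planted_truth")
  list(blood = blood,
       joint_small = joint_rep("small", "_S"),
       joint_large = joint_rep("large", "_L"),
       truth = truth)
}

#' Emit UMI-tagged annotated reads from a repertoire
#'
#' Each molecule receives an independent random UMI of `umi_length` bases
#' and a shifted-Poisson (>= 1) number of reads with mean
#' `reads_per_molecule_mean`. Each read independently suffers a single-base
#' junction miscall with probability `clonotype_miscall_rate`, creating a
#' near-neighbour clonotype key that the UMI consensus step must absorb.
#'
#' @param rep a `repertoire`.
#' @param config a [simulation_config()].
#' @param seed integer seed for this emission.
#' @return data.frame of annotated reads: `read_id`, `sample_id`, `umi`,
#'   `v_call`, `j_call`, `junction`, `productive`.
#' @export
emit_reads <- function(rep, config, seed = config$seed) {
  validate_sim_config(config)
  stopifnot(inherits(rep, "repertoire"))
  tab <- rep$clonotypes
  with_seed(seed, {
    midx <- rep.int(seq_len(nrow(tab)), tab$count)
    nmol <- length(midx)
    umi <- random_nt(nmol, config$umi_length)
    nreads <- 1L + stats::rpois(nmol, config$reads_per_molecule_mean - 1)
    ridx <- rep.int(seq_len(nmol), nreads)
    junction <- tab$junction[midx][ridx]
    if (config$clonotype_miscall_rate > 0) {
      mis <- stats::runif(length(ridx)) < config$clonotype_miscall_rate
      junction[mis] <- corrupt_nt(junction[mis])
    }
    data.frame(read_id = sprintf("%s_r%07d", rep$sample_id,
                                 seq_along(ridx)),
               sample_id = rep$sample_id,
               umi = umi[ridx],
               v_call = tab$v_call[midx][ridx],
               j_call = tab$j_call[midx][ridx],
               junction = junction,
               productive = tab$productive[midx][ridx],
               stringsAsFactors = FALSE)
  })
}

#' Simulate a probes x samples log2 expression matrix
#'
#' Generative model per probe and sample: probe baseline (Normal(7, 1))
#' plus, for RA samples, the planted pathway log2 effect and a per-patient
#' random intercept Normal(0, sigma_patient^2) shared by both joints, plus
#' residual Normal(0, sigma_resid^2). OA reference samples receive baseline
#' plus residual only. The T-cell pathway effect is scaled per patient by
#' `1 + tcell_infiltration_link * (u - 1/2)` where u is the patient's
#' latent infiltration level recorded in the repertoire truth.
#'
#' @param config a [simulation_config()].
#' @param truths list of `planted_truth` objects (one per patient), as
#'   returned by [simulate_patient()]; supplies the infiltration levels.
#' @param n_oa number of OA reference samples (>= 2).
#' @return list of class `expression_sim`: `matrix` (probes x samples, log2),
#'   `sample_sheet` (sample_id, patient_id, disease, joint, tissue),
#'   `gene_sets` (pathway name -> probe ids), and `truth` (probe pathway
#'   membership, planted effects, patient intercepts, infiltration levels).
#' @export
simulate_expression <- function(config, truths, n_oa = 4L) {
  validate_sim_config(config)
  if (n_oa < 2L) stop("at least 2 OA reference samples are required")
  npat <- length(truths)
  if (npat < 1L) stop("at least one patient truth is required")
  with_seed(sub_seed(config$seed, "expression"), {
    np <- config$n_probes
    probes <- sprintf("probe_%05d", seq_len(np))
    membership <- rep(NA_character_, np)
    pos <- 1L
    for (k in seq_along(config$pathway_sizes)) {
      sz <- as.integer(config$pathway_sizes[k])
      membership[pos:(pos + sz - 1L)] <- names(config$pathway_sizes)[k]
      pos <- pos + sz
    }
    gene_sets <- lapply(seq_along(config$pathway_sizes), function(k)
      probes[which(membership == names(config$pathway_sizes)[k])])
    names(gene_sets) <- names(config$pathway_sizes)
    baseline <- stats::rnorm(np, 7, 1)
    effect <- rep(0, np)
    in_pw <- !is.na(membership)
    effect[in_pw] <- config$delta_pathway[membership[in_pw]]
    tcell <- if (length(config$pathway_sizes)) names(config$pathway_sizes)[1]
             else NA_character_
    intercept <- stats::rnorm(npat, 0, config$sigma_patient)
    u <- vapply(truths, function(t) t$infiltration, numeric(1))
    pids <- vapply(truths, function(t) t$patient_id, character(1))
    ra_ids <- as.vector(rbind(paste0(pids, "_S"), paste0(pids, "_L")))
    oa_ids <- sprintf("OA%02d", seq_len(n_oa))
    sheet <- data.frame(
      sample_id = c(ra_ids, oa_ids),
      patient_id = c(rep(pids, each = 2L), oa_ids),
      disease = c(rep("RA", length(ra_ids)), rep("OA", n_oa)),
      joint = c(rep(c("small", "large"), npat), rep("none", n_oa)),
      tissue = "synovium", stringsAsFactors = FALSE)
    vals <- matrix(NA_real_, np, nrow(sheet),
                   dimnames = list(probes, sheet$sample_id))
    link <- config$tcell_infiltration_link
    for (j in seq_len(nrow(sheet))) {
      col <- baseline + stats::rnorm(np, 0, config$sigma_resid)
      if (sheet$disease[j] == "RA") {
        p <- match(sheet$patient_id[j], pids)
        eff <- effect
        if (!is.na(tcell) && link != 0) {
          sel <- which(membership == tcell)
          eff[sel] <- eff[sel] * (1 + link * (u[p] - 0.5))
        }
        col <- col + eff + intercept[p]
      }
      vals[, j] <- col
    }
    structure(list(matrix = vals, sample_sheet = sheet,
                   gene_sets = gene_sets,
                   truth = list(probe_pathway = membership,
                                probe_effect = effect,
                                patient_intercept = setNames(intercept, pids),
                                infiltration = setNames(u, pids))),
              class = "expression_sim")
  })
}

#' Simulate paired ordinal histology scores
#'
#' For each patient and marker, a latent bivariate standard normal with
#' correlation `histology_pair_rho` is discretised at the standard-normal
#' quartiles into ordinal scores 0-3 for the small- and large-joint sample,
#' mimicking semiquantitative histology/immunohistochemistry grading.
#'
#' @param config a [simulation_config()].
#' @return data.frame with columns `sample_id`, `patient_id`, `joint`,
#'   `marker`, `score` (integer in 0..3); markers are synovial hyperplasia,
#'   infiltrates, vascularity, fibrinoid necrosis, CD3, CD20, CD68.
#' @export
simulate_histology <- function(config) {
  validate_sim_config(config)
  with_seed(sub_seed(config$seed, "histology"), {
    cuts <- stats::qnorm(c(0.25, 0.5, 0.75))
    npat <- config$n_patients
    pids <- patient_id_of(seq_len(npat))
    rho <- config$histology_pair_rho
    out <- lapply(HISTOLOGY_MARKERS, function(mk) {
      z1 <- stats::rnorm(npat)
      z2 <- rho * z1 + sqrt(max(1 - rho^2, 0)) * stats::rnorm(npat)
      data.frame(sample_id = c(paste0(pids, "_S"), paste0(pids, "_L")),
                 patient_id = rep(pids, 2L),
                 joint = rep(c("small", "large"), each = npat),
                 marker = mk,
                 score = c(findInterval(z1, cuts), findInterval(z2, cuts)),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a complete paired-joint study bundle
#'
#' Runs the repertoire, expression and histology generators under one config
#' and returns everything the pipeline consumes, together with the planted
#' ground truth.
#'
#' @param config a [simulation_config()].
#' @param n_oa number of OA reference expression samples.
#' @param emit_reads if `TRUE`, additionally emit per-read UMI-tagged tables
#'   for every sample (exercises the UMI-collapse path); default `FALSE`
#'   returns molecule-level repertoires only.
#' @return list of class `sim_bundle`: `repertoires` (per patient: blood,
#'   joint_small, joint_large), `truths`, `expression` (an `expression_sim`),
#'   `histology`, `pairing`, `sample_sheet` (repertoire and expression
#'   samples), optionally `reads`, and the `config`.
#' @export
simulate_bundle <- function(config, n_oa = 4L, emit_reads = FALSE) {
  validate_sim_config(config)
  sims <- lapply(seq_len(config$n_patients),
                 function(i) simulate_patient(config, i))
  truths <- lapply(sims, `[[`, "truth")
  pids <- vapply(truths, `[[`, character(1), "patient_id")
  expr <- simulate_expression(config, truths, n_oa)
  hist <- simulate_histology(config)
  pairing <- data.frame(patient_id = pids,
                        small_sample_id = paste0(pids, "_S"),
                        large_sample_id = paste0(pids, "_L"),
                        stringsAsFactors = FALSE)
  blood_sheet <- data.frame(sample_id = paste0(pids, "_B"),
                            patient_id = pids, disease = "RA",
                            joint = "none", tissue = "blood",
                            stringsAsFactors = FALSE)
  sheet <- rbind(expr$sample_sheet, blood_sheet)
  reps <- lapply(sims, function(s) s[c("blood", "joint_small", "joint_large")])
  names(reps) <- pids
  bundle <- list(repertoires = reps, truths = truths, expression = expr,
                 histology = hist, pairing = pairing, sample_sheet = sheet,
                 config = config)
  if (emit_reads) {
    all_reps <- unlist(reps, recursive = FALSE)
    bundle$reads <- do.call(rbind, lapply(seq_along(all_reps), function(i)
      emit_reads(all_reps[[i]], config,
                 sub_seed(config$seed, "reads", i))))
    rownames(bundle$reads) <- NULL
  }
  structure(bundle, class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf(
    "Simulated paired-joint bundle: %d patients, %d expression samples, %s\n",
    length(x$repertoires), ncol(x$expression$matrix),
    if (is.null(x$reads)) "molecule-level repertoires"
    else sprintf("%d emitted reads", nrow(x$reads))))
  invisible(x)
}
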