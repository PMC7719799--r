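#' Simulation configuration
#'
#' Bundles every tunable of the synthetic paired-joint study: clone-size law
#' of the blood repertoire, planted clonal expansions and their sharing
#' between joints, UMI/read emission noise, and the expression / histology
#' generative model. Defaults emulate the study design the pipeline targets:
#' 10 RA patients each contributing one blood sample and two synovial
#' biopsies (one small, one large joint), with a handful of strongly
#' tissue-expanded clonotypes per joint and a heavy-tailed blood background.
#'
#' @param n_patients number of simulated RA patients.
#' @param n_background_clones number of blood background clonotypes per
#'   patient.
#' @param clone_size_law list describing the clone-size distribution:
#'   `list(family = "lognormal", mu, sigma)` or
#'   `list(family = "power_law", alpha)` (weights proportional to
#'   rank^-alpha).
#' @param n_planted_per_joint target number of planted clonal expansions per
#'   joint. Each expansion is systemic (raised in both joints) with
#'   probability `sharing_theta`, otherwise private to one joint chosen at
#'   random.
#' @param planted_tissue_freq synovial frequency each planted clone is
#'   raised to; fraction in (0, 1).
#' @param sharing_theta probability a planted expansion is systemic, in
#'   [0, 1]. When `tcell_infiltration_link != 0` the per-patient probability
#'   is shifted by the patient's latent T-cell infiltration level.
#' @param molecules_per_sample UMI molecules per sample; blood needs at
#'   least 20,000 so the fixed-size blood subsample is valid.
#' @param reads_per_molecule_mean mean of the shifted-Poisson (>= 1) read
#'   count per cDNA molecule.
#' @param clonotype_miscall_rate per-read probability of a single-base
#'   junction miscall, in [0, 1).
#' @param umi_length length of the random UMI barcode (12 keeps collisions
#'   negligible at these depths).
#' @param n_probes number of expression probes.
#' @param pathway_sizes named integer vector of pathway sizes (probes per
#'   pathway, assigned to disjoint probe blocks). The first pathway is
#'   treated as the T-cell / TCR-signaling pathway.
#' @param delta_pathway named numeric vector of planted log2 effects in RA
#'   synovium, aligned with `pathway_sizes`.
#' @param sigma_patient SD of the per-patient random intercept (log2 units);
#'   the same intercept applies to both joints of a patient.
#' @param sigma_resid residual SD per probe and sample (log2 units).
#' @param tcell_infiltration_link slope tying a patient's latent
#'   infiltration level u ~ Uniform(0,1) to both the sharing probability
#'   (`theta_p = theta + link * (u - 1/2)`, clamped to [0, 1]) and the
#'   T-cell pathway effect (scaled by `1 + link * (u - 1/2)`).
#' @param histology_pair_rho latent correlation between small- and
#'   large-joint histology scores, in [-1, 1].
#' @param seed master seed; all substreams derive from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(n_patients = 2, n_background_clones = 100,
#'                          molecules_per_sample = 20000, seed = 7)
#' rep <- simulate_blood_repertoire(cfg, 1)
#' rep$total_molecules
simulation_config <- function(n_patients = 10L,
                              n_background_clones = 5000L,
                              clone_size_law = list(family = "lognormal",
                                                    mu = 0, sigma = 2),
                              n_planted_per_joint = 5L,
                              planted_tissue_freq = 0.01,
                              sharing_theta = 0.6,
                              molecules_per_sample = 20000L,
                              reads_per_molecule_mean = 3,
                              clonotype_miscall_rate = 0.02,
                              umi_length = 12L,
                              n_probes = 2000L,
                              pathway_sizes = c(TCR_SIGNALING = 50L,
                                                RESPONSE_TO_TNF = 50L,
                                                T_CELL_COSTIMULATION = 30L),
                              delta_pathway = c(TCR_SIGNALING = 2,
                                                RESPONSE_TO_TNF = 1.5,
                                                T_CELL_COSTIMULATION = 1),
                              sigma_patient = 1,
                              sigma_resid = 0.5,
                              tcell_infiltration_link = 1,
                              histology_pair_rho = 0.7,
                              seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_background_clones = as.integer(n_background_clones),
              clone_size_law = clone_size_law,
              n_planted_per_joint = as.integer(n_planted_per_joint),
              planted_tissue_freq = planted_tissue_freq,
              sharing_theta = sharing_theta,
              molecules_per_sample = as.integer(molecules_per_sample),
              reads_per_molecule_mean = reads_per_molecule_mean,
              clonotype_miscall_rate = clonotype_miscall_rate,
              umi_length = as.integer(umi_length),
              n_probes = as.integer(n_probes),
              pathway_sizes = pathway_sizes,
              delta_pathway = delta_pathway,
              sigma_patient = sigma_patient,
              sigma_resid = sigma_resid,
              tcell_infiltration_link = tcell_infiltration_link,
              histology_pair_rho = histology_pair_rho,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid simulation configuration: ", msg,
                                 call. = FALSE)
  if (cfg$n_patients < 1L) stop_cfg("n_patients must be positive")
  if (cfg$n_background_clones < 1L)
    stop_cfg("n_background_clones must be positive")
  law <- cfg$clone_size_law
  if (!is.list(law) || is.null(law$family))
    stop_cfg("clone_size_law must name a family")
  if (law$family == "lognormal") {
    if (is.null(law$mu) || is.null(law$sigma) || law$sigma <= 0)
      stop_cfg("lognormal law needs mu and sigma > 0")
  } else if (law$family == "power_law") {
    if (is.null(law$alpha) || law$alpha <= 0)
      stop_cfg("power_law law needs alpha > 0")
  } else stop_cfg(sprintf("unknown clone_size_law family '%s'", law$family))
  if (cfg$n_planted_per_joint < 0L)
    stop_cfg("n_planted_per_joint must be non-negative")
  if (cfg$planted_tissue_freq <= 0 || cfg$planted_tissue_freq >= 1)
    stop_cfg("planted_tissue_freq must lie in (0, 1)")
  if (cfg$n_planted_per_joint * cfg$planted_tissue_freq >= 1)
    stop_cfg("planted frequencies sum to >= 1")
  if (cfg$sharing_theta < 0 || cfg$sharing_theta > 1)
    stop_cfg("sharing_theta must lie in [0, 1]")
  if (cfg$molecules_per_sample < 20000L)
    stop_cfg("molecules_per_sample must be >= 20,000 so the blood subsample is valid")
  if (cfg$reads_per_molecule_mean < 1)
    stop_cfg("reads_per_molecule_mean must be >= 1")
  if (cfg$clonotype_miscall_rate < 0 || cfg$clonotype_miscall_rate >= 1)
    stop_cfg("clonotype_miscall_rate must lie in [0, 1)")
  if (cfg$umi_length < 1L) stop_cfg("umi_length must be positive")
  if (cfg$n_probes < 1L) stop_cfg("n_probes must be positive")
  if (length(cfg$pathway_sizes)) {
    if (is.null(names(cfg$pathway_sizes)) || any(!nzchar(names(cfg$pathway_sizes))))
      stop_cfg("pathway_sizes must be named")
    if (any(cfg$pathway_sizes < 1L)) stop_cfg("pathway sizes must be positive")
    if (sum(cfg$pathway_sizes) > cfg$n_probes)
      stop_cfg("pathway sizes exceed n_probes")
    if (!identical(sort(names(cfg$pathway_sizes)), sort(names(cfg$delta_pathway))))
      stop_cfg("delta_pathway names must match pathway_sizes")
  }
  if (cfg$sigma_patient < 0) stop_cfg("sigma_patient must be non-negative")
  if (cfg$sigma_resid <= 0) stop_cfg("sigma_resid must be positive")
  if (abs(cfg$histology_pair_rho) > 1)
    stop_cfg("histology_pair_rho must lie in [-1, 1]")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Paired-joint repertoire/expression simulation configuration\n")
  cat(sprintf("  patients: %d, background clones: %d, molecules/sample: %d\n",
              x$n_patients, x$n_background_clones, x$molecules_per_sample))
  law <- x$clone_size_law
  cat(sprintf("  clone-size law: %s(%s)\n", law$family,
              paste(sprintf("%s=%g", setdiff(names(law), "family"),
                            unlist(law[setdiff(names(law), "family")])),
                    collapse = ", ")))
  cat(sprintf("  planted/joint: %d at freq %g, sharing theta: %g (link %g)\n",
              x$n_planted_per_joint, x$planted_tissue_freq, x$sharing_theta,
              x$tcell_infiltration_link))
  cat(sprintf("  probes: %d (%s), sigma_patient %g, sigma_resid %g\n",
              x$n_probes,
              paste(sprintf("%s=%d", names(x$pathway_sizes),
                            as.integer(x$pathway_sizes)), collapse = ", "),
              x$sigma_patient, x$sigma_resid))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
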