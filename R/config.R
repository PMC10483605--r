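#' Calling and classification thresholds
#'
#' Bundles every tunable threshold used along the screening pipeline, from the
#' consensus-read calling filters to the MRD decision rules. Defaults are the
#' values used throughout: UMI-consensus calling requires depth >= 100, alt
#' support by at least one duplex (double-strand) consensus read or >= 3
#' single-strand consensus reads, and VAF above -ln(alpha)/depth with
#' alpha = 0.01; pre-operative plasma additionally requires VAF >= 0.5% and
#' tumor tissue VAF > 10%. Mutations with MVFC below `mvfc_threshold` (0.2)
#' are classified as tumor-derived, and MRD is positive when any tumor-class
#' mutation has post-operative VAF strictly above `mrd_min_post_vaf` (0.1%).
#' Serum positivity uses AFP > 20 ng/mL and DCP > 40 mAU/mL.
#'
#' Inequality conventions: the depth cutoff and the pre-plasma VAF floor are
#' inclusive; the formula threshold, the tumor-tissue 10% cutoff, the MVFC
#' class boundary, the MRD VAF floor and the serum cutoffs are strict.
#'
#' @param min_depth Minimum consensus read depth for a callable site (reads).
#' @param min_single_strand_reads Minimum alt-supporting single-strand
#'   consensus reads when no duplex read supports the variant.
#' @param alpha Detection probability bound; the per-site VAF must exceed
#'   \code{-log(alpha) / depth}.
#' @param pre_plasma_min_vaf VAF floor for pre-operative plasma calls
#'   (fraction; inclusive).
#' @param tumor_tissue_min_vaf VAF cutoff for tumor-tissue calls (fraction;
#'   strict).
#' @param mvfc_threshold MVFC below which a mutation is classified as
#'   tumor-derived (strict).
#' @param mrd_min_post_vaf Post-operative VAF a tumor-class mutation must
#'   exceed (strictly) to count toward an MRD-positive call.
#' @param afp_cutoff AFP positivity cutoff, ng/mL (strict).
#' @param dcp_cutoff DCP positivity cutoff, mAU/mL (strict).
#' @param early_recurrence_days Horizon defining early recurrence, days.
#' @return An object of class `calling_config` (a named list).
#' @examples
#' cfg <- calling_config()
#' cfg$mvfc_threshold
#' @export
calling_config <- function(min_depth = 100L,
                           min_single_strand_reads = 3L,
                           alpha = 0.01,
                           pre_plasma_min_vaf = 0.005,
                           tumor_tissue_min_vaf = 0.10,
                           mvfc_threshold = 0.2,
                           mrd_min_post_vaf = 0.001,
                           afp_cutoff = 20,
                           dcp_cutoff = 40,
                           early_recurrence_days = 183L) {
  cfg <- list(
    min_depth = as.integer(min_depth),
    min_single_strand_reads = as.integer(min_single_strand_reads),
    alpha = alpha,
    pre_plasma_min_vaf = pre_plasma_min_vaf,
    tumor_tissue_min_vaf = tumor_tissue_min_vaf,
    mvfc_threshold = mvfc_threshold,
    mrd_min_post_vaf = mrd_min_post_vaf,
    afp_cutoff = afp_cutoff,
    dcp_cutoff = dcp_cutoff,
    early_recurrence_days = as.integer(early_recurrence_days)
  )
  num <- vapply(cfg, is.numeric, logical(1))
  if (!all(num)) stop("all calling_config fields must be numeric")
  if (any(vapply(cfg, function(x) length(x) != 1L || is.na(x), logical(1)))) {
    stop("all calling_config fields must be non-missing scalars")
  }
  if (cfg$min_depth < 1L) stop("min_depth must be >= 1")
  if (cfg$min_single_strand_reads < 1L) {
    stop("min_single_strand_reads must be >= 1")
  }
  if (cfg$alpha <= 0 || cfg$alpha > 1) stop("alpha must be in (0, 1]")
  if (cfg$mvfc_threshold <= 0 || cfg$mvfc_threshold >= 1) {
    stop("mvfc_threshold must be in (0, 1)")
  }
  for (f in c("pre_plasma_min_vaf", "tumor_tissue_min_vaf", "mrd_min_post_vaf",
              "afp_cutoff", "dcp_cutoff", "early_recurrence_days")) {
    if (cfg[[f]] <= 0) stop(f, " must be > 0")
  }
  class(cfg) <- "calling_config"
  cfg
}

#' @export
print.calling_config <- function(x, ...) {
  cat("Calling configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Synthetic cohort parameterization
#'
#' Full parameterization of the synthetic cfDNA cohort generator. The
#' generator emulates the data-generating assumptions behind MVFC screening:
#' tumor-derived plasma mutations whose expected VAF collapses after surgery
#' by `residual_ratio` (in patients with residual disease) or
#' `residual_ratio_negative` (in patients without), persistent non-tumor
#' plasma mutations whose VAF is unaffected by surgery, hematopoietic
#' (PBMC-shared) mutations with calling-level support in the PBMC sample,
#' binomial sequencing sampling at roughly 1500x consensus depth, and
#' recurrence times linked to residual-disease status through a Weibull
#' proportional-hazards model.
#'
#' @param seed Integer seed; identical configs produce bit-identical cohorts.
#' @param n_patients Number of patients.
#' @param depth_mean,pbmc_depth_mean,tumor_depth_mean Mean consensus depth for
#'   plasma, PBMC and tumor-tissue samples (negative-binomial, reads).
#' @param depth_dispersion Negative-binomial size parameter for depth.
#' @param n_tumor_mut_mean,n_nontumor_mut_mean,n_pbmc_mut_mean Poisson means
#'   of per-patient tumor-derived, non-tumor plasma, and PBMC-shared mutation
#'   counts.
#' @param tumor_vaf_range,nontumor_vaf_range Uniform pre-operative plasma VAF
#'   interval for tumor-derived and non-tumor mutations (fractions).
#' @param tumor_tissue_vaf_range Uniform VAF interval of tumor-derived
#'   mutations in tumor tissue.
#' @param pbmc_vaf_range Uniform VAF interval of PBMC-shared mutations in the
#'   PBMC sample (their plasma VAF is drawn from `nontumor_vaf_range`).
#' @param duplex_fraction Probability that an alt consensus read is duplex.
#' @param error_rate Per-site background alt fraction added to every expected
#'   VAF.
#' @param frac_mrd_positive Fraction of patients with residual disease.
#' @param residual_ratio Post-/pre-operative tumor-fraction ratio in
#'   residual-disease-positive patients.
#' @param residual_ratio_negative Same ratio in negative patients.
#' @param survival Named list: `shape`, `scale` (Weibull baseline, days),
#'   `hr_mrd` (hazard ratio for residual disease), `hr_afp` (hazard ratio for
#'   AFP positivity), `censor_min`, `censor_max` (uniform administrative
#'   censoring window, days).
#' @param afp_model,dcp_model Named lists of lognormal parameters
#'   (`meanlog_negative`, `sdlog_negative`, `meanlog_positive`,
#'   `sdlog_positive`) for the serum marker conditional on residual-disease
#'   truth. Units: ng/mL (AFP), mAU/mL (DCP).
#' @param include_pbmc,include_tumor_tissue Emit PBMC / tumor-tissue samples.
#' @param followup_days Optional data.frame with columns `day` and
#'   `multiplier` giving follow-up timepoints and the tumor-fraction
#'   multiplier at each (used by [simulate_followup_series()]).
#' @return An object of class `simulation_config`.
#' @examples
#' sim <- simulation_config(seed = 1, n_patients = 5)
#' cohort <- simulate_cohort(sim)
#' @export
simulation_config <- function(seed = 1L,
                              n_patients = 50L,
                              depth_mean = 1500,
                              depth_dispersion = 50,
                              pbmc_depth_mean = 850,
                              tumor_depth_mean = 1380,
                              n_tumor_mut_mean = 11.65,
                              n_nontumor_mut_mean = 79,
                              n_pbmc_mut_mean = 10,
                              tumor_vaf_range = c(0.005, 0.05),
                              nontumor_vaf_range = c(0.005, 0.05),
                              tumor_tissue_vaf_range = c(0.05, 0.60),
                              pbmc_vaf_range = c(0.01, 0.10),
                              duplex_fraction = 0.5,
                              error_rate = 1e-4,
                              frac_mrd_positive = 0.3,
                              residual_ratio = 0.02,
                              residual_ratio_negative = 0,
                              survival = list(shape = 0.9, scale = 2296,
                                              hr_mrd = 4, hr_afp = 2,
                                              censor_min = 90,
                                              censor_max = 1869),
                              afp_model = list(meanlog_negative = log(4),
                                               sdlog_negative = 0.85,
                                               meanlog_positive = log(30),
                                               sdlog_positive = 1.0),
                              dcp_model = list(meanlog_negative = log(15),
                                               sdlog_negative = 0.8,
                                               meanlog_positive = log(80),
                                               sdlog_positive = 1.0),
                              include_pbmc = TRUE,
                              include_tumor_tissue = TRUE,
                              followup_days = NULL) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  cfg$n_patients <- as.integer(n_patients)
  if (cfg$n_patients < 0L) stop("n_patients must be >= 0")
  for (f in c("depth_mean", "depth_dispersion", "pbmc_depth_mean",
              "tumor_depth_mean", "n_tumor_mut_mean", "n_nontumor_mut_mean")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) stop(f, " must be > 0")
  }
  if (cfg$n_pbmc_mut_mean < 0) stop("n_pbmc_mut_mean must be >= 0")
  .check_prob <- function(x, nm) {
    if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
      stop(nm, " must lie in [0, 1]")
    }
  }
  .check_prob(cfg$duplex_fraction, "duplex_fraction")
  .check_prob(cfg$error_rate, "error_rate")
  .check_prob(cfg$frac_mrd_positive, "frac_mrd_positive")
  if (cfg$residual_ratio < 0 || cfg$residual_ratio >= 1) {
    stop("residual_ratio must lie in [0, 1)")
  }
  if (cfg$residual_ratio_negative < 0 || cfg$residual_ratio_negative >= 1) {
    stop("residual_ratio_negative must lie in [0, 1)")
  }
  for (f in c("tumor_vaf_range", "nontumor_vaf_range",
              "tumor_tissue_vaf_range", "pbmc_vaf_range")) {
    r <- cfg[[f]]
    if (length(r) != 2L || r[1] > r[2] || r[1] < 0 || r[2] > 1) {
      stop(f, " must be an increasing interval within [0, 1]")
    }
  }
  sv <- cfg$survival
  need <- c("shape", "scale", "hr_mrd", "hr_afp", "censor_min", "censor_max")
  if (!all(need %in% names(sv))) {
    stop("survival must name: ", paste(need, collapse = ", "))
  }
  if (sv$shape <= 0 || sv$scale <= 0 || sv$hr_mrd <= 0 || sv$hr_afp <= 0) {
    stop("survival shape/scale/hazard ratios must be > 0")
  }
  if (sv$censor_min <= 0 || sv$censor_max < sv$censor_min) {
    stop("censoring window must satisfy 0 < censor_min <= censor_max")
  }
  for (m in c("afp_model", "dcp_model")) {
    need <- c("meanlog_negative", "sdlog_negative",
              "meanlog_positive", "sdlog_positive")
    if (!all(need %in% names(cfg[[m]]))) {
      stop(m, " must name: ", paste(need, collapse = ", "))
    }
  }
  if (!is.null(cfg$followup_days)) {
    fu <- cfg$followup_days
    if (!is.data.frame(fu) || !all(c("day", "multiplier") %in% names(fu))) {
      stop("followup_days must be a data.frame with columns day, multiplier")
    }
    if (any(fu$multiplier < 0)) stop("follow-up multipliers must be >= 0")
  }
  class(cfg) <- "simulation_config"
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("Simulation configuration: %d patients, seed %d\n",
              x$n_patients, x$seed))
  cat(sprintf("  plasma depth NB(mu = %g, size = %g); error rate %g\n",
              x$depth_mean, x$depth_dispersion, x$error_rate))
  cat(sprintf("  mutations/patient: %.2f tumor + %.2f non-tumor + %.2f PBMC-shared\n",
              x$n_tumor_mut_mean, x$n_nontumor_mut_mean, x$n_pbmc_mut_mean))
  cat(sprintf("  residual ratio %g (positive, %g%% of patients) / %g (negative)\n",
              x$residual_ratio, 100 * x$frac_mrd_positive,
              x$residual_ratio_negative))
  invisible(x)
}

#' Read a pipeline configuration file
#'
#' Reads a YAML configuration with optional top-level sections `calling`,
#' `simulation`, `input` (paths `pileup`, `manifest` for pre-existing tables),
#' and `evaluate` (e.g. `times` for the time-dependent AUC grid). Keys inside
#' `calling` and `simulation` mirror the arguments of [calling_config()] and
#' [simulation_config()]; unspecified keys keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `calling` (`calling_config`), `simulation`
#'   (`simulation_config` or `NULL`), `input`, and `evaluate`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  calling <- do.call(calling_config, as.list(raw$calling))
  simulation <- NULL
  if (!is.null(raw$simulation)) {
    sim <- as.list(raw$simulation)
    for (f in c("tumor_vaf_range", "nontumor_vaf_range",
                "tumor_tissue_vaf_range", "pbmc_vaf_range")) {
      if (!is.null(sim[[f]])) sim[[f]] <- as.numeric(unlist(sim[[f]]))
    }
    if (!is.null(sim$followup_days)) {
      sim$followup_days <- as.data.frame(
        lapply(sim$followup_days, unlist)
      )
    }
    simulation <- do.call(simulation_config, sim)
  }
  evaluate <- raw$evaluate
  if (is.null(evaluate$times)) evaluate$times <- c(183, 365, 730)
  evaluate$times <- as.numeric(unlist(evaluate$times))
  list(calling = calling, simulation = simulation,
       input = raw$input, evaluate = evaluate)
}
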