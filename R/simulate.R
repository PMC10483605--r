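#' Simulate consensus counts for one or more sites
#'
#' Draws the total alt-supporting consensus count binomially from the depth
#' and the true VAF, then splits it into duplex and single-strand reads
#' binomially with `duplex_fraction`. Vectorized over its arguments; uses the
#' current RNG state (call `set.seed()` upstream for reproducibility).
#'
#' @param true_vaf Expected alt fraction(s) in `[0, 1]`.
#' @param depth Consensus depth(s), >= 1.
#' @param duplex_fraction Probability an alt consensus read is duplex.
#' @return A data.frame with columns `depth`, `alt_duplex`, `alt_single`.
#' @examples
#' set.seed(1)
#' simulate_site(0.01, 1500, 0.5)
#' @export
simulate_site <- function(true_vaf, depth, duplex_fraction = 0.5) {
  if (any(true_vaf < 0 | true_vaf > 1)) stop("true_vaf must lie in [0, 1]")
  if (any(duplex_fraction < 0 | duplex_fraction > 1)) {
    stop("duplex_fraction must lie in [0, 1]")
  }
  if (any(depth < 1)) stop("depth must be >= 1")
  n <- max(length(true_vaf), length(depth))
  depth <- as.integer(rep_len(depth, n))
  true_vaf <- rep_len(true_vaf, n)
  alt_total <- stats::rbinom(n, depth, true_vaf)
  alt_duplex <- stats::rbinom(n, alt_total, rep_len(duplex_fraction, n))
  data.frame(depth = depth, alt_duplex = alt_duplex,
             alt_single = alt_total - alt_duplex)
}

# draw per-mutation site identities; duplicates within a patient are dropped
# upstream (collision probability is negligible at panel scale)
.draw_sites <- function(n) {
  data.frame(
    chrom = paste0("chr", sample.int(22, n, replace = TRUE)),
    pos = sample.int(2.5e8, n, replace = TRUE),
    ref = sample(.BASES, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

.empty_pileup <- function() {
  df <- data.frame(sample_id = character(0), patient_id = character(0),
                   sample_type = character(0), collection_day = integer(0),
                   chrom = character(0), pos = integer(0),
                   ref = character(0), alt = character(0),
                   depth = integer(0), alt_duplex = integer(0),
                   alt_single = integer(0), stringsAsFactors = FALSE)
  df
}

#' Simulate a synthetic cfDNA cohort
#'
#' Generates per-patient pre- and post-operative plasma pileups (plus PBMC
#' and tumor-tissue samples when enabled), a patient manifest with serum
#' markers and relapse-free survival, and ground-truth labels. Mutation
#' origins are `tumor` (expected plasma VAF collapses after surgery to
#' `residual_ratio` times its pre-operative value in residual-disease
#' positive patients, `residual_ratio_negative` otherwise), `nontumor_plasma`
#' (VAF unaffected by surgery, e.g. clonal hematopoiesis below PBMC
#' detection or other-tissue somatic), and `pbmc_shared` (hematopoietic
#' variants with calling-level support in the PBMC sample, so the PBMC
#' removal rule is exercised). Every site's expected VAF additionally
#' receives the background `error_rate`; observed counts are binomial via
#' [simulate_site()]. Recurrence times follow a Weibull proportional-hazards
#' model whose hazard is multiplied by `hr_mrd` for residual-disease-positive
#' patients and `hr_afp` for AFP-positive patients, with uniform
#' administrative censoring.
#'
#' @param config A [simulation_config()] object.
#' @return A list of class `mvfc_cohort` with elements `pileup` (observation
#'   table), `manifest` (patient table), and `truth` (list with `patients`:
#'   per-patient residual-disease truth, and `mutations`: per-mutation origin
#'   and expected pre/post VAFs).
#' @examples
#' cohort <- simulate_cohort(simulation_config(seed = 7, n_patients = 3))
#' table(cohort$truth$mutations$origin)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("config must be a simulation_config object")
  }
  set.seed(config$seed)
  n <- config$n_patients
  if (n == 0L) {
    return(structure(list(
      pileup = .empty_pileup(),
      manifest = data.frame(patient_id = character(0), afp = numeric(0),
                            dcp = numeric(0), rfs_days = integer(0),
                            relapse_event = logical(0)),
      truth = list(
        patients = data.frame(patient_id = character(0),
                              mrd_positive = logical(0)),
        mutations = data.frame()
      )
    ), class = "mvfc_cohort"))
  }
  patient_id <- sprintf("P%04d", seq_len(n))
  mrd_positive <- stats::runif(n) < config$frac_mrd_positive

  n_tum <- stats::rpois(n, config$n_tumor_mut_mean)
  n_non <- stats::rpois(n, config$n_nontumor_mut_mean)
  n_pb <- stats::rpois(n, config$n_pbmc_mut_mean)

  # long per-mutation table, vectorized over patients
  origin <- rep(rep(c("tumor", "nontumor_plasma", "pbmc_shared"), n),
                times = as.vector(rbind(n_tum, n_non, n_pb)))
  pat_of_mut <- rep(rep(patient_id, each = 3),
                    times = as.vector(rbind(n_tum, n_non, n_pb)))
  m <- length(origin)
  mut <- .draw_sites(m)
  mut$alt <- vapply(mut$ref, function(r) sample(setdiff(.BASES, r), 1),
                    character(1))
  mut$patient_id <- pat_of_mut
  mut$origin <- origin
  dup <- duplicated(paste(mut$patient_id, .site_key(mut)))
  mut <- mut[!dup, , drop = FALSE]
  m <- nrow(mut)

  runif_range <- function(k, r) stats::runif(k, r[1], r[2])
  mut$vaf_plasma <- NA_real_
  is_tum <- mut$origin == "tumor"
  mut$vaf_plasma[is_tum] <- runif_range(sum(is_tum), config$tumor_vaf_range)
  mut$vaf_plasma[!is_tum] <- runif_range(sum(!is_tum),
                                         config$nontumor_vaf_range)
  mut$vaf_tissue <- 0
  mut$vaf_tissue[is_tum] <- runif_range(sum(is_tum),
                                        config$tumor_tissue_vaf_range)
  is_pb <- mut$origin == "pbmc_shared"
  mut$vaf_pbmc <- 0
  mut$vaf_pbmc[is_pb] <- runif_range(sum(is_pb), config$pbmc_vaf_range)

  pos_pat <- mut$patient_id %in% patient_id[mrd_positive]
  ratio <- ifelse(pos_pat, config$residual_ratio,
                  config$residual_ratio_negative)
  post_mult <- ifelse(is_tum, ratio, 1)
  er <- config$error_rate
  mut$vaf_pre_expected <- pmin(1, mut$vaf_plasma + er)
  mut$vaf_post_expected <- pmin(1, mut$vaf_plasma * post_mult + er)

  draw_sample <- function(type, day, expected, depth_mean) {
    depth <- pmax(1L, stats::rnbinom(m, mu = depth_mean,
                                     size = config$depth_dispersion))
    counts <- simulate_site(expected, depth, config$duplex_fraction)
    data.frame(
      sample_id = paste0(mut$patient_id, "_", type),
      patient_id = mut$patient_id, sample_type = type,
      collection_day = as.integer(day),
      chrom = mut$chrom, pos = mut$pos, ref = mut$ref, alt = mut$alt,
      depth = counts$depth, alt_duplex = counts$alt_duplex,
      alt_single = counts$alt_single, stringsAsFactors = FALSE
    )
  }
  pileup <- rbind(
    draw_sample("pre_plasma", -1L, mut$vaf_pre_expected, config$depth_mean),
    draw_sample("post_plasma", 30L, mut$vaf_post_expected, config$depth_mean)
  )
  if (config$include_pbmc) {
    pileup <- rbind(pileup, draw_sample(
      "pbmc", -1L, pmin(1, mut$vaf_pbmc + er), config$pbmc_depth_mean
    ))
  }
  if (config$include_tumor_tissue) {
    pileup <- rbind(pileup, draw_sample(
      "tumor", 0L, pmin(1, mut$vaf_tissue + er), config$tumor_depth_mean
    ))
  }

  # serum markers conditional on residual-disease truth
  draw_marker <- function(model) {
    ml <- ifelse(mrd_positive, model$meanlog_positive, model$meanlog_negative)
    sl <- ifelse(mrd_positive, model$sdlog_positive, model$sdlog_negative)
    stats::rlnorm(n, ml, sl)
  }
  afp <- draw_marker(config$afp_model)
  dcp <- draw_marker(config$dcp_model)

  sv <- config$survival
  afp_pos <- afp > 20
  log_hr <- log(sv$hr_mrd) * mrd_positive + log(sv$hr_afp) * afp_pos
  u <- stats::runif(n)
  t_rec <- sv$scale * (-log(u) / exp(log_hr))^(1 / sv$shape)
  cens <- stats::runif(n, sv$censor_min, sv$censor_max)
  rfs_days <- pmax(1L, as.integer(ceiling(pmin(t_rec, cens))))
  relapse_event <- t_rec <= cens

  manifest <- data.frame(
    patient_id = patient_id, afp = afp, dcp = dcp,
    rfs_days = rfs_days, relapse_event = relapse_event,
    age = as.integer(round(stats::rnorm(n, 55, 10))),
    tumor_number = 1L + stats::rpois(n, 0.5),
    tumor_size = round(stats::rlnorm(n, log(4), 0.5), 1),
    differentiation = sample(c("well", "moderate", "poor"), n,
                             replace = TRUE, prob = c(0.2, 0.55, 0.25)),
    smoking = stats::runif(n) < 0.4,
    alcohol = stats::runif(n) < 0.3,
    bclc_stage = sample(c("0", "A", "B", "C"), n, replace = TRUE,
                        prob = c(0.1, 0.55, 0.25, 0.1)),
    stringsAsFactors = FALSE
  )

  truth_mut <- mut[, c("patient_id", "chrom", "pos", "ref", "alt", "origin",
                       "vaf_pre_expected", "vaf_post_expected")]
  structure(list(
    pileup = pileup,
    manifest = manifest,
    truth = list(
      patients = data.frame(patient_id = patient_id,
                            mrd_positive = mrd_positive,
                            stringsAsFactors = FALSE),
      mutations = truth_mut
    )
  ), class = "mvfc_cohort")
}

#' @export
print.mvfc_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cfDNA cohort: %d patients, %d observations (%d sites)\n",
    nrow(x$manifest), nrow(x$pileup), nrow(x$truth$mutations)
  ))
  if (nrow(x$truth$mutations) > 0) {
    print(table(origin = x$truth$mutations$origin))
  }
  invisible(x)
}

#' Simulate follow-up plasma samples along a clinical course
#'
#' Given the ground-truth mutation table of a simulated patient and a set of
#' follow-up timepoints with tumor-fraction multipliers, draws one
#' follow-up plasma sample per timepoint. Tumor-origin sites scale their
#' expected VAF by the timepoint multiplier (0 = no detectable burden, 1 =
#' pre-operative burden, >1 = progression); non-tumor sites are
#' burden-independent. Uses the current RNG state.
#'
#' @param truth_mutations Ground-truth mutation rows for one patient (from
#'   `simulate_cohort()$truth$mutations`; the pre-surgery expected VAF minus
#'   the error rate is treated as the tumor-fraction-1 reference level).
#' @param timepoints data.frame with columns `day` and `multiplier`.
#' @param config A [simulation_config()] object (depth, error and duplex
#'   parameters are reused).
#' @return A pileup data.frame of `followup_plasma` observations.
#' @export
simulate_followup_series <- function(truth_mutations, timepoints, config) {
  if (!inherits(config, "simulation_config")) {
    stop("config must be a simulation_config object")
  }
  if (!all(c("day", "multiplier") %in% names(timepoints))) {
    stop("timepoints must have columns day, multiplier")
  }
  if (any(timepoints$multiplier < 0)) stop("multipliers must be >= 0")
  if (length(unique(truth_mutations$patient_id)) > 1) {
    stop("truth_mutations must describe a single patient")
  }
  m <- nrow(truth_mutations)
  er <- config$error_rate
  base_vaf <- pmax(0, truth_mutations$vaf_pre_expected - er)
  out <- vector("list", nrow(timepoints))
  for (i in seq_len(nrow(timepoints))) {
    mult <- timepoints$multiplier[i]
    expected <- ifelse(truth_mutations$origin == "tumor",
                       base_vaf * mult, base_vaf)
    expected <- pmin(1, expected + er)
    depth <- pmax(1L, stats::rnbinom(m, mu = config$depth_mean,
                                     size = config$depth_dispersion))
    counts <- simulate_site(expected, depth, config$duplex_fraction)
    out[[i]] <- data.frame(
      sample_id = paste0(truth_mutations$patient_id, "_fu",
                         timepoints$day[i]),
      patient_id = truth_mutations$patient_id,
      sample_type = "followup_plasma",
      collection_day = as.integer(timepoints$day[i]),
      chrom = truth_mutations$chrom, pos = truth_mutations$pos,
      ref = truth_mutations$ref, alt = truth_mutations$alt,
      depth = counts$depth, alt_duplex = counts$alt_duplex,
      alt_single = counts$alt_single, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
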