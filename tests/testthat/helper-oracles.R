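# Independent oracle implementations used to cross-check the package.
# These re-derive each statistic from first principles, clause by clause,
# and must stay independent of the code paths they verify.

options(mvfcscreen.verbose = FALSE)

# --- calling oracle: naive clause-by-clause filter ------------------------
oracle_call_one <- function(depth, alt_duplex, alt_single, sample_type,
                            cfg = calling_config()) {
  vaf <- (alt_duplex + alt_single) / depth
  if (depth < cfg$min_depth) return(FALSE)
  support <- (alt_duplex >= 1) || (alt_single >= cfg$min_single_strand_reads)
  if (!support) return(FALSE)
  if (!(vaf > -log(cfg$alpha) / depth)) return(FALSE)
  if (sample_type == "pre_plasma" && !(vaf >= cfg$pre_plasma_min_vaf)) {
    return(FALSE)
  }
  if (sample_type == "tumor" && !(vaf > cfg$tumor_tissue_min_vaf)) {
    return(FALSE)
  }
  TRUE
}

# random site observations spanning the filter boundaries
random_sites <- function(n, sample_type = "pre_plasma") {
  depth <- sample(c(50:150, 500, 1000, 1500, 4605), n, replace = TRUE)
  alt_total <- pmin(depth, stats::rpois(n, lambda = sample(c(0:5, 10, 60, 200),
                                                           n, replace = TRUE)))
  alt_duplex <- stats::rbinom(n, alt_total, 0.5)
  data.frame(
    sample_id = "S1", patient_id = "P1", sample_type = sample_type,
    collection_day = -1L,
    chrom = "chr1", pos = seq_len(n), ref = "A", alt = "T",
    depth = as.integer(depth), alt_duplex = as.integer(alt_duplex),
    alt_single = as.integer(alt_total - alt_duplex),
    stringsAsFactors = FALSE
  )
}

# --- Pearson chi-square from the definition ------------------------------
oracle_pearson <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# --- two-group log-rank by hand-tabulated O, E, V per event time ---------
oracle_logrank <- function(time, event, group) {
  group <- as.integer(as.factor(group))
  ev_times <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & group == 1)
    d_j <- sum(event & time == t)
    d1_j <- sum(event & time == t & group == 1)
    O <- O + d1_j
    E <- E + d_j * n1_j / n_j
    if (n_j > 1) {
      V <- V + d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
    }
  }
  (O - E)^2 / V
}

# --- Efron log partial likelihood from the definition --------------------
oracle_efron_lpl <- function(beta, time, event, X) {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  r <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    sum_R <- sum(r[R])
    sum_D <- sum(r[D])
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum_R - (l / d) * sum_D)
    }
  }
  ll
}

# refined grid-search maximizer of the Efron partial likelihood
oracle_grid_cox <- function(time, event, X, lower = -3, upper = 3,
                            rounds = 7, pts = 25) {
  X <- as.matrix(X)
  p <- ncol(X)
  lo <- rep(lower, p); hi <- rep(upper, p)
  best <- rep(0, p)
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(p), function(j) seq(lo[j], hi[j],
                                                length.out = pts))
    combos <- as.matrix(expand.grid(grids))
    vals <- apply(combos, 1, function(b) {
      oracle_efron_lpl(b, time, event, X)
    })
    best <- combos[which.max(vals), ]
    width <- (hi - lo) / (pts - 1)
    lo <- best - 2 * width
    hi <- best + 2 * width
  }
  unname(best)
}

# --- AUC by exhaustive pair comparison -----------------------------------
oracle_auc_pairs <- function(marker, status) {
  cases <- marker[status == 1]
  ctrls <- marker[status == 0]
  cmp <- outer(cases, ctrls, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# --- shared fixtures -----------------------------------------------------
make_pileup_row <- function(sample_id = "S1", patient_id = "P1",
                            sample_type = "pre_plasma",
                            collection_day = -1L, chrom = "chr1", pos = 100L,
                            ref = "A", alt = "T", depth = 1000L,
                            alt_duplex = 2L, alt_single = 8L) {
  data.frame(sample_id = sample_id, patient_id = patient_id,
             sample_type = sample_type,
             collection_day = as.integer(collection_day),
             chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             depth = as.integer(depth), alt_duplex = as.integer(alt_duplex),
             alt_single = as.integer(alt_single), stringsAsFactors = FALSE)
}

run_cohort_screen <- function(cohort, cfg = calling_config()) {
  pre <- cohort$pileup[cohort$pileup$sample_type == "pre_plasma", ]
  pbmc <- cohort$pileup[cohort$pileup$sample_type == "pbmc", ]
  calls <- call_sample_mutations(pre, cfg)
  calls <- subtract_pbmc(calls, pbmc, cfg)
  screen_patient(calls, cohort$pileup, cfg)
}

mutation_key <- function(df) paste(df$patient_id, df$chrom, df$pos,
                                   df$ref, df$alt)
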