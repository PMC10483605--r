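#' Mutation variant frequency change
#'
#' The MVFC of a mutation is its post-operative plasma VAF divided by its
#' pre-operative plasma VAF. Values near 0 indicate a mutation whose
#' circulating level collapsed with the tumor burden removed at surgery;
#' values near 1 indicate a burden-independent (non-tumor) origin.
#'
#' @param vaf_pre Pre-operative VAF(s), > 0 (screened mutations always pass
#'   the pre-operative VAF floor).
#' @param vaf_post Post-operative VAF(s), >= 0.
#' @return `vaf_post / vaf_pre`, vectorized.
#' @examples
#' compute_mvfc(0.01, 0.002)  # 0.2
#' @export
compute_mvfc <- function(vaf_pre, vaf_post) {
  if (any(vaf_pre <= 0)) stop("vaf_pre must be > 0")
  if (any(vaf_post < 0)) stop("vaf_post must be >= 0")
  vaf_post / vaf_pre
}

#' Classify mutations by MVFC
#'
#' Mutations with MVFC strictly below the threshold are classified as
#' tumor-derived (`"tumor"`); others as `"nontumor"`. Missing MVFC (no
#' evaluable post-operative coverage) yields `"unevaluable"`.
#'
#' @param mvfc Numeric vector of MVFC values (NA = not evaluable).
#' @param threshold Class boundary, default 0.2 (strict `<`).
#' @return Character vector in `{"tumor", "nontumor", "unevaluable"}`.
#' @export
classify_mvfc <- function(mvfc, threshold = 0.2) {
  ifelse(is.na(mvfc), "unevaluable",
         ifelse(mvfc < threshold, "tumor", "nontumor"))
}

#' Screen pre-operative plasma mutations by MVFC
#'
#' For each PBMC-subtracted pre-operative plasma call, looks up the same
#' site in the raw post-operative pileup of the same patient and computes
#' the MVFC. No calling filters are applied to the post-operative sample:
#' the ratio deliberately uses the raw post-operative frequency, since tumor
#' mutations are expected to fall to (near) zero there and would never
#' re-pass the calling rules. Sites absent from the post-operative table, or
#' covered below `min_depth` there, are classed `unevaluable` rather than
#' assigned MVFC 0, so that absence of data is never read as absence of the
#' mutation. A post-operative VAF of exactly 0 gives MVFC 0 (class tumor).
#'
#' @param pre_calls Pre-operative plasma calls (PBMC-subtracted), any number
#'   of patients.
#' @param post_sample Post-operative pileup rows (other sample types are
#'   ignored).
#' @param config A [calling_config()].
#' @return A data.frame with one row per pre-operative call: `patient_id`,
#'   site columns, `vaf_pre`, `pre_depth`, `vaf_post`, `post_depth`, `mvfc`,
#'   `mvfc_class`.
#' @export
screen_patient <- function(pre_calls, post_sample,
                           config = calling_config()) {
  post <- post_sample[post_sample$sample_type == "post_plasma", ,
                      drop = FALSE]
  if (nrow(pre_calls) == 0) {
    return(data.frame(patient_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), vaf_pre = numeric(0),
                      pre_depth = integer(0), vaf_post = numeric(0),
                      post_depth = integer(0), mvfc = numeric(0),
                      mvfc_class = character(0), stringsAsFactors = FALSE))
  }
  vaf_pre <- (pre_calls$alt_duplex + pre_calls$alt_single) / pre_calls$depth
  key_pre <- paste(pre_calls$patient_id, .site_key(pre_calls))
  key_post <- paste(post$patient_id, .site_key(post))
  idx <- match(key_pre, key_post)
  post_depth <- post$depth[idx]
  vaf_post <- (post$alt_duplex[idx] + post$alt_single[idx]) / post_depth
  evaluable <- !is.na(idx) & post_depth >= config$min_depth
  vaf_post[!evaluable] <- NA_real_
  post_depth[!evaluable] <- NA_integer_
  mvfc <- rep(NA_real_, length(vaf_pre))
  mvfc[evaluable] <- compute_mvfc(vaf_pre[evaluable], vaf_post[evaluable])
  out <- data.frame(
    patient_id = pre_calls$patient_id,
    chrom = pre_calls$chrom, pos = pre_calls$pos,
    ref = pre_calls$ref, alt = pre_calls$alt,
    vaf_pre = vaf_pre, pre_depth = pre_calls$depth,
    vaf_post = vaf_post, post_depth = post_depth,
    mvfc = mvfc,
    mvfc_class = classify_mvfc(mvfc, config$mvfc_threshold),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  .log_msg("screen_patient: %d mutations (%d tumor / %d nontumor / %d unevaluable)",
           nrow(out), sum(out$mvfc_class == "tumor"),
           sum(out$mvfc_class == "nontumor"),
           sum(out$mvfc_class == "unevaluable"))
  out
}

#' MVFC histogram over evaluable mutations
#'
#' Bins the MVFC values of evaluable screened mutations, for drawing the
#' MVFC distribution plot used to check (or re-choose) the class dividing
#' point on a new panel or clinical scenario.
#'
#' @param screened Screened mutations from [screen_patient()].
#' @param bins Number of equal-width bins (>= 1).
#' @param limits Histogram range; values above the upper limit are clamped
#'   into the last bin. Default `c(0, 2)`.
#' @param threshold MVFC threshold reported alongside, default 0.2.
#' @return A list with `histogram` (data.frame `bin_left`, `bin_right`,
#'   `count`), `n_evaluable`, and `fraction_below_threshold`.
#' @export
mvfc_distribution <- function(screened, bins = 20, limits = c(0, 2),
                              threshold = 0.2) {
  if (bins < 1) stop("bins must be >= 1")
  mvfc <- screened$mvfc[!is.na(screened$mvfc)]
  breaks <- seq(limits[1], limits[2], length.out = bins + 1)
  hist_df <- data.frame(bin_left = breaks[-length(breaks)],
                        bin_right = breaks[-1])
  if (length(mvfc) == 0) {
    hist_df$count <- integer(bins)
    return(list(histogram = hist_df, n_evaluable = 0L,
                fraction_below_threshold = NA_real_))
  }
  clamped <- pmin(pmax(mvfc, limits[1]), limits[2])
  idx <- pmin(bins, pmax(1L, findInterval(clamped, breaks,
                                          rightmost.closed = TRUE)))
  hist_df$count <- tabulate(idx, nbins = bins)
  list(histogram = hist_df, n_evaluable = length(mvfc),
       fraction_below_threshold = mean(mvfc < threshold))
}

#' Track screened mutations across follow-up samples
#'
#' Looks up each screened mutation in follow-up plasma pileups and reports
#' its raw VAF per timepoint, labeled by MVFC class, for tumor-burden
#' trajectory plots along the clinical course. Sites absent from a timepoint
#' are reported with NA VAF.
#'
#' @param screened Screened mutations from [screen_patient()].
#' @param followup_samples Pileup rows of `followup_plasma` samples sharing
#'   the screened patients' ids.
#' @return A data.frame: `patient_id`, site columns, `mvfc_class`,
#'   `collection_day`, `depth`, `vaf`.
#' @export
track_followup <- function(screened, followup_samples) {
  fu <- followup_samples[followup_samples$sample_type == "followup_plasma", ,
                         drop = FALSE]
  days <- sort(unique(fu$collection_day))
  if (nrow(screened) == 0 || length(days) == 0) {
    return(data.frame(patient_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), mvfc_class = character(0),
                      collection_day = integer(0), depth = integer(0),
                      vaf = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(days, function(d) {
    fu_d <- fu[fu$collection_day == d, , drop = FALSE]
    idx <- match(paste(screened$patient_id, .site_key(screened)),
                 paste(fu_d$patient_id, .site_key(fu_d)))
    vaf <- (fu_d$alt_duplex[idx] + fu_d$alt_single[idx]) / fu_d$depth[idx]
    data.frame(
      patient_id = screened$patient_id,
      chrom = screened$chrom, pos = screened$pos,
      ref = screened$ref, alt = screened$alt,
      mvfc_class = screened$mvfc_class,
      collection_day = d, depth = fu_d$depth[idx], vaf = vaf,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
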