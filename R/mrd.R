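#' Call ctDNA-based residual disease per patient
#'
#' A patient is MRD positive on ctDNA when at least one MVFC-identified
#' tumor mutation (class `tumor`) is detected in post-operative plasma at a
#' VAF strictly above `mrd_min_post_vaf` (default 0.1%). Unevaluable
#' mutations never contribute. No support-rule re-check is applied to the
#' post-operative counts: positivity is defined on the VAF alone.
#'
#' @param screened Screened mutations from [screen_patient()] (any number of
#'   patients).
#' @param config A [calling_config()].
#' @return A data.frame with one row per patient present in `screened`:
#'   `patient_id`, `ctdna_positive`, `n_positive_mutations`.
#' @export
call_ctdna_mrd <- function(screened, config = calling_config()) {
  if (nrow(screened) == 0) {
    return(data.frame(patient_id = character(0), ctdna_positive = logical(0),
                      n_positive_mutations = integer(0),
                      stringsAsFactors = FALSE))
  }
  qualifies <- screened$mvfc_class == "tumor" &
    !is.na(screened$vaf_post) &
    screened$vaf_post > config$mrd_min_post_vaf
  counts <- tapply(qualifies, screened$patient_id, sum)
  out <- data.frame(patient_id = names(counts),
                    ctdna_positive = as.vector(counts) >= 1L,
                    n_positive_mutations = as.integer(counts),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Serum biomarker positivity
#'
#' AFP is positive above 20 ng/mL and DCP above 40 mAU/mL (both strict).
#' Missing input yields a missing call.
#'
#' @param afp AFP level(s), ng/mL, or NA.
#' @param dcp DCP level(s), mAU/mL, or NA.
#' @param config A [calling_config()].
#' @return A data.frame with logical columns `afp_positive`, `dcp_positive`
#'   (NA where the marker is absent).
#' @export
call_serum_markers <- function(afp, dcp, config = calling_config()) {
  if (any(afp < 0, na.rm = TRUE) || any(dcp < 0, na.rm = TRUE)) {
    stop("serum marker levels must be non-negative")
  }
  data.frame(afp_positive = afp > config$afp_cutoff,
             dcp_positive = dcp > config$dcp_cutoff)
}

#' Combine ctDNA and AFP marker calls
#'
#' The combined marker is positive when at least one of the two biomarkers
#' is positive (logical OR).
#'
#' @param ctdna Logical ctDNA MRD call(s).
#' @param afp_positive Logical AFP call(s).
#' @return Logical vector; NA where `afp_positive` is NA.
#' @export
combine_markers <- function(ctdna, afp_positive) {
  ifelse(is.na(afp_positive), NA, ctdna | afp_positive)
}

#' Per-patient MRD classification across markers
#'
#' Joins the ctDNA call (from screened mutations), the serum marker calls
#' (from the manifest) and their combination into one row per patient.
#' Manifest patients without screened mutations get a negative ctDNA call
#' with zero qualifying mutations.
#'
#' @param screened Screened mutations from [screen_patient()].
#' @param manifest Patient manifest (see [read_patient_manifest()]).
#' @param config A [calling_config()].
#' @return A data.frame: `patient_id`, `ctdna_positive`,
#'   `n_positive_mutations`, `afp_positive`, `dcp_positive`,
#'   `combined_positive`.
#' @export
call_mrd <- function(screened, manifest, config = calling_config()) {
  ct <- call_ctdna_mrd(screened, config)
  idx <- match(manifest$patient_id, ct$patient_id)
  ctdna_positive <- ct$ctdna_positive[idx]
  n_pos <- ct$n_positive_mutations[idx]
  ctdna_positive[is.na(ctdna_positive)] <- FALSE
  n_pos[is.na(n_pos)] <- 0L
  serum <- call_serum_markers(manifest$afp, manifest$dcp, config)
  out <- data.frame(
    patient_id = manifest$patient_id,
    ctdna_positive = ctdna_positive,
    n_positive_mutations = n_pos,
    afp_positive = serum$afp_positive,
    dcp_positive = serum$dcp_positive,
    combined_positive = combine_markers(ctdna_positive, serum$afp_positive),
    stringsAsFactors = FALSE
  )
  .log_msg("call_mrd: %d/%d patients ctDNA-MRD positive",
           sum(out$ctdna_positive), nrow(out))
  out
}
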