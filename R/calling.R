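#' Depth-dependent minimum VAF threshold
#'
#' The minimum variant allele frequency a site must strictly exceed to be
#' callable, `-log(alpha) / depth`. With the default `alpha = 0.01` this is
#' the frequency at which a variant present at the threshold level would be
#' missed entirely (zero alt reads) with probability at most ~1%: under
#' binomial sampling, P(0 alt reads) = (1 - v)^depth <= exp(-v * depth) =
#' alpha at v = -log(alpha)/depth.
#'
#' @param depth Consensus read depth(s), >= 1.
#' @param alpha Detection probability bound in (0, 1].
#' @return The VAF threshold(s), vectorized over `depth`.
#' @examples
#' min_vaf_threshold(100)   # 0.04605...
#' min_vaf_threshold(4605)  # ~0.001
#' @export
min_vaf_threshold <- function(depth, alpha = 0.01) {
  if (any(depth < 1)) stop("depth must be >= 1")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  -log(alpha) / depth
}

#' Duplex / single-strand support rule
#'
#' A variant is supported when backed by at least one duplex (double-strand)
#' consensus read, or by at least `min_single_strand_reads` (default 3)
#' single-strand consensus reads.
#'
#' @param alt_duplex Alt-supporting duplex consensus read count(s).
#' @param alt_single Alt-supporting single-strand consensus read count(s).
#' @param config A [calling_config()].
#' @return Logical vector.
#' @export
passes_support_rule <- function(alt_duplex, alt_single,
                                config = calling_config()) {
  if (any(alt_duplex < 0) || any(alt_single < 0)) {
    stop("alt counts must be >= 0")
  }
  alt_duplex >= 1L | alt_single >= config$min_single_strand_reads
}

#' Call mutations from consensus pileup observations
#'
#' Applies the consensus calling criteria to each observation: depth >=
#' `min_depth` (inclusive), the duplex/single-strand support rule, and VAF
#' strictly above [min_vaf_threshold()]. Sample-type-specific floors are
#' applied on top: pre-operative plasma requires VAF >= `pre_plasma_min_vaf`
#' (inclusive) and tumor tissue VAF > `tumor_tissue_min_vaf` (strict).
#' Rows may come from any number of samples; each row is filtered under its
#' own `sample_type`.
#'
#' @param sample A pileup data.frame (see [read_pileup_table()]).
#' @param config A [calling_config()].
#' @return A data.frame of calls: the pileup columns plus `vaf` and
#'   `passed_filters` (comma-joined names of the filters applied).
#' @export
call_sample_mutations <- function(sample, config = calling_config()) {
  sample <- validate_pileup(sample)
  if (nrow(sample) == 0) {
    out <- sample
    out$vaf <- numeric(0)
    out$passed_filters <- character(0)
    return(out)
  }
  vaf <- (sample$alt_duplex + sample$alt_single) / sample$depth
  keep <- sample$depth >= config$min_depth &
    passes_support_rule(sample$alt_duplex, sample$alt_single, config) &
    vaf > min_vaf_threshold(pmax(sample$depth, 1), config$alpha)
  is_pre <- sample$sample_type == "pre_plasma"
  is_tumor <- sample$sample_type == "tumor"
  keep <- keep &
    (!is_pre | vaf >= config$pre_plasma_min_vaf) &
    (!is_tumor | vaf > config$tumor_tissue_min_vaf)
  out <- sample[keep, , drop = FALSE]
  out$vaf <- vaf[keep]
  filters <- ifelse(is_pre[keep], "depth,support,vaf_formula,pre_plasma_vaf",
                    ifelse(is_tumor[keep],
                           "depth,support,vaf_formula,tumor_tissue_vaf",
                           "depth,support,vaf_formula"))
  out$passed_filters <- filters
  rownames(out) <- NULL
  .log_msg("call_sample_mutations: %d of %d sites retained",
           nrow(out), nrow(sample))
  out
}

#' Remove PBMC-detected mutations from plasma calls
#'
#' Removes any plasma call whose site, in the matched patient's PBMC sample,
#' both passes the duplex/single-strand support rule and has VAF strictly
#' above the depth-dependent threshold (both clauses must hold). Sites
#' absent from the PBMC table are retained: no PBMC evidence, no removal.
#' This subtracts clonal-hematopoiesis and germline-leak variants so that
#' they do not contaminate plasma mutation screening.
#'
#' @param plasma_calls Calls from [call_sample_mutations()].
#' @param pbmc PBMC pileup rows (sample_type `pbmc`); may span patients.
#' @param config A [calling_config()].
#' @return The retained plasma calls.
#' @export
subtract_pbmc <- function(plasma_calls, pbmc, config = calling_config()) {
  if (nrow(plasma_calls) == 0) return(plasma_calls)
  if (nrow(pbmc) == 0) return(plasma_calls)
  if (!all(pbmc$sample_type == "pbmc")) {
    stop("pbmc table must contain only sample_type == 'pbmc' rows")
  }
  pbmc_vaf <- (pbmc$alt_duplex + pbmc$alt_single) / pbmc$depth
  pbmc_hit <- passes_support_rule(pbmc$alt_duplex, pbmc$alt_single, config) &
    pbmc_vaf > min_vaf_threshold(pmax(pbmc$depth, 1), config$alpha)
  hit_keys <- paste(pbmc$patient_id, .site_key(pbmc))[pbmc_hit]
  call_keys <- paste(plasma_calls$patient_id, .site_key(plasma_calls))
  keep <- !(call_keys %in% hit_keys)
  out <- plasma_calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  .log_msg("subtract_pbmc: removed %d of %d plasma calls",
           sum(!keep), length(keep))
  out
}
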