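#' @keywords internal
.log_msg <- function(fmt, ...) {
  if (isTRUE(getOption("mvfcscreen.verbose", TRUE))) {
    message(sprintf(fmt, ...))
  }
  invisible(NULL)
}

.SAMPLE_TYPES <- c("pre_plasma", "post_plasma", "followup_plasma",
                   "pbmc", "tumor")
.BASES <- c("A", "C", "G", "T")

.PILEUP_COLS <- c("sample_id", "patient_id", "sample_type", "collection_day",
                  "chrom", "pos", "ref", "alt", "depth",
                  "alt_duplex", "alt_single")

#' @keywords internal
.site_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Validate a pileup table
#'
#' Checks the per-site invariants of a consensus pileup table: all counts
#' non-negative, alt_duplex + alt_single <= depth, positions >= 1, ref/alt
#' single distinct bases in A/C/G/T, sample types from the closed set, and at
#' most one row per (sample, site). Violations raise errors naming the
#' offending row numbers.
#'
#' @param df A data.frame with the pileup columns (see [read_pileup_table()]).
#' @return The validated data.frame, invisibly usable downstream.
#' @export
validate_pileup <- function(df) {
  missing_cols <- setdiff(.PILEUP_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("pileup format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) return(df)
  for (col in c("collection_day", "pos", "depth", "alt_duplex", "alt_single")) {
    df[[col]] <- as.integer(df[[col]])
  }
  .bad <- function(cond, what) {
    if (any(cond, na.rm = TRUE) || anyNA(cond)) {
      rows <- which(cond | is.na(cond))
      stop(sprintf("pileup validation error (%s) in row(s): %s", what,
                   paste(utils::head(rows, 10), collapse = ", ")))
    }
  }
  .bad(df$depth < 0 | df$alt_duplex < 0 | df$alt_single < 0, "negative count")
  .bad(df$alt_duplex + df$alt_single > df$depth, "alt counts exceed depth")
  .bad(df$pos < 1, "position < 1")
  .bad(!(df$ref %in% .BASES) | !(df$alt %in% .BASES), "ref/alt not in ACGT")
  .bad(df$ref == df$alt, "ref equals alt")
  .bad(!(df$sample_type %in% .SAMPLE_TYPES), "unknown sample_type")
  dup <- duplicated(paste(df$sample_id, .site_key(df)))
  .bad(dup, "duplicate site within sample")
  df
}

#' Read a consensus pileup table
#'
#' Reads a tab-separated per-sample per-site table of UMI-consensus counts.
#' Required columns: `sample_id`, `patient_id`, `sample_type` (one of
#' pre_plasma, post_plasma, followup_plasma, pbmc, tumor), `collection_day`
#' (days relative to surgery), `chrom`, `pos` (1-based), `ref`, `alt`,
#' `depth`, `alt_duplex` (alt-supporting duplex consensus reads),
#' `alt_single` (alt-supporting single-strand consensus reads, both strands
#' summed). Rows violating the site invariants raise row-numbered errors.
#'
#' @param path Path to a TSV file.
#' @return A validated data.frame of observations (one row per sample-site).
#' @seealso [read_pileup_vcf()] for VCF input, [write_pileup_table()].
#' @export
read_pileup_table <- function(path) {
  if (!file.exists(path)) stop("pileup file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(.PILEUP_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("pileup format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[, .PILEUP_COLS]
  if (nrow(df) > 0) {
    for (col in c("collection_day", "pos", "depth",
                  "alt_duplex", "alt_single")) {
      x <- suppressWarnings(as.integer(df[[col]]))
      if (anyNA(x) && !anyNA(df[[col]])) {
        stop("pileup format error: non-integer values in column ", col)
      }
      df[[col]] <- x
    }
  } else {
    for (col in c("collection_day", "pos", "depth",
                  "alt_duplex", "alt_single")) {
      df[[col]] <- integer(0)
    }
  }
  df <- validate_pileup(df)
  .log_msg("read_pileup_table: %d observations from %d sample(s) [%s]",
           nrow(df), length(unique(df$sample_id)), basename(path))
  df
}

#' Write a consensus pileup table
#'
#' @param df A pileup data.frame (see [read_pileup_table()] for columns).
#' @param path Output path; written as TSV.
#' @export
write_pileup_table <- function(df, path) {
  df <- validate_pileup(df)
  utils::write.table(df[, .PILEUP_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a patient manifest
#'
#' Reads a comma- or tab-separated manifest with one row per patient.
#' Required columns: `patient_id`, `afp` (ng/mL), `dcp` (mAU/mL), `rfs_days`
#' (relapse-free survival, days), `relapse_event` (0/1 or TRUE/FALSE). Any
#' additional columns are kept as clinical covariates. Missing AFP/DCP cells
#' become `NA` ("marker absent"); duplicate patients or non-positive
#' `rfs_days` are errors.
#'
#' @param path Path to a CSV or TSV file (separator auto-detected from the
#'   header line).
#' @return A data.frame with one row per patient.
#' @export
read_patient_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  need <- c("patient_id", "afp", "dcp", "rfs_days", "relapse_event")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("manifest format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$patient_id)) {
    stop("manifest validation error: duplicate patient_id: ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]),
               collapse = ", "))
  }
  df$afp <- as.numeric(df$afp)
  df$dcp <- as.numeric(df$dcp)
  df$rfs_days <- as.integer(df$rfs_days)
  df$relapse_event <- as.logical(df$relapse_event) |
    (suppressWarnings(as.numeric(df$relapse_event)) > 0)
  df$relapse_event[is.na(df$relapse_event)] <- FALSE
  bad <- which(is.na(df$rfs_days) | df$rfs_days <= 0)
  if (length(bad) > 0) {
    stop("manifest validation error: rfs_days must be > 0 in row(s): ",
         paste(bad, collapse = ", "))
  }
  if (any(df$afp < 0, na.rm = TRUE) || any(df$dcp < 0, na.rm = TRUE)) {
    stop("manifest validation error: negative serum marker value")
  }
  .log_msg("read_patient_manifest: %d patients [%s]", nrow(df),
           basename(path))
  df
}

#' Write a patient manifest
#'
#' @param df Manifest data.frame as returned by [read_patient_manifest()].
#' @param path Output path; written as TSV.
#' @export
write_patient_manifest <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- .fmt_num(out[[col]])
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# full-precision decimal formatting so that numeric round-trips are exact
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

.SCREENED_COLS <- c("patient_id", "chrom", "pos", "ref", "alt",
                    "vaf_pre", "pre_depth", "vaf_post", "post_depth",
                    "mvfc", "mvfc_class")

#' Write screened mutations
#'
#' Writes a screened-mutation table (see [screen_patient()]) as TSV with a
#' deterministic column order. Ratios are written with 17 significant digits
#' so a round-trip read reproduces them bit-exactly.
#'
#' @param muts Screened mutation data.frame.
#' @param path Output path.
#' @export
write_screened_mutations <- function(muts, path) {
  missing_cols <- setdiff(.SCREENED_COLS, names(muts))
  if (length(missing_cols) > 0) {
    stop("screened-mutation table missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  out <- muts[, .SCREENED_COLS]
  for (col in c("vaf_pre", "vaf_post", "mvfc")) {
    out[[col]] <- .fmt_num(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read screened mutations
#'
#' @param path Path to a TSV written by [write_screened_mutations()].
#' @return A screened mutation data.frame.
#' @export
read_screened_mutations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  missing_cols <- setdiff(.SCREENED_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("screened-mutation format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  df$pos <- as.integer(df$pos)
  df$pre_depth <- as.integer(df$pre_depth)
  df$post_depth <- as.integer(df$post_depth)
  for (col in c("vaf_pre", "vaf_post", "mvfc")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' Import a pileup from a VCF file
#'
#' Builds a pileup table from a (possibly multi-sample) VCF, taking the
#' consensus depth and the duplex / single-strand alt-supporting counts from
#' configurable per-sample FORMAT fields. Only biallelic SNVs are imported;
#' positions are 1-based as in the VCF. Because a VCF does not carry sample
#' metadata, a `sample_info` table maps VCF sample names to `patient_id`,
#' `sample_type` and `collection_day`.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param sample_info data.frame with columns `sample_id`, `patient_id`,
#'   `sample_type`, `collection_day`; `sample_id` must match the VCF sample
#'   columns.
#' @param depth_field,duplex_field,single_field FORMAT field names holding
#'   the consensus depth and the duplex / single-strand alt counts.
#' @return A validated pileup data.frame (see [read_pileup_table()]).
#' @export
read_pileup_vcf <- function(path, sample_info,
                            depth_field = "DP",
                            duplex_field = "DX",
                            single_field = "SX") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF import requires the vcfR package")
  }
  need <- c("sample_id", "patient_id", "sample_type", "collection_day")
  if (!all(need %in% names(sample_info))) {
    stop("sample_info must have columns: ", paste(need, collapse = ", "))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  snv <- fix$REF %in% .BASES & fix$ALT %in% .BASES
  if (!any(snv)) {
    return(validate_pileup(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(.PILEUP_COLS))), .PILEUP_COLS
    )))
  }
  get_field <- function(field) {
    m <- vcfR::extract.gt(vcf, element = field, as.numeric = TRUE)
    m[snv, , drop = FALSE]
  }
  dp <- get_field(depth_field)
  dx <- get_field(duplex_field)
  sx <- get_field(single_field)
  samples <- colnames(dp)
  unknown <- setdiff(samples, sample_info$sample_id)
  if (length(unknown) > 0) {
    stop("VCF sample(s) missing from sample_info: ",
         paste(unknown, collapse = ", "))
  }
  rows <- lapply(samples, function(s) {
    info <- sample_info[sample_info$sample_id == s, ][1, ]
    keep <- !is.na(dp[, s])
    data.frame(
      sample_id = s, patient_id = info$patient_id,
      sample_type = info$sample_type,
      collection_day = as.integer(info$collection_day),
      chrom = fix$CHROM[snv][keep],
      pos = as.integer(fix$POS[snv][keep]),
      ref = fix$REF[snv][keep], alt = fix$ALT[snv][keep],
      depth = as.integer(dp[keep, s]),
      alt_duplex = as.integer(dx[keep, s]),
      alt_single = as.integer(sx[keep, s]),
      stringsAsFactors = FALSE
    )
  })
  validate_pileup(do.call(rbind, rows))
}
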