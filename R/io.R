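#' Read a paired-variant table (MAF-like TSV)
#'
#' One row per candidate variant per timepoint, with 1-based coordinates and
#' the paired PB/BM allele counts. Required columns:
#' `patient_id, timepoint, chrom, pos, ref, alt, gene, variant_class,
#' pb_alt, pb_ref, bm_alt, bm_ref`. Unknown extra columns are preserved and
#' reported via a message (some, like `protein_change` and `revalidated`,
#' are consumed by the candidate filter when present). Lines starting with
#' `#` are treated as comment headers.
#'
#' @param path path to a tab-separated file with a header row.
#' @param dialect table dialect; only `"maf_like_tsv"` is supported.
#' @return a [PairedVariantSet-class].
#' @export
readVariantTable <- function(path, dialect = c("maf_like_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         colClasses = "character", comment.char = "#",
                         check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(.VARIANT_COLS, names(d))
  if (length(missing))
    stop("variant table format error: missing column(s) ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(d), .VARIANT_COLS)
  if (length(extra))
    message("ignoring/preserving unknown column(s): ",
            paste(extra, collapse = ", "))
  for (col in c("timepoint", "pos", "pb_alt", "pb_ref", "bm_alt", "bm_ref")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    lo <- if (col == "pos") 1 else 0
    bad <- which(is.na(v) | v != round(v) | v < lo)
    if (length(bad))
      stop(sprintf("validation error in column '%s' at data row(s) %s",
                   col, paste(utils::head(bad, 10), collapse = ", ")))
    d[[col]] <- as.integer(v)
  }
  if ("revalidated" %in% names(d))
    d$revalidated <- as.logical(d$revalidated)
  PairedVariantSet(d)
}

#' Write a paired-variant table
#'
#' @param x a [PairedVariantSet-class] (or conforming data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVariantTable <- function(x, path) {
  d <- if (is(x, "PairedVariantSet")) x@data else as.data.frame(x)
  d <- d[, c(.VARIANT_COLS, setdiff(names(d), .VARIANT_COLS)), drop = FALSE]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tumor-context table
#'
#' Per-locus purity, ploidy, allele-specific copy number, and TiN, one row
#' per (patient, chrom, pos). Columns:
#' `patient_id, chrom, pos, purity, ploidy, cn_major, cn_minor, tin`.
#'
#' @param path path to a tab-separated file with a header row.
#' @return a [TumorContextTable-class].
#' @export
readTumorContext <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                         stringsAsFactors = FALSE)
  missing <- setdiff(.CONTEXT_COLS, names(d))
  if (length(missing))
    stop("context table format error: missing column(s) ",
         paste(missing, collapse = ", "))
  bad <- which(d$purity < 0 | d$purity > 1)
  if (length(bad))
    stop("validation error: purity outside [0,1] at data row(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  bad <- which(d$tin < 0 | d$tin > 1)
  if (length(bad))
    stop("validation error: tin outside [0,1] at data row(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  TumorContextTable(d)
}

#' Write a tumor-context table
#' @param x a [TumorContextTable-class] (or conforming data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTumorContext <- function(x, path) {
  d <- if (is(x, "TumorContextTable")) x@data else as.data.frame(x)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up the tumor context for one locus
#'
#' When the patient has context rows but none at this locus, local copy
#' number defaults to the balanced diploid state (1, 1) and the lookup is
#' flagged `"cn_default"`; purity/tin/ploidy are taken from the patient's
#' other rows (their first row). When the patient is absent entirely,
#' `NULL` is returned (callers apply cohort-level defaults and flag).
#'
#' @param ctx a [TumorContextTable-class].
#' @param patient_id,chrom,pos the locus key.
#' @return a list with `purity, ploidy, cn_major, cn_minor, tin, flags`,
#'   or `NULL`.
#' @export
contextLookup <- function(ctx, patient_id, chrom, pos) {
  d <- contextData(ctx)
  i <- which(d$patient_id == patient_id & d$chrom == chrom & d$pos == pos)
  if (length(i)) {
    r <- d[i[1], ]
    return(list(purity = r$purity, ploidy = r$ploidy, cn_major = r$cn_major,
                cn_minor = r$cn_minor, tin = r$tin, flags = character()))
  }
  j <- which(d$patient_id == patient_id)
  if (!length(j)) return(NULL)
  r <- d[j[1], ]
  list(purity = r$purity, ploidy = r$ploidy, cn_major = 1, cn_minor = 1,
       tin = r$tin, flags = "cn_default")
}

.CLASSIFICATION_COLS <- c(
  "patient_id", "timepoint", "chrom", "pos", "ref", "alt", "gene",
  "loglik_germline", "loglik_tumor", "loglik_ch",
  "posterior_germline", "posterior_tumor", "posterior_ch",
  "label", "chosen_f", "filter_flags")

.CLASSIFICATION_NUM <- c("loglik_germline", "loglik_tumor", "loglik_ch",
                         "posterior_germline", "posterior_tumor",
                         "posterior_ch", "chosen_f")

#' Write classification records
#'
#' Deterministic column order; numeric columns are written with 17
#' significant digits so that [readClassifications()] round-trips exactly.
#'
#' @param records data.frame of classification records as returned by
#'   [classifyCohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeClassifications <- function(records, path) {
  d <- as.data.frame(records)
  missing <- setdiff(.CLASSIFICATION_COLS, names(d))
  if (length(missing))
    stop("classification records missing column(s): ",
         paste(missing, collapse = ", "))
  d <- d[, .CLASSIFICATION_COLS, drop = FALSE]
  for (col in .CLASSIFICATION_NUM)
    d[[col]] <- sprintf("%.17g", d[[col]])
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read classification records written by [writeClassifications()]
#' @param path input path.
#' @return data.frame of classification records.
#' @export
readClassifications <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                         colClasses = "character", stringsAsFactors = FALSE)
  missing <- setdiff(.CLASSIFICATION_COLS, names(d))
  if (length(missing))
    stop("classification table missing column(s): ",
         paste(missing, collapse = ", "))
  for (col in .CLASSIFICATION_NUM) d[[col]] <- as.numeric(d[[col]])
  for (col in c("timepoint", "pos")) d[[col]] <- as.integer(d[[col]])
  d
}

#' Read a CH whitelist rules table
#'
#' Columns: `gene, rule_kind, detail, source`. `rule_kind` is one of
#' `any` (any variant in the gene), `any_truncating` (nonsense, splice-site,
#' frameshift), `listed_missense_positions` (missense at codons listed in
#' `detail`, comma-separated), `hotspot_codon_set` (any class at the listed
#' codons). Codon matching requires a `protein_change` annotation on the
#' variant (e.g. `p.R882H`).
#'
#' @param path path to the rules TSV.
#' @return data.frame of rules.
#' @export
readWhitelist <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                         colClasses = "character", stringsAsFactors = FALSE)
  need <- c("gene", "rule_kind", "detail")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("whitelist format error: missing column(s) ",
         paste(missing, collapse = ", "))
  known <- c("any", "any_truncating", "listed_missense_positions",
             "hotspot_codon_set")
  bad <- which(!d$rule_kind %in% known)
  if (length(bad))
    stop("unknown rule_kind at row(s) ", paste(bad, collapse = ", "))
  if (is.null(d$source)) d$source <- NA_character_
  d
}

#' The packaged default CH driver whitelist
#'
#' A synthetic curation of the canonically reported CH driver genes and
#' hotspots (DNMT3A, TET2, ASXL1, PPM1D, TP53, JAK2 V617F, SF3B1, SRSF2
#' P95, IDH1/2, CBL, GNB1, GNAS, ...). It is a user-replaceable stand-in
#' for a study-specific pathogenicity table, not a clinical resource.
#'
#' @return data.frame of rules (see [readWhitelist()]).
#' @export
defaultWhitelist <- function() {
  readWhitelist(system.file("extdata", "ch_whitelist_synthetic.tsv",
                            package = "chorigin", mustWork = TRUE))
}
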