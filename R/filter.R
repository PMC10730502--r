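.TRUNCATING <- c("nonsense", "splice_site", "frameshift_del", "frameshift_ins")

# First integer in a protein-change string, e.g. "p.R882H" -> 882.
.codonOf <- function(protein_change) {
  if (is.null(protein_change) || !length(protein_change) ||
      is.na(protein_change)) return(NA_integer_)
  m <- regmatches(protein_change, regexpr("[0-9]+", protein_change))
  if (!length(m)) return(NA_integer_)
  as.integer(m)
}

#' Does a variant match a CH whitelist rule?
#'
#' @param gene HGNC symbol.
#' @param variant_class one of
#'   `missense, nonsense, splice_site, frameshift_del, frameshift_ins, other`.
#' @param whitelist rules data.frame (see [readWhitelist()]).
#' @param protein_change optional protein annotation (e.g. `"p.R882H"`);
#'   required for codon-based rules to match.
#' @return `TRUE` if any rule matches.
#' @export
whitelistMatch <- function(gene, variant_class, whitelist,
                           protein_change = NA_character_) {
  rules <- whitelist[whitelist$gene == gene, , drop = FALSE]
  if (!nrow(rules)) return(FALSE)
  codon <- .codonOf(protein_change)
  for (k in seq_len(nrow(rules))) {
    kind <- rules$rule_kind[k]
    detail <- rules$detail[k]
    codons <- suppressWarnings(as.integer(strsplit(detail %||% "", ",")[[1]]))
    hit <- switch(kind,
      any = TRUE,
      any_truncating = variant_class %in% .TRUNCATING,
      listed_missense_positions =
        variant_class == "missense" && !is.na(codon) && codon %in% codons,
      hotspot_codon_set = !is.na(codon) && codon %in% codons,
      FALSE)
    if (isTRUE(hit)) return(TRUE)
  }
  FALSE
}

#' Evaluate the candidate-selection rules for one variant
#'
#' Applies, in order, on the PB sample (the CH compartment): whitelist
#' membership; minimum supporting alt reads; minimum VAF; maximum VAF with
#' the driver-gene exemption. All firing reasons are returned, not just the
#' first. A variant carrying a truthy `revalidated` annotation is exempt
#' from the minimum-VAF rule when the config allows it.
#'
#' @param obs one observation: a single-row [PairedVariantSet-class] or a
#'   one-row data.frame/list with the variant columns.
#' @param cfg a [FilterConfig-class].
#' @return list with `keep` (logical) and `reasons` (character vector of
#'   rule identifiers that fired; empty iff kept).
#' @examples
#' cfg <- FilterConfig()
#' obs <- list(gene = "DNMT3A", variant_class = "missense",
#'             protein_change = "p.R882H", pb_alt = 40L, pb_ref = 60L)
#' evaluateCandidate(obs, cfg)  # kept: DNMT3A exempt from the 35% ceiling
#' @export
evaluateCandidate <- function(obs, cfg) {
  if (is(obs, "PairedVariantSet")) obs <- as.list(obs@data[1, ])
  depth <- obs$pb_alt + obs$pb_ref
  if (depth <= 0) stop("no PB coverage")
  vaf <- obs$pb_alt / depth
  reasons <- character()
  if (!whitelistMatch(obs$gene, obs$variant_class, cfg@whitelist,
                      obs$protein_change %||% NA_character_))
    reasons <- c(reasons, "not_whitelisted")
  if (obs$pb_alt < cfg@minAltReads)
    reasons <- c(reasons, "min_alt_reads")
  revalidated <- isTRUE(obs$revalidated)
  if (vaf < cfg@minVaf &&
      !(cfg@allowRevalidatedBelowMinVaf && revalidated))
    reasons <- c(reasons, "min_vaf")
  if (vaf > cfg@maxVaf && !(obs$gene %in% cfg@maxVafExemptGenes))
    reasons <- c(reasons, "max_vaf")
  list(keep = length(reasons) == 0L, reasons = reasons)
}

#' Apply the candidate filters to a cohort
#'
#' @param cohort a [PairedVariantSet-class].
#' @param cfg a [FilterConfig-class].
#' @return list with `kept` (a `PairedVariantSet` of passing variants, input
#'   order preserved) and `audit` (data.frame with one row per input variant:
#'   key columns, `keep`, and semicolon-joined `reasons`). Variants with zero
#'   PB depth are excluded with reason `no_pb_coverage` rather than erroring,
#'   so one bad row never aborts a batch.
#' @export
applyFilters <- function(cohort, cfg) {
  d <- variantData(cohort)
  n <- nrow(d)
  keep <- logical(n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    obs <- as.list(d[i, ])
    if (obs$pb_alt + obs$pb_ref <= 0) {
      keep[i] <- FALSE
      reasons[i] <- "no_pb_coverage"
    } else {
      dec <- evaluateCandidate(obs, cfg)
      keep[i] <- dec$keep
      reasons[i] <- paste(dec$reasons, collapse = ";")
    }
  }
  audit <- data.frame(row = seq_len(n),
                      patient_id = d$patient_id, timepoint = d$timepoint,
                      chrom = d$chrom, pos = d$pos, alt = d$alt,
                      gene = d$gene, keep = keep, reasons = reasons,
                      stringsAsFactors = FALSE)
  list(kept = PairedVariantSet(d[keep, , drop = FALSE]), audit = audit)
}
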