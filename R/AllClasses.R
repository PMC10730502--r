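#' @import methods
NULL

setOldClass(c("distSpec", "list"))

.VARIANT_CLASSES <- c("missense", "nonsense", "splice_site",
                      "frameshift_del", "frameshift_ins", "other")

.VARIANT_COLS <- c("patient_id", "timepoint", "chrom", "pos", "ref", "alt",
                   "gene", "variant_class", "pb_alt", "pb_ref",
                   "bm_alt", "bm_ref")

.CONTEXT_COLS <- c("patient_id", "chrom", "pos", "purity", "ploidy",
                   "cn_major", "cn_minor", "tin")

#' Paired blood/marrow variant observations
#'
#' Container for candidate variants with alternate/reference allele counts in
#' the peripheral-blood (PB) and bone-marrow (BM) samples of one or more
#' patients, one row per variant per timepoint. The PB sample hosts the CH
#' compartment; the BM sample is the tumor-enriched compartment.
#'
#' @slot data a `data.frame` with at least the columns
#'   `patient_id, timepoint, chrom, pos, ref, alt, gene, variant_class,
#'   pb_alt, pb_ref, bm_alt, bm_ref`. Extra columns (e.g. `protein_change`,
#'   `revalidated`) are preserved and used by downstream rules when present.
#' @exportClass PairedVariantSet
setClass("PairedVariantSet", representation(data = "data.frame"))

setValidity("PairedVariantSet", function(object) {
  d <- object@data
  missing <- setdiff(.VARIANT_COLS, names(d))
  if (length(missing))
    return(sprintf("missing required column(s): %s",
                   paste(missing, collapse = ", ")))
  msgs <- character()
  for (col in c("pb_alt", "pb_ref", "bm_alt", "bm_ref")) {
    bad <- which(!is.finite(d[[col]]) | d[[col]] < 0 | d[[col]] != round(d[[col]]))
    if (length(bad))
      msgs <- c(msgs, sprintf("column '%s': non-negative integer required at row(s) %s",
                              col, paste(utils::head(bad, 5), collapse = ", ")))
  }
  bad <- which(!is.finite(d$pos) | d$pos < 1)
  if (length(bad))
    msgs <- c(msgs, sprintf("'pos' must be >= 1 (1-based) at row(s) %s",
                            paste(utils::head(bad, 5), collapse = ", ")))
  bad <- which(!is.finite(d$timepoint) | d$timepoint < 0)
  if (length(bad))
    msgs <- c(msgs, sprintf("'timepoint' must be >= 0 at row(s) %s",
                            paste(utils::head(bad, 5), collapse = ", ")))
  bad <- which(!d$variant_class %in% .VARIANT_CLASSES)
  if (length(bad))
    msgs <- c(msgs, sprintf("unknown 'variant_class' at row(s) %s",
                            paste(utils::head(bad, 5), collapse = ", ")))
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Per-locus tumor context table
#'
#' Purity, ploidy, local allele-specific copy number, and tumor-in-normal
#' (TiN) fraction for each (patient, locus), as produced upstream by
#' ABSOLUTE-style and deTiN-style analyses.
#'
#' @slot data a `data.frame` with columns
#'   `patient_id, chrom, pos, purity, ploidy, cn_major, cn_minor, tin`.
#' @exportClass TumorContextTable
setClass("TumorContextTable", representation(data = "data.frame"))

setValidity("TumorContextTable", function(object) {
  d <- object@data
  missing <- setdiff(.CONTEXT_COLS, names(d))
  if (length(missing))
    return(sprintf("missing required column(s): %s",
                   paste(missing, collapse = ", ")))
  msgs <- character()
  if (any(d$purity < 0 | d$purity > 1, na.rm = TRUE))
    msgs <- c(msgs, "'purity' outside [0, 1]")
  if (any(d$tin < 0 | d$tin > 1, na.rm = TRUE))
    msgs <- c(msgs, "'tin' outside [0, 1]")
  if (any(d$ploidy <= 0, na.rm = TRUE))
    msgs <- c(msgs, "'ploidy' must be positive")
  if (any(d$cn_minor < 0 | d$cn_major < d$cn_minor, na.rm = TRUE))
    msgs <- c(msgs, "require cn_major >= cn_minor >= 0")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Candidate-filter configuration
#'
#' Thresholds and gene lists implementing the CH candidate-selection rules:
#' whitelist membership, a minimum number of supporting reads in PB, a
#' minimum PB VAF, and a maximum PB VAF from which canonical CH driver genes
#' are exempt (high-VAF variants in other genes usually being germline
#' polymorphisms).
#'
#' @slot minAltReads minimum PB alt reads to keep a call (calls with fewer
#'   supporting reads are discarded; default 4, i.e. 3 or fewer is rejected).
#' @slot minVaf minimum PB VAF (default 0.02).
#' @slot maxVaf maximum PB VAF for non-exempt genes (default 0.35).
#' @slot maxVafExemptGenes genes exempt from the `maxVaf` ceiling.
#' @slot whitelist data.frame of per-gene rules with columns
#'   `gene, rule_kind, detail, source`; `rule_kind` is one of
#'   `any`, `any_truncating`, `listed_missense_positions`, `hotspot_codon_set`.
#' @slot allowRevalidatedBelowMinVaf if `TRUE`, a variant carrying a truthy
#'   `revalidated` annotation is not rejected by the `minVaf` rule
#'   (per-variant override for manually re-counted events).
#' @exportClass FilterConfig
setClass("FilterConfig", representation(
  minAltReads = "numeric", minVaf = "numeric", maxVaf = "numeric",
  maxVafExemptGenes = "character", whitelist = "data.frame",
  allowRevalidatedBelowMinVaf = "logical"))

setValidity("FilterConfig", function(object) {
  msgs <- character()
  if (!(object@minVaf >= 0 && object@minVaf < object@maxVaf && object@maxVaf <= 1))
    msgs <- c(msgs, "require 0 <= minVaf < maxVaf <= 1")
  if (object@minAltReads < 1)
    msgs <- c(msgs, "minAltReads must be >= 1")
  need <- c("gene", "rule_kind", "detail")
  if (length(setdiff(need, names(object@whitelist))))
    msgs <- c(msgs, "whitelist needs columns gene, rule_kind, detail")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Prior probabilities over variant origin
#'
#' @slot pGermline,pTumor,pCH non-negative priors; normalized to sum to 1 by
#'   the constructor.
#' @exportClass ModelPriors
setClass("ModelPriors", representation(
  pGermline = "numeric", pTumor = "numeric", pCH = "numeric"))

setValidity("ModelPriors", function(object) {
  p <- c(object@pGermline, object@pTumor, object@pCH)
  if (any(p < 0)) return("priors must be non-negative")
  if (abs(sum(p) - 1) > 1e-12) return("priors must sum to 1")
  TRUE
})

#' Numerical integration control for the joint likelihoods
#'
#' @slot nodes Gauss-Legendre nodes per dimension (default 101).
#' @slot mode `"integrate"` marginalizes the nuisance clone fractions under a
#'   Uniform(0,1) prior; `"profile"` maximizes over them instead.
#' @slot minLog floor applied to log-densities to keep joint sums finite in
#'   impossible-evidence limits (default `-Inf`, i.e. no floor).
#' @exportClass IntegrationControl
setClass("IntegrationControl", representation(
  nodes = "integer", mode = "character", minLog = "numeric"))

setValidity("IntegrationControl", function(object) {
  if (object@nodes < 3) return("nodes must be >= 3")
  if (!object@mode %in% c("integrate", "profile"))
    return("mode must be 'integrate' or 'profile'")
  TRUE
})

#' Synthetic paired-cohort configuration
#'
#' Defines the generative conditions of a simulated cohort: per-label variant
#' counts, per-sample depth distributions, and the latent-parameter
#' distributions for each origin hypothesis. Defaults emulate a
#' myeloma-style paired WES cohort: sorted-marrow purity with median ~0.93,
#' ~113X coverage, CH clone VAF with median ~7% and mean ~11%, low TiN.
#'
#' @slot nVariantsPerLabel variants simulated per origin label.
#' @slot depthPB,depthBM `distSpec` for per-sample sequencing depth.
#' @slot purityDist,tinDist,chVafDist,tumorPsiDist,xBloodDist `distSpec`
#'   objects for tumor purity, TiN fraction, CH clone VAF theta, tumor
#'   alt-fraction psi (within tumor DNA), and the fraction x of BM non-cancer
#'   DNA that is blood-derived.
#' @slot cnvRate probability a locus carries a non-diploid allele-specific
#'   copy-number state.
#' @slot overdispersion beta-binomial overdispersion rho in [0,1); 0 means
#'   pure binomial read sampling.
#' @slot seed integer seed; fully determines the output.
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(
  nVariantsPerLabel = "integer", depthPB = "distSpec", depthBM = "distSpec",
  purityDist = "distSpec", tinDist = "distSpec", chVafDist = "distSpec",
  tumorPsiDist = "distSpec", xBloodDist = "distSpec", cnvRate = "numeric",
  overdispersion = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msgs <- c(
    if (object@nVariantsPerLabel < 0) "nVariantsPerLabel must be >= 0",
    .checkDistSpec(object@depthPB, "depthPB", 1),
    .checkDistSpec(object@depthBM, "depthBM", 1),
    .checkDistSpec(object@purityDist, "purityDist", 0, 1),
    .checkDistSpec(object@tinDist, "tinDist", 0, 0.1),
    .checkDistSpec(object@chVafDist, "chVafDist", 0, 1),
    .checkDistSpec(object@tumorPsiDist, "tumorPsiDist", 0, 0.6),
    .checkDistSpec(object@xBloodDist, "xBloodDist", 0, 1),
    if (object@cnvRate < 0 || object@cnvRate > 1) "cnvRate must be in [0,1]",
    if (object@overdispersion < 0 || object@overdispersion >= 1)
      "overdispersion must be in [0,1)")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
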