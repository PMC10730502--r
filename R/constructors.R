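#' Construct a PairedVariantSet from a data.frame
#'
#' @param data data.frame with the required variant columns (see
#'   [PairedVariantSet-class]).
#' @return a `PairedVariantSet`.
#' @examples
#' df <- data.frame(patient_id = "P1", timepoint = 0L, chrom = "2",
#'                  pos = 25234373L, ref = "C", alt = "T", gene = "DNMT3A",
#'                  variant_class = "missense", pb_alt = 8L, pb_ref = 92L,
#'                  bm_alt = 1L, bm_ref = 110L)
#' PairedVariantSet(df)
#' @export
PairedVariantSet <- function(data) {
  data <- as.data.frame(data)
  rownames(data) <- NULL
  new("PairedVariantSet", data = data)
}

#' Construct a TumorContextTable from a data.frame
#'
#' @param data data.frame with the required context columns (see
#'   [TumorContextTable-class]).
#' @return a `TumorContextTable`.
#' @export
TumorContextTable <- function(data) {
  data <- as.data.frame(data)
  rownames(data) <- NULL
  new("TumorContextTable", data = data)
}

#' Construct a FilterConfig
#'
#' Defaults implement the standard CH candidate-selection rules: at least 4
#' supporting PB reads, PB VAF in \[2%, 35%\] with the canonical CH driver
#' genes exempt from the 35% ceiling, membership in a CH driver whitelist,
#' and an opt-in override keeping explicitly re-validated sub-2% events.
#'
#' @param minAltReads,minVaf,maxVaf,maxVafExemptGenes,whitelist,allowRevalidatedBelowMinVaf
#'   see [FilterConfig-class].
#' @return a `FilterConfig`.
#' @export
FilterConfig <- function(minAltReads = 4,
                         minVaf = 0.02,
                         maxVaf = 0.35,
                         maxVafExemptGenes = c("DNMT3A", "TET2", "ASXL1",
                                               "PPM1D", "TP53", "JAK2",
                                               "SF3B1", "SRSF2"),
                         whitelist = defaultWhitelist(),
                         allowRevalidatedBelowMinVaf = TRUE) {
  new("FilterConfig", minAltReads = minAltReads, minVaf = minVaf,
      maxVaf = maxVaf, maxVafExemptGenes = maxVafExemptGenes,
      whitelist = whitelist,
      allowRevalidatedBelowMinVaf = allowRevalidatedBelowMinVaf)
}

#' Construct ModelPriors
#'
#' @param pGermline,pTumor,pCH non-negative weights; normalized to sum to 1.
#' @param preset `"uniform"` (default, 1/3 each: posteriors proportional to
#'   likelihoods) or `"frequency"` (germline-skewed, for sensitivity
#'   analysis: most rare variants genome-wide are germline).
#' @return a `ModelPriors`.
#' @export
ModelPriors <- function(pGermline = NULL, pTumor = NULL, pCH = NULL,
                        preset = c("uniform", "frequency")) {
  if (is.null(pGermline) && is.null(pTumor) && is.null(pCH)) {
    preset <- match.arg(preset)
    p <- switch(preset,
      uniform   = c(1, 1, 1) / 3,
      frequency = c(0.90, 0.05, 0.05))
  } else {
    p <- c(pGermline %||% 0, pTumor %||% 0, pCH %||% 0)
  }
  if (any(p < 0)) stop("priors must be non-negative")
  s <- sum(p)
  if (s <= 0) stop("priors must have positive sum")
  p <- p / s
  new("ModelPriors", pGermline = p[1], pTumor = p[2], pCH = p[3])
}

#' Construct an IntegrationControl
#'
#' @param nodes,mode,minLog see [IntegrationControl-class].
#' @return an `IntegrationControl`.
#' @export
IntegrationControl <- function(nodes = 101L,
                               mode = c("integrate", "profile"),
                               minLog = -Inf) {
  new("IntegrationControl", nodes = as.integer(nodes),
      mode = match.arg(mode), minLog = minLog)
}

#' Construct a SimulationConfig
#'
#' Defaults emulate a newly diagnosed myeloma paired-WES cohort: sorted BM
#' purity with median 0.93 (`Beta(9.55, 1)`), ~113X Poisson depth in both
#' samples, CH clone VAF with median 0.07 and mean ~0.11
#' (`Beta(0.691, 5.648)`), TiN concentrated below a few percent
#' (`0.1 * Beta(1, 9)`), tumor alt-fraction psi Uniform(0.05, 0.6), blood
#' fraction x of BM non-cancer DNA Uniform(0, 1), and a 20% rate of
#' non-diploid local copy-number states.
#'
#' @param nVariantsPerLabel variants per origin label (default 100).
#' @param depthPB,depthBM,purityDist,tinDist,chVafDist,tumorPsiDist,xBloodDist
#'   `distSpec` objects (see [distSpec]).
#' @param cnvRate,overdispersion,seed see [SimulationConfig-class].
#' @return a `SimulationConfig`.
#' @export
SimulationConfig <- function(nVariantsPerLabel = 100L,
                             depthPB = distSpec("poisson", lambda = 113, min = 20),
                             depthBM = distSpec("poisson", lambda = 113, min = 20),
                             purityDist = distSpec("beta", shape1 = 9.55, shape2 = 1),
                             tinDist = distSpec("beta", shape1 = 1, shape2 = 9, scale = 0.1),
                             chVafDist = distSpec("beta", shape1 = 0.691, shape2 = 5.648),
                             tumorPsiDist = distSpec("uniform", min = 0.05, max = 0.6),
                             xBloodDist = distSpec("uniform", min = 0, max = 1),
                             cnvRate = 0.2,
                             overdispersion = 0,
                             seed = 1L) {
  new("SimulationConfig", nVariantsPerLabel = as.integer(nVariantsPerLabel),
      depthPB = depthPB, depthBM = depthBM, purityDist = purityDist,
      tinDist = tinDist, chVafDist = chVafDist, tumorPsiDist = tumorPsiDist,
      xBloodDist = xBloodDist, cnvRate = cnvRate,
      overdispersion = overdispersion, seed = as.integer(seed))
}

#' @describeIn PairedVariantSet-class number of observations (rows).
#' @param x a `PairedVariantSet`.
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname PairedVariantSet-class
#' @export
setMethod("nVariants", "PairedVariantSet", function(x) nrow(x@data))

#' Extract the underlying data.frame of a variant set
#' @param x a `PairedVariantSet`.
#' @export
setGeneric("variantData", function(x) standardGeneric("variantData"))

#' @rdname variantData
#' @export
setMethod("variantData", "PairedVariantSet", function(x) x@data)

#' Extract the underlying data.frame of a tumor-context table
#' @param x a `TumorContextTable`.
#' @export
setGeneric("contextData", function(x) standardGeneric("contextData"))

#' @rdname contextData
#' @export
setMethod("contextData", "TumorContextTable", function(x) x@data)

#' Observed PB variant allele fraction, alt/(alt+ref)
#' @param x a `PairedVariantSet`.
#' @return numeric vector; `NaN` where PB depth is zero.
#' @export
setGeneric("pbVaf", function(x) standardGeneric("pbVaf"))

#' @rdname pbVaf
#' @export
setMethod("pbVaf", "PairedVariantSet", function(x)
  x@data$pb_alt / (x@data$pb_alt + x@data$pb_ref))

#' Observed BM variant allele fraction, alt/(alt+ref)
#' @param x a `PairedVariantSet`.
#' @return numeric vector; `NaN` where BM depth is zero.
#' @export
setGeneric("bmVaf", function(x) standardGeneric("bmVaf"))

#' @rdname bmVaf
#' @export
setMethod("bmVaf", "PairedVariantSet", function(x)
  x@data$bm_alt / (x@data$bm_alt + x@data$bm_ref))

#' Subset a PairedVariantSet by row
#' @param x a `PairedVariantSet`; `i` row index.
#' @rdname PairedVariantSet-class
#' @export
setMethod("[", "PairedVariantSet", function(x, i, j, ..., drop = FALSE) {
  PairedVariantSet(x@data[i, , drop = FALSE])
})

setMethod("show", "PairedVariantSet", function(object) {
  d <- object@data
  cat(sprintf("PairedVariantSet with %d observation(s), %d patient(s)\n",
              nrow(d), length(unique(d$patient_id))))
  if (nrow(d)) {
    cat(sprintf("  genes: %s\n",
                paste(utils::head(sort(unique(d$gene)), 8), collapse = ", ")))
    cat(sprintf("  timepoints: %s\n",
                paste(sort(unique(d$timepoint)), collapse = ", ")))
  }
})

setMethod("show", "TumorContextTable", function(object) {
  d <- object@data
  cat(sprintf("TumorContextTable with %d locus/loci, %d patient(s)\n",
              nrow(d), length(unique(d$patient_id))))
  if (nrow(d))
    cat(sprintf("  purity median %.3g; TiN median %.3g\n",
                stats::median(d$purity), stats::median(d$tin)))
})

setMethod("show", "FilterConfig", function(object) {
  cat(sprintf(paste0("FilterConfig: >=%d PB alt reads, PB VAF in [%.3g, %.3g]",
                     " (%d exempt gene(s) from ceiling), %d whitelist rule(s)\n"),
              object@minAltReads, object@minVaf, object@maxVaf,
              length(object@maxVafExemptGenes), nrow(object@whitelist)))
})

setMethod("show", "ModelPriors", function(object) {
  cat(sprintf("ModelPriors: germline %.4g, tumor %.4g, CH %.4g\n",
              object@pGermline, object@pTumor, object@pCH))
})

setMethod("show", "IntegrationControl", function(object) {
  cat(sprintf("IntegrationControl: %d Gauss-Legendre nodes/dim, mode '%s'\n",
              object@nodes, object@mode))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d variants/label, seed %d, cnvRate %.3g\n",
              object@nVariantsPerLabel, object@seed, object@cnvRate))
})
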