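#' Site-specific tumor-DNA fraction of a sample
#'
#' DNA-mass mixture form: a sample containing a cell fraction `cf` of tumor
#' cells with local total copy number `Ct` (and normal cells at copy number
#' `normalCn`, diploid by default) contains a tumor-DNA fraction of
#' `cf * Ct / (cf * Ct + normalCn * (1 - cf))`. Used with `cf = purity` for
#' the BM sample (`rho_bm`) and `cf = tin` for the PB sample (`rho_pb`).
#' At a homozygous deletion with `cf = 1` the denominator vanishes; the
#' fraction is then defined as 0 (no tumor DNA at the locus).
#'
#' @param cellFraction tumor cell fraction in `[0, 1]` (purity or TiN).
#' @param localCnTotal local total copy number in the tumor cells (>= 0).
#' @param normalCn copy number in normal cells (default 2).
#' @return tumor-DNA fraction in `[0, 1]`; vectorized.
#' @examples
#' tumorDnaFraction(0.93, 2)  # diploid locus: fraction equals purity
#' tumorDnaFraction(0.5, 4)   # amplified locus: 2/3
#' @export
tumorDnaFraction <- function(cellFraction, localCnTotal, normalCn = 2) {
  stopifnot(all(cellFraction >= 0 & cellFraction <= 1),
            all(localCnTotal >= 0), all(normalCn > 0))
  num <- cellFraction * localCnTotal
  den <- num + normalCn * (1 - cellFraction)
  out <- ifelse(den > 0, num / den, 0)
  as.numeric(out)
}

#' Germline allelic copy ratios at a locus
#'
#' The heterozygous germline allelic copy ratio `f` in the tumor cells is
#' the fraction of the locus's tumor DNA copies carrying one parental
#' allele; there are two possible values, one per parental allele. A locus
#' with total copy number 0 is degenerate and returns (0.5, 0.5) with a
#' flag.
#'
#' @param cnMajor,cnMinor allele-specific copy numbers (major >= minor >= 0).
#' @return list with `fMajor`, `fMinor` (summing to 1), and `flags`.
#' @examples
#' germlineAllelicRatios(2, 1)  # 2/3 and 1/3
#' @export
germlineAllelicRatios <- function(cnMajor, cnMinor) {
  stopifnot(cnMajor >= cnMinor, cnMinor >= 0)
  tot <- cnMajor + cnMinor
  if (tot <= 0)
    return(list(fMajor = 0.5, fMinor = 0.5, flags = "degenerate_cn"))
  list(fMajor = cnMajor / tot, fMinor = cnMinor / tot, flags = character())
}

#' Choose the allelic ratio closest to the observed BM VAF
#'
#' Of the two possible germline allelic ratios, picks the one whose
#' model-expected germline BM VAF, `(1 - rho_bm)/2 + rho_bm * f`, is closest
#' to the observed BM VAF; ties go to the major allele.
#'
#' @param fMajor,fMinor the two allelic ratios.
#' @param observedBmVaf observed BM alt/(alt+ref).
#' @param rhoBm site-specific tumor-DNA fraction in the BM sample.
#' @return the chosen `f`.
#' @export
chooseF <- function(fMajor, fMinor, observedBmVaf, rhoBm) {
  dMaj <- abs(expectedVafGermline(rhoBm, fMajor) - observedBmVaf)
  dMin <- abs(expectedVafGermline(rhoBm, fMinor) - observedBmVaf)
  if (dMin < dMaj) fMinor else fMajor
}

#' Both contamination fractions for one locus
#'
#' @param ctx locus context list or one row of a [TumorContextTable-class]
#'   data: needs `purity`, `tin`, `cn_major`, `cn_minor`.
#' @param tinMode `"site_specific"` (default) passes TiN through the same
#'   copy-number-aware mixture as purity; `"global"` uses the TiN value
#'   directly as `rho_pb`.
#' @param fractionFun the tumor-DNA fraction function; injectable so an
#'   alternative derivation can be swapped in.
#' @return list with `rhoPb`, `rhoBm`, `flags`.
#' @export
contaminationFractions <- function(ctx, tinMode = c("site_specific", "global"),
                                   fractionFun = tumorDnaFraction) {
  tinMode <- match.arg(tinMode)
  ct <- ctx$cn_major + ctx$cn_minor
  flags <- character()
  if (ct <= 0) flags <- c(flags, "homozygous_deletion")
  rhoBm <- fractionFun(ctx$purity, ct)
  rhoPb <- if (tinMode == "site_specific") fractionFun(ctx$tin, ct) else ctx$tin
  list(rhoPb = rhoPb, rhoBm = rhoBm, flags = flags)
}
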