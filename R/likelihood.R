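#' Beta log-likelihood of an underlying VAF given allele counts
#'
#' Observing `alt` alternate and `ref` reference reads, the likelihood of
#' the true underlying VAF `theta` is represented by a
#' `Beta(alt + 1, ref + 1)` density (the posterior under a flat prior on
#' `theta`), whose mode is the usual estimate `alt / (alt + ref)`. With no
#' reads at all the density is uniform and the log-density is 0 everywhere,
#' so a zero-depth sample contributes nothing to a joint model.
#'
#' @param theta VAF value(s) in `[0, 1]`.
#' @param alt,ref non-negative read counts.
#' @return log-density at `theta` (vectorized over `theta`); `-Inf` where
#'   the density is 0 (e.g. `theta = 0` with `alt > 0`).
#' @examples
#' betaLogDensity(0.5, 1, 1)  # log(1.5): Beta(2,2) density 6*t*(1-t)
#' @export
betaLogDensity <- function(theta, alt, ref) {
  stopifnot(alt >= 0, ref >= 0)
  if (any(theta < 0 | theta > 1)) stop("theta outside [0, 1]")
  stats::dbeta(theta, alt + 1, ref + 1, log = TRUE)
}

#' Expected germline VAF in a contaminated sample
#'
#' A heterozygous germline variant contributes VAF 0.5 from the sample's
#' normal DNA and the allelic copy ratio `f` from its tumor DNA:
#' `(1 - rho) * 0.5 + rho * f`, with `rho` the sample's site-specific
#' tumor-DNA fraction.
#'
#' @param rho tumor-DNA fraction in the sample (`rho_pb` or `rho_bm`).
#' @param f site-specific germline allelic copy ratio in the tumor cells.
#' @return expected VAF; vectorized.
#' @export
expectedVafGermline <- function(rho, f) (1 - rho) * 0.5 + rho * f

#' Expected VAF of a tumor mutation in a contaminated sample
#'
#' A tumor somatic mutation with alt fraction `psi` within tumor DNA is seen
#' in a sample only through that sample's tumor DNA: expected VAF
#' `rho * psi`. No clonality is assumed for `psi`.
#'
#' @param rho tumor-DNA fraction in the sample.
#' @param psi alt fraction of the mutation within tumor DNA, in `[0, 1]`.
#' @return expected VAF; vectorized.
#' @export
expectedVafTumor <- function(rho, psi) rho * psi

#' Expected VAF of a CH mutation in the BM sample
#'
#' The BM sample's non-cancer DNA fraction is `1 - rho_bm`, of which an
#' unknown fraction `x` is blood-derived and carries the CH clone at VAF
#' `theta`: expected BM VAF `x * (1 - rho_bm) * theta`. In the PB sample the
#' expected VAF under CH is `theta` itself.
#'
#' @param rhoBm tumor-DNA fraction in the BM sample.
#' @param x fraction of the BM non-cancer DNA that is blood-derived, in
#'   `[0, 1]`.
#' @param theta CH clone VAF in blood DNA.
#' @return expected BM VAF; vectorized.
#' @export
expectedVafChBm <- function(rhoBm, x, theta) x * (1 - rhoBm) * theta

#' Joint germline log-likelihood of a paired observation
#'
#' For each of the two possible allelic copy ratios `f`, sums the PB and BM
#' Beta log-densities at the model-expected germline VAFs and returns the
#' larger (profile over the parental allele), together with the selected
#' `f`; on an exact tie the major-allele ratio is reported.
#'
#' @param pbAlt,pbRef,bmAlt,bmRef paired allele counts.
#' @param rhoPb,rhoBm site-specific tumor-DNA fractions.
#' @param fMajor,fMinor the two allelic copy ratios at the locus.
#' @return list with `loglik` and `chosenF`.
#' @export
jointLogLikGermline <- function(pbAlt, pbRef, bmAlt, bmRef,
                                rhoPb, rhoBm, fMajor, fMinor) {
  ll <- function(f)
    betaLogDensity(expectedVafGermline(rhoPb, f), pbAlt, pbRef) +
    betaLogDensity(expectedVafGermline(rhoBm, f), bmAlt, bmRef)
  lMaj <- ll(fMajor)
  lMin <- ll(fMinor)
  if (lMin > lMaj) list(loglik = lMin, chosenF = fMinor)
  else list(loglik = lMaj, chosenF = fMajor)
}

# Marginalize (or profile) a vector of log-integrand values over Uniform(0,1)
# Gauss-Legendre nodes. `logw` are log node weights.
.logMarginal <- function(logvals, logw, mode) {
  if (mode == "profile") max(logvals) else logSumExp(logvals + logw)
}

#' Joint tumor log-likelihood of a paired observation
#'
#' The tumor model places the mutation in tumor DNA at unknown alt fraction
#' `psi` (clonality-free), giving expected VAFs `rho_pb * psi` in PB and
#' `rho_bm * psi` in BM. `psi` is marginalized under a Uniform(0, 1) prior
#' by Gauss-Legendre quadrature with log-sum-exp accumulation (or profiled,
#' per the control's `mode`).
#'
#' @param pbAlt,pbRef,bmAlt,bmRef paired allele counts.
#' @param rhoPb,rhoBm site-specific tumor-DNA fractions.
#' @param ctrl an [IntegrationControl-class].
#' @return log-likelihood (scalar; `-Inf` in impossible-evidence limits,
#'   e.g. `rho_bm = 0` with BM alt reads).
#' @export
jointLogLikTumor <- function(pbAlt, pbRef, bmAlt, bmRef, rhoPb, rhoBm,
                             ctrl = IntegrationControl()) {
  gl <- glNodes(ctrl@nodes)
  psi <- gl$x
  logvals <- betaLogDensity(expectedVafTumor(rhoPb, psi), pbAlt, pbRef) +
             betaLogDensity(expectedVafTumor(rhoBm, psi), bmAlt, bmRef)
  .logMarginal(logvals, log(gl$w), ctrl@mode)
}

#' Joint CH log-likelihood of a paired observation
#'
#' The CH model places the clone in blood DNA at unknown VAF `theta`
#' (expected PB VAF `theta`); the BM sample sees the clone only through its
#' blood-derived non-cancer DNA, at expected VAF
#' `x * (1 - rho_bm) * theta` with `x` unknown. Both `theta` and `x` are
#' marginalized under Uniform(0, 1) priors on a two-dimensional
#' Gauss-Legendre grid (or profiled, per the control's `mode`).
#'
#' @inheritParams jointLogLikTumor
#' @return log-likelihood (scalar).
#' @export
jointLogLikCh <- function(pbAlt, pbRef, bmAlt, bmRef, rhoBm,
                          ctrl = IntegrationControl()) {
  gl <- glNodes(ctrl@nodes)
  theta <- gl$x
  x <- gl$x
  logw <- log(gl$w)
  pbTerm <- betaLogDensity(theta, pbAlt, pbRef)           # over theta
  bmVaf <- outer(theta, x, function(t, xx) expectedVafChBm(rhoBm, xx, t))
  bmTerm <- matrix(betaLogDensity(as.vector(bmVaf), bmAlt, bmRef),
                   nrow = length(theta))
  logJoint <- bmTerm + pbTerm  # pbTerm recycles down columns (theta axis)
  if (ctrl@mode == "profile") return(max(logJoint))
  logSumExp(logJoint + outer(logw, logw, `+`))
}

#' All three joint log-likelihoods for one observation
#'
#' Convenience wrapper computing the germline, tumor, and CH joint
#' log-likelihoods at once from a locus context.
#'
#' @param pbAlt,pbRef,bmAlt,bmRef paired allele counts.
#' @param ctx locus context list (`purity`, `tin`, `cn_major`, `cn_minor`).
#' @param ctrl an [IntegrationControl-class].
#' @param tinMode see [contaminationFractions()].
#' @return list with `germline`, `tumor`, `ch`, `chosenF`, `rhoPb`,
#'   `rhoBm`, `flags`.
#' @export
jointLogLiks <- function(pbAlt, pbRef, bmAlt, bmRef, ctx,
                         ctrl = IntegrationControl(),
                         tinMode = c("site_specific", "global")) {
  fr <- contaminationFractions(ctx, match.arg(tinMode))
  ar <- germlineAllelicRatios(ctx$cn_major, ctx$cn_minor)
  g <- jointLogLikGermline(pbAlt, pbRef, bmAlt, bmRef,
                           fr$rhoPb, fr$rhoBm, ar$fMajor, ar$fMinor)
  t <- jointLogLikTumor(pbAlt, pbRef, bmAlt, bmRef, fr$rhoPb, fr$rhoBm, ctrl)
  c_ <- jointLogLikCh(pbAlt, pbRef, bmAlt, bmRef, fr$rhoBm, ctrl)
  list(germline = g$loglik, tumor = t, ch = c_, chosenF = g$chosenF,
       rhoPb = fr$rhoPb, rhoBm = fr$rhoBm,
       flags = c(fr$flags, ar$flags))
}
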