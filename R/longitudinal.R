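#' Fisher exact test for a clone-size change between two timepoints
#'
#' Two-sided exact test on the 2x2 table of (alt, ref) counts at two
#' timepoints, with the standard minimum-likelihood two-tailed definition
#' (sum of the probabilities of all tables, at fixed margins, no more
#' probable than the observed one).
#'
#' @param alt1,ref1 counts at the first timepoint (depth must be > 0).
#' @param alt2,ref2 counts at the second timepoint (depth must be > 0).
#' @return two-sided p-value.
#' @examples
#' fisherChangeTest(16, 84, 5, 95)  # a 16% clone dropping to 5% at depth 100
#' @export
fisherChangeTest <- function(alt1, ref1, alt2, ref2) {
  counts <- c(alt1, ref1, alt2, ref2)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (alt1 + ref1 <= 0 || alt2 + ref2 <= 0)
    stop("zero depth at a timepoint")
  stats::fisher.test(matrix(counts, nrow = 2, byrow = TRUE))$p.value
}

#' Label per-interval clone dynamics along a trajectory
#'
#' For each consecutive pair of timepoints, tests the (alt, ref) change
#' with [fisherChangeTest()] and labels the interval `shrink` (VAF
#' decreased, p < alpha), `expand` (VAF increased, p < alpha), or `stable`.
#'
#' @param trajectory data.frame with columns `timepoint, pb_alt, pb_ref`
#'   (one row per timepoint; sorted internally by `timepoint`).
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per interval: `from, to, vaf_from,
#'   vaf_to, p_value, direction`.
#' @export
classifyDynamics <- function(trajectory, alpha = 0.05) {
  tr <- trajectory[order(trajectory$timepoint), , drop = FALSE]
  if (nrow(tr) < 2) stop("need >= 2 timepoints")
  if (any(duplicated(tr$timepoint))) stop("timepoints must be distinct")
  vaf <- tr$pb_alt / (tr$pb_alt + tr$pb_ref)
  n <- nrow(tr) - 1L
  out <- data.frame(from = tr$timepoint[seq_len(n)],
                    to = tr$timepoint[seq_len(n) + 1L],
                    vaf_from = vaf[seq_len(n)], vaf_to = vaf[seq_len(n) + 1L],
                    p_value = NA_real_, direction = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    p <- fisherChangeTest(tr$pb_alt[i], tr$pb_ref[i],
                          tr$pb_alt[i + 1L], tr$pb_ref[i + 1L])
    out$p_value[i] <- p
    out$direction[i] <-
      if (p < alpha && out$vaf_to[i] < out$vaf_from[i]) "shrink"
      else if (p < alpha && out$vaf_to[i] > out$vaf_from[i]) "expand"
      else "stable"
  }
  out
}

#' Clone trajectories for all serial variants in a cohort
#'
#' Builds per-(patient, variant) VAF trajectories from a variant set with
#' multiple timepoints and labels every interval with [classifyDynamics()].
#'
#' @param cohort a [PairedVariantSet-class] containing serial observations.
#' @param alpha significance level for interval calls.
#' @return data.frame with one row per variant interval: key columns plus
#'   the [classifyDynamics()] columns. Variants seen at a single timepoint
#'   are omitted.
#' @export
cloneTrajectories <- function(cohort, alpha = 0.05) {
  d <- variantData(cohort)
  key <- interaction(d$patient_id, d$chrom, d$pos, d$alt, drop = TRUE)
  groups <- split(d, key)
  rows <- lapply(groups, function(g) {
    if (nrow(g) < 2) return(NULL)
    dyn <- classifyDynamics(g, alpha)
    cbind(data.frame(patient_id = g$patient_id[1], chrom = g$chrom[1],
                     pos = g$pos[1], alt = g$alt[1], gene = g$gene[1],
                     stringsAsFactors = FALSE)[rep(1, nrow(dyn)), ],
          dyn)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(patient_id = character(), chrom = character(),
                      pos = integer(), alt = character(), gene = character(),
                      from = integer(), to = integer(),
                      vaf_from = numeric(), vaf_to = numeric(),
                      p_value = numeric(), direction = character())
  rownames(out) <- NULL
  out
}

#' Detect emergent clones in serial samples
#'
#' An emergent clone is a variant that fails the candidate-selection rules
#' at baseline (timepoint 0) but passes them at a later timepoint; the
#' first passing timepoint is recorded.
#'
#' @param cohort a [PairedVariantSet-class] with serial observations.
#' @param cfg a [FilterConfig-class].
#' @return data.frame with key columns and `first_detected` (timepoint) for
#'   each emergent variant (possibly zero rows).
#' @export
emergentClones <- function(cohort, cfg = FilterConfig()) {
  d <- variantData(cohort)
  filt <- applyFilters(cohort, cfg)$audit
  d$pass <- filt$keep
  key <- interaction(d$patient_id, d$chrom, d$pos, d$alt, drop = TRUE)
  groups <- split(d, key)
  rows <- lapply(groups, function(g) {
    g <- g[order(g$timepoint), ]
    base <- g$pass[g$timepoint == 0]
    baseAbsent <- length(base) == 0 || !any(base)
    later <- g[g$timepoint > 0 & g$pass, , drop = FALSE]
    if (!baseAbsent || !nrow(later)) return(NULL)
    data.frame(patient_id = g$patient_id[1], chrom = g$chrom[1],
               pos = g$pos[1], alt = g$alt[1], gene = g$gene[1],
               first_detected = min(later$timepoint),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(patient_id = character(), chrom = character(),
                      pos = integer(), alt = character(), gene = character(),
                      first_detected = integer())
  rownames(out) <- NULL
  out
}

#' Exact test of CH prevalence against a population expectation
#'
#' Default: exact two-sided binomial test of `k` CH-positive out of `n`
#' patients against a reference proportion `p0` (e.g. the age-matched
#' general-population CH prevalence). When reference counts `refK`/`refN`
#' are supplied, a two-sided Fisher exact test of the 2x2 table
#' `[[k, n-k], [refK, refN-refK]]` is performed instead.
#'
#' @param k CH-positive patients in the cohort.
#' @param n cohort size.
#' @param p0 reference proportion in (0, 1) (ignored in Fisher mode).
#' @param refK,refN optional reference cohort counts enabling Fisher mode.
#' @return two-sided exact p-value.
#' @export
prevalenceVsExpectation <- function(k, n, p0 = 0.06,
                                    refK = NULL, refN = NULL) {
  stopifnot(k >= 0, k <= n)
  if (!is.null(refK) && !is.null(refN)) {
    stopifnot(refK >= 0, refK <= refN)
    return(stats::fisher.test(matrix(c(k, n - k, refK, refN - refK),
                                     nrow = 2, byrow = TRUE))$p.value)
  }
  stopifnot(p0 > 0, p0 < 1)
  stats::binom.test(k, n, p0)$p.value
}
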