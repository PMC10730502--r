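.LABELS <- c("germline", "tumor", "CH")

#' Classify one paired observation to CH, tumor, or germline
#'
#' Computes the three joint log-likelihoods, combines them with the priors
#' by log-sum-exp normalization, and assigns the label of the largest
#' posterior. Exact ties are broken in the fixed order
#' germline > tumor > CH and flagged `"tie"`.
#'
#' @param obs one observation: a single-row [PairedVariantSet-class], or a
#'   one-row data.frame/list with the variant columns.
#' @param ctx locus context list (`purity`, `tin`, `cn_major`, `cn_minor`,
#'   optionally `flags`), e.g. from [contextLookup()].
#' @param priors a [ModelPriors-class].
#' @param ctrl an [IntegrationControl-class].
#' @param tinMode see [contaminationFractions()].
#' @return one-row data.frame classification record with the observation
#'   key, the three log-likelihoods, normalized posteriors, `label`,
#'   `chosen_f`, and semicolon-joined `filter_flags`.
#' @examples
#' obs <- list(patient_id = "P1", timepoint = 0L, chrom = "2",
#'             pos = 25234373L, ref = "C", alt = "T", gene = "DNMT3A",
#'             variant_class = "missense", pb_alt = 10L, pb_ref = 90L,
#'             bm_alt = 0L, bm_ref = 100L)
#' ctx <- list(purity = 0.9, tin = 0, cn_major = 1, cn_minor = 1)
#' classifyVariant(obs, ctx, ModelPriors())$label  # "CH"
#' @export
classifyVariant <- function(obs, ctx, priors = ModelPriors(),
                            ctrl = IntegrationControl(),
                            tinMode = c("site_specific", "global")) {
  if (is(obs, "PairedVariantSet")) obs <- as.list(obs@data[1, ])
  if (obs$pb_alt + obs$pb_ref <= 0 && obs$bm_alt + obs$bm_ref <= 0)
    stop("no evidence: both PB and BM depths are zero")
  ll <- jointLogLiks(obs$pb_alt, obs$pb_ref, obs$bm_alt, obs$bm_ref,
                     ctx, ctrl, match.arg(tinMode))
  logPost <- log(c(priors@pGermline, priors@pTumor, priors@pCH)) +
    c(ll$germline, ll$tumor, ll$ch)
  norm <- logSumExp(logPost)
  if (!is.finite(norm))
    stop("all posteriors vanish: every model assigns zero likelihood")
  post <- exp(logPost - norm)
  best <- max(post)
  winners <- which(post == best)
  flags <- c(ctx$flags %||% character(), ll$flags)
  if (length(winners) > 1L) flags <- c(flags, "tie")
  label <- .LABELS[winners[1L]]   # fixed order germline > tumor > CH
  data.frame(
    patient_id = obs$patient_id, timepoint = obs$timepoint,
    chrom = obs$chrom, pos = obs$pos, ref = obs$ref, alt = obs$alt,
    gene = obs$gene,
    loglik_germline = ll$germline, loglik_tumor = ll$tumor,
    loglik_ch = ll$ch,
    posterior_germline = post[1], posterior_tumor = post[2],
    posterior_ch = post[3],
    label = label, chosen_f = ll$chosenF,
    filter_flags = paste(unique(flags), collapse = ";"),
    stringsAsFactors = FALSE)
}

#' Classify a cohort of paired observations
#'
#' Order-preserving, per-variant independent classification. A variant
#' whose locus is missing from the context table is classified with
#' documented defaults — purity equal to the cohort median of the supplied
#' contexts, TiN 0, balanced diploid copy number — and flagged
#' `"ctx_default"`, never dropped. Per-variant errors yield a flagged
#' record with `NA` label instead of aborting the batch.
#'
#' @param cohort a [PairedVariantSet-class].
#' @param contexts a [TumorContextTable-class].
#' @param priors a [ModelPriors-class].
#' @param ctrl an [IntegrationControl-class].
#' @param tinMode see [contaminationFractions()].
#' @return data.frame of classification records, one row per observation.
#' @export
classifyCohort <- function(cohort, contexts, priors = ModelPriors(),
                           ctrl = IntegrationControl(),
                           tinMode = c("site_specific", "global")) {
  tinMode <- match.arg(tinMode)
  d <- variantData(cohort)
  cd <- contextData(contexts)
  medPurity <- if (nrow(cd)) stats::median(cd$purity) else 0.9
  out <- vector("list", nrow(d))
  for (i in seq_len(nrow(d))) {
    obs <- as.list(d[i, ])
    ctx <- contextLookup(contexts, obs$patient_id, obs$chrom, obs$pos)
    if (is.null(ctx))
      ctx <- list(purity = medPurity, ploidy = 2, cn_major = 1, cn_minor = 1,
                  tin = 0, flags = "ctx_default")
    rec <- tryCatch(
      classifyVariant(obs, ctx, priors, ctrl, tinMode),
      error = function(e) data.frame(
        patient_id = obs$patient_id, timepoint = obs$timepoint,
        chrom = obs$chrom, pos = obs$pos, ref = obs$ref, alt = obs$alt,
        gene = obs$gene,
        loglik_germline = NA_real_, loglik_tumor = NA_real_,
        loglik_ch = NA_real_,
        posterior_germline = NA_real_, posterior_tumor = NA_real_,
        posterior_ch = NA_real_,
        label = NA_character_, chosen_f = NA_real_,
        filter_flags = paste0("error:", conditionMessage(e)),
        stringsAsFactors = FALSE))
    out[[i]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-timepoint classification consistency
#'
#' Groups classification records by (patient, chrom, pos, alt) and reports,
#' for every variant observed at two or more timepoints, whether its label
#' is identical across all of them.
#'
#' @param records data.frame of classification records
#'   (from [classifyCohort()]).
#' @return list with `perVariant` (data.frame: key, `n_timepoints`,
#'   `labels` joined by `/` in timepoint order, `consistent`) and
#'   `fractionConsistent` (over variants with >= 2 timepoints; `NaN` if
#'   none).
#' @export
timepointConsistency <- function(records) {
  key <- interaction(records$patient_id, records$chrom, records$pos,
                     records$alt, drop = TRUE)
  groups <- split(records, key)
  rows <- lapply(groups, function(g) {
    g <- g[order(g$timepoint), ]
    data.frame(patient_id = g$patient_id[1], chrom = g$chrom[1],
               pos = g$pos[1], alt = g$alt[1],
               n_timepoints = nrow(g),
               labels = paste(g$label, collapse = "/"),
               consistent = length(unique(g$label)) == 1L,
               stringsAsFactors = FALSE)
  })
  perVariant <- do.call(rbind, rows)
  rownames(perVariant) <- NULL
  serial <- perVariant[perVariant$n_timepoints >= 2, , drop = FALSE]
  list(perVariant = perVariant,
       fractionConsistent = mean(serial$consistent))
}

#' Summarize classification records
#'
#' Cohort-level summary of a classification run: label counts, per-class
#' variant counts, PB VAF summaries of the CH calls, top mutated genes
#' among CH calls, and the number of distinct patients with a CH call.
#'
#' @param records classification records (data.frame).
#' @param variants the matching [PairedVariantSet-class] (same order), used
#'   for observed VAFs and variant classes.
#' @return list with `labelCounts`, `chMedianVaf`, `chMeanVaf`,
#'   `chSnvCount`, `chFrameshiftMedianVaf`, `chGeneCounts`,
#'   `chPatientCount`.
#' @export
summarizeClassifications <- function(records, variants) {
  d <- variantData(variants)
  stopifnot(nrow(d) == nrow(records))
  vaf <- d$pb_alt / (d$pb_alt + d$pb_ref)
  isCh <- !is.na(records$label) & records$label == "CH"
  snv <- d$variant_class %in% c("missense", "nonsense", "splice_site")
  fs <- d$variant_class %in% c("frameshift_del", "frameshift_ins")
  list(
    labelCounts = table(factor(records$label, levels = .LABELS)),
    chMedianVaf = stats::median(vaf[isCh]),
    chMeanVaf = mean(vaf[isCh]),
    chSnvCount = sum(isCh & snv),
    chFrameshiftMedianVaf = stats::median(vaf[isCh & fs]),
    chGeneCounts = sort(table(d$gene[isCh]), decreasing = TRUE),
    chPatientCount = length(unique(d$patient_id[isCh])))
}
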