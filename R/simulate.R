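# Gene pools used by the generator. CH weights loosely follow the driver
# spectrum reported across CH cohorts (DNMT3A-dominated, then TET2/ASXL1).
.CH_GENES <- c(DNMT3A = 0.40, TET2 = 0.18, ASXL1 = 0.12, PPM1D = 0.09,
               TP53 = 0.08, JAK2 = 0.04, SF3B1 = 0.04, SRSF2 = 0.05)
.TUMOR_GENES <- c(KRAS = 0.35, NRAS = 0.35, TP53 = 0.15, BRAF = 0.15)

# Allele-specific copy-number states sampled at CNV loci.
.CNV_STATES <- list(c(1, 0), c(2, 0), c(2, 1), c(3, 1), c(2, 2), c(3, 2))

.rcounts <- function(n, depth, mu, overdispersion) {
  mu <- pmin(pmax(mu, 0), 1)
  if (overdispersion <= 0) return(stats::rbinom(n, depth, mu))
  od <- overdispersion
  p <- numeric(n)
  inner <- mu > 0 & mu < 1
  p[!inner] <- mu[!inner]
  if (any(inner)) {
    a <- mu[inner] * (1 - od) / od
    b <- (1 - mu[inner]) * (1 - od) / od
    p[inner] <- stats::rbeta(sum(inner), a, b)
  }
  stats::rbinom(n, depth, p)
}

.simClassAndProtein <- function(gene) {
  # pick a variant class (and protein annotation where hotspot rules need it)
  # so simulated CH/driver variants match the packaged whitelist rules
  truncating <- c("nonsense", "splice_site", "frameshift_del", "frameshift_ins")
  hotspot <- c(DNMT3A = "p.R882H", JAK2 = "p.V617F", SF3B1 = "p.K700E",
               SRSF2 = "p.P95H", KRAS = "p.G12D", NRAS = "p.Q61K",
               BRAF = "p.V600E", TP53 = "p.R175H")
  if (gene %in% c("TET2", "ASXL1", "PPM1D")) {
    cls <- sample(truncating, 1, prob = c(0.35, 0.25, 0.3, 0.1))
    list(class = cls, protein = NA_character_)
  } else if (gene == "DNMT3A") {
    if (stats::runif(1) < 0.5)
      list(class = "missense", protein = "p.R882H")
    else
      list(class = sample(truncating, 1), protein = NA_character_)
  } else if (gene %in% names(hotspot)) {
    list(class = "missense", protein = unname(hotspot[gene]))
  } else {
    list(class = "missense", protein = NA_character_)
  }
}

#' Simulate a paired PB/BM cohort with known origin labels
#'
#' Generates, for each variant: a tumor context (purity, TiN,
#' allele-specific copy number), the latent parameters of its true origin
#' (allelic ratio `f` for germline; alt fraction `psi` for tumor; clone VAF
#' `theta` and blood fraction `x` for CH), the model-expected PB/BM VAFs
#' computed with exactly the classification formulas
#' ([expectedVafGermline()], [expectedVafTumor()], [expectedVafChBm()]),
#' and binomial (optionally beta-binomial) read counts at the configured
#' depths. One simulated patient per variant. The seed fully determines the
#' output.
#'
#' @param cfg a [SimulationConfig-class].
#' @return list with `variants` ([PairedVariantSet-class]), `contexts`
#'   ([TumorContextTable-class]), and `truth` (data.frame with the label
#'   and latent parameters; never an input to classification).
#' @export
simulateCohort <- function(cfg) {
  validObject(cfg)
  n <- 3L * cfg@nVariantsPerLabel
  labels <- rep(c("germline", "tumor", "CH"), each = cfg@nVariantsPerLabel)
  if (n == 0L) {
    empty <- data.frame(patient_id = character(), timepoint = integer(),
                        chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        gene = character(), variant_class = character(),
                        pb_alt = integer(), pb_ref = integer(),
                        bm_alt = integer(), bm_ref = integer(),
                        protein_change = character())
    emptyCtx <- data.frame(patient_id = character(), chrom = character(),
                           pos = integer(), purity = numeric(),
                           ploidy = numeric(), cn_major = numeric(),
                           cn_minor = numeric(), tin = numeric())
    truth <- data.frame(patient_id = character(), chrom = character(),
                        pos = integer(), alt = character(),
                        label = character(), f = numeric(), psi = numeric(),
                        theta = numeric(), x = numeric(),
                        evaf_pb = numeric(), evaf_bm = numeric())
    return(list(variants = PairedVariantSet(empty),
                contexts = TumorContextTable(emptyCtx), truth = truth))
  }
  withSeed(cfg@seed, {
    patient <- sprintf("SIM_%05d", seq_len(n))
    chrom <- as.character(sample(1:22, n, replace = TRUE))
    pos <- sample.int(2e8, n)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")

    gene <- character(n)
    vclass <- character(n)
    protein <- character(n)
    for (i in seq_len(n)) {
      pool <- if (labels[i] == "tumor") .TUMOR_GENES else .CH_GENES
      gene[i] <- sample(names(pool), 1, prob = pool)
      cp <- .simClassAndProtein(gene[i])
      vclass[i] <- cp$class
      protein[i] <- cp$protein
    }
    # frameshift indels get explicit indel alleles
    isFs <- vclass %in% c("frameshift_del", "frameshift_ins")
    alt[isFs & vclass == "frameshift_ins"] <-
      paste0(ref[isFs & vclass == "frameshift_ins"], "A")
    ref[isFs & vclass == "frameshift_del"] <-
      paste0(ref[isFs & vclass == "frameshift_del"], "T")
    alt[isFs & vclass == "frameshift_del"] <-
      substr(ref[isFs & vclass == "frameshift_del"], 1, 1)

    purity <- drawDist(cfg@purityDist, n)
    tin <- drawDist(cfg@tinDist, n)
    hasCnv <- stats::runif(n) < cfg@cnvRate
    cnIdx <- sample.int(length(.CNV_STATES), n, replace = TRUE)
    cnMajor <- ifelse(hasCnv, vapply(cnIdx, function(k) .CNV_STATES[[k]][1], 0), 1)
    cnMinor <- ifelse(hasCnv, vapply(cnIdx, function(k) .CNV_STATES[[k]][2], 0), 1)
    cnTotal <- cnMajor + cnMinor
    ploidy <- 2 + (cnTotal - 2) * 0.1  # near-diploid genomes with focal events

    rhoBm <- tumorDnaFraction(purity, cnTotal)
    rhoPb <- tumorDnaFraction(tin, cnTotal)

    f <- psi <- theta <- x <- rep(NA_real_, n)
    evafPb <- evafBm <- numeric(n)
    for (i in seq_len(n)) {
      if (labels[i] == "germline") {
        ar <- germlineAllelicRatios(cnMajor[i], cnMinor[i])
        f[i] <- if (stats::runif(1) < 0.5) ar$fMajor else ar$fMinor
        evafPb[i] <- expectedVafGermline(rhoPb[i], f[i])
        evafBm[i] <- expectedVafGermline(rhoBm[i], f[i])
      } else if (labels[i] == "tumor") {
        psi[i] <- drawDist(cfg@tumorPsiDist, 1)
        evafPb[i] <- expectedVafTumor(rhoPb[i], psi[i])
        evafBm[i] <- expectedVafTumor(rhoBm[i], psi[i])
      } else {
        theta[i] <- drawDist(cfg@chVafDist, 1)
        x[i] <- drawDist(cfg@xBloodDist, 1)
        evafPb[i] <- theta[i]
        evafBm[i] <- expectedVafChBm(rhoBm[i], x[i], theta[i])
      }
    }

    depthPb <- drawDist(cfg@depthPB, n)
    depthBm <- drawDist(cfg@depthBM, n)
    pbAlt <- .rcounts(n, depthPb, evafPb, cfg@overdispersion)
    bmAlt <- .rcounts(n, depthBm, evafBm, cfg@overdispersion)

    variants <- data.frame(
      patient_id = patient, timepoint = 0L, chrom = chrom, pos = pos,
      ref = ref, alt = alt, gene = gene, variant_class = vclass,
      pb_alt = pbAlt, pb_ref = as.integer(depthPb) - pbAlt,
      bm_alt = bmAlt, bm_ref = as.integer(depthBm) - bmAlt,
      protein_change = protein, stringsAsFactors = FALSE)
    contexts <- data.frame(
      patient_id = patient, chrom = chrom, pos = pos, purity = purity,
      ploidy = ploidy, cn_major = cnMajor, cn_minor = cnMinor, tin = tin,
      stringsAsFactors = FALSE)
    truth <- data.frame(
      patient_id = patient, chrom = chrom, pos = pos, alt = alt,
      label = labels, f = f, psi = psi, theta = theta, x = x,
      evaf_pb = evafPb, evaf_bm = evafBm, stringsAsFactors = FALSE)
    list(variants = PairedVariantSet(variants),
         contexts = TumorContextTable(contexts), truth = truth)
  })
}

#' Simulate serial PB/BM samples with evolving CH clones
#'
#' Starts from [simulateCohort()] and adds later timepoints. The CH clone
#' VAF `theta` evolves multiplicatively per interval (truncated to
#' `[0, 0.5]`); germline and tumor expected VAFs are held fixed. Read
#' counts and depths are redrawn independently at every timepoint.
#'
#' @param cfg a [SimulationConfig-class].
#' @param growthRates positive per-interval multiplier(s) for CH clone
#'   VAFs, recycled over the CH variants.
#' @param nTimepoints number of timepoints including baseline (default 2).
#' @return list with `variants` (a [PairedVariantSet-class] containing all
#'   timepoints), `contexts`, and `truth` (one row per variant per
#'   timepoint, with the evolving `theta`).
#' @export
simulateLongitudinal <- function(cfg, growthRates = 1.5, nTimepoints = 2L) {
  stopifnot(all(growthRates > 0), nTimepoints >= 1)
  base <- simulateCohort(cfg)
  d0 <- variantData(base$variants)
  truth0 <- base$truth
  n <- nrow(d0)
  if (n == 0L || nTimepoints == 1L)
    return(list(variants = base$variants, contexts = base$contexts,
                truth = cbind(truth0, timepoint = rep(0L, nrow(truth0)))))
  isCh <- truth0$label == "CH"
  growth <- rep_len(growthRates, sum(isCh))
  varList <- list(d0)
  truthList <- list(cbind(truth0, timepoint = 0L))
  withSeed(cfg@seed + 1L, {
    theta <- truth0$theta
    for (t in seq_len(nTimepoints - 1L)) {
      theta[isCh] <- pmin(0.5, pmax(0, theta[isCh] * growth))
      evafPb <- truth0$evaf_pb
      evafBm <- truth0$evaf_bm
      ctx <- contextData(base$contexts)
      rhoBm <- tumorDnaFraction(ctx$purity, ctx$cn_major + ctx$cn_minor)
      evafPb[isCh] <- theta[isCh]
      evafBm[isCh] <- expectedVafChBm(rhoBm[isCh], truth0$x[isCh], theta[isCh])
      depthPb <- drawDist(cfg@depthPB, n)
      depthBm <- drawDist(cfg@depthBM, n)
      pbAlt <- .rcounts(n, depthPb, evafPb, cfg@overdispersion)
      bmAlt <- .rcounts(n, depthBm, evafBm, cfg@overdispersion)
      dt <- d0
      dt$timepoint <- t
      dt$pb_alt <- pbAlt
      dt$pb_ref <- as.integer(depthPb) - pbAlt
      dt$bm_alt <- bmAlt
      dt$bm_ref <- as.integer(depthBm) - bmAlt
      varList[[t + 1L]] <- dt
      tt <- truth0
      tt$theta <- theta
      tt$evaf_pb <- evafPb
      tt$evaf_bm <- evafBm
      truthList[[t + 1L]] <- cbind(tt, timepoint = t)
    }
  })
  allVar <- do.call(rbind, varList)
  allTruth <- do.call(rbind, truthList)
  rownames(allVar) <- rownames(allTruth) <- NULL
  list(variants = PairedVariantSet(allVar), contexts = base$contexts,
       truth = allTruth)
}
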