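cfg <- FilterConfig()

test_that("supporting-read rule rejects calls with 3 or fewer alt reads", {
  obs <- makeObs(3, 97, 0, 100, gene = "TET2", variant_class = "nonsense")
  dec <- evaluateCandidate(obs, cfg)
  expect_false(dec$keep)
  expect_true("min_alt_reads" %in% dec$reasons)
  # 4 supporting reads passes that rule (VAF 4% also passes)
  dec4 <- evaluateCandidate(makeObs(4, 96, 0, 100, gene = "TET2",
                                    variant_class = "nonsense"), cfg)
  expect_true(dec4$keep)
})

test_that("VAF ceiling applies except for exempt driver genes", {
  highNonExempt <- makeObs(40, 60, 0, 100, gene = "GNB1",
                           variant_class = "missense",
                           protein_change = "p.K57E")
  dec <- evaluateCandidate(highNonExempt, cfg)
  expect_false(dec$keep)
  expect_identical(dec$reasons, "max_vaf")

  highDnmt3a <- makeObs(40, 60, 0, 100, gene = "DNMT3A",
                        variant_class = "missense",
                        protein_change = "p.R882H")
  expect_true(evaluateCandidate(highDnmt3a, cfg)$keep)
})

test_that("minimum-VAF rule fires below 2% unless revalidated", {
  low <- makeObs(3, 297, 0, 100, gene = "TET2", variant_class = "nonsense")
  dec <- evaluateCandidate(low, cfg)
  expect_setequal(dec$reasons, c("min_alt_reads", "min_vaf"))

  # the per-variant revalidation override lifts only the VAF rule
  reval <- makeObs(5, 495, 0, 100, gene = "TET2",
                   variant_class = "nonsense", revalidated = TRUE)
  expect_true(evaluateCandidate(reval, cfg)$keep)
  cfgStrict <- FilterConfig(allowRevalidatedBelowMinVaf = FALSE)
  expect_false(evaluateCandidate(reval, cfgStrict)$keep)
})

test_that("non-whitelisted variants are excluded with all reasons reported", {
  obs <- makeObs(2, 98, 0, 100, gene = "TTN", variant_class = "missense")
  dec <- evaluateCandidate(obs, cfg)
  expect_false(dec$keep)
  expect_setequal(dec$reasons, c("not_whitelisted", "min_alt_reads"))
  expect_error(evaluateCandidate(makeObs(0, 0, 10, 90), cfg), "no PB coverage")
})

test_that("codon rules need protein annotation to match", {
  hot <- makeObs(10, 90, 0, 100, gene = "JAK2", variant_class = "missense",
                 protein_change = "p.V617F")
  expect_true(evaluateCandidate(hot, cfg)$keep)
  noAnno <- makeObs(10, 90, 0, 100, gene = "JAK2", variant_class = "missense")
  expect_true("not_whitelisted" %in% evaluateCandidate(noAnno, cfg)$reasons)
})

test_that("applyFilters handles empty input and all-pass identity", {
  empty <- PairedVariantSet(exampleVariantDf(3)[0, ])
  res <- applyFilters(empty, cfg)
  expect_equal(nVariants(res$kept), 0L)
  expect_equal(nrow(res$audit), 0L)

  allPass <- PairedVariantSet(exampleVariantDf(4))
  res <- applyFilters(allPass, cfg)
  expect_identical(variantData(res$kept), variantData(allPass))
  # idempotence
  res2 <- applyFilters(res$kept, cfg)
  expect_identical(variantData(res2$kept), variantData(res$kept))
})

test_that("audit reason counts equal planted violation counts", {
  set.seed(42)
  blocks <- list(
    pass       = list(n = 40, pb_alt = 10L, pb_ref = 90L, gene = "DNMT3A"),
    low_reads  = list(n = 15, pb_alt = 3L, pb_ref = 47L, gene = "TET2"),
    low_vaf    = list(n = 15, pb_alt = 6L, pb_ref = 594L, gene = "ASXL1"),
    high_vaf   = list(n = 15, pb_alt = 45L, pb_ref = 55L, gene = "GNB1"),
    not_listed = list(n = 15, pb_alt = 10L, pb_ref = 90L, gene = "TTN"))
  rows <- lapply(names(blocks), function(nm) {
    b <- blocks[[nm]]
    cls <- if (b$gene %in% c("TET2", "ASXL1")) "nonsense"
           else "missense"
    pc <- if (b$gene == "DNMT3A") "p.R882H"
          else if (b$gene == "GNB1") "p.K57E" else NA_character_
    data.frame(patient_id = paste0(nm, seq_len(b$n)), timepoint = 0L,
               chrom = "1", pos = seq_len(b$n), ref = "A", alt = "T",
               gene = b$gene, variant_class = cls,
               pb_alt = b$pb_alt, pb_ref = b$pb_ref,
               bm_alt = 0L, bm_ref = 100L, protein_change = pc,
               stringsAsFactors = FALSE)
  })
  cohort <- PairedVariantSet(do.call(rbind, rows))
  res <- applyFilters(cohort, cfg)
  expect_equal(sum(res$audit$keep), 40)
  expect_equal(sum(grepl("min_alt_reads", res$audit$reasons)), 15)
  expect_equal(sum(grepl("min_vaf", res$audit$reasons)), 15)
  expect_equal(sum(grepl("max_vaf", res$audit$reasons)), 15)
  expect_equal(sum(grepl("not_whitelisted", res$audit$reasons)), 15)
})

test_that("raising min_vaf or shrinking exemptions never grows the kept set", {
  set.seed(11)
  n <- 60
  df <- data.frame(patient_id = paste0("P", 1:n), timepoint = 0L, chrom = "1",
                   pos = 1:n, ref = "A", alt = "T",
                   gene = sample(c("DNMT3A", "TET2", "GNB1"), n, TRUE),
                   variant_class = "nonsense",
                   pb_alt = rbinom(n, 100, runif(n, 0.01, 0.6)),
                   bm_alt = 0L, bm_ref = 100L, stringsAsFactors = FALSE)
  df$pb_ref <- 100L - df$pb_alt
  df$pb_alt <- as.integer(df$pb_alt)
  cohort <- PairedVariantSet(df)
  keptAt <- function(cfg) variantData(applyFilters(cohort, cfg)$kept)$patient_id
  base <- keptAt(FilterConfig())
  stricterVaf <- keptAt(FilterConfig(minVaf = 0.10))
  fewerExempt <- keptAt(FilterConfig(maxVafExemptGenes = "DNMT3A"))
  expect_true(all(stricterVaf %in% base))
  expect_true(all(fewerExempt %in% base))
})
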