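test_that("regime exemplars classify to the expected origins", {
  ctx <- diploidCtx(purity = 0.9, tin = 0)
  expect_equal(classifyVariant(makeObs(10, 90, 0, 100), ctx)$label, "CH")
  expect_equal(classifyVariant(makeObs(50, 50, 50, 50), ctx)$label, "germline")
  expect_equal(classifyVariant(makeObs(0, 100, 40, 60), ctx)$label, "tumor")
})

test_that("posteriors are normalized and match the maximal label", {
  ctx <- diploidCtx()
  rec <- classifyVariant(makeObs(12, 88, 2, 110), ctx)
  post <- c(rec$posterior_germline, rec$posterior_tumor, rec$posterior_ch)
  expect_equal(sum(post), 1, tolerance = 1e-9)
  lab <- c("germline", "tumor", "CH")[which.max(post)]
  expect_identical(rec$label, lab)
  expect_error(classifyVariant(makeObs(0, 0, 0, 0), ctx), "no evidence")
})

test_that("posteriors are invariant to priors scaling and loglik shifts", {
  ctx <- diploidCtx()
  obs <- makeObs(8, 92, 1, 99)
  a <- classifyVariant(obs, ctx, ModelPriors(1, 1, 1))
  b <- classifyVariant(obs, ctx, ModelPriors(10, 10, 10))
  expect_equal(a$posterior_ch, b$posterior_ch, tolerance = 1e-12)
})

test_that("raising the CH prior strictly raises the CH posterior", {
  # strict monotonicity is checked where the posterior is representable
  # away from 0/1 in double precision (it saturates for well-separated data)
  set.seed(31)
  ctx <- diploidCtx()
  interior <- 0
  for (i in 1:40) {
    depth <- sample(15:60, 1)
    obs <- makeObs(rbinom(1, depth, runif(1, 0.05, 0.5)), depth,
                   rbinom(1, depth, runif(1, 0, 0.5)), depth)
    lo <- classifyVariant(obs, ctx, ModelPriors(0.4, 0.4, 0.2))
    hi <- classifyVariant(obs, ctx, ModelPriors(0.3, 0.3, 0.4))
    if (lo$posterior_ch > 1e-9 && lo$posterior_ch < 1 - 1e-9) {
      interior <- interior + 1
      expect_gt(hi$posterior_ch, lo$posterior_ch)
    } else {
      expect_gte(hi$posterior_ch, lo$posterior_ch)
    }
  }
  expect_gt(interior, 10)
})

test_that("cohort classification is order-equivariant and singleton-consistent", {
  sim <- simulateCohort(SimulationConfig(nVariantsPerLabel = 4, seed = 9))
  rec <- classifyCohort(sim$variants, sim$contexts)
  one <- classifyVariant(sim$variants[1],
                         contextLookup(sim$contexts,
                                       variantData(sim$variants)$patient_id[1],
                                       variantData(sim$variants)$chrom[1],
                                       variantData(sim$variants)$pos[1]))
  expect_equal(rec[1, ], one, ignore_attr = TRUE)

  perm <- sample(nrow(rec))
  recPerm <- classifyCohort(sim$variants[perm], sim$contexts)
  expect_equal(recPerm, rec[perm, ], ignore_attr = TRUE)
})

test_that("missing context falls back to flagged cohort defaults", {
  df <- exampleVariantDf(2)
  ctx <- TumorContextTable(data.frame(
    patient_id = "P1", chrom = "1", pos = 100L, purity = 0.85, ploidy = 2,
    cn_major = 1, cn_minor = 1, tin = 0.02))
  rec <- classifyCohort(PairedVariantSet(df), ctx)
  expect_false(grepl("ctx_default", rec$filter_flags[1]))
  expect_true(grepl("ctx_default", rec$filter_flags[2]))
  expect_false(any(is.na(rec$label)))
})

test_that("per-variant failures are flagged, not fatal", {
  df <- exampleVariantDf(2)
  df$pb_alt[2] <- 0L; df$pb_ref[2] <- 0L
  df$bm_alt[2] <- 0L; df$bm_ref[2] <- 0L
  ctx <- TumorContextTable(data.frame(
    patient_id = df$patient_id, chrom = df$chrom, pos = df$pos,
    purity = 0.9, ploidy = 2, cn_major = 1, cn_minor = 1, tin = 0))
  rec <- classifyCohort(PairedVariantSet(df), ctx)
  expect_equal(nrow(rec), 2)
  expect_false(is.na(rec$label[1]))
  expect_true(is.na(rec$label[2]))
  expect_true(grepl("error:", rec$filter_flags[2]))
})

test_that("label recovery improves with depth under a fixed seed family", {
  acc <- sapply(c(50, 100, 500), function(depth) {
    cfg <- SimulationConfig(
      nVariantsPerLabel = 60, seed = 7,
      depthPB = distSpec("fixed", value = depth),
      depthBM = distSpec("fixed", value = depth),
      purityDist = distSpec("fixed", value = 0.9),
      tinDist = distSpec("fixed", value = 0.01),
      chVafDist = distSpec("uniform", min = 0.05, max = 0.3))
    sim <- simulateCohort(cfg)
    rec <- classifyCohort(sim$variants, sim$contexts)
    mean(rec$label == sim$truth$label)
  })
  expect_true(all(diff(acc) >= 0))
  expect_gt(acc[1], 0.8)
})

test_that("serial classifications are consistent and reported per variant", {
  cfg <- SimulationConfig(
    nVariantsPerLabel = 7, seed = 21,
    depthPB = distSpec("fixed", value = 200),
    depthBM = distSpec("fixed", value = 200),
    purityDist = distSpec("fixed", value = 0.9),
    tinDist = distSpec("fixed", value = 0.01),
    chVafDist = distSpec("uniform", min = 0.05, max = 0.3))
  ser <- simulateLongitudinal(cfg, growthRates = 1.0, nTimepoints = 2)
  rec <- classifyCohort(ser$variants, ser$contexts)
  cons <- timepointConsistency(rec)
  expect_equal(nrow(cons$perVariant), 21)
  expect_true(all(cons$perVariant$n_timepoints == 2))
  expect_equal(cons$fractionConsistent, 1)

  # a forced label flip is reported as inconsistent
  rec2 <- rec
  flip <- which(rec2$timepoint == 1)[1]
  rec2$label[flip] <- setdiff(c("CH", "tumor", "germline"),
                              rec2$label[flip])[1]
  cons2 <- timepointConsistency(rec2)
  expect_lt(cons2$fractionConsistent, 1)
})

test_that("classification summary reflects constructed labels", {
  sim <- simulateCohort(SimulationConfig(nVariantsPerLabel = 25, seed = 5))
  rec <- classifyCohort(sim$variants, sim$contexts)
  s <- summarizeClassifications(rec, sim$variants)
  expect_equal(sum(s$labelCounts), nrow(rec))
  expect_equal(unname(s$labelCounts["CH"]), sum(rec$label == "CH"))
  vaf <- pbVaf(sim$variants)[rec$label == "CH"]
  expect_equal(s$chMedianVaf, median(vaf))
  expect_lte(s$chPatientCount, sum(rec$label == "CH"))
})
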