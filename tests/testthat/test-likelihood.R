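test_that("Beta VAF log-density matches hand-derived values", {
  # no reads: uniform density, log 1 = 0 everywhere
  expect_equal(betaLogDensity(c(0.1, 0.5, 0.9), 0, 0), c(0, 0, 0))
  # Beta(2,1) density 2*theta
  expect_equal(betaLogDensity(0.5, 1, 0), log(2 * 0.5))
  # Beta(2,2) density 6*theta*(1-theta)
  expect_equal(betaLogDensity(0.5, 1, 1), log(1.5))
  # mode at alt/(alt+ref)
  th <- seq(0.01, 0.99, by = 0.001)
  expect_equal(th[which.max(betaLogDensity(th, 30, 70))], 0.3)
  expect_error(betaLogDensity(1.2, 3, 4), "theta")
  # log-space stability at very high depth
  expect_true(is.finite(betaLogDensity(0.5, 5000, 5000)))
})

test_that("expected-VAF formulas reproduce the mixture arithmetic", {
  expect_equal(expectedVafGermline(0, 0.9), 0.5)
  expect_equal(expectedVafGermline(1, 2 / 3), 2 / 3)
  expect_equal(expectedVafGermline(0.93, 1 / 3), 0.07 * 0.5 + 0.93 / 3)
  expect_equal(expectedVafTumor(0, 0.7), 0)
  expect_equal(expectedVafTumor(0.02, 0.5), 0.01)
  expect_equal(expectedVafTumor(0.93, 0.5), 0.465)
  expect_equal(expectedVafChBm(0.9, 0, 0.3), 0)
  expect_equal(expectedVafChBm(1, 0.8, 0.3), 0)    # pure-tumor marrow
  expect_equal(expectedVafChBm(0.93, 1, 0.10), 0.07 * 0.10)
})

test_that("germline joint likelihood profiles over the two allelic ratios", {
  # balanced diploid, no contamination: both f give expected VAF 0.5
  g <- jointLogLikGermline(50, 50, 50, 50, 0, 0, 0.5, 0.5)
  expect_equal(g$loglik, 2 * betaLogDensity(0.5, 50, 50))
  expect_equal(g$chosenF, 0.5)
  # cn (2,1) with rho_bm = 1: BM VAF 0.3 fits f = 1/3 better
  g2 <- jointLogLikGermline(48, 52, 30, 70, 0, 1, 2 / 3, 1 / 3)
  lMin <- betaLogDensity(0.5, 48, 52) + betaLogDensity(1 / 3, 30, 70)
  lMaj <- betaLogDensity(0.5, 48, 52) + betaLogDensity(2 / 3, 30, 70)
  expect_equal(g2$loglik, max(lMin, lMaj))
  expect_equal(g2$chosenF, 1 / 3)
  # zero BM depth: BM term is flat, PB drives the value
  g3 <- jointLogLikGermline(50, 50, 0, 0, 0, 0.9, 0.6, 0.4)
  expect_equal(g3$loglik,
               max(betaLogDensity(0.5, 50, 50) + 0,
                   betaLogDensity(0.5, 50, 50) + 0))
})

test_that("tumor marginal matches a fine-grid Riemann oracle", {
  cases <- list(
    list(10, 90, 45, 55, 0.02, 0.9),
    list(0, 100, 30, 70, 0, 0.93),    # PB term constant (rho_pb 0, no alt)
    list(3, 97, 52, 48, 0.05, 0.8))
  for (cs in cases) {
    got <- jointLogLikTumor(cs[[1]], cs[[2]], cs[[3]], cs[[4]],
                            cs[[5]], cs[[6]])
    oracle <- riemannTumorLogLik(cs[[1]], cs[[2]], cs[[3]], cs[[4]],
                                 cs[[5]], cs[[6]])
    expect_equal(got, oracle, tolerance = 1e-6)
  }
})

test_that("impossible-evidence limits give -Inf tumor likelihood", {
  # rho_bm = 0 but BM alt reads exist: tumor model cannot explain them
  expect_identical(jointLogLikTumor(5, 95, 10, 90, 0, 0), -Inf)
  # symmetry: swapping the two samples with equal rho swaps nothing
  a <- jointLogLikTumor(7, 93, 20, 80, 0.4, 0.4)
  b <- jointLogLikTumor(20, 80, 7, 93, 0.4, 0.4)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("CH double integral matches a nested Riemann oracle", {
  got <- jointLogLikCh(10, 90, 0, 100, rhoBm = 0.9)
  oracle <- riemannChLogLik(10, 90, 0, 100, 0.9, n = 1000L)
  expect_equal(got, oracle, tolerance = 1e-4)
  # pure-tumor marrow with BM alt reads: CH cannot explain them
  chPure <- jointLogLikCh(10, 90, 5, 95, rhoBm = 1)
  tmPure <- jointLogLikTumor(10, 90, 5, 95, 0.1, 1)
  expect_lt(chPure, tmPure - 10)
  # clean-marrow CH beats tumor when blood carries the clone and tin = 0
  ch <- jointLogLikCh(10, 90, 0, 100, rhoBm = 0.9)
  tm <- jointLogLikTumor(10, 90, 0, 100, 0, 0.9)
  expect_gt(ch, tm)
})

test_that("quadrature is converged at the default resolution", {
  obs <- list(c(12, 88, 3, 97), c(5, 195, 40, 60), c(30, 70, 0, 113))
  for (o in obs) {
    c1 <- IntegrationControl(nodes = 101)
    c2 <- IntegrationControl(nodes = 202)
    expect_equal(jointLogLikTumor(o[1], o[2], o[3], o[4], 0.03, 0.9, c1),
                 jointLogLikTumor(o[1], o[2], o[3], o[4], 0.03, 0.9, c2),
                 tolerance = 1e-6)
    expect_equal(jointLogLikCh(o[1], o[2], o[3], o[4], 0.9, c1),
                 jointLogLikCh(o[1], o[2], o[3], o[4], 0.9, c2),
                 tolerance = 1e-6)
  }
})

test_that("profile mode upper-bounds the integrated marginal", {
  intg <- IntegrationControl(mode = "integrate")
  prof <- IntegrationControl(mode = "profile")
  expect_gt(jointLogLikTumor(10, 90, 40, 60, 0.02, 0.9, prof),
            jointLogLikTumor(10, 90, 40, 60, 0.02, 0.9, intg))
  expect_gt(jointLogLikCh(10, 90, 2, 98, 0.9, prof),
            jointLogLikCh(10, 90, 2, 98, 0.9, intg))
})

test_that("deeper data separates the true model more strongly", {
  # Average loglik margin of the true (CH) model over tumor grows with depth
  set.seed(202)
  margin <- sapply(c(50, 200), function(depth) {
    m <- replicate(120, {
      theta <- runif(1, 0.05, 0.2)
      pbA <- rbinom(1, depth, theta)
      bmA <- rbinom(1, depth, 0.05 * theta)  # x*(1-rho_bm)=0.05
      jointLogLikCh(pbA, depth - pbA, bmA, depth - bmA, 0.95) -
        jointLogLikTumor(pbA, depth - pbA, bmA, depth - bmA, 0.01, 0.95)
    })
    mean(m)
  })
  expect_true(all(margin > 0))
  expect_gt(margin[2], margin[1])
})
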