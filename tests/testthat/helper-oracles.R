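# Independent numerical oracles. These deliberately avoid the package's own
# quadrature/log-sum-exp code paths: plain midpoint Riemann sums and direct
# enumeration, computed with base R only.

.lse <- function(v) {
  m <- max(v)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(v - m)))
}

# log integral over psi in (0,1) of Beta-likelihood product, midpoint rule
riemannTumorLogLik <- function(pbAlt, pbRef, bmAlt, bmRef, rhoPb, rhoBm,
                               n = 2000L) {
  psi <- (seq_len(n) - 0.5) / n
  v <- dbeta(rhoPb * psi, pbAlt + 1, pbRef + 1, log = TRUE) +
       dbeta(rhoBm * psi, bmAlt + 1, bmRef + 1, log = TRUE)
  .lse(v) - log(n)
}

# log double integral over (theta, x) in (0,1)^2, midpoint rule
riemannChLogLik <- function(pbAlt, pbRef, bmAlt, bmRef, rhoBm, n = 2000L) {
  g <- (seq_len(n) - 0.5) / n
  pb <- dbeta(g, pbAlt + 1, pbRef + 1, log = TRUE)        # over theta (rows)
  bmv <- outer(g * (1 - rhoBm), g)                        # theta_i * x_j
  v <- matrix(dbeta(as.vector(bmv), bmAlt + 1, bmRef + 1, log = TRUE),
              nrow = n) + pb
  .lse(v) - 2 * log(n)
}

# Two-sided Fisher p for [[a, b], [c, d]] by hypergeometric enumeration:
# sum of probabilities of all tables with the observed margins that are no
# more probable than the observed table.
fisherEnumOracle <- function(a, b, c, d) {
  n1 <- a + b
  K <- a + c
  N <- a + b + c + d
  support <- max(0, K - (N - n1)):min(K, n1)
  probs <- dhyper(support, K, N - K, n1)
  pObs <- dhyper(a, K, N - K, n1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Two-sided exact binomial p by direct pmf enumeration (minlike convention)
binomEnumOracle <- function(k, n, p0) {
  probs <- dbinom(0:n, n, p0)
  pObs <- probs[k + 1]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one-observation constructor used across tests
makeObs <- function(pb_alt, pb_ref, bm_alt, bm_ref, gene = "DNMT3A",
                    variant_class = "missense", patient_id = "P1",
                    timepoint = 0L, pos = 1000L, ...) {
  c(list(patient_id = patient_id, timepoint = timepoint, chrom = "1",
         pos = pos, ref = "A", alt = "T", gene = gene,
         variant_class = variant_class, pb_alt = pb_alt, pb_ref = pb_ref,
         bm_alt = bm_alt, bm_ref = bm_ref), list(...))
}

diploidCtx <- function(purity = 0.9, tin = 0, cn_major = 1, cn_minor = 1)
  list(purity = purity, tin = tin, cn_major = cn_major, cn_minor = cn_minor)

# small well-formed variant data.frame
exampleVariantDf <- function(n = 3) {
  data.frame(
    patient_id = paste0("P", seq_len(n)), timepoint = 0L,
    chrom = as.character(seq_len(n)), pos = 100L * seq_len(n),
    ref = "A", alt = "T", gene = "DNMT3A", variant_class = "nonsense",
    pb_alt = 5L + seq_len(n), pb_ref = 95L, bm_alt = 0L, bm_ref = 100L,
    stringsAsFactors = FALSE)
}
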