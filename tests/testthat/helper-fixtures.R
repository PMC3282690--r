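# Fit skeletons with prescribed MLEs and confidence intervals, bypassing
# HMM fitting, so clustering can be exercised in isolation.
fitWithCi <- function(id, k12, k21, sdLog12, sdLog21, level = 0.90) {
  z <- qnorm((1 + level) / 2)
  p <- hmmParams(twoStateMatrix(k12, k21), mu = c(100, 150))
  ci <- list(
    "A[1,2]" = list(param = "A[1,2]", level = level, mode = "conditional",
                    mle = k12, lo = 10^(log10(k12) - z * sdLog12),
                    hi = 10^(log10(k12) + z * sdLog12),
                    clippedLo = FALSE, clippedHi = FALSE),
    "A[2,1]" = list(param = "A[2,1]", level = level, mode = "conditional",
                    mle = k21, lo = 10^(log10(k21) - z * sdLog21),
                    hi = 10^(log10(k21) + z * sdLog21),
                    clippedLo = FALSE, clippedHi = FALSE))
  new("HmmFit", spec = modelSpec("2-state", 2), params = p, loglik = -1,
      nIter = 1L, converged = TRUE, degenerate = FALSE,
      posteriors = matrix(numeric(0), 0, 2), restartsUsed = 1L,
      loglikTrace = -1, traceId = id, ci = ci)
}

# A synthetic population: true log10-rates drawn around per-population
# centers with known per-trace measurement sd.
syntheticInput <- function(n, centers, sdLog, seed) {
  set.seed(seed)
  pop <- rep(seq_len(nrow(centers)), length.out = n)
  fits <- lapply(seq_len(n), function(i) {
    l12 <- rnorm(1, centers[pop[i], 1], sdLog)
    l21 <- rnorm(1, centers[pop[i], 2], sdLog)
    fitWithCi(paste0("s", i), 10^l12, 10^l21, sdLog, sdLog)
  })
  list(input = buildClusterInput(fits, c("A[1,2]", "A[2,1]")), pop = pop)
}
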