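makeFit <- function(traceId, spec, loglik, params = NULL) {
  if (is.null(params)) {
    K <- spec@K
    A <- if (K == 1) matrix(1, 1, 1) else {
      A <- matrix(0.1 / (K - 1), K, K); diag(A) <- 0.9; A
    }
    params <- hmmParams(A, mu = seq(100, by = 50, length.out = K))
  }
  new("HmmFit", spec = spec, params = params, loglik = loglik,
      nIter = 1L, converged = TRUE, degenerate = FALSE,
      posteriors = matrix(numeric(0), 0, spec@K), restartsUsed = 1L,
      loglikTrace = loglik, traceId = traceId, ci = list())
}

test_that("BIC evaluates the exact formula", {
  tr <- newTrace("b1", rpois(1000, 50))
  fit <- makeFit("b1", modelSpec("2-state", 2), loglik = -100)  # k = 4
  b <- bicScore(fit, tr)
  expect_equal(b$bic, 200 + 4 * log(1000), tolerance = 1e-10)
  expect_equal(b$bic, 227.6310, tolerance = 1e-4)
  expect_equal(b$k, 4L)
  expect_equal(b$N, 1000L)
  # short traces rejected
  expect_error(bicScore(makeFit("s", modelSpec("1-state", 1), -1),
                        newTrace("s", 5)), "fewer than 2")
})

test_that("equal-likelihood models differ by the parameter penalty", {
  tr <- newTrace("b2", rpois(100, 50))
  f2 <- makeFit("b2", modelSpec("2-state", 2), loglik = -50)   # k = 4
  cyc <- makeFit("b2", builtinModels()[["3-cycle"]], loglik = -50) # k = 9
  expect_equal(bicScore(cyc, tr)$bic - bicScore(f2, tr)$bic,
               5 * log(100), tolerance = 1e-10)
})

test_that("selectModel ranks by BIC with deterministic tie-breaking", {
  tr <- newTrace("r1", rpois(500, 50))
  m <- builtinModels()
  fits <- list(makeFit("r1", m[["1-state"]], -1210),
               makeFit("r1", m[["2-state"]], -1150),
               makeFit("r1", m[["3-linear"]], -1149))
  rank <- selectModel(fits, tr)
  expect_equal(rank$model[1], "2-state")
  expect_equal(rank$deltaBic[1], 0)
  expect_true(all(diff(rank$bic) >= 0))
  # single-model menu
  one <- selectModel(fits[1], tr)
  expect_equal(nrow(one), 1L)
  expect_equal(one$deltaBic, 0)
  # tie: same bic achieved with loglik compensating k -> smaller k first
  lA <- -100
  lB <- lA - (countFreeParameters(m[["3-cycle"]]) -
              countFreeParameters(m[["2-state"]])) * log(500) / -2
  tie <- selectModel(list(makeFit("r1", m[["3-cycle"]], lB),
                          makeFit("r1", m[["2-state"]], lA)), tr)
  expect_equal(tie$model[1], "2-state")
  # mismatched trace ids are rejected
  expect_error(selectModel(list(makeFit("other", m[["1-state"]], -1)), tr),
               "same trace")
})

test_that("BIC ranking is invariant to state relabeling of a fit", {
  p <- hmmParams(twoStateMatrix(0.3, 0.1), mu = c(100, 150))
  tr <- simulateTrace(simConfig(p, snr = 5, T = 400,
                                lengthMode = "fixed"), seed = 10)
  fit <- fitHmm(tr, modelSpec("2-state", 2), nRestarts = 1)
  perm <- c(2, 1)
  pp <- fittedParams(fit)
  permParams <- new("HmmParams", A = pp@A[perm, perm],
                    mu = pp@mu[perm, , drop = FALSE],
                    sd = pp@sd[perm, , drop = FALSE],
                    pi0 = pp@pi0[perm], families = pp@families)
  fitPerm <- fit
  fitPerm@params <- permParams
  fitPerm@loglik <- logLikelihood(tr, permParams)
  expect_equal(bicScore(fitPerm, tr)$bic, bicScore(fit, tr)$bic,
               tolerance = 1e-8)
})

test_that("extra states raise likelihood but can raise BIC too", {
  p <- hmmParams(twoStateMatrix(0.2, 0.2), mu = c(100, meansForSnr(5, 100)))
  tr <- simulateTrace(simConfig(p, snr = 5, T = 1500,
                                lengthMode = "fixed"), seed = 19)
  m <- builtinModels()
  f2 <- fitHmm(tr, m[["2-state"]], nRestarts = 2, seed = 1)
  f3 <- fitHmm(tr, m[["3-cycle"]], nRestarts = 2, seed = 1)
  expect_gte(f3@loglik, f2@loglik - 0.1)
  expect_gt(bicScore(f3, tr)$bic, bicScore(f2, tr)$bic)
})
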