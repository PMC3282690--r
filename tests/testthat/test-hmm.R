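test_that("forward recursion matches brute-force path enumeration", {
  for (seed in 1:20) {
    inst <- randomSmallInstance(seed)
    expect_equal(logLikelihood(inst$trace, inst$params),
                 bruteLoglik(inst$trace, inst$params),
                 tolerance = 1e-9)
  }
})

test_that("smoothing posteriors match brute-force marginals", {
  for (seed in 21:32) {
    inst <- randomSmallInstance(seed)
    post <- posteriorStateProbs(inst$trace, inst$params)
    expect_equal(post, brutePosteriors(inst$trace, inst$params),
                 tolerance = 1e-9)
    expect_equal(rowSums(post), rep(1, traceLength(inst$trace)),
                 tolerance = 1e-10)
  }
})

test_that("one-state likelihood reduces to the iid Poisson log-pmf", {
  x <- c(4, 7, 5, 9, 6)
  tr <- newTrace("k1", x)
  p <- hmmParams(matrix(1, 1, 1), mu = 6)
  expect_equal(logLikelihood(tr, p), sum(dpois(x, 6, log = TRUE)),
               tolerance = 1e-12)
  expect_true(all(posteriorStateProbs(tr, p) == 1))
})

test_that("likelihood is invariant under joint state relabeling", {
  inst <- randomSmallInstance(55, maxK = 3)
  p <- inst$params
  K <- nrow(p@A)
  if (K > 1) {
    perm <- rev(seq_len(K))
    pPerm <- new("HmmParams", A = p@A[perm, perm],
                 mu = p@mu[perm, , drop = FALSE],
                 sd = p@sd[perm, , drop = FALSE], pi0 = p@pi0[perm],
                 families = p@families)
    expect_equal(logLikelihood(inst$trace, p),
                 logLikelihood(inst$trace, pPerm), tolerance = 1e-10)
  }
})

test_that("posterior decoding recovers the true path at high SNR", {
  p <- hmmParams(twoStateMatrix(0.1, 0.1),
                 mu = c(100, meansForSnr(12, 100)))
  sim <- simulateTrace(simConfig(p, snr = 12, c = 1e4), seed = 31,
                       returnStates = TRUE)
  post <- posteriorStateProbs(sim$trace, p)
  decoded <- max.col(post)
  expect_gt(mean(decoded == sim$states), 0.99)
})

test_that("Baum-Welch log-likelihood is non-decreasing and converges", {
  p <- hmmParams(twoStateMatrix(0.3, 0.3), mu = c(100, meansForSnr(5, 100)))
  cfg <- simConfig(p, snr = 5, c = 1e4)
  for (seed in 1:5) {
    tr <- simulateTrace(cfg, seed = seed)
    fit <- fitHmm(tr, modelSpec("2-state", 2), nRestarts = 2, seed = seed)
    expect_true(fit@converged)
    expect_true(all(diff(fit@loglikTrace) >= -1e-8))
    expect_equal(rowSums(posteriorMatrix(fit)),
                 rep(1, traceLength(tr)), tolerance = 1e-8)
  }
})

test_that("initializing at the truth stays near the truth", {
  p <- hmmParams(twoStateMatrix(0.3, 0.3), mu = c(100, meansForSnr(5, 100)))
  tr <- simulateTrace(simConfig(p, snr = 5, c = 1e4), seed = 77)
  fit <- fitHmm(tr, modelSpec("2-state", 2), nRestarts = 1, init = p)
  expect_true(all(diff(fit@loglikTrace) >= -1e-8))
  expect_gte(fit@loglik, logLikelihood(tr, p) - 1e-6)
  expect_lt(abs(fittedParams(fit)@A[1, 2] - 0.3), 0.05)
  expect_lt(abs(fittedParams(fit)@mu[1, 1] - 100) / 100, 0.02)
})

test_that("richer models never fit worse (nesting, up to restart noise)", {
  p <- hmmParams(twoStateMatrix(0.2, 0.1), mu = c(100, 130))
  tr <- simulateTrace(simConfig(p, snr = 3, T = 800,
                                lengthMode = "fixed"), seed = 9)
  m <- builtinModels()
  ll <- sapply(c("1-state", "2-state", "3-cycle", "3-thermo"),
               function(nm) fitHmm(tr, m[[nm]], nRestarts = 2,
                                   seed = 4)@loglik)
  expect_gte(ll["2-state"], ll["1-state"] - 1e-6)
  expect_gte(ll["3-cycle"], ll["2-state"] - 0.1)   # restart slack
  expect_gte(ll["3-cycle"], ll["3-thermo"] - 0.1)  # constraint nests
})

test_that("transition probabilities recover the truth at moderate SNR", {
  p <- hmmParams(twoStateMatrix(0.1, 0.1), mu = c(100, meansForSnr(4, 100)))
  cfg <- simConfig(p, snr = 4, c = 1e4, nTraces = 40)
  set <- simulateTraces(cfg, seed = 101)
  two <- modelSpec("2-state", 2)
  relErr <- sapply(traces(set), function(tr) {
    A <- fittedParams(fitHmm(tr, two, nRestarts = 2, seed = 5))@A
    abs(c(A[1, 2], A[2, 1]) - 0.1) / 0.1
  })
  expect_lt(median(relErr), 0.15)
})

test_that("topology zeros are preserved through fitting", {
  gen <- smtrace:::threeLinearParams(4, 100, 0.1)
  tr <- simulateTrace(simConfig(gen, snr = 4, c = 8e3), seed = 12)
  lin <- builtinModels()[["3-linear"]]
  A <- fittedParams(fitHmm(tr, lin, nRestarts = 2, seed = 2))@A
  expect_equal(A[1, 3], 0)
  expect_equal(A[3, 1], 0)
})

test_that("detailed-balance fits satisfy the stationary-flux symmetry", {
  gen <- smtrace:::threeLinearParams(4, 100, 0.1)
  thermo <- builtinModels()[["3-thermo"]]
  for (seed in c(3, 14)) {
    tr <- simulateTrace(simConfig(gen, snr = 4, c = 8e3), seed = seed)
    fit <- fitHmm(tr, thermo, nRestarts = 1, seed = seed)
    A <- fittedParams(fit)@A
    pi <- stationaryDistribution(A)
    expect_lt(max(abs(pi * A - t(pi * A))), 1e-8)
    expect_true(all(diff(fit@loglikTrace) >= -1e-8))
  }
})

test_that("tied emission states share their fitted parameters", {
  p <- hmmParams(twoStateMatrix(0.15, 0.15), mu = c(100, 150))
  tr <- simulateTrace(simConfig(p, snr = 4, T = 500,
                                lengthMode = "fixed"), seed = 6)
  tied <- modelSpec("2-tied", 2, tieGroups = list(c(1L, 1L)))
  fit <- fitHmm(tr, tied, nRestarts = 1)
  mu <- fittedParams(fit)@mu
  expect_equal(mu[1, 1], mu[2, 1])
  expect_true(fit@degenerate)  # identical emissions flagged
})

test_that("an all-constant trace yields a flagged degenerate fit", {
  tr <- newTrace("const", rep(100, 50))
  fit <- fitHmm(tr, modelSpec("2-state", 2), nRestarts = 1)
  expect_true(fit@degenerate)
  expect_s4_class(fit, "HmmFit")
})

test_that("too-short traces and channel mismatches are rejected", {
  expect_error(fitHmm(newTrace("tiny", 5), modelSpec("2-state", 2)),
               "T < 2")
  p2 <- hmmParams(twoStateMatrix(0.1, 0.1),
                  mu = cbind(c(10, 20), c(20, 10)),
                  families = c("poisson", "poisson"))
  tr1 <- newTrace("onech", rpois(20, 10))
  expect_error(logLikelihood(tr1, p2), "channel")
})

test_that("fixed parameters are honored by the M-step", {
  p <- hmmParams(twoStateMatrix(0.3, 0.3), mu = c(100, 144))
  tr <- simulateTrace(simConfig(p, snr = 5, T = 1000,
                                lengthMode = "fixed"), seed = 3)
  fit <- fitHmm(tr, modelSpec("2-state", 2), nRestarts = 1,
                fixedParams = list("A[1,2]" = 0.25))
  expect_equal(fittedParams(fit)@A[1, 2], 0.25, tolerance = 1e-12)
  expect_equal(rowSums(fittedParams(fit)@A), c(1, 1), tolerance = 1e-10)
  fitMu <- fitHmm(tr, modelSpec("2-state", 2), nRestarts = 1,
                  fixedParams = list("mu[1,1]" = 90))
  expect_equal(fittedParams(fitMu)@mu[1, 1], 90)
})

test_that("gaussian emission fits recover means and spreads", {
  p <- hmmParams(twoStateMatrix(0.1, 0.1), mu = c(0, 5),
                 sd = c(1, 1), families = "gaussian")
  tr <- simulateTrace(simConfig(p, snr = 5, T = 3000,
                                lengthMode = "fixed"), seed = 44)
  spec <- modelSpec("2-gauss", 2, families = "gaussian")
  fit <- fitHmm(tr, spec, nRestarts = 2)
  est <- fittedParams(fit)
  expect_lt(abs(est@mu[1, 1] - 0), 0.1)
  expect_lt(abs(est@mu[2, 1] - 5), 0.1)
  expect_lt(abs(est@sd[1, 1] - 1), 0.1)
  expect_lt(abs(est@A[1, 2] - 0.1), 0.03)
})
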