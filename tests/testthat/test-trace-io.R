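test_that("trace TSV format round-trips, including awkward metadata", {
  for (seed in c(11, 12, 13)) {
    set <- randomTraceSet(seed)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeTraces(set, path)
    back <- readTraces(path)
    expectTraceSetsEqual(set, back)
  }
})

test_that("a minimal one-trace file parses to the expected shape", {
  tr <- newTrace("m1", matrix(1:10, 5, 2), dt = 0.05)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTraces(traceSet(list(tr)), path)
  back <- readTraces(path)
  expect_equal(length(back), 1L)
  expect_equal(dim(intensities(back[["m1"]])), c(5L, 2L))
  expect_equal(samplingInterval(back[["m1"]]), 0.05)
})

test_that("simulated Poisson counts round-trip bit-exact", {
  p <- hmmParams(twoStateMatrix(0.2, 0.2), mu = c(100, 150))
  set <- simulateTraces(simConfig(p, snr = 4, T = 100,
                                  lengthMode = "fixed", nTraces = 20),
                        seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTraces(set, path)
  back <- readTraces(path)
  for (i in seq_len(20))
    expect_identical(intensities(back[[i]]), intensities(set[[i]]))
})

test_that("malformed files are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# dt=1", "1"), path)              # no trace_id first
  expect_error(readTraces(path), "line 1")

  writeLines(c("# trace_id=a", "# channels=1", "1", "2"), path)
  expect_error(readTraces(path), "missing dt")

  writeLines(c("# trace_id=a", "# dt=1", "# channels=1", "1", "2",
               "# trace_id=a", "# dt=1", "# channels=1", "3", "4"), path)
  expect_error(readTraces(path), "duplicate trace id.*a")

  writeLines(c("# trace_id=neg", "# dt=1", "# channels=1", "5", "-2"),
             path)
  expect_error(readTraces(path, poissonChannels = 1),
               "negative intensity.*Poisson")
})

test_that("empty TraceSet writes a valid (empty) file", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTraces(traceSet(), path)
  expect_equal(length(readTraces(path)), 0L)
})

test_that("duplicate ids are rejected at construction", {
  tr <- newTrace("dup", 1:5)
  expect_error(traceSet(list(tr, tr)), "duplicate trace ids: dup")
})

test_that("selectTraces filters on metadata and fitted parameters", {
  set <- traceSet(lapply(1:6, function(i)
    newTrace(paste0("t", i), rpois(10, 50),
             metadata = list(experiment_id = ifelse(i <= 3, "X", "Y")))))
  # identity and empty selections
  expect_equal(traceIds(selectTraces(set, ~ TRUE)), traceIds(set))
  expect_equal(length(selectTraces(set, ~ experiment_id == "Z")), 0L)
  # unknown key names the key
  expect_error(selectTraces(set, ~ nonesuch > 1), "nonesuch")

  # range criterion over attached fits equals a brute-force filter
  set.seed(42)
  k12s <- runif(6, 0, 0.3)
  fits <- lapply(1:6, function(i) {
    p <- hmmParams(twoStateMatrix(k12s[i], 0.1), mu = c(10, 20))
    new("HmmFit", spec = modelSpec("2-state", 2), params = p,
        loglik = -1, nIter = 1L, converged = TRUE, degenerate = FALSE,
        posteriors = matrix(numeric(0), 0, 2), restartsUsed = 1L,
        loglikTrace = -1, traceId = paste0("t", i), ci = list())
  })
  got <- traceIds(selectTraces(set, ~ k12 >= 0.05 & k12 <= 0.2,
                               fits = fits))
  want <- paste0("t", which(k12s >= 0.05 & k12s <= 0.2))
  expect_identical(got, want)

  # sequential filtering equals the conjunction
  a <- selectTraces(selectTraces(set, ~ experiment_id == "X", fits = fits),
                    ~ k12 <= 0.2, fits = fits)
  b <- selectTraces(set, ~ experiment_id == "X" & k12 <= 0.2, fits = fits)
  expect_identical(traceIds(a), traceIds(b))
})

test_that("fit results JSON round-trips parameters and intervals", {
  p <- hmmParams(twoStateMatrix(0.25, 0.1), mu = c(100, 150))
  tr <- simulateTrace(simConfig(p, snr = 5, T = 300,
                                lengthMode = "fixed"), seed = 8)
  fit <- fitHmm(tr, modelSpec("2-state", 2), nRestarts = 1)
  fit <- addConfidenceIntervals(tr, fit, "A[1,2]")
  path <- withr::local_tempfile(fileext = ".json")
  writeFitResults(list(fit), path, set = traceSet(list(tr)))
  back <- readFitResults(path)[[traceId(tr)]]
  expect_equal(fittedParams(back)@A, fittedParams(fit)@A, tolerance = 1e-12)
  expect_equal(fitLogLik(back), fitLogLik(fit), tolerance = 1e-12)
  expect_equal(confidenceIntervals(back)[["A[1,2]"]]$lo,
               fit@ci[["A[1,2]"]]$lo, tolerance = 1e-12)
  expect_identical(back@spec@name, "2-state")
})
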