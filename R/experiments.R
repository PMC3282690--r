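# Shared setup for the simulation studies: a two-state Poisson model at
# a given SNR with photobleaching-coupled trace length (T * SNR = c).
twoStateConfig <- function(snr, p12, p21, mu1, c, nTraces) {
  mu2 <- meansForSnr(snr, mu1)
  params <- hmmParams(twoStateMatrix(p12, p21), mu = c(mu1, mu2))
  simConfig(params, snr = snr, c = c, nTraces = nTraces)
}

#' SNR sweep: HMM versus thresholding
#'
#' Regenerates the benchmark comparing the two estimators across a grid
#' of signal-to-noise ratios with trace length inversely proportional to
#' SNR (photobleaching, `T * SNR = c`).  At each SNR, traces are
#' simulated from a two-state model, rates are inferred by a two-state
#' HMM fit and by threshold analysis (threshold at the midpoint of the
#' generating means), and a 1-state versus 2-state BIC comparison
#' records how often kinetic information is recoverable at all.
#'
#' @param snrGrid numeric vector of SNRs.
#' @param nPerSnr traces per grid point.
#' @param p12,p21 generating per-step transition probabilities.
#' @param mu1 low-state Poisson mean.
#' @param c photobleaching constant.
#' @param seed integer seed.
#' @param nRestarts,maxIter passed to [fitHmm()].
#' @return list with `config` and `table`: per SNR, the mean and 5-95%
#'   spread of HMM and threshold `k12` estimates, the mean transition
#'   count, and the fraction of traces whose BIC prefers two states.
#' @export
runSnrSweep <- function(snrGrid = c(0.5, 1, 2, 5, 10, 30),
                        nPerSnr = 50L, p12 = 0.3, p21 = 0.3, mu1 = 100,
                        c = 1e4, seed = 1L, nRestarts = 2L,
                        maxIter = 300L) {
  one <- modelSpec("1-state", 1L)
  two <- modelSpec("2-state", 2L)
  rows <- lapply(seq_along(snrGrid), function(gi) {
    snr <- snrGrid[gi]
    cfg <- twoStateConfig(snr, p12, p21, mu1, c, nPerSnr)
    set <- simulateTraces(cfg, seed = traceSeed(seed, gi))
    thr <- (mu1 + meansForSnr(snr, mu1)) / 2
    hmmK <- numeric(0); thrK <- numeric(0); twoState <- logical(0)
    nTransTrue <- numeric(0)
    for (tr in traces(set)) {
      f2 <- fitHmm(tr, two, nRestarts = nRestarts, maxIter = maxIter,
                   seed = seed)
      f1 <- fitHmm(tr, one, nRestarts = 1L, maxIter = maxIter,
                   seed = seed)
      rank <- selectModel(list(f1, f2), tr)
      twoState <- c(twoState, rank$model[1] == "2-state")
      hmmK <- c(hmmK, f2@params@A[1, 2])
      tf <- tryCatch(thresholdFit(tr, threshold = thr),
                     error = function(e) NULL)
      if (!is.null(tf) && !tf@excluded) thrK <- c(thrK, tf@p12)
    }
    data.frame(snr = snr, n = nPerSnr,
               hmmMeanK12 = mean(hmmK),
               hmmLo = quantile(hmmK, 0.05, names = FALSE),
               hmmHi = quantile(hmmK, 0.95, names = FALSE),
               thrMeanK12 = if (length(thrK)) mean(thrK) else NA_real_,
               thrLo = if (length(thrK)) quantile(thrK, 0.05, names = FALSE)
                       else NA_real_,
               thrHi = if (length(thrK)) quantile(thrK, 0.95, names = FALSE)
                       else NA_real_,
               nThresholdIncluded = length(thrK),
               fracTwoState = mean(twoState))
  })
  list(config = list(snrGrid = snrGrid, nPerSnr = nPerSnr, p12 = p12,
                     p21 = p21, mu1 = mu1, c = c, seed = seed),
       table = do.call(rbind, rows))
}

# The three-state linear generating model: outer states as in the
# two-state benchmark (SNR between them set by `snrOuter`), middle state
# with emission halfway between, giving an effective SNR of ~2 between
# adjacent states.  States ordered by emission mean; transitions connect
# adjacent levels.
threeLinearParams <- function(snrOuter = 4, mu1 = 100, rate = 0.1) {
  mu3 <- meansForSnr(snrOuter, mu1)
  mu2 <- (mu1 + mu3) / 2
  A <- matrix(0, 3, 3)
  A[1, 2] <- rate; A[2, 1] <- rate
  A[2, 3] <- rate; A[3, 2] <- rate
  diag(A) <- 1 - rowSums(A)
  hmmParams(A, mu = c(mu1, mu2, mu3))
}

#' Model-menu BIC study
#'
#' Simulates traces from the three-state linear model (outer states at
#' `snrOuter`, middle state halfway between them), fits the six-model
#' menu of [builtinModels()] to every trace, and tabulates which model
#' the BIC selects and the distribution of each model's BIC difference
#' from `3-linear`.
#'
#' @param n number of traces.
#' @param snrOuter SNR between the outer states (sets trace length via
#'   `T = c / snrOuter`).
#' @param rate per-step transition probability along the chain.
#' @param mu1 low-state Poisson mean.
#' @param c photobleaching constant.
#' @param seed integer seed.
#' @param nRestarts,maxIter passed to [fitHmm()].
#' @return list with `config`, `winners` (named counts of minimum-BIC
#'   models), `deltaBic` (n x 6 matrix of BIC differences from
#'   3-linear), and `fracTrue` (fraction of traces where 3-linear wins).
#' @export
runModelSelectionStudy <- function(n = 100L, snrOuter = 4, rate = 0.1,
                                   mu1 = 100, c = 1e4, seed = 1L,
                                   nRestarts = 2L, maxIter = 300L) {
  gen <- threeLinearParams(snrOuter, mu1, rate)
  cfg <- simConfig(gen, snr = snrOuter, c = c, nTraces = n)
  set <- simulateTraces(cfg, seed = seed)
  menu <- builtinModels()
  winners <- character(n)
  deltaBic <- matrix(NA_real_, n, length(menu),
                     dimnames = list(NULL, names(menu)))
  for (i in seq_len(n)) {
    tr <- set[[i]]
    fits <- lapply(menu, function(spec)
      fitHmm(tr, spec, nRestarts = nRestarts, maxIter = maxIter,
             seed = seed))
    rank <- selectModel(fits, tr)
    winners[i] <- rank$model[1]
    ref <- rank$bic[rank$model == "3-linear"]
    deltaBic[i, rank$model] <- rank$bic - ref
  }
  list(config = list(n = n, snrOuter = snrOuter, rate = rate, mu1 = mu1,
                     c = c, seed = seed),
       winners = table(winners),
       deltaBic = deltaBic,
       fracTrue = mean(winners == "3-linear"))
}

#' Two-population clustering study
#'
#' Simulates two non-exchanging populations of two-state molecules whose
#' kinetics differ two-fold in one transition probability, fits each
#' trace with a two-state HMM plus 90% confidence intervals for both
#' transition probabilities, and runs the uncertainty-weighted cluster
#' EM on `(log10 k12, log10 k21)` for `C = 1 .. Cmax`.  For the
#' two-cluster fit the fraction of traces whose maximum-responsibility
#' cluster matches their generating population (under the best
#' cluster-to-population mapping) measures partition accuracy.
#'
#' @param snr simulation SNR (trace length `T = c / snr`).
#' @param nPerPop traces per population.
#' @param ratesA,ratesB `c(p12, p21)` for the two populations.
#' @param mu1 low-state Poisson mean.
#' @param c photobleaching constant.
#' @param Cmax largest cluster count to fit.
#' @param level confidence level for the per-trace intervals.
#' @param seed integer seed.
#' @param nRestarts,maxIter passed to [fitHmm()].
#' @return list with `config`, `selection` (the [selectClusterNumber()]
#'   table), `fits` (cluster fits), `accuracy2` (two-cluster partition
#'   accuracy), `sizes` (per-C cluster sizes), `truePop` (generating
#'   population labels), and `input` (the clustering input).
#' @export
runClusteringStudy <- function(snr = 2, nPerPop = 100L,
                               ratesA = c(0.1, 0.1), ratesB = c(0.1, 0.2),
                               mu1 = 100, c = 1e4, Cmax = 3L,
                               level = 0.90, seed = 1L, nRestarts = 2L,
                               maxIter = 300L) {
  two <- modelSpec("2-state", 2L)
  cfgA <- twoStateConfig(snr, ratesA[1], ratesA[2], mu1, c, nPerPop)
  cfgB <- twoStateConfig(snr, ratesB[1], ratesB[2], mu1, c, nPerPop)
  setA <- simulateTraces(cfgA, seed = traceSeed(seed, 1L))
  setB <- simulateTraces(cfgB, seed = traceSeed(seed, 2L))
  all <- traceSet(c(lapply(seq_along(traces(setA)), function(i) {
    tr <- setA[[i]]; tr@id <- paste0("A-", i); tr
  }), lapply(seq_along(traces(setB)), function(i) {
    tr <- setB[[i]]; tr@id <- paste0("B-", i); tr
  })), provenance = "two-population clustering study")
  truePop <- rep(c(1L, 2L), each = nPerPop)
  fits <- lapply(traces(all), function(tr) {
    fit <- fitHmm(tr, two, nRestarts = nRestarts, maxIter = maxIter,
                  seed = seed)
    addConfidenceIntervals(tr, fit, c("A[1,2]", "A[2,1]"), level = level)
  })
  input <- buildClusterInput(fits, c("A[1,2]", "A[2,1]"),
                             transform = "log10", level = level)
  sel <- selectClusterNumber(input, Cmax, seed = seed)
  fit2 <- sel$fits[[min(2L, Cmax)]]
  accuracy2 <- NA_real_
  if (fit2@C == 2L) {
    assign <- clusterAssignments(fit2)
    acc <- mean(assign == truePop)
    accuracy2 <- max(acc, 1 - acc)   # best cluster-to-population mapping
  }
  list(config = list(snr = snr, nPerPop = nPerPop, ratesA = ratesA,
                     ratesB = ratesB, mu1 = mu1, c = c, Cmax = Cmax,
                     level = level, seed = seed),
       selection = sel$table, fits = sel$fits, accuracy2 = accuracy2,
       sizes = lapply(sel$fits, function(f) f@sizes),
       truePop = truePop, input = input)
}

#' Mixed-SNR homogeneous population demonstration
#'
#' The cautionary workflow: a single kinetically homogeneous two-state
#' population observed at two different SNRs.  Threshold analysis makes
#' the low-SNR molecules look faster (spurious heterogeneity); HMM fits
#' with confidence-interval-weighted clustering recover a single
#' cluster.
#'
#' @param nPerSnr traces per SNR level.
#' @param snrs the two SNR levels.
#' @param p12,p21 generating transition probabilities.
#' @param mu1 low-state Poisson mean.
#' @param c photobleaching constant.
#' @param Cmax largest cluster count to fit.
#' @param level confidence level.
#' @param seed integer seed.
#' @param nRestarts,maxIter passed to [fitHmm()].
#' @return list with `config`, `thresholdRates` (per-trace threshold
#'   estimates with their SNR), `selection` (cluster-number table),
#'   `bestC` (minimum-BIC cluster count).
#' @export
runMixedSnrDemo <- function(nPerSnr = 100L, snrs = c(4, 12), p12 = 0.1,
                            p21 = 0.1, mu1 = 100, c = 1e4, Cmax = 3L,
                            level = 0.90, seed = 1L, nRestarts = 2L,
                            maxIter = 300L) {
  two <- modelSpec("2-state", 2L)
  allTraces <- list()
  snrOf <- numeric(0)
  for (si in seq_along(snrs)) {
    cfg <- twoStateConfig(snrs[si], p12, p21, mu1, c, nPerSnr)
    set <- simulateTraces(cfg, seed = traceSeed(seed, si))
    for (i in seq_along(traces(set))) {
      tr <- set[[i]]
      tr@id <- sprintf("snr%g-%d", snrs[si], i)
      allTraces[[length(allTraces) + 1L]] <- tr
      snrOf <- c(snrOf, snrs[si])
    }
  }
  all <- traceSet(allTraces, provenance = "mixed-SNR homogeneous demo")
  thrRows <- lapply(seq_along(allTraces), function(i) {
    tr <- all[[i]]
    thr <- (mu1 + meansForSnr(snrOf[i], mu1)) / 2
    tf <- tryCatch(thresholdFit(tr, threshold = thr),
                   error = function(e) NULL)
    data.frame(traceId = tr@id, snr = snrOf[i],
               p12 = if (!is.null(tf) && !tf@excluded) tf@p12 else NA_real_)
  })
  fits <- lapply(traces(all), function(tr) {
    fit <- fitHmm(tr, two, nRestarts = nRestarts, maxIter = maxIter,
                  seed = seed)
    addConfidenceIntervals(tr, fit, c("A[1,2]", "A[2,1]"), level = level)
  })
  input <- buildClusterInput(fits, c("A[1,2]", "A[2,1]"),
                             transform = "log10", level = level)
  sel <- selectClusterNumber(input, Cmax, seed = seed)
  list(config = list(nPerSnr = nPerSnr, snrs = snrs, p12 = p12,
                     p21 = p21, mu1 = mu1, c = c, Cmax = Cmax,
                     level = level, seed = seed),
       thresholdRates = do.call(rbind, thrRows),
       selection = sel$table,
       bestC = sel$table$C[sel$table$minBic])
}
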