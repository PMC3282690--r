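#' Construct concrete HMM parameter values
#'
#' @param A K x K row-stochastic transition probability matrix.
#' @param mu emission means: K x C matrix (or vector for one channel).
#' @param sd emission standard deviations, same shape as `mu`; ignored
#'   (and stored as `NA`) for Poisson channels.
#' @param families per-channel emission family.
#' @param pi0 initial state distribution; default the stationary
#'   distribution of `A`.
#' @return an [HmmParams] object.
#' @examples
#' p <- hmmParams(twoStateMatrix(0.1, 0.1), mu = c(100, 144))
#' @export
hmmParams <- function(A, mu, sd = NULL, families = "poisson", pi0 = NULL) {
  A <- as.matrix(A)
  mu <- if (is.matrix(mu)) mu else matrix(mu, ncol = 1)
  families <- rep_len(families, ncol(mu))
  if (is.null(sd)) sd <- matrix(NA_real_, nrow(mu), ncol(mu))
  sd <- if (is.matrix(sd)) sd else matrix(sd, ncol = 1)
  sd[, families == "poisson"] <- NA_real_
  if (is.null(pi0)) pi0 <- stationaryDistribution(A)
  new("HmmParams", A = A, mu = mu, sd = sd, pi0 = pi0,
      families = families)
}

#' Two-state transition matrix from the two transition probabilities
#'
#' @param p12,p21 per-step transition probabilities.
#' @return 2 x 2 row-stochastic matrix.
#' @export
twoStateMatrix <- function(p12, p21) {
  matrix(c(1 - p12, p12, p21, 1 - p21), 2, 2, byrow = TRUE)
}

#' Stationary distribution of a Markov chain
#'
#' Solves `pi A = pi`, `sum(pi) = 1` via the unit left eigenvector.  The
#' chain must have a unique stationary distribution (one unit eigenvalue);
#' reducible chains such as the identity matrix are rejected.
#'
#' @param A row-stochastic K x K matrix.
#' @param tol tolerance for the row-stochastic check.
#' @return probability vector `pi` with `pi %*% A = pi`.
#' @examples
#' stationaryDistribution(twoStateMatrix(0.2, 0.1))  # c(1/3, 2/3)
#' @export
stationaryDistribution <- function(A, tol = 1e-10) {
  A <- as.matrix(A)
  K <- nrow(A)
  if (K == 1L) return(1)
  if (any(abs(rowSums(A) - 1) > tol)) stop("A must be row-stochastic")
  eg <- eigen(t(A))
  unit <- which(abs(eg$values - 1) < 1e-8)
  if (length(unit) != 1L)
    stop("chain has no unique stationary distribution ",
         "(reducible or degenerate)")
  v <- Re(eg$vectors[, unit])
  v <- v / sum(v)
  if (any(v < -1e-10))
    stop("chain has no unique stationary distribution")
  pmax(v, 0) / sum(pmax(v, 0))
}

#' Two-state signal-to-noise ratio
#'
#' SNR of a single channel distinguishing two states: the separation of
#' the state means relative to the pooled noise spread,
#' `|mu2 - mu1| / sqrt((mu1 + mu2)/2)` for a Poisson channel (the
#' variance of a Poisson count equals its mean) and
#' `|mu2 - mu1| / sqrt((sd1^2 + sd2^2)/2)` for a Gaussian channel.
#' A Poisson channel with means 100 and 110 has SNR close to 1.
#'
#' @param mu1,mu2 state mean intensities.
#' @param family `"poisson"` or `"gaussian"`.
#' @param sd1,sd2 Gaussian state standard deviations.
#' @return the (non-negative) SNR.
#' @examples
#' snrTwoState(100, 110)  # ~0.976
#' @export
snrTwoState <- function(mu1, mu2, family = c("poisson", "gaussian"),
                        sd1 = NULL, sd2 = NULL) {
  family <- match.arg(family)
  if (family == "poisson") {
    if (mu1 <= 0 || mu2 <= 0) stop("poisson means must be positive")
    abs(mu2 - mu1) / sqrt((mu1 + mu2) / 2)
  } else {
    if (is.null(sd1) || is.null(sd2))
      stop("gaussian SNR needs sd1 and sd2")
    if (sd1 <= 0 || sd2 <= 0) stop("gaussian sds must be positive")
    abs(mu2 - mu1) / sqrt((sd1^2 + sd2^2) / 2)
  }
}

#' Combine per-channel SNRs
#'
#' Independent channels add information in quadrature: the overall SNR is
#' the root-sum-square of the per-channel SNRs, so two identical channels
#' of SNR 1 give sqrt(2).
#'
#' @param snrs numeric vector of non-negative per-channel SNRs.
#' @return combined SNR.
#' @export
combinedSnr <- function(snrs) {
  if (!length(snrs)) stop("at least one channel SNR is required")
  if (any(snrs < 0)) stop("SNRs must be non-negative")
  sqrt(sum(snrs^2))
}

#' Solve for the second state mean giving a target SNR
#'
#' Inverse of [snrTwoState()]: given the first state's mean and a target
#' SNR, returns the (larger) second mean.  For a Poisson channel this
#' solves the quadratic `(mu2 - mu1)^2 = snr^2 (mu1 + mu2) / 2`.
#'
#' @param snr target SNR (>= 0).
#' @param mu1 base state mean (> 0 for Poisson).
#' @param family emission family.
#' @param sd common Gaussian standard deviation for both states.
#' @return `mu2 >= mu1` with `snrTwoState(mu1, mu2) == snr`.
#' @export
meansForSnr <- function(snr, mu1, family = c("poisson", "gaussian"),
                        sd = NULL) {
  family <- match.arg(family)
  stopifnot(snr >= 0)
  if (family == "poisson") {
    stopifnot(mu1 > 0)
    d <- (snr^2 / 2 + sqrt(snr^4 / 4 + 4 * snr^2 * mu1)) / 2
    mu1 + d
  } else {
    if (is.null(sd) || sd <= 0) stop("gaussian meansForSnr needs sd > 0")
    mu1 + snr * sd
  }
}

# Deterministic per-trace RNG stream: seeds derived from (seed, index) so
# a population is reproducible regardless of generation order.  Kept
# below 2^31 for 32-bit R integers.
traceSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %%
             2147483647)
}

#' Simulation settings
#'
#' Bundles everything [simulateTraces()] needs: concrete generating
#' parameters, the target SNR, and the photobleaching constant `c`.
#' In `"photobleach"` mode trace length is `T = round(c / snr)`: higher
#' excitation power buys SNR at the cost of faster photobleaching, so the
#' product of trace length and SNR is held constant, `T * SNR = c`
#' (`c` is the mean photon budget of a dye).  In `"fixed"` mode `T` is
#' given directly.  With `stochasticLength = TRUE` the photobleach length
#' is drawn exponentially with mean `c / snr` instead of fixed.
#'
#' @param params generating [HmmParams].
#' @param snr target SNR (used for bookkeeping and length coupling; the
#'   emission means in `params` define the actual SNR).
#' @param c photobleaching constant (time steps x SNR); default 1e4.
#' @param nTraces number of traces.
#' @param lengthMode `"photobleach"` or `"fixed"`.
#' @param T trace length for `"fixed"` mode.
#' @param stochasticLength draw exponential lengths in photobleach mode.
#' @param dt sampling interval in seconds.
#' @return a list of class `simConfig`.
#' @export
simConfig <- function(params, snr, c = 1e4, nTraces = 1L,
                      lengthMode = c("photobleach", "fixed"), T = NULL,
                      stochasticLength = FALSE, dt = 1) {
  lengthMode <- match.arg(lengthMode)
  stopifnot(snr > 0, c > 0, nTraces >= 1)
  if (lengthMode == "fixed" && is.null(T))
    stop("fixed length mode requires T")
  structure(list(params = params, snr = snr, c = c,
                 nTraces = as.integer(nTraces), lengthMode = lengthMode,
                 T = T, stochasticLength = stochasticLength, dt = dt),
            class = "simConfig")
}

#' Simulate one trace from an HMM
#'
#' Draws a hidden state path (initial state from the stationary
#' distribution of the transition matrix, then Markov steps) and emits
#' per-channel intensities conditionally independent given the state:
#' Poisson counts or Gaussian values with the state's parameters.
#' Deterministic given `(seed, index)`.
#'
#' @param config a [simConfig()].
#' @param index 1-based trace index within the population (selects the
#'   per-trace RNG stream and names the trace).
#' @param seed integer population seed.
#' @param returnStates also return the hidden path (for test oracles).
#' @return a [Trace]; with `returnStates = TRUE`, a list
#'   `list(trace, states)`.
#' @export
simulateTrace <- function(config, index = 1L, seed = 1L,
                          returnStates = FALSE) {
  p <- config$params
  K <- nrow(p@A)
  set.seed(traceSeed(seed, index))
  T <- if (config$lengthMode == "fixed") config$T else {
    len <- config$c / config$snr
    if (config$stochasticLength) stats::rexp(1, rate = 1 / len) else len
  }
  T <- as.integer(round(T))
  if (T < 2L)
    stop("trace length ", T, " < 2 after rounding; increase c")
  states <- integer(T)
  states[1] <- sample.int(K, 1, prob = p@pi0)
  if (K > 1L) {
    u <- runif(T - 1L)
    cumA <- t(apply(p@A, 1, cumsum))
    for (t in 2:T)
      states[t] <- findInterval(u[t - 1L], cumA[states[t - 1L], ]) + 1L
  } else states[] <- 1L
  C <- ncol(p@mu)
  ch <- matrix(0, T, C)
  for (cc in seq_len(C)) {
    mus <- p@mu[states, cc]
    ch[, cc] <- if (p@families[cc] == "poisson") rpois(T, mus)
                else rnorm(T, mus, p@sd[states, cc])
  }
  tr <- new("Trace", id = sprintf("sim-%d-%d", seed, index),
            dt = config$dt, channels = ch,
            metadata = list(snr = config$snr, seed = seed, index = index))
  if (returnStates) list(trace = tr, states = states) else tr
}

#' Simulate a population of traces
#'
#' @inheritParams simulateTrace
#' @return a [TraceSet] of `config$nTraces` traces (with
#'   `returnStates = TRUE`, a list `list(set, states)` where `states` is
#'   a list of hidden paths).
#' @examples
#' cfg <- simConfig(hmmParams(twoStateMatrix(0.3, 0.3),
#'                            mu = c(100, meansForSnr(5, 100))),
#'                  snr = 5, c = 1e4, nTraces = 3)
#' simulateTraces(cfg, seed = 7)
#' @export
simulateTraces <- function(config, seed = 1L, returnStates = FALSE) {
  out <- lapply(seq_len(config$nTraces), simulateTrace, config = config,
                seed = seed, returnStates = returnStates)
  if (returnStates) {
    set <- new("TraceSet", traces = lapply(out, `[[`, "trace"),
               provenance = sprintf("simulated population, seed %d", seed))
    list(set = set, states = lapply(out, `[[`, "states"))
  } else {
    new("TraceSet", traces = out,
        provenance = sprintf("simulated population, seed %d", seed))
  }
}
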