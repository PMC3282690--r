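# Per-time log emission densities, channels multiplied (conditional
# independence given the hidden state).  Poisson channels evaluate the
# count pmf at round(x) so camera-calibrated (real-valued) intensities
# remain usable; the lgamma(x+1) terms are precomputed once per trace.
emissionCache <- function(channels, families) {
  lapply(seq_len(ncol(channels)), function(ch) {
    x <- channels[, ch]
    if (families[ch] == "poisson") {
      xr <- round(x)
      list(x = xr, lfact = lgamma(xr + 1))
    } else list(x = x)
  })
}

emissionLogB <- function(cache, mu, sd, families) {
  T <- length(cache[[1]]$x)
  K <- nrow(mu)
  logB <- matrix(0, T, K)
  for (ch in seq_along(cache)) {
    cc <- cache[[ch]]
    if (families[ch] == "poisson") {
      for (k in seq_len(K))
        logB[, k] <- logB[, k] +
          cc$x * log(mu[k, ch]) - mu[k, ch] - cc$lfact
    } else {
      for (k in seq_len(K))
        logB[, k] <- logB[, k] +
          dnorm(cc$x, mu[k, ch], sd[k, ch], log = TRUE)
    }
  }
  logB
}

#' Log-likelihood of a trace under an HMM
#'
#' Natural log of `p(data | model)` by the scaled forward recursion: the
#' sum over all hidden state paths of path probability times emission
#' probability, contracted efficiently in `O(T K^2)`.  Multi-channel
#' emissions multiply (channels are conditionally independent given the
#' hidden state).
#'
#' @param trace a [Trace].
#' @param params an [HmmParams] with matching channel count.
#' @return finite numeric log-likelihood.
#' @examples
#' p <- hmmParams(twoStateMatrix(0.3, 0.3), mu = c(100, 144))
#' tr <- simulateTrace(simConfig(p, snr = 5, T = 200,
#'                               lengthMode = "fixed"), seed = 1)
#' logLikelihood(tr, p)
#' @export
logLikelihood <- function(trace, params) {
  if (ncol(trace@channels) != ncol(params@mu))
    stop("trace has ", ncol(trace@channels), " channel(s) but params ",
         "describe ", ncol(params@mu))
  cache <- emissionCache(trace@channels, params@families)
  logB <- emissionLogB(cache, params@mu, params@sd, params@families)
  forward_loglik_cpp(logB, params@A, params@pi0)
}

#' Posterior state probabilities
#'
#' Forward-backward smoothing: for every time step, the probability of
#' each hidden state conditioned on the whole trace (all past and future
#' observations), the quantity that replaces thresholding's absolute
#' local state call.  Rows sum to 1.
#'
#' @inheritParams logLikelihood
#' @return T x K matrix of state probabilities.
#' @export
posteriorStateProbs <- function(trace, params) {
  if (ncol(trace@channels) != ncol(params@mu))
    stop("channel count mismatch")
  cache <- emissionCache(trace@channels, params@families)
  logB <- emissionLogB(cache, params@mu, params@sd, params@families)
  fb <- forward_backward_cpp(logB, params@A, params@pi0)
  fb$gamma
}

# --- M-step helpers ---------------------------------------------------

# Unconstrained transition update: expected counts normalized per row,
# restricted to allowed entries (zeros of the topology are preserved).
mstepTransitions <- function(xi, edges, K, Aold) {
  allowed <- matrix(FALSE, K, K)
  diag(allowed) <- TRUE
  if (nrow(edges)) allowed[edges] <- TRUE
  xi[!allowed] <- 0
  A <- matrix(0, K, K)
  rs <- rowSums(xi)
  for (i in seq_len(K)) {
    if (rs[i] > 0) A[i, ] <- xi[i, ] / rs[i]
    else A[i, ] <- Aold[i, ]      # state never visited; keep previous row
  }
  A
}

# Reversible (detailed-balance) transition update: maximize the expected
# complete-data log-likelihood over symmetric edge weights x_ij = x_ji,
# A_ij = x_ij / x_i (which satisfies detailed balance with pi_i
# proportional to x_i), by the standard fixed-point iteration
#   x_ij <- (c_ij + c_ji) / (c_i / x_i + c_j / x_j).
mstepTransitionsDB <- function(xi, edges, K, Aold, maxInner = 300,
                               innerTol = 1e-12) {
  allowed <- matrix(FALSE, K, K)
  diag(allowed) <- TRUE
  if (nrow(edges)) allowed[edges] <- TRUE
  cmat <- xi
  cmat[!allowed] <- 0
  ci <- rowSums(cmat)                # expected visits per state
  csym <- cmat + t(cmat)
  csym[!allowed] <- 0
  if (all(csym == 0)) return(Aold)
  # warm start: if Aold is already reversible its flux matrix pi_i A_ij
  # is symmetric and close to the new optimum late in EM
  piOld <- tryCatch(stationaryDistribution(Aold),
                    error = function(e) rep(1 / K, K))
  x <- piOld * Aold
  x <- (x + t(x)) / 2
  x[csym == 0] <- 0
  if (all(x == 0)) x <- csym / 2
  x <- x * (sum(csym) / 2 / sum(x))  # match the count scale
  pos <- which(csym > 0 & row(csym) != col(csym))
  ri <- row(csym)[pos]; cj <- col(csym)[pos]
  cpos <- csym[pos]
  dvec <- diag(cmat)
  tiny <- .Machine$double.xmin
  for (it in seq_len(maxInner)) {
    rowx <- pmax(.rowSums(x, K, K), tiny)
    g <- ci / rowx                   # stationarity Lagrange terms
    xnew <- matrix(0, K, K)
    xnew[pos] <- cpos / (g[ri] + g[cj])
    diag(xnew) <- ifelse(ci > 0, dvec / pmax(g, tiny), 0)
    delta <- max(abs(xnew - x)) / max(max(x), tiny)
    x <- xnew
    if (delta < innerTol) break
  }
  rs <- .rowSums(x, K, K)
  A <- matrix(0, K, K)
  for (i in seq_len(K))
    A[i, ] <- if (rs[i] > 0) x[i, ] / rs[i] else Aold[i, ]
  A
}

# Pooled emission update over tie groups with posterior weights gamma.
mstepEmissions <- function(gamma, cache, spec, muOld, sdOld) {
  K <- spec@K
  C <- length(spec@families)
  mu <- muOld
  sdm <- sdOld
  for (ch in seq_len(C)) {
    x <- cache[[ch]]$x
    groups <- spec@tieGroups[[ch]]
    for (g in unique(groups)) {
      states <- which(groups == g)
      w <- rowSums(gamma[, states, drop = FALSE])
      sw <- sum(w)
      if (sw <= 0) next
      m <- sum(w * x) / sw
      if (spec@families[ch] == "poisson") {
        mu[states, ch] <- max(m, 1e-8)
      } else {
        v <- sum(w * (x - m)^2) / sw
        floorSd <- 1e-6 * max(diff(range(x)), 1e-12)
        mu[states, ch] <- m
        sdm[states, ch] <- max(sqrt(v), floorSd)
      }
    }
  }
  list(mu = mu, sd = sdm)
}

# Apply user-fixed parameters ("A[i,j]", "mu[s,c]", "sd[s,c]") after an
# M-step.  Fixed transition entries take their value and the free
# entries of the row are rescaled to keep it stochastic.
applyFixedParams <- function(A, mu, sdm, fixed) {
  if (!length(fixed)) return(list(A = A, mu = mu, sd = sdm))
  aFix <- list()
  for (nm in names(fixed)) {
    m <- regmatches(nm, regexec("^([A-Za-z]+)\\[(\\d+),(\\d+)\\]$", nm))[[1]]
    if (length(m) != 4) stop("cannot parse fixed parameter name '", nm, "'")
    what <- m[2]; i <- as.integer(m[3]); j <- as.integer(m[4])
    v <- fixed[[nm]]
    if (what == "A") aFix[[length(aFix) + 1]] <- list(i = i, j = j, v = v)
    else if (what == "mu") mu[i, j] <- v
    else if (what == "sd") sdm[i, j] <- v
    else stop("unknown fixed parameter '", nm, "'")
  }
  if (length(aFix)) {
    rows <- unique(vapply(aFix, `[[`, integer(1), "i"))
    for (r in rows) {
      entries <- Filter(function(e) e$i == r, aFix)
      jfix <- vapply(entries, `[[`, integer(1), "j")
      vfix <- vapply(entries, `[[`, numeric(1), "v")
      if (sum(vfix) > 1) stop("fixed probabilities in row ", r, " exceed 1")
      free <- setdiff(seq_len(ncol(A)), jfix)
      sfree <- sum(A[r, free])
      A[r, free] <- if (sfree > 0) A[r, free] / sfree * (1 - sum(vfix))
                    else (1 - sum(vfix)) / length(free)
      A[r, jfix] <- vfix
    }
  }
  list(A = A, mu = mu, sd = sdm)
}

# Quantile-based initialization: emission means at the K group quantiles
# of the pooled intensities (scale-free), transition matrix with 0.1
# off-diagonal mass spread over the allowed edges of each row.
initParams <- function(trace, spec, jitter = 0, rng = NULL) {
  K <- spec@K
  C <- ncol(trace@channels)
  mu <- matrix(0, K, C)
  sdm <- matrix(NA_real_, K, C)
  for (ch in seq_len(C)) {
    x <- trace@channels[, ch]
    groups <- spec@tieGroups[[ch]]
    ng <- length(unique(groups))
    qs <- quantile(x, probs = (2 * seq_len(ng) - 1) / (2 * ng),
                   names = FALSE)
    for (gi in seq_along(unique(groups))) {
      g <- unique(groups)[gi]
      m <- qs[gi]
      if (jitter > 0 && !is.null(rng))
        m <- m * (1 + jitter * (2 * rng() - 1))
      if (spec@families[ch] == "poisson") m <- max(m, 1e-3)
      mu[groups == g, ch] <- m
    }
    if (spec@families[ch] == "gaussian")
      sdm[, ch] <- max(sd(x) / sqrt(ng), 1e-6 * max(diff(range(x)), 1e-12))
  }
  A <- diag(K)
  if (nrow(spec@edges)) {
    outdeg <- tabulate(spec@edges[, 1], K)
    for (r in seq_len(nrow(spec@edges))) {
      i <- spec@edges[r, 1]; j <- spec@edges[r, 2]
      A[i, j] <- 0.1 / outdeg[i]
    }
    diag(A) <- 0
    diag(A) <- 1 - rowSums(A)
  }
  if (spec@detailedBalance && nrow(spec@edges)) {
    # build from symmetric weights so the start already satisfies the
    # constraint the M-step will enforce
    w <- matrix(0, K, K)
    w[spec@edges] <- 1
    w <- (w + t(w)) / 2
    diag(w) <- pmax(rowSums(w) * 9, 1)   # ~0.1 off-diagonal mass
    A <- w / rowSums(w)
  }
  pi0 <- tryCatch(stationaryDistribution(A),
                  error = function(e) rep(1 / K, K))
  new("HmmParams", A = A, mu = mu, sd = sdm, pi0 = pi0,
      families = spec@families)
}

#' Fit a hidden Markov model to a trace by Baum-Welch
#'
#' Maximum-likelihood estimation of the transition probabilities and
#' emission parameters of a [ModelSpec] for one trace, by the Baum-Welch
#' (EM) algorithm.  The per-iteration log-likelihood is non-decreasing
#' (up to numerical slack); iteration stops when the increment falls
#' below `tol` or after `maxIter` iterations.  Restarts jitter the
#' initial emission means by +/-10% and the best final likelihood is
#' kept.  Tied emission states share a pooled update; topology zeros are
#' preserved; when the spec requests detailed balance the transition
#' update is constrained to a reversible chain (symmetric edge-weight
#' parameterization), so the returned matrix satisfies
#' `pi_i A_ij = pi_j A_ji` exactly.
#'
#' By default the initial state distribution is tied to the stationary
#' distribution of the current transition matrix -- matching how
#' equilibrium experiments sample molecules -- and contributes no free
#' parameters; `pi0Mode = "free"` estimates it instead (remember
#' `freePi0 = TRUE` in [countFreeParameters()]).
#'
#' @param trace a [Trace].
#' @param spec a [ModelSpec] with the trace's channel count.
#' @param maxIter maximum EM iterations (default 1000).
#' @param tol absolute convergence tolerance on the log-likelihood
#'   increment (default 1e-6).
#' @param nRestarts number of random restarts (default 3).
#' @param seed integer seed controlling restart jitter.
#' @param pi0Mode `"stationary"` (default) or `"free"`.
#' @param fixedParams named list pinning parameters during the fit, e.g.
#'   `list("A[1,2]" = 0.25)`; used by profile-likelihood scans.
#' @param init optional [HmmParams] to initialize from (restart 1).
#' @return an [HmmFit].
#' @examples
#' p <- hmmParams(twoStateMatrix(0.3, 0.3), mu = c(100, 144.2))
#' tr <- simulateTrace(simConfig(p, snr = 5), seed = 3)
#' fit <- fitHmm(tr, modelSpec("2-state", 2))
#' fittedParams(fit)@A
#' @export
fitHmm <- function(trace, spec, maxIter = 1000L, tol = 1e-6,
                   nRestarts = 3L, seed = 1L,
                   pi0Mode = c("stationary", "free"),
                   fixedParams = list(), init = NULL) {
  pi0Mode <- match.arg(pi0Mode)
  if (traceLength(trace) < 2L) stop("trace too short to fit (T < 2)")
  if (ncol(trace@channels) != length(spec@families))
    stop("trace has ", ncol(trace@channels), " channel(s) but model '",
         spec@name, "' describes ", length(spec@families))
  viol <- validateModel(spec)
  if (length(viol)) stop("invalid model: ", viol[1])
  cache <- emissionCache(trace@channels, spec@families)

  set.seed(traceSeed(seed, 0L))
  jseq <- runif(max(nRestarts, 1L) * 64L)  # jitter stream for restarts
  jpos <- 0L
  rng <- function() { jpos <<- jpos + 1L; jseq[jpos] }

  best <- NULL
  for (r in seq_len(max(nRestarts, 1L))) {
    params <- if (r == 1L && !is.null(init)) init
              else initParams(trace, spec, jitter = if (r > 1L) 0.1 else 0,
                              rng = rng)
    fx <- applyFixedParams(params@A, params@mu, params@sd, fixedParams)
    A <- fx$A; mu <- fx$mu; sdm <- fx$sd
    pi0 <- params@pi0
    llTrace <- numeric(0)
    llPrev <- -Inf
    converged <- FALSE
    gamma <- NULL
    iter <- 0L
    prev <- NULL
    repeat {
      iter <- iter + 1L
      logB <- emissionLogB(cache, mu, sdm, spec@families)
      fb <- forward_backward_cpp(logB, A, pi0)
      if (is.finite(llPrev) && fb$loglik < llPrev) {
        # the stationary-pi0 tie makes the update approximate EM; when
        # the objective stops improving, keep the previous iterate
        A <- prev$A; mu <- prev$mu; sdm <- prev$sd; pi0 <- prev$pi0
        gamma <- prev$gamma
        iter <- iter - 1L
        converged <- TRUE
        break
      }
      llTrace <- c(llTrace, fb$loglik)
      gamma <- fb$gamma
      if (is.finite(llPrev) && abs(fb$loglik - llPrev) < tol) {
        converged <- TRUE
        break
      }
      if (iter >= maxIter) break
      llPrev <- fb$loglik
      prev <- list(A = A, mu = mu, sd = sdm, pi0 = pi0, gamma = gamma)
      # M-step
      A <- if (spec@detailedBalance)
        mstepTransitionsDB(fb$xi, spec@edges, spec@K, A)
      else mstepTransitions(fb$xi, spec@edges, spec@K, A)
      em <- mstepEmissions(gamma, cache, spec, mu, sdm)
      mu <- em$mu; sdm <- em$sd
      fx <- applyFixedParams(A, mu, sdm, fixedParams)
      A <- fx$A; mu <- fx$mu; sdm <- fx$sd
      pi0 <- if (pi0Mode == "stationary")
        tryCatch(stationaryDistribution(A),
                 error = function(e) pi0)
      else gamma[1, ] / sum(gamma[1, ])
    }
    ll <- llTrace[length(llTrace)]
    if (is.null(best) || ll > best$ll)
      best <- list(ll = ll, A = A, mu = mu, sd = sdm, pi0 = pi0,
                   gamma = gamma, iter = iter, converged = converged,
                   llTrace = llTrace)
  }

  ord <- order(best$mu[, 1])   # canonical state order: first-channel mean
  A <- best$A[ord, ord, drop = FALSE]
  mu <- best$mu[ord, , drop = FALSE]
  sdm <- best$sd[ord, , drop = FALSE]
  pi0 <- best$pi0[ord]
  gamma <- best$gamma[, ord, drop = FALSE]
  # re-validate topology after reordering: specs in the built-in menu are
  # symmetric under the orderings we produce only if edges allow; guard
  # by keeping the original order when the permuted A violates topology.
  if (nrow(spec@edges)) {
    allowed <- matrix(FALSE, spec@K, spec@K)
    diag(allowed) <- TRUE
    allowed[spec@edges] <- TRUE
    if (any(A[!allowed] > 0)) {
      A <- best$A; mu <- best$mu; sdm <- best$sd
      pi0 <- best$pi0; gamma <- best$gamma
    }
  }
  degenerate <- spec@K > 1 &&
    any(vapply(seq_len(spec@K - 1), function(s)
      all(abs(mu[s, ] - mu[s + 1, ]) <=
            1e-6 * pmax(abs(mu[s, ]), 1)), logical(1)))
  params <- new("HmmParams", A = A, mu = mu, sd = sdm, pi0 = pi0,
                families = spec@families)
  new("HmmFit", spec = spec, params = params, loglik = best$ll,
      nIter = best$iter, converged = best$converged,
      degenerate = degenerate, posteriors = gamma,
      restartsUsed = as.integer(max(nRestarts, 1L)),
      loglikTrace = best$llTrace, traceId = trace@id, ci = list())
}

#' Fit an HMM to every trace of a population
#'
#' @param set a [TraceSet].
#' @param spec a [ModelSpec].
#' @param ... passed to [fitHmm()].
#' @return list of [HmmFit], one per trace, in set order.
#' @export
fitHmmSet <- function(set, spec, ...) {
  lapply(set@traces, fitHmm, spec = spec, ...)
}
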