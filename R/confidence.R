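parseParamName <- function(name) {
  m <- regmatches(name,
                  regexec("^([A-Za-z]+)\\[(\\d+),(\\d+)\\]$", name))[[1]]
  if (length(m) == 4)
    return(list(what = m[2], i = as.integer(m[3]), j = as.integer(m[4])))
  m <- regmatches(name, regexec("^k(\\d)(\\d)$", name))[[1]]
  if (length(m) == 3)
    return(list(what = "A", i = as.integer(m[2]), j = as.integer(m[3])))
  stop("cannot parse parameter name '", name, "'")
}

getParamValue <- function(params, pn) {
  switch(pn$what,
         A = params@A[pn$i, pn$j],
         mu = params@mu[pn$i, pn$j],
         sd = params@sd[pn$i, pn$j],
         stop("unknown parameter '", pn$what, "'"))
}

# Conditional log-likelihood as a function of one parameter, all others
# held at the MLE.  For a transition probability the diagonal of its row
# absorbs the change so the matrix stays stochastic.
conditionalLoglikFun <- function(trace, fit, pn) {
  params <- fit@params
  cache <- emissionCache(trace@channels, params@families)
  if (pn$what == "A") {
    i <- pn$i; j <- pn$j
    offOther <- sum(params@A[i, -c(i, j)])
    hi <- 1 - offOther           # diagonal reaches 0 here
    logB <- emissionLogB(cache, params@mu, params@sd, params@families)
    f <- function(theta) {
      A <- params@A
      A[i, j] <- theta
      A[i, i] <- 1 - offOther - theta
      pi0 <- tryCatch(stationaryDistribution(A),
                      error = function(e) params@pi0)
      forward_loglik_cpp(logB, A, pi0)
    }
    list(f = f, lo = 0, hi = hi)
  } else if (pn$what == "mu") {
    fam <- params@families[pn$j]
    f <- function(theta) {
      mu <- params@mu
      mu[pn$i, pn$j] <- theta
      logB <- emissionLogB(cache, mu, params@sd, params@families)
      forward_loglik_cpp(logB, params@A, params@pi0)
    }
    list(f = f, lo = if (fam == "poisson") 1e-9 else -Inf, hi = Inf)
  } else {
    f <- function(theta) {
      sdm <- params@sd
      sdm[pn$i, pn$j] <- theta
      logB <- emissionLogB(cache, params@mu, sdm, params@families)
      forward_loglik_cpp(logB, params@A, params@pi0)
    }
    list(f = f, lo = 1e-12, hi = Inf)
  }
}

profileLoglikFun <- function(trace, fit, pn, name) {
  params <- fit@params
  if (pn$what == "A") {
    i <- pn$i
    offOther <- sum(params@A[i, -c(i, pn$j)])
    dom <- list(lo = 0, hi = 1 - offOther)
  } else if (pn$what == "mu") {
    dom <- list(lo = if (params@families[pn$j] == "poisson") 1e-9 else -Inf,
                hi = Inf)
  } else dom <- list(lo = 1e-12, hi = Inf)
  canonical <- sprintf("%s[%d,%d]", pn$what, pn$i, pn$j)
  f <- function(theta) {
    refit <- fitHmm(trace, fit@spec, nRestarts = 1L,
                    fixedParams = setNames(list(theta), canonical),
                    init = params, maxIter = 200L)
    refit@loglik
  }
  list(f = f, lo = dom$lo, hi = dom$hi)
}

# Find theta on one side of the MLE where f(theta) = target, by
# geometric bracket expansion then bisection.
solveBound <- function(f, hatv, target, side, domLo, domHi, relTol = 1e-4) {
  scale <- max(abs(hatv), 1e-4)
  step <- 0.05 * scale
  inner <- hatv
  clipped <- FALSE
  outer <- NA_real_
  for (it in 1:200) {
    cand <- if (side == "hi") hatv + step else hatv - step
    if (side == "hi" && cand >= domHi) cand <- domHi
    if (side == "lo" && cand <= domLo) cand <- domLo
    val <- f(cand)
    if (val < target) { outer <- cand; break }
    inner <- cand
    if ((side == "hi" && cand >= domHi) ||
        (side == "lo" && cand <= domLo)) {
      clipped <- TRUE
      break
    }
    step <- step * 2
  }
  if (clipped || is.na(outer))
    return(list(bound = if (side == "hi") min(inner, domHi)
                        else max(inner, domLo),
                clipped = TRUE))
  tol <- relTol * max(abs(hatv), 1e-6)
  while (abs(outer - inner) > tol) {
    mid <- (outer + inner) / 2
    if (f(mid) >= target) inner <- mid else outer <- mid
  }
  list(bound = (inner + outer) / 2, clipped = FALSE)
}

#' Likelihood-ratio confidence interval for a fitted parameter
#'
#' Computes a confidence interval by varying the parameter value around
#' the MLE and recording the decrease in the data log-likelihood: the
#' bounds are where the log-likelihood has dropped by
#' `qchisq(level, 1) / 2` below its maximum (1.3529 at the default 90%
#' level), found by bisection to a relative tolerance of 1e-4.  In
#' `"conditional"` mode (default) all other parameters stay fixed at
#' their MLE -- the transition-row diagonal absorbs changes to a
#' transition probability; in `"profile"` mode the remaining parameters
#' are re-maximized at every scan point (slower).  When the likelihood
#' never drops below the threshold before a domain edge (e.g. a
#' transition probability hitting 0), the bound is clipped to the edge
#' and flagged.
#'
#' @param trace the fitted [Trace].
#' @param fit a converged [HmmFit] of that trace.
#' @param param parameter name: `"A[i,j]"` / `"kij"` for transition
#'   probabilities, `"mu[state,channel]"` or `"sd[state,channel]"` for
#'   emission parameters.
#' @param level confidence level in (0, 1); default 0.90.
#' @param mode `"conditional"` or `"profile"`.
#' @return a list with `param`, `level`, `mode`, `mle`, `lo`, `hi`,
#'   `clippedLo`, `clippedHi`.
#' @export
confidenceInterval <- function(trace, fit, param, level = 0.90,
                               mode = c("conditional", "profile")) {
  mode <- match.arg(mode)
  if (!fit@converged)
    stop("confidence intervals require a converged fit")
  stopifnot(level > 0, level < 1)
  pn <- parseParamName(param)
  hatv <- getParamValue(fit@params, pn)
  delta <- qchisq(level, df = 1) / 2
  fun <- if (mode == "conditional") conditionalLoglikFun(trace, fit, pn)
         else profileLoglikFun(trace, fit, pn, param)
  ll0 <- fun$f(hatv)
  target <- ll0 - delta
  up <- solveBound(fun$f, hatv, target, "hi", fun$lo, fun$hi)
  dn <- solveBound(fun$f, hatv, target, "lo", fun$lo, fun$hi)
  list(param = param, level = level, mode = mode, mle = hatv,
       lo = dn$bound, hi = up$bound,
       clippedLo = dn$clipped, clippedHi = up$clipped)
}

#' Attach confidence intervals to a fit
#'
#' Convenience wrapper running [confidenceInterval()] for several
#' parameters and storing the results in the fit's `ci` slot (keyed by
#' parameter name), the form [buildClusterInput()] consumes.
#'
#' @inheritParams confidenceInterval
#' @param params character vector of parameter names.
#' @return the [HmmFit] with its `ci` slot filled.
#' @export
addConfidenceIntervals <- function(trace, fit, params, level = 0.90,
                                   mode = c("conditional", "profile")) {
  mode <- match.arg(mode)
  for (pname in params)
    fit@ci[[pname]] <- confidenceInterval(trace, fit, pname,
                                          level = level, mode = mode)
  fit
}
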