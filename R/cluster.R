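#' Assemble clustering input from fitted traces
#'
#' Bridges per-molecule HMM fits to population clustering: for each fit,
#' up to three named parameters are taken at their MLE (optionally on a
#' log10 scale, the natural coordinate for rate-like parameters whose
#' confidence intervals are multiplicative) and each parameter's
#' standard deviation is derived from its likelihood-ratio confidence
#' interval via the Gaussian approximation of the likelihood:
#' `sd = half-width / z(level)` with `z(0.90) = 1.645`.  Asymmetric
#' intervals are symmetrized by averaging the two half-widths.  Bounds
#' clipped at a domain edge (e.g. a lower bound of 0 on the log scale)
#' are floored at `mle / 100` before transforming.
#'
#' @param fits list of [HmmFit] objects with confidence intervals
#'   attached (see [addConfidenceIntervals()]).
#' @param paramNames up to three parameter names, e.g.
#'   `c("k12", "k21")`.
#' @param transform `"log10"` (default) or `"linear"`.
#' @param level the confidence level the stored CIs were computed at.
#' @return list with `theta` (n x d matrix of estimates), `sd` (n x d
#'   matrix of per-trace standard deviations), `paramNames`,
#'   `transform`, `level`, `traceIds`.
#' @export
buildClusterInput <- function(fits, paramNames,
                              transform = c("log10", "linear"),
                              level = 0.90) {
  transform <- match.arg(transform)
  if (length(paramNames) > 3L)
    stop("clustering supports at most three parameters")
  z <- qnorm((1 + level) / 2)
  n <- length(fits)
  d <- length(paramNames)
  theta <- matrix(NA_real_, n, d, dimnames = list(NULL, paramNames))
  sdm <- matrix(NA_real_, n, d)
  ids <- character(n)
  for (i in seq_len(n)) {
    fit <- fits[[i]]
    ids[i] <- fit@traceId
    for (j in seq_len(d)) {
      ciKey <- paramNames[j]
      ci <- fit@ci[[ciKey]]
      if (is.null(ci)) {
        canonical <- tryCatch({
          pn <- parseParamName(ciKey)
          sprintf("%s[%d,%d]", pn$what, pn$i, pn$j)
        }, error = function(e) NULL)
        if (!is.null(canonical)) ci <- fit@ci[[canonical]]
        if (is.null(ci) && !is.null(canonical)) {
          alt <- names(fit@ci)[vapply(names(fit@ci), function(nm)
            tryCatch({
              p2 <- parseParamName(nm)
              sprintf("%s[%d,%d]", p2$what, p2$i, p2$j) == canonical
            }, error = function(e) FALSE), logical(1))]
          if (length(alt)) ci <- fit@ci[[alt[1]]]
        }
      }
      if (is.null(ci))
        stop("trace '", fit@traceId, "' has no confidence interval for '",
             ciKey, "'")
      mle <- ci$mle; lo <- ci$lo; hi <- ci$hi
      if (transform == "log10") {
        floorv <- mle / 100
        lo <- max(lo, floorv)
        hi <- max(hi, lo)
        theta[i, j] <- log10(mle)
        sdm[i, j] <- (log10(hi) - log10(lo)) / 2 / z
      } else {
        theta[i, j] <- mle
        sdm[i, j] <- (hi - lo) / 2 / z
      }
      if (!is.finite(sdm[i, j]) || sdm[i, j] <= 0)
        sdm[i, j] <- 1e-6 * max(abs(theta[i, j]), 1)
    }
  }
  list(theta = theta, sd = sdm, paramNames = paramNames,
       transform = transform, level = level, traceIds = ids)
}

clusterLoglik <- function(theta, sdm, centers, weights) {
  n <- nrow(theta); C <- nrow(centers)
  logR <- matrix(0, n, C)
  for (cc in seq_len(C)) {
    ll <- log(weights[cc])
    for (j in seq_len(ncol(theta)))
      ll <- ll + dnorm(theta[, j], centers[cc, j], sdm[, j], log = TRUE)
    logR[, cc] <- ll
  }
  m <- apply(logR, 1, max)
  lse <- m + log(rowSums(exp(logR - m)))
  list(loglik = sum(lse), resp = exp(logR - lse))
}

#' Uncertainty-weighted EM clustering of molecules
#'
#' Fits a `C`-component mixture to per-molecule parameter estimates in
#' which each molecule keeps its own diagonal covariance (from
#' [buildClusterInput()]): the likelihood of molecule `i` under cluster
#' `c` is `Normal(theta_i; m_c, Sigma_i)` -- the cluster has a center
#' but no spread of its own, and precisely measured molecules constrain
#' the centers more strongly than noisy ones.  The E-step computes
#' responsibilities, the M-step moves each center to the
#' responsibility-and-precision-weighted mean and updates the mixture
#' weights; the log-likelihood is non-decreasing.  The best of `nInit`
#' random initializations (centers seeded on data points with a
#' k-means++-style spread) is returned.
#'
#' @param input output of [buildClusterInput()].
#' @param C number of clusters (1 <= C <= n).
#' @param nInit random initializations (default 10).
#' @param seed integer seed.
#' @param tol absolute convergence tolerance on the log-likelihood.
#' @param maxIter maximum EM iterations.
#' @return a [ClusterFit].
#' @export
fitClusters <- function(input, C, nInit = 10L, seed = 1L, tol = 1e-8,
                        maxIter = 500L) {
  theta <- input$theta; sdm <- input$sd
  n <- nrow(theta); d <- ncol(theta)
  C <- as.integer(C)
  if (C < 1L) stop("C must be >= 1")
  if (C > n) stop("more clusters (", C, ") than traces (", n, ")")
  set.seed(traceSeed(seed, C))
  best <- NULL
  for (ini in seq_len(max(nInit, 1L))) {
    # k-means++-style seeding on the estimates
    centers <- matrix(0, C, d)
    idx <- sample.int(n, 1)
    centers[1, ] <- theta[idx, ]
    if (C > 1) for (cc in 2:C) {
      d2 <- apply(theta, 1, function(row)
        min(colSums((t(centers[seq_len(cc - 1), , drop = FALSE]) - row)^2)))
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[cc, ] <- theta[sample.int(n, 1, prob = prob), ]
    }
    weights <- rep(1 / C, C)
    llPrev <- -Inf
    llTrace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(maxIter)) {
      es <- clusterLoglik(theta, sdm, centers, weights)
      llTrace <- c(llTrace, es$loglik)
      if (abs(es$loglik - llPrev) < tol) { converged <- TRUE; break }
      llPrev <- es$loglik
      r <- es$resp
      prec <- 1 / sdm^2
      for (cc in seq_len(C)) {
        wnum <- colSums(r[, cc] * prec * theta)
        wden <- colSums(r[, cc] * prec)
        centers[cc, ] <- ifelse(wden > 0, wnum / wden, centers[cc, ])
      }
      weights <- pmax(colMeans(r), 1e-12)
      weights <- weights / sum(weights)
    }
    es <- clusterLoglik(theta, sdm, centers, weights)
    if (is.null(best) || es$loglik > best$loglik)
      best <- list(loglik = es$loglik, centers = centers,
                   weights = weights, resp = es$resp,
                   converged = converged, llTrace = llTrace)
  }
  k <- C * (d + 1L) - 1L   # d per center plus C-1 free weights
  colnames(best$centers) <- input$paramNames
  out <- new("ClusterFit", centers = best$centers,
             weights = best$weights, responsibilities = best$resp,
             sizes = colSums(best$resp), loglik = best$loglik,
             bic = -2 * best$loglik + k * log(n),
             converged = best$converged, loglikTrace = best$llTrace,
             paramNames = input$paramNames, transform = input$transform,
             traceIds = input$traceIds)
  out@C <- C    # assigned post hoc: "C" partially matches new()'s Class
  validObject(out)
  out
}

#' Choose the number of clusters
#'
#' Fits `C = 1 .. Cmax` clusters and tabulates the log-likelihood, its
#' increment over the previous `C`, and the BIC of each cluster model
#' (`k = C (d + 1) - 1` free parameters).  The minimum-BIC row is
#' flagged; the levelling-off of the log-likelihood increase is left to
#' inspection -- both views together indicate when the correct number of
#' clusters has been surpassed.
#'
#' @param input output of [buildClusterInput()].
#' @param Cmax largest number of clusters to try.
#' @param ... passed to [fitClusters()].
#' @return list with `table` (data.frame: `C`, `loglik`, `deltaLoglik`,
#'   `bic`, `minBic`) and `fits` (list of [ClusterFit]).
#' @export
selectClusterNumber <- function(input, Cmax, ...) {
  fits <- lapply(seq_len(Cmax), function(C) fitClusters(input, C, ...))
  ll <- vapply(fits, function(f) f@loglik, numeric(1))
  bic <- vapply(fits, function(f) f@bic, numeric(1))
  tab <- data.frame(C = seq_len(Cmax), loglik = ll,
                    deltaLoglik = c(NA, diff(ll)), bic = bic,
                    minBic = seq_len(Cmax) == which.min(bic))
  list(table = tab, fits = fits)
}

#' Hard cluster assignment
#'
#' @param fit a [ClusterFit].
#' @return integer vector: each trace's maximum-responsibility cluster.
#' @export
clusterAssignments <- function(fit) {
  max.col(fit@responsibilities, ties.method = "first")
}
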