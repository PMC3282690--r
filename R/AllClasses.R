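#' @import methods
#' @importFrom stats dpois dnorm rpois rnorm runif quantile median qchisq
#'   qnorm kmeans sd setNames
#' @importFrom utils modifyList
#' @useDynLib smtrace, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Trace: one molecule's intensity time series
#'
#' A `Trace` holds the recorded intensities of a single molecule: a T x C
#' matrix (T time steps, C channels, e.g. donor and acceptor photon
#' counts), the sampling interval `dt` in seconds, and free-form metadata
#' (experiment id, condition, ...). Intensities must be finite and, for
#' channels modelled as Poisson counts, non-negative.
#'
#' @slot id character scalar, unique within a [TraceSet].
#' @slot dt sampling interval in seconds per time step (> 0).
#' @slot channels numeric matrix, T rows (time) by C columns (channels).
#' @slot metadata named list of scalar annotations.
#' @seealso [newTrace()], [readTraces()], [simulateTraces()]
#' @export
setClass("Trace",
  representation(id = "character", dt = "numeric",
                 channels = "matrix", metadata = "list"))

setValidity("Trace", function(object) {
  msgs <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msgs <- c(msgs, "id must be a single non-empty string")
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    msgs <- c(msgs, "dt must be a single positive number")
  ch <- object@channels
  if (!is.numeric(ch) || nrow(ch) < 1L || ncol(ch) < 1L)
    msgs <- c(msgs, "channels must be a numeric matrix with T >= 1, C >= 1")
  else if (!all(is.finite(ch)))
    msgs <- c(msgs, "all intensities must be finite")
  if (length(object@metadata) && is.null(names(object@metadata)))
    msgs <- c(msgs, "metadata must be a named list")
  if (length(msgs)) msgs else TRUE
})

#' TraceSet: an ordered collection of traces
#'
#' Container for a population of [Trace] objects with unique ids, plus a
#' free-text provenance description.  Supports `length()`, `[`, `[[` and
#' iteration in input order.
#'
#' @slot traces list of [Trace] objects.
#' @slot provenance character scalar describing the origin of the set.
#' @export
setClass("TraceSet",
  representation(traces = "list", provenance = "character"))

setValidity("TraceSet", function(object) {
  msgs <- character()
  if (!all(vapply(object@traces, is, logical(1), "Trace")))
    msgs <- c(msgs, "all elements must be Trace objects")
  else {
    ids <- vapply(object@traces, function(tr) tr@id, character(1))
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
      msgs <- c(msgs, paste0("duplicate trace ids: ",
                             paste(dup, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' ModelSpec: a candidate kinetic + emission model
#'
#' Describes one entry of the model menu fitted to each trace: the number
#' of hidden states `K`, the set of directed transitions allowed to carry
#' probability, the per-channel emission family (`"poisson"` or
#' `"gaussian"`), optional tie groups constraining states to share
#' emission parameters within a channel, and whether the fitted chain must
#' satisfy detailed balance (thermodynamic closure), as appropriate for
#' systems at equilibrium.
#'
#' @slot name model label, e.g. `"2-state"` or `"3-thermo"`.
#' @slot K integer number of hidden states (>= 1).
#' @slot edges integer matrix with two columns (from, to), one row per
#'   allowed directed transition; self-transitions are implicit.
#' @slot detailedBalance logical; if `TRUE` every edge must be reversible
#'   and fits are constrained so that `pi_i A_ij = pi_j A_ji`.
#' @slot families character vector, one emission family per channel.
#' @slot tieGroups list, one integer vector of length `K` per channel,
#'   assigning each state to an emission tie group.
#' @seealso [modelSpec()], [builtinModels()], [countFreeParameters()]
#' @export
setClass("ModelSpec",
  representation(name = "character", K = "integer", edges = "matrix",
                 detailedBalance = "logical", families = "character",
                 tieGroups = "list"))

setValidity("ModelSpec", function(object) {
  v <- validateModel(object)
  if (length(v)) v else TRUE
})

#' HmmParams: concrete parameter values for an HMM
#'
#' Numeric parameter values for a [ModelSpec]: the K x K row-stochastic
#' transition probability matrix `A`, per-(state, channel) emission means
#' `mu` (and standard deviations `sd`, `NA` for Poisson channels), and the
#' initial state distribution `pi0` (by default the stationary
#' distribution of `A`).
#'
#' @slot A K x K row-stochastic transition probability matrix.
#' @slot mu K x C matrix of emission means.
#' @slot sd K x C matrix of emission standard deviations (`NA` where the
#'   channel family is Poisson).
#' @slot pi0 initial state probability vector of length K.
#' @slot families character vector of per-channel emission families.
#' @seealso [hmmParams()], [fitHmm()], [logLikelihood()]
#' @export
setClass("HmmParams",
  representation(A = "matrix", mu = "matrix", sd = "matrix",
                 pi0 = "numeric", families = "character"))

setValidity("HmmParams", function(object) {
  msgs <- character()
  A <- object@A
  K <- nrow(A)
  if (K != ncol(A)) msgs <- c(msgs, "A must be square")
  if (any(A < -1e-12) || any(A > 1 + 1e-12))
    msgs <- c(msgs, "entries of A must lie in [0, 1]")
  if (any(abs(rowSums(A) - 1) > 1e-8))
    msgs <- c(msgs, "rows of A must sum to 1")
  if (nrow(object@mu) != K)
    msgs <- c(msgs, "mu must have one row per state")
  if (!identical(dim(object@mu), dim(object@sd)))
    msgs <- c(msgs, "mu and sd must have identical dimensions")
  if (length(object@families) != ncol(object@mu))
    msgs <- c(msgs, "families must have one entry per channel")
  if (length(object@pi0) != K || any(object@pi0 < -1e-12) ||
      abs(sum(object@pi0) - 1) > 1e-8)
    msgs <- c(msgs, "pi0 must be a probability vector of length K")
  for (ch in seq_along(object@families)) {
    if (object@families[ch] == "poisson" && any(object@mu[, ch] <= 0))
      msgs <- c(msgs, sprintf("poisson means must be > 0 (channel %d)", ch))
    if (object@families[ch] == "gaussian" &&
        any(!is.na(object@sd[, ch]) & object@sd[, ch] <= 0))
      msgs <- c(msgs, sprintf("gaussian sds must be > 0 (channel %d)", ch))
  }
  if (length(msgs)) msgs else TRUE
})

#' HmmFit: the result of fitting an HMM to one trace
#'
#' Produced by [fitHmm()].  Carries the maximum-likelihood [HmmParams],
#' the log-likelihood at the MLE, convergence diagnostics (iteration
#' count, per-iteration log-likelihood sequence, restarts), the T x K
#' posterior state-probability matrix from forward-backward smoothing,
#' and any confidence intervals attached later by [confidenceInterval()].
#'
#' @slot spec the [ModelSpec] that was fitted.
#' @slot params the fitted [HmmParams] (maximum-likelihood estimate).
#' @slot loglik natural-log data likelihood at the MLE.
#' @slot nIter number of Baum-Welch iterations used by the best restart.
#' @slot converged logical; `TRUE` when the log-likelihood increment fell
#'   below tolerance before `maxIter`.
#' @slot degenerate logical; flags fits where distinct states collapsed
#'   onto identical emissions (e.g. an all-constant trace).
#' @slot posteriors T x K matrix of smoothed state probabilities.
#' @slot restartsUsed number of random restarts performed.
#' @slot loglikTrace per-iteration log-likelihood of the best restart.
#' @slot traceId id of the fitted trace.
#' @slot ci named list of confidence intervals (see [confidenceInterval()]).
#' @export
setClass("HmmFit",
  representation(spec = "ModelSpec", params = "HmmParams",
                 loglik = "numeric", nIter = "integer",
                 converged = "logical", degenerate = "logical",
                 posteriors = "matrix", restartsUsed = "integer",
                 loglikTrace = "numeric", traceId = "character",
                 ci = "list"))

setValidity("HmmFit", function(object) {
  msgs <- character()
  if (!is.finite(object@loglik)) msgs <- c(msgs, "loglik must be finite")
  if (nrow(object@posteriors) > 0 &&
      any(abs(rowSums(object@posteriors) - 1) > 1e-8))
    msgs <- c(msgs, "posterior rows must sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' ThresholdFit: baseline threshold-crossing analysis of one trace
#'
#' Result of [thresholdFit()]: each time point of a single channel is
#' labelled by its side of an intensity threshold, dwell times between
#' crossings are extracted (first and last, censored, dwells dropped) and
#' per-step transition probabilities are estimated as the reciprocal mean
#' completed dwell in each state -- the maximum-likelihood fit of the
#' geometric (discrete-time exponential) dwell law.  Traces with fewer
#' than two transitions are flagged as excluded.
#'
#' @slot traceId id of the analysed trace.
#' @slot threshold intensity threshold used.
#' @slot nTransitions number of threshold crossings.
#' @slot dwells1,dwells2 completed dwell lengths (time steps) below/above
#'   the threshold.
#' @slot p12,p21 estimated per-step transition probabilities (`NA` when
#'   excluded).
#' @slot excluded logical; `TRUE` when fewer than two transitions.
#' @slot reason character; why the trace was excluded, or `""`.
#' @export
setClass("ThresholdFit",
  representation(traceId = "character", threshold = "numeric",
                 nTransitions = "integer", dwells1 = "numeric",
                 dwells2 = "numeric", p12 = "numeric", p21 = "numeric",
                 excluded = "logical", reason = "character"))

#' ClusterFit: uncertainty-weighted EM clustering of fitted parameters
#'
#' Result of [fitClusters()]: a mixture model over per-molecule parameter
#' estimates in which each molecule keeps its own (diagonal) measurement
#' covariance derived from its confidence intervals, so precisely
#' determined molecules pull cluster centers harder than noisy ones.
#'
#' @slot C number of clusters.
#' @slot centers C x d matrix of cluster centers.
#' @slot weights mixture proportions (length C, sums to 1).
#' @slot responsibilities n x C posterior membership probabilities.
#' @slot sizes expected number of traces per cluster (column sums of
#'   responsibilities; total equals n).
#' @slot loglik mixture log-likelihood at convergence.
#' @slot bic Bayesian information criterion of the cluster model.
#' @slot converged logical.
#' @slot loglikTrace per-iteration log-likelihood of the best start.
#' @slot paramNames names of the clustered parameters.
#' @slot transform `"log10"` or `"linear"` coordinate scale.
#' @slot traceIds ids of the clustered traces, in row order.
#' @export
setClass("ClusterFit",
  representation(C = "integer", centers = "matrix", weights = "numeric",
                 responsibilities = "matrix", sizes = "numeric",
                 loglik = "numeric", bic = "numeric", converged = "logical",
                 loglikTrace = "numeric", paramNames = "character",
                 transform = "character", traceIds = "character"))

setValidity("ClusterFit", function(object) {
  msgs <- character()
  n <- nrow(object@responsibilities)
  if (abs(sum(object@weights) - 1) > 1e-8)
    msgs <- c(msgs, "mixture weights must sum to 1")
  if (n > 0 && any(abs(rowSums(object@responsibilities) - 1) > 1e-8))
    msgs <- c(msgs, "responsibility rows must sum to 1")
  if (n > 0 && abs(sum(object@sizes) - n) > 1e-8)
    msgs <- c(msgs, "cluster sizes must sum to the number of traces")
  if (length(msgs)) msgs else TRUE
})
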