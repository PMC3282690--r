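#' Threshold-crossing baseline analysis of a trace
#'
#' The classical alternative to HMM fitting: every time point of one
#' channel is assigned to state 1 (below threshold) or state 2 (above),
#' a transition is a change of side between consecutive points, and the
#' dwell times between transitions are fitted to a model of
#' exponentially distributed dwells.  In discrete time the dwell law is
#' geometric, whose maximum-likelihood fit is the closed form
#' `p = 1 / mean(completed dwells)` -- no histogram binning needed.
#' The first and last dwells are censored (their starts/ends were not
#' observed) and are discarded.  Traces with fewer than two transitions
#' carry no usable kinetic information and are flagged `excluded`.
#'
#' Applied to pure one-state noise with the threshold at the median, each
#' point falls on either side with probability 1/2, so the estimated
#' per-step transition probability converges to 0.5 -- the signature of
#' fitting noise rather than kinetics.
#'
#' @param trace a [Trace].
#' @param channel channel index to threshold.
#' @param threshold intensity cutoff; when `NULL`, the midpoint of the
#'   two k-means (k = 2) centroids of the channel's intensities.
#' @return a [ThresholdFit].
#' @examples
#' tr <- newTrace("alt", rep(c(0, 10), 50))
#' thresholdFit(tr, threshold = 5)  # p12 = p21 = 1
#' @export
thresholdFit <- function(trace, channel = 1L, threshold = NULL) {
  x <- trace@channels[, channel]
  if (length(x) < 2L) stop("trace too short to threshold (T < 2)")
  if (is.null(threshold)) {
    km <- suppressWarnings(kmeans(x, centers = 2L, nstart = 5L))
    threshold <- mean(km$centers)
  }
  if (threshold <= min(x) || threshold >= max(x))
    stop("threshold ", threshold, " lies outside the data range [",
         min(x), ", ", max(x), "]")
  lab <- ifelse(x > threshold, 2L, 1L)
  runs <- rle(lab)
  nTrans <- length(runs$lengths) - 1L
  if (nTrans < 2L) {
    return(new("ThresholdFit", traceId = trace@id, threshold = threshold,
               nTransitions = as.integer(nTrans), dwells1 = numeric(0),
               dwells2 = numeric(0), p12 = NA_real_, p21 = NA_real_,
               excluded = TRUE, reason = "fewer than two transitions"))
  }
  keep <- 2:(length(runs$lengths) - 1L)   # drop censored first/last dwell
  dwells <- runs$lengths[keep]
  states <- runs$values[keep]
  d1 <- as.numeric(dwells[states == 1L])
  d2 <- as.numeric(dwells[states == 2L])
  p12 <- if (length(d1)) 1 / mean(d1) else NA_real_
  p21 <- if (length(d2)) 1 / mean(d2) else NA_real_
  new("ThresholdFit", traceId = trace@id, threshold = threshold,
      nTransitions = as.integer(nTrans), dwells1 = d1, dwells2 = d2,
      p12 = p12, p21 = p21, excluded = FALSE, reason = "")
}

#' Threshold analysis of a population
#'
#' @param set a [TraceSet].
#' @param ... passed to [thresholdFit()].
#' @return list of [ThresholdFit], one per trace.
#' @export
thresholdFitSet <- function(set, ...) {
  lapply(set@traces, thresholdFit, ...)
}
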