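#' @rdname Trace-class
#' @param object,x a `Trace` or `TraceSet`.
#' @export
setGeneric("traceId", function(object) standardGeneric("traceId"))

#' @rdname Trace-class
#' @export
setGeneric("samplingInterval",
           function(object) standardGeneric("samplingInterval"))

#' @rdname Trace-class
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname Trace-class
#' @export
setGeneric("traceLength", function(object) standardGeneric("traceLength"))

#' @rdname Trace-class
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @rdname Trace-class
#' @export
setGeneric("traceMetadata", function(object) standardGeneric("traceMetadata"))

#' @rdname TraceSet-class
#' @param object,x a `TraceSet`.
#' @export
setGeneric("traces", function(object) standardGeneric("traces"))

#' @rdname TraceSet-class
#' @export
setGeneric("traceIds", function(object) standardGeneric("traceIds"))

#' Accessors for Trace objects
#' @name Trace-accessors
#' @keywords internal
NULL

setMethod("traceId", "Trace", function(object) object@id)
setMethod("samplingInterval", "Trace", function(object) object@dt)
setMethod("intensities", "Trace", function(object) object@channels)
setMethod("traceLength", "Trace", function(object) nrow(object@channels))
setMethod("nChannels", "Trace", function(object) ncol(object@channels))
setMethod("traceMetadata", "Trace", function(object) object@metadata)

setMethod("traces", "TraceSet", function(object) object@traces)
setMethod("traceIds", "TraceSet", function(object)
  vapply(object@traces, traceId, character(1)))

#' @rdname TraceSet-class
#' @export
setMethod("length", "TraceSet", function(x) length(x@traces))

#' @rdname TraceSet-class
#' @param i index or character trace id.
#' @param j,drop,... ignored.
#' @export
setMethod("[[", "TraceSet", function(x, i, j, ...) {
  if (is.character(i)) {
    hit <- match(i, traceIds(x))
    if (is.na(hit)) stop("no trace with id '", i, "'")
    i <- hit
  }
  x@traces[[i]]
})

#' @rdname TraceSet-class
#' @export
setMethod("[", "TraceSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, traceIds(x))
  new("TraceSet", traces = x@traces[i], provenance = x@provenance)
})

setMethod("show", "Trace", function(object) {
  cat(sprintf("Trace '%s': %d time steps x %d channel(s), dt = %g s\n",
              object@id, traceLength(object), nChannels(object),
              object@dt))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), unlist(object@metadata),
                             sep = "=", collapse = ", "), "\n")
})

setMethod("show", "TraceSet", function(object) {
  cat(sprintf("TraceSet with %d trace(s)\n", length(object)))
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
  n <- length(object)
  if (n) {
    lens <- vapply(object@traces, traceLength, integer(1))
    cat(sprintf("  trace lengths: %d-%d steps\n", min(lens), max(lens)))
  }
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec '%s': K = %d, %d directed edge(s)%s\n",
              object@name, object@K, nrow(object@edges),
              if (object@detailedBalance) ", detailed balance" else ""))
  cat("  emission families:", paste(object@families, collapse = ", "), "\n")
})

setMethod("show", "HmmParams", function(object) {
  cat(sprintf("HmmParams: %d states, %d channel(s)\n",
              nrow(object@A), ncol(object@mu)))
  cat("  A:\n")
  print(round(object@A, 4))
  cat("  emission means:\n")
  print(round(object@mu, 3))
})

setMethod("show", "HmmFit", function(object) {
  cat(sprintf("HmmFit of trace '%s' to model '%s'\n",
              object@traceId, object@spec@name))
  cat(sprintf("  loglik = %.4f after %d iteration(s)%s%s\n",
              object@loglik, object@nIter,
              if (object@converged) " (converged)" else " (NOT converged)",
              if (object@degenerate) " [degenerate]" else ""))
  if (length(object@ci))
    cat("  confidence intervals for:",
        paste(names(object@ci), collapse = ", "), "\n")
})

setMethod("show", "ThresholdFit", function(object) {
  cat(sprintf("ThresholdFit of trace '%s': threshold = %g\n",
              object@traceId, object@threshold))
  if (object@excluded)
    cat("  excluded:", object@reason, "\n")
  else
    cat(sprintf("  %d transitions; p12 = %.4g, p21 = %.4g\n",
                object@nTransitions, object@p12, object@p21))
})

setMethod("show", "ClusterFit", function(object) {
  cat(sprintf("ClusterFit: C = %d on (%s), %s scale\n", object@C,
              paste(object@paramNames, collapse = ", "), object@transform))
  cat("  sizes:", paste(sprintf("%.1f", object@sizes), collapse = ", "), "\n")
  cat(sprintf("  loglik = %.4f, BIC = %.4f\n", object@loglik, object@bic))
})

#' Fitted parameters and likelihood accessors
#'
#' `fittedParams()` returns the [HmmParams] of a fit; `logLik()` style
#' access is provided by `fitLogLik()`; `posteriorMatrix()` returns the
#' T x K smoothing posteriors; `confidenceIntervals()` returns the CI
#' table attached by [confidenceInterval()].
#'
#' @param object an [HmmFit].
#' @return See each accessor's description.
#' @export
setGeneric("fittedParams", function(object) standardGeneric("fittedParams"))

#' @rdname fittedParams
#' @export
setGeneric("fitLogLik", function(object) standardGeneric("fitLogLik"))

#' @rdname fittedParams
#' @export
setGeneric("posteriorMatrix",
           function(object) standardGeneric("posteriorMatrix"))

#' @rdname fittedParams
#' @export
setGeneric("confidenceIntervals",
           function(object) standardGeneric("confidenceIntervals"))

setMethod("fittedParams", "HmmFit", function(object) object@params)
setMethod("fitLogLik", "HmmFit", function(object) object@loglik)
setMethod("posteriorMatrix", "HmmFit", function(object) object@posteriors)
setMethod("confidenceIntervals", "HmmFit", function(object) object@ci)
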