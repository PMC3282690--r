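specToList <- function(spec) {
  list(name = spec@name, K = spec@K,
       edges = lapply(seq_len(nrow(spec@edges)),
                      function(r) as.integer(spec@edges[r, ])),
       detailed_balance = spec@detailedBalance,
       channels = lapply(seq_along(spec@families), function(ch)
         list(family = spec@families[ch],
              tie_groups = as.integer(spec@tieGroups[[ch]]))))
}

specFromList <- function(l) {
  edges <- if (length(l$edges)) do.call(rbind, lapply(l$edges, as.integer))
           else matrix(integer(), 0, 2)
  modelSpec(l$name, l$K, edges,
            families = vapply(l$channels, `[[`, character(1), "family"),
            nChannels = length(l$channels),
            tieGroups = lapply(l$channels,
                               function(ch) as.integer(ch$tie_groups)),
            detailedBalance = isTRUE(l$detailed_balance))
}

#' Write fit results to JSON
#'
#' Fit results live in a JSON sidecar keyed by trace id -- the trace
#' file itself is never mutated.  Each entry records the model
#' specification, the MLE parameter values, the log-likelihood,
#' convergence diagnostics, any attached confidence intervals, and
#' (when the matching traces are supplied) the BIC.
#'
#' @param fits list of [HmmFit] objects.
#' @param path output file.
#' @param set optional [TraceSet]; when given, each fit's BIC is
#'   computed against its trace and stored.
#' @return invisibly, `path`.
#' @seealso [readFitResults()]
#' @export
writeFitResults <- function(fits, path, set = NULL) {
  byId <- list()
  for (fit in fits) {
    p <- fit@params
    entry <- list(
      model = specToList(fit@spec),
      loglik = fit@loglik,
      converged = fit@converged,
      degenerate = fit@degenerate,
      n_iter = fit@nIter,
      params = list(A = unname(p@A), mu = unname(p@mu),
                    sd = unname(p@sd), pi0 = unname(p@pi0)))
    if (!is.null(set)) {
      tr <- tryCatch(set[[fit@traceId]], error = function(e) NULL)
      if (!is.null(tr)) entry$bic <- bicScore(fit, tr)$bic
    }
    if (length(fit@ci)) entry$ci <- fit@ci
    byId[[fit@traceId]] <- entry
  }
  jsonlite::write_json(byId, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read fit results from JSON
#'
#' Reconstructs [HmmFit] objects written by [writeFitResults()].
#' Posterior matrices are not stored on disk; the returned fits have an
#' empty `posteriors` slot (re-derivable via [posteriorStateProbs()]).
#'
#' @param path JSON file written by [writeFitResults()].
#' @return named list of [HmmFit] keyed by trace id.
#' @export
readFitResults <- function(path) {
  raw <- jsonlite::read_json(path)
  out <- list()
  for (id in names(raw)) {
    e <- raw[[id]]
    spec <- specFromList(e$model)
    toMat <- function(x) {
      if (is.null(x)) return(matrix(NA_real_, spec@K, length(spec@families)))
      do.call(rbind, lapply(x, function(row)
        vapply(row, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
               numeric(1))))
    }
    params <- new("HmmParams", A = toMat(e$params$A),
                  mu = toMat(e$params$mu), sd = toMat(e$params$sd),
                  pi0 = vapply(e$params$pi0, as.numeric, numeric(1)),
                  families = spec@families)
    ci <- if (!is.null(e$ci)) lapply(e$ci, function(x) x) else list()
    out[[id]] <- new("HmmFit", spec = spec, params = params,
                     loglik = e$loglik, nIter = as.integer(e$n_iter),
                     converged = isTRUE(e$converged),
                     degenerate = isTRUE(e$degenerate),
                     posteriors = matrix(numeric(0), 0, spec@K),
                     restartsUsed = 0L, loglikTrace = numeric(0),
                     traceId = id, ci = ci)
  }
  out
}
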