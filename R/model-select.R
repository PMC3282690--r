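#' Bayesian information criterion of a fitted model
#'
#' `BIC = -2 log p(data | model) + k log(N)` with `k` the number of free
#' parameters (transition probabilities, emission means and standard
#' deviations; see [countFreeParameters()]) and `N` the trace length in
#' time steps.  Natural logarithms throughout.  Lower is better: the BIC
#' rewards likelihood and punishes free parameters.
#'
#' @param fit an [HmmFit].
#' @param trace the fitted [Trace] (provides `N`).
#' @param freePi0 passed to [countFreeParameters()]; set `TRUE` if the
#'   fit estimated the initial distribution freely.
#' @return list with `model`, `loglik`, `k`, `N`, `bic`.
#' @export
bicScore <- function(fit, trace, freePi0 = FALSE) {
  N <- traceLength(trace)
  if (N < 2) stop("BIC undefined for traces with fewer than 2 steps")
  if (fit@traceId != trace@id)
    stop("fit is for trace '", fit@traceId, "', not '", trace@id, "'")
  k <- countFreeParameters(fit@spec, freePi0 = freePi0)
  list(model = fit@spec@name, loglik = fit@loglik, k = k, N = N,
       bic = -2 * fit@loglik + k * log(N))
}

#' Rank candidate models for one trace by BIC
#'
#' Sorts a menu of fits of the same trace by ascending BIC and reports
#' each model's difference from the minimum (delta-BIC).  The model with
#' the lowest BIC provides the optimal fit among those compared.  Ties
#' break toward fewer parameters, then by name.
#'
#' @param fits list of [HmmFit] objects for the same trace under
#'   different models.
#' @param trace the fitted [Trace].
#' @param freePi0 passed to [bicScore()].
#' @return data.frame with columns `model`, `loglik`, `k`, `N`, `bic`,
#'   `deltaBic`, sorted ascending by `bic`.
#' @export
selectModel <- function(fits, trace, freePi0 = FALSE) {
  if (!length(fits)) stop("no fits supplied")
  ids <- vapply(fits, function(f) f@traceId, character(1))
  if (length(unique(ids)) != 1L || ids[1] != trace@id)
    stop("all fits must be of the same trace ('", trace@id, "')")
  rows <- lapply(fits, bicScore, trace = trace, freePi0 = freePi0)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(model = r$model, loglik = r$loglik, k = r$k, N = r$N,
               bic = r$bic, stringsAsFactors = FALSE)))
  df <- df[order(df$bic, df$k, df$model), , drop = FALSE]
  df$deltaBic <- df$bic - df$bic[1]
  rownames(df) <- NULL
  df
}
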