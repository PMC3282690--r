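#' Create a Trace
#'
#' @param id unique trace identifier.
#' @param channels numeric T x C matrix of intensities (a vector is taken
#'   as one channel).
#' @param dt sampling interval in seconds per time step.
#' @param metadata named list of scalar annotations.
#' @return a validated [Trace].
#' @export
newTrace <- function(id, channels, dt = 1, metadata = list()) {
  if (!is.matrix(channels)) channels <- matrix(channels, ncol = 1)
  new("Trace", id = as.character(id), dt = dt,
      channels = channels, metadata = metadata)
}

#' Create a TraceSet
#'
#' @param traces list of [Trace] objects.
#' @param provenance free-text description of where the set came from.
#' @return a validated [TraceSet].
#' @export
traceSet <- function(traces = list(), provenance = "") {
  new("TraceSet", traces = traces, provenance = provenance)
}

# Metadata values may contain the field delimiters; escape backslash,
# tab and newline so headers stay one line per key.
escapeMeta <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

unescapeMeta <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[i], "", fixed = TRUE)[[1]]
    res <- character(0)
    j <- 1
    while (j <= length(chars)) {
      if (chars[j] == "\\" && j < length(chars)) {
        res <- c(res, switch(chars[j + 1],
                             "t" = "\t", "n" = "\n", "\\" = "\\",
                             chars[j + 1]))
        j <- j + 2
      } else {
        res <- c(res, chars[j])
        j <- j + 1
      }
    }
    out[i] <- paste(res, collapse = "")
  }
  out
}

#' Write traces to a self-describing TSV file
#'
#' The on-disk trace format is plain text: each trace begins with header
#' lines `# trace_id=<id>`, `# dt=<seconds>`, `# channels=<C>` and one
#' `# meta.<key>=<value>` line per metadata entry, followed by one row of
#' C tab-separated intensities per time step.  Multiple traces are
#' concatenated.  Intensities are written at full precision (17
#' significant digits), so simulated Poisson counts round-trip exactly.
#'
#' @param set a [TraceSet].
#' @param path output file path.
#' @return invisibly, `path`.
#' @seealso [readTraces()]
#' @export
writeTraces <- function(set, path) {
  validObject(set)
  con <- file(path, "w")
  on.exit(close(con))
  for (tr in set@traces) {
    writeLines(c(sprintf("# trace_id=%s", escapeMeta(tr@id)),
                 sprintf("# dt=%.17g", tr@dt),
                 sprintf("# channels=%d", ncol(tr@channels))), con)
    if (length(tr@metadata))
      writeLines(sprintf("# meta.%s=%s", names(tr@metadata),
                         escapeMeta(vapply(tr@metadata, function(v)
                           if (is.numeric(v)) sprintf("%.17g", v)
                           else as.character(v), character(1)))), con)
    utils::write.table(format(tr@channels, digits = 17, trim = TRUE,
                              scientific = FALSE),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read traces from the TSV trace format
#'
#' Parses the format written by [writeTraces()].  Numeric-looking
#' metadata values are restored as numbers.  Malformed headers raise an
#' error naming the offending line; negative intensities are rejected
#' when `poissonChannels` marks a channel as Poisson counts.
#'
#' @param path file path.
#' @param poissonChannels integer vector of channel indices declared to
#'   hold Poisson counts (validated to be non-negative), or `NULL`.
#' @return a [TraceSet].
#' @export
readTraces <- function(path, poissonChannels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  traces <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    if (!startsWith(lines[i], "# trace_id="))
      stop("format error at line ", i,
           ": expected '# trace_id=' header, got: ", lines[i])
    id <- unescapeMeta(sub("^# trace_id=", "", lines[i]))
    hdr <- list(dt = NULL, channels = NULL)
    meta <- list()
    i <- i + 1L
    while (i <= n && startsWith(lines[i], "#")) {
      ln <- sub("^#\\s?", "", lines[i])
      if (grepl("^dt=", ln)) hdr$dt <- as.numeric(sub("^dt=", "", ln))
      else if (grepl("^channels=", ln))
        hdr$channels <- as.integer(sub("^channels=", "", ln))
      else if (grepl("^meta\\.", ln)) {
        kv <- sub("^meta\\.", "", ln)
        eq <- regexpr("=", kv, fixed = TRUE)
        if (eq < 1) stop("format error at line ", i,
                         ": metadata line without '='")
        key <- substr(kv, 1, eq - 1)
        val <- unescapeMeta(substr(kv, eq + 1, nchar(kv)))
        num <- suppressWarnings(as.numeric(val))
        meta[[key]] <- if (!is.na(num)) num else val
      } else stop("format error at line ", i, ": unknown header: ",
                  lines[i])
      i <- i + 1L
    }
    if (is.null(hdr$dt) || is.na(hdr$dt))
      stop("format error: trace '", id, "' missing dt header")
    if (is.null(hdr$channels))
      stop("format error: trace '", id, "' missing channels header")
    first <- i
    while (i <= n && nzchar(trimws(lines[i])) &&
           !startsWith(lines[i], "#")) i <- i + 1L
    if (i == first) stop("format error: trace '", id, "' has no data rows")
    rows <- strsplit(lines[first:(i - 1L)], "\t", fixed = TRUE)
    ncols <- lengths(rows)
    if (any(ncols != hdr$channels))
      stop("format error at line ", first + which(ncols != hdr$channels)[1] - 1,
           ": expected ", hdr$channels, " columns")
    ch <- matrix(as.numeric(unlist(rows)), ncol = hdr$channels,
                 byrow = TRUE)
    if (anyNA(ch)) stop("format error: non-numeric intensity in trace '",
                        id, "'")
    if (!is.null(poissonChannels)) {
      for (pc in poissonChannels)
        if (pc <= ncol(ch) && any(ch[, pc] < 0))
          stop("validation error: negative intensity in Poisson channel ",
               pc, " of trace '", id, "'")
    }
    traces[[length(traces) + 1L]] <-
      new("Trace", id = id, dt = hdr$dt, channels = ch, metadata = meta)
  }
  ids <- vapply(traces, traceId, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate trace id(s) in file: ", paste(dup, collapse = ", "))
  new("TraceSet", traces = traces,
      provenance = paste("read from", path))
}

#' Select traces by metadata and fitted parameters
#'
#' Filters a population on its metadata and, if per-trace fits are
#' supplied, on fitted parameter values -- e.g. keep only molecules whose
#' fitted transition probability lies in a range.  `criteria` is a
#' one-sided formula evaluated per trace with the trace's metadata and
#' flattened fit parameters (see [flattenFitParams()]) in scope, or a
#' predicate `function(trace, fit)`.  Order is preserved and the input
#' set is never modified.
#'
#' @param set a [TraceSet].
#' @param criteria one-sided formula (e.g. `~ k12 >= 0.05 & k12 <= 0.2`)
#'   or `function(trace, fit)` returning a single logical.
#' @param fits optional list of [HmmFit] objects; matched to traces by
#'   trace id.
#' @return the filtered [TraceSet].
#' @examples
#' set <- traceSet(list(newTrace("a", 1:5, metadata = list(cond = "wt")),
#'                      newTrace("b", 1:5, metadata = list(cond = "mut"))))
#' length(selectTraces(set, ~ cond == "wt"))  # 1
#' @export
selectTraces <- function(set, criteria, fits = NULL) {
  fitById <- list()
  if (!is.null(fits)) {
    names(fits) <- vapply(fits, function(f) f@traceId, character(1))
    fitById <- fits
  }
  keep <- vapply(set@traces, function(tr) {
    fit <- fitById[[tr@id]]
    if (is.function(criteria)) return(isTRUE(criteria(tr, fit)))
    stopifnot(inherits(criteria, "formula"))
    expr <- criteria[[length(criteria)]]
    env <- c(tr@metadata,
             if (!is.null(fit)) as.list(flattenFitParams(fit)))
    missing <- setdiff(all.vars(expr), names(env))
    if (length(missing))
      stop("unknown selection key(s): ", paste(missing, collapse = ", "))
    isTRUE(eval(expr, env, environment(criteria)))
  }, logical(1))
  new("TraceSet", traces = set@traces[keep], provenance = set@provenance)
}

#' Flatten fitted parameters to a named numeric vector
#'
#' Used by [selectTraces()] and the results files.  Off-diagonal
#' transition probabilities are exposed both as `A[i,j]` and as the
#' kinetic shorthand `kij` (e.g. `k12`); emission parameters as
#' `mu[state,channel]` and `sd[state,channel]`; plus `loglik`.
#'
#' @param fit an [HmmFit].
#' @return named numeric vector.
#' @export
flattenFitParams <- function(fit) {
  p <- fit@params
  K <- nrow(p@A)
  out <- c()
  for (i in seq_len(K)) for (j in seq_len(K)) if (i != j) {
    out[sprintf("A[%d,%d]", i, j)] <- p@A[i, j]
    out[sprintf("k%d%d", i, j)] <- p@A[i, j]
  }
  for (s in seq_len(K)) for (ch in seq_len(ncol(p@mu))) {
    out[sprintf("mu[%d,%d]", s, ch)] <- p@mu[s, ch]
    if (!is.na(p@sd[s, ch]))
      out[sprintf("sd[%d,%d]", s, ch)] <- p@sd[s, ch]
  }
  out["loglik"] <- fit@loglik
  out
}
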