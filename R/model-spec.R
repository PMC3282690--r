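#' Construct a kinetic + emission model specification
#'
#' Builds a [ModelSpec] describing one candidate model of the menu fitted
#' to each trace: `K` hidden states, an explicit set of allowed directed
#' transitions, per-channel emission families and optional emission tie
#' groups (states constrained to share emission parameters, for systems
#' where multiple states produce identical signals), and optionally a
#' detailed-balance (thermodynamic closure) constraint.
#'
#' @param name model label used in reports and results files.
#' @param K number of hidden states.
#' @param edges two-column matrix (from, to) of allowed directed
#'   transitions, or `NULL` for a fully connected chain.
#' @param families per-channel emission family, `"poisson"` or
#'   `"gaussian"`; recycled to `nChannels`.
#' @param nChannels number of intensity channels the model applies to.
#' @param tieGroups list with one integer vector of length `K` per
#'   channel assigning states to emission tie groups; default no ties.
#' @param detailedBalance logical; constrain fits to satisfy
#'   `pi_i A_ij = pi_j A_ji`.
#' @return a validated [ModelSpec].
#' @examples
#' twoState <- modelSpec("2-state", K = 2)
#' countFreeParameters(twoState)  # 2 transition probs + 2 Poisson means
#' @export
modelSpec <- function(name, K, edges = NULL, families = "poisson",
                      nChannels = 1L, tieGroups = NULL,
                      detailedBalance = FALSE) {
  K <- as.integer(K)
  if (is.null(edges)) {
    edges <- if (K > 1) {
      g <- expand.grid(from = seq_len(K), to = seq_len(K))
      as.matrix(g[g$from != g$to, , drop = FALSE])
    } else matrix(integer(), 0L, 2L)
  }
  edges <- matrix(as.integer(edges), ncol = 2L,
                  dimnames = list(NULL, c("from", "to")))
  families <- rep_len(match.arg(families, c("poisson", "gaussian"),
                                several.ok = TRUE), nChannels)
  if (is.null(tieGroups))
    tieGroups <- rep(list(seq_len(K)), nChannels)
  tieGroups <- lapply(tieGroups, as.integer)
  new("ModelSpec", name = name, K = K, edges = edges,
      detailedBalance = isTRUE(detailedBalance), families = families,
      tieGroups = tieGroups)
}

#' Validate a model specification
#'
#' Checks all [ModelSpec] invariants and returns a character vector of
#' human-readable violations (empty when the spec is valid) rather than
#' raising, so a model menu can be vetted in bulk.
#'
#' @param spec a [ModelSpec] (validity is bypassed so broken objects can
#'   be inspected).
#' @return character vector of violations; `character(0)` if valid.
#' @export
validateModel <- function(spec) {
  msgs <- character()
  K <- spec@K
  if (length(K) != 1L || K < 1L) {
    return("K must be a single integer >= 1")
  }
  e <- spec@edges
  if (ncol(e) != 2L) msgs <- c(msgs, "edges must have two columns")
  if (nrow(e)) {
    bad <- e[, 1] < 1 | e[, 1] > K | e[, 2] < 1 | e[, 2] > K
    if (any(bad))
      msgs <- c(msgs, sprintf("edge (%d,%d) references a state outside 1..%d",
                              e[bad, 1][1], e[bad, 2][1], K))
    if (any(e[, 1] == e[, 2]))
      msgs <- c(msgs, "self-transitions are implicit and must not be listed")
    if (anyDuplicated(paste(e[, 1], e[, 2])))
      msgs <- c(msgs, "duplicate edges")
  }
  if (spec@detailedBalance && nrow(e)) {
    key <- paste(e[, 1], e[, 2])
    rev <- paste(e[, 2], e[, 1])
    oneWay <- !(rev %in% key)
    if (any(oneWay))
      msgs <- c(msgs, sprintf(
        "detailed balance requires reversible edges; (%d,%d) has no reverse",
        e[oneWay, 1][1], e[oneWay, 2][1]))
  }
  if (length(spec@tieGroups) != length(spec@families))
    msgs <- c(msgs, "tieGroups must have one entry per channel")
  else for (ch in seq_along(spec@tieGroups)) {
    g <- spec@tieGroups[[ch]]
    if (length(g) != K || any(is.na(g)) || any(g < 1))
      msgs <- c(msgs, sprintf(
        "tie groups for channel %d must assign every state a group", ch))
  }
  badFam <- !spec@families %in% c("poisson", "gaussian")
  if (any(badFam))
    msgs <- c(msgs, paste0("unknown emission family: ",
                           spec@families[badFam][1]))
  msgs
}

# Cycle rank (number of independent undirected cycles) of the topology:
# E_undirected - K + number of connected components.  This is the number
# of independent Kolmogorov constraints detailed balance imposes, hence
# the parameters it removes; tree topologies lose none.
cycleRank <- function(K, edges) {
  if (!nrow(edges)) return(0L)
  und <- unique(t(apply(edges, 1, sort)))
  parent <- seq_len(K)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
  for (r in seq_len(nrow(und))) {
    a <- findRoot(und[r, 1]); b <- findRoot(und[r, 2])
    if (a != b) parent[a] <- b
  }
  comps <- length(unique(vapply(seq_len(K), findRoot, integer(1))))
  nrow(und) - K + comps
}

#' Count the free parameters of a model
#'
#' The number of independently fitted parameters `k` entering the BIC:
#' one per allowed directed transition, minus one per independent
#' undirected cycle when detailed balance is imposed (the Kolmogorov
#' criterion fixes one degree of freedom per cycle; for a single 3-cycle
#' that is exactly 1), plus the emission parameters -- one per tie group
#' per Poisson channel, two (mean, sd) per tie group per Gaussian
#' channel.  The initial state distribution is tied to the stationary
#' distribution of the transition matrix and contributes nothing;
#' set `freePi0 = TRUE` when fitting with a freely estimated initial
#' distribution, adding `K - 1`.
#'
#' @param spec a [ModelSpec].
#' @param freePi0 logical; count `K - 1` parameters for a freely
#'   estimated initial state distribution.
#' @return integer parameter count.
#' @examples
#' countFreeParameters(modelSpec("2-state", K = 2))          # 4
#' cyc <- modelSpec("3-cycle", K = 3)
#' thermo <- modelSpec("3-thermo", K = 3, detailedBalance = TRUE)
#' countFreeParameters(cyc) - countFreeParameters(thermo)    # 1
#' @export
countFreeParameters <- function(spec, freePi0 = FALSE) {
  kTrans <- nrow(spec@edges)
  if (spec@detailedBalance)
    kTrans <- kTrans - cycleRank(spec@K, spec@edges)
  perFam <- c(poisson = 1L, gaussian = 2L)
  kEmis <- sum(vapply(seq_along(spec@families), function(ch) {
    length(unique(spec@tieGroups[[ch]])) * perFam[[spec@families[ch]]]
  }, integer(1)))
  k <- kTrans + kEmis
  if (freePi0) k <- k + spec@K - 1L
  as.integer(k)
}

#' Convert a transition probability to a rate constant
#'
#' Kinetic models here are discrete-time: parameters are transition
#' probabilities per time step.  The approximate conversion to a
#' continuous-time rate constant is division by the sampling interval
#' (i.e. multiplication by the sampling rate), accurate to first order for
#' small probabilities.  For an exact conversion of a whole transition
#' matrix use [matrixProbToRate()].
#'
#' @param p transition probability per time step, in `[0, 1)`.
#' @param dt sampling interval in seconds.
#' @return rate constant in 1/seconds.
#' @examples
#' probToRate(0.1, dt = 0.1)  # 1 s^-1
#' @export
probToRate <- function(p, dt) {
  stopifnot(all(p >= 0 & p < 1), dt > 0)
  p / dt
}

#' Exact conversion of a transition matrix to a rate matrix
#'
#' Computes the continuous-time generator `Q = logm(A) / dt` by
#' eigendecomposition of the full transition matrix.  This is a standard
#' matrix-logarithm convention for embedding a discrete-time chain in
#' continuous time; it agrees with [probToRate()] to first order as
#' probabilities shrink.  Not every stochastic matrix is embeddable: if
#' the logarithm has off-diagonal entries below `-tol` the function
#' raises an error.
#'
#' @param A row-stochastic transition probability matrix.
#' @param dt sampling interval in seconds.
#' @param tol tolerance on negative off-diagonal generator entries.
#' @return K x K rate matrix (1/seconds); off-diagonals are the rate
#'   constants, rows sum to 0.
#' @examples
#' A <- matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2, byrow = TRUE)
#' matrixProbToRate(A, dt = 1)[1, 2]  # -log(0.4)/2 = 0.4581
#' @export
matrixProbToRate <- function(A, dt, tol = 1e-8) {
  stopifnot(nrow(A) == ncol(A), dt > 0)
  if (any(abs(rowSums(A) - 1) > 1e-8)) stop("A must be row-stochastic")
  eg <- eigen(A)
  if (any(Re(eg$values) <= 0 & abs(Im(eg$values)) < 1e-12))
    stop("matrix logarithm undefined: non-positive real eigenvalue")
  Q <- eg$vectors %*% diag(log(eg$values), nrow(A)) %*% solve(eg$vectors)
  if (max(abs(Im(Q))) > 1e-8)
    stop("matrix logarithm is not real; no valid generator")
  Q <- Re(Q)
  offdiag <- Q[row(Q) != col(Q)]
  if (any(offdiag < -tol))
    stop("no valid generator: negative off-diagonal rate ",
         format(min(offdiag)))
  Q[Q < 0 & row(Q) != col(Q)] <- 0
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q / dt
}

#' The built-in model menu
#'
#' The six candidate models routinely compared by BIC on three-state
#' data: `1-state`, `2-state`, `3-linear` (chain 1-2-3), `3-cycle` (all
#' transitions among three states), `3-thermo` (same topology as 3-cycle
#' but constrained to detailed balance, hence one fewer free parameter),
#' and `4-state` (linear chain of four states).
#'
#' @param nChannels number of channels the models apply to.
#' @param family emission family for every channel.
#' @return named list of [ModelSpec] objects.
#' @export
builtinModels <- function(nChannels = 1L, family = "poisson") {
  lin <- function(K) {
    i <- seq_len(K - 1)
    cbind(from = c(i, i + 1L), to = c(i + 1L, i))
  }
  specs <- list(
    modelSpec("1-state", 1L, matrix(integer(), 0, 2),
              family, nChannels),
    modelSpec("2-state", 2L, families = family, nChannels = nChannels),
    modelSpec("3-linear", 3L, lin(3L), family, nChannels),
    modelSpec("3-cycle", 3L, families = family, nChannels = nChannels),
    modelSpec("3-thermo", 3L, families = family, nChannels = nChannels,
              detailedBalance = TRUE),
    modelSpec("4-state", 4L, lin(4L), family, nChannels))
  names(specs) <- vapply(specs, function(s) s@name, character(1))
  specs
}

#' Read / write model specifications as YAML
#'
#' A `ModelSpec` serializes to a small YAML document with fields `name`,
#' `K`, `edges` (list of `[from, to]` pairs), `detailed_balance`, and a
#' `channels` list of `{family, tie_groups}`.  The six built-in menu
#' models ship in `system.file("extdata/models", package = "smtrace")`.
#'
#' @param path file path.
#' @return `readModelSpec` returns a [ModelSpec]; `writeModelSpec`
#'   invisibly returns `path`.
#' @export
readModelSpec <- function(path) {
  y <- yaml::read_yaml(path)
  edges <- if (length(y$edges))
    do.call(rbind, lapply(y$edges, as.integer))
  else matrix(integer(), 0, 2)
  modelSpec(y$name, y$K, edges,
            families = vapply(y$channels, `[[`, character(1), "family"),
            nChannels = length(y$channels),
            tieGroups = lapply(y$channels, function(ch)
              as.integer(ch$tie_groups)),
            detailedBalance = isTRUE(y$detailed_balance))
}

#' @rdname readModelSpec
#' @param spec a [ModelSpec].
#' @export
writeModelSpec <- function(spec, path) {
  y <- list(
    name = spec@name, K = spec@K,
    edges = lapply(seq_len(nrow(spec@edges)),
                   function(r) as.integer(spec@edges[r, ])),
    detailed_balance = spec@detailedBalance,
    channels = lapply(seq_along(spec@families), function(ch)
      list(family = spec@families[ch],
           tie_groups = as.integer(spec@tieGroups[[ch]]))))
  yaml::write_yaml(y, path)
  invisible(path)
}
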