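# Independent brute-force oracles: enumerate all K^T hidden paths and sum
# path probability x emission probability.  Feasible for K <= 3, T <= 8.

brutePathTable <- function(trace, params) {
  K <- nrow(params@A)
  T <- traceLength(trace)
  x <- intensities(trace)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  logp <- apply(paths, 1, function(s) {
    lp <- log(params@pi0[s[1]])
    if (T > 1)
      for (t in 2:T) lp <- lp + log(params@A[s[t - 1], s[t]])
    for (ch in seq_len(ncol(x))) {
      if (params@families[ch] == "poisson")
        lp <- lp + sum(dpois(round(x[, ch]), params@mu[s, ch], log = TRUE))
      else
        lp <- lp + sum(dnorm(x[, ch], params@mu[s, ch],
                             params@sd[s, ch], log = TRUE))
    }
    lp
  })
  list(paths = paths, logp = logp)
}

bruteLoglik <- function(trace, params) {
  tab <- brutePathTable(trace, params)
  m <- max(tab$logp)
  m + log(sum(exp(tab$logp - m)))
}

brutePosteriors <- function(trace, params) {
  tab <- brutePathTable(trace, params)
  K <- nrow(params@A)
  T <- traceLength(trace)
  w <- exp(tab$logp - max(tab$logp))
  w <- w / sum(w)
  post <- matrix(0, T, K)
  for (t in seq_len(T)) for (k in seq_len(K))
    post[t, k] <- sum(w[tab$paths[, t] == k])
  post
}

# Random small HMM instance (valid params + a matching trace) for the
# oracle-equivalence property suite.
randomSmallInstance <- function(seed, maxK = 3, maxT = 8) {
  set.seed(seed)
  K <- sample(1:maxK, 1)
  T <- sample(2:maxT, 1)
  A <- matrix(runif(K * K), K, K)
  A <- A / rowSums(A)
  family <- sample(c("poisson", "gaussian"), 1)
  mu <- matrix(sort(runif(K, 5, 50)), K, 1)
  sdm <- if (family == "gaussian") matrix(runif(K, 0.5, 3), K, 1)
         else matrix(NA_real_, K, 1)
  pi0 <- runif(K); pi0 <- pi0 / sum(pi0)
  params <- new("HmmParams", A = A, mu = mu, sd = sdm, pi0 = pi0,
                families = family)
  x <- if (family == "poisson") rpois(T, mean(mu))
       else rnorm(T, mean(mu), mean(sdm))
  trace <- newTrace(sprintf("rand-%d", seed), matrix(x, ncol = 1))
  list(trace = trace, params = params)
}

# Random TraceSet (with awkward metadata) for round-trip property tests.
randomTraceSet <- function(seed, n = 3) {
  set.seed(seed)
  traces <- lapply(seq_len(n), function(i) {
    T <- sample(2:20, 1)
    C <- sample(1:2, 1)
    ch <- matrix(round(runif(T * C, 0, 500), 3), T, C)
    newTrace(sprintf("tr-%d-%d", seed, i), ch,
             dt = runif(1, 0.01, 2),
             metadata = list(condition = sample(c("wt", "mut"), 1),
                             note = "has\ttab and \\slash and\nnewline",
                             snr = round(runif(1, 1, 10), 4)))
  })
  traceSet(traces, provenance = sprintf("random set %d", seed))
}

expectTraceSetsEqual <- function(a, b) {
  expect_equal(length(a), length(b))
  for (i in seq_len(length(a))) {
    ta <- a[[i]]; tb <- b[[i]]
    expect_identical(traceId(ta), traceId(tb))
    expect_equal(samplingInterval(ta), samplingInterval(tb))
    expect_equal(intensities(ta), intensities(tb))
    expect_equal(traceMetadata(ta)[order(names(traceMetadata(ta)))],
                 traceMetadata(tb)[order(names(traceMetadata(tb)))])
  }
}
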