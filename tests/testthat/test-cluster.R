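test_that("CI-to-sd conversion inverts the Gaussian construction", {
  # linear: CI exactly MLE +/- 1.645 sigma -> recovered sd = sigma
  sigma <- 0.01
  fit <- fitWithCi("a", 0.1, 0.1, 1, 1)
  fit@ci[["A[1,2]"]]$lo <- 0.1 - qnorm(0.95) * sigma
  fit@ci[["A[1,2]"]]$hi <- 0.1 + qnorm(0.95) * sigma
  inp <- buildClusterInput(list(fit), "A[1,2]", transform = "linear")
  expect_equal(unname(inp$sd[1, 1]), sigma, tolerance = 1e-9)
  expect_equal(unname(inp$theta[1, 1]), 0.1)
  expect_equal(dim(inp$sd), c(1L, 1L))  # d = 1 -> 1x1 covariance

  # log10: MLE 0.1 with CI (0.05, 0.2) -> theta = -1,
  # sd = log10(4) / (2 * 1.645)
  fit2 <- fitWithCi("b", 0.1, 0.1, 1, 1)
  fit2@ci[["A[1,2]"]]$lo <- 0.05
  fit2@ci[["A[1,2]"]]$hi <- 0.2
  inp2 <- buildClusterInput(list(fit2), "A[1,2]", transform = "log10")
  expect_equal(unname(inp2$theta[1, 1]), -1)
  expect_equal(unname(inp2$sd[1, 1]), log10(4) / (2 * qnorm(0.95)),
               tolerance = 1e-9)
})

test_that("missing intervals are reported with trace and parameter", {
  fit <- fitWithCi("c", 0.1, 0.1, 1, 1)
  fit@ci[["A[2,1]"]] <- NULL
  expect_error(buildClusterInput(list(fit), c("A[1,2]", "A[2,1]")),
               "'c'.*A\\[2,1\\]")
  expect_error(buildClusterInput(list(fit), paste0("p", 1:4)),
               "at most three")
})

test_that("one cluster reduces to the precision-weighted mean", {
  sim <- syntheticInput(30, matrix(c(-1, -1), 1), 0.1, seed = 5)
  fit <- fitClusters(sim$input, C = 1, nInit = 1)
  w <- 1 / sim$input$sd^2
  expect_equal(as.numeric(fit@centers),
               unname(colSums(sim$input$theta * w) / colSums(w)),
               tolerance = 1e-8)
  expect_equal(sum(fit@sizes), 30, tolerance = 1e-8)
  expect_equal(fit@weights, 1)
})

test_that("cluster mass is conserved and EM is monotone", {
  sim <- syntheticInput(40, rbind(c(-1, -1), c(-1, -0.7)), 0.08, seed = 9)
  for (C in 1:3) {
    fit <- fitClusters(sim$input, C, seed = 2)
    expect_equal(sum(fit@sizes), 40, tolerance = 1e-8)
    expect_equal(sum(fit@weights), 1, tolerance = 1e-10)
    expect_equal(rowSums(fit@responsibilities), rep(1, 40),
                 tolerance = 1e-10)
    expect_true(all(diff(fit@loglikTrace) >= -1e-8))
  }
  expect_error(fitClusters(sim$input, 41), "more clusters")
})

test_that("tiny-n EM matches a dense grid search", {
  # n = 4, d = 1, C = 2: compare against brute-force maximization over
  # (m1, m2, pi) on a fine grid
  fits <- list(fitWithCi("g1", 0.05, 0.1, 0.05, 0.05),
               fitWithCi("g2", 0.06, 0.1, 0.05, 0.05),
               fitWithCi("g3", 0.20, 0.1, 0.05, 0.05),
               fitWithCi("g4", 0.22, 0.1, 0.05, 0.05))
  inp <- buildClusterInput(fits, "A[1,2]")
  em <- fitClusters(inp, 2, nInit = 10, seed = 3)
  grid <- seq(min(inp$theta), max(inp$theta), length.out = 60)
  pis <- seq(0.1, 0.9, by = 0.1)
  bestGrid <- -Inf
  bestM <- NULL
  for (m1 in grid) for (m2 in grid) if (m2 >= m1) for (pi1 in pis) {
    ll <- sum(log(pi1 * dnorm(inp$theta[, 1], m1, inp$sd[, 1]) +
                  (1 - pi1) * dnorm(inp$theta[, 1], m2, inp$sd[, 1])))
    if (ll > bestGrid) { bestGrid <- ll; bestM <- c(m1, m2) }
  }
  expect_gte(em@loglik, bestGrid - 1e-6)
  gridStep <- diff(grid)[1]
  expect_equal(sort(as.numeric(em@centers)), bestM,
               tolerance = 2 * gridStep)
})

test_that("well-separated populations are recovered", {
  centers <- rbind(c(-1.3, -1), c(-0.7, -1))   # 6 pooled sd apart in dim 1
  sim <- syntheticInput(60, centers, 0.1, seed = 11)
  fit <- fitClusters(sim$input, 2, seed = 4)
  got <- fit@centers[order(fit@centers[, 1]), ]
  se <- 0.1 / sqrt(30)
  expect_lt(abs(got[1, 1] - -1.3), 3 * se)
  expect_lt(abs(got[2, 1] - -0.7), 3 * se)
  assign <- clusterAssignments(fit)
  acc <- mean(assign == sim$pop)
  expect_gt(max(acc, 1 - acc), 0.95)
})

test_that("cluster-number table prefers one cluster for homogeneous data", {
  wins <- sapply(1:10, function(rep) {
    sim <- syntheticInput(40, matrix(c(-1, -1), 1), 0.1, seed = 100 + rep)
    sel <- selectClusterNumber(sim$input, Cmax = 3, seed = rep, nInit = 5)
    sel$table$C[sel$table$minBic]
  })
  expect_gte(mean(wins == 1), 0.9)
})

test_that("Cmax = 1 yields a single flagged row", {
  sim <- syntheticInput(10, matrix(c(-1, -1), 1), 0.1, seed = 3)
  sel <- selectClusterNumber(sim$input, Cmax = 1)
  expect_equal(nrow(sel$table), 1L)
  expect_true(sel$table$minBic)
})
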