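# Hat matrices, F statistics, permutation machinery, pooled FDR and the
# full testing pipeline.

test_that("hat matrices are projections onto the actual column space", {
  H1 <- hatMatrix(matrix(1, 3, 1))
  expect_equal(H1, matrix(1 / 3, 3, 3))
  expect_equal(hatMatrix(diag(4)), diag(4))
  # rank deficiency: duplicated column projects like a single column
  D <- matrix(rnorm(12), 6, 2)
  D2 <- cbind(D[, 1], D[, 1])
  expect_equal(hatMatrix(D2), hatMatrix(D[, 1, drop = FALSE]), tolerance = 1e-10)
  # empty design
  expect_equal(hatMatrix(NULL, n = 3), matrix(0, 3, 3))
  # symmetric and idempotent
  H <- hatMatrix(D)
  expect_equal(H, t(H), tolerance = 1e-10)
  expect_equal(H %*% H, H, tolerance = 1e-8)
})

test_that("the F statistic matches its textbook value and invariances", {
  expect_equal(fStatistic(c(1, 2, 3, 4), c(0, 0, 1, 1)), 8)
  expect_equal(fStatistic(10 * c(1, 2, 3, 4), c(0, 0, 1, 1)), 8)        # scale
  expect_equal(fStatistic(c(1, 2, 3, 4) - 7, c(0, 0, 1, 1)), 8)         # shift
  expect_equal(fStatistic(rep(2, 6), rep(c(0, 1), 3)), 0)               # constant U
  expect_error(fStatistic(1:4, rep(1, 4)), "collinear",
               class = "disc_validation_error")
})

test_that("permutation plans are reproducible and uniform over the group", {
  p1 <- makePermutationPlan(6, B = 50, seed = 9)
  p2 <- makePermutationPlan(6, B = 50, seed = 9)
  expect_identical(p1@perm, p2@perm)
  expect_equal(nrow(makePermutationPlan(5, B = 1, seed = 1)@perm), 1L)
  # N = 3: the 6 permutations occur uniformly (chi-square GOF)
  plan <- makePermutationPlan(3, B = 1200, seed = 123)
  key <- apply(plan@perm, 1, paste, collapse = "")
  tab <- table(key)
  expect_equal(length(tab), 6L)
  chi <- sum((tab - 200)^2 / 200)
  expect_lt(chi, qchisq(0.999, df = 5))
})

test_that("permuted responses follow the plain and Smith schemes", {
  Y <- matrix(c(1, 3, 2, 5, 4, 6), ncol = 1)
  expect_equal(permutedResponse(Y, NULL, 1:6, "plain"), Y)
  expect_equal(permutedResponse(Y, NULL, c(2, 1, 4, 3, 6, 5), "plain"),
               Y[c(2, 1, 4, 3, 6, 5), , drop = FALSE])
  # smith without covariates: centered Y, flagged
  expect_message(E <- permutedResponse(Y, NULL, sample(6), "smith"), "centered")
  expect_equal(colMeans(E), 0, ignore_attr = TRUE, tolerance = 1e-12)
  # smith with Z orthogonal to Y: residuals are the centered Y itself
  Z <- matrix(rep(c(-1, 1), 3), ncol = 1)     # orthogonal to centered Y below
  Yc <- matrix(c(1, 1, 2, 2, 3, 3), ncol = 1)
  stopifnot(abs(sum(Z * scale(Yc, scale = FALSE))) < 1e-12)
  perm <- c(3, 1, 2, 6, 4, 5)
  expect_equal(permutedResponse(Yc, Z, perm, "smith"),
               scale(Yc, scale = FALSE)[perm, , drop = FALSE],
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("permutation p-values follow the printed counting formula", {
  obs <- c(5, 1, 3)
  perm <- rbind(c(rep(6, 4), rep(0, 95)),   # 4 of 99 >= 5  -> 0.04
                rep(2, 99),                 # all >=       -> 99/100
                rep(0, 99))                 # none >=      -> 0
  expect_equal(permutationPvalues(obs, perm), c(0.04, 0.99, 0))
  expect_equal(permutationPvalues(obs, perm, addOne = TRUE), c(0.05, 1, 0.01))
})

test_that("pooled permutation q-values match hand enumeration and edge rules", {
  obs <- c(10, 5, 1)
  perm <- matrix(c(0.5, 2, 6, 1, 0.2, 3), nrow = 3, byrow = TRUE)
  expect_equal(as.numeric(permutationFDR(obs, perm)),
               c(0.25, 0.25, 2 / 3), tolerance = 1e-12)
  # all observed beat every permuted value: the pseudo-count gives
  # q-tilde = 0.5/(i B), and the cumulative minimum from the bottom makes
  # every q equal to 0.5/(M B)
  obs2 <- c(9, 8, 7); perm2 <- matrix(0.1, 3, 4)
  q2 <- permutationFDR(obs2, perm2)
  expect_equal(as.numeric(q2), rep(0.5 / (3 * 4), 3), tolerance = 1e-12)
  # ties: >= includes permuted values equal to the observed one, and the
  # cumulative minimum propagates 2/4 up to the top gene
  obs3 <- c(2, 2); perm3 <- matrix(c(2, 0, 2, 0), 2, 2)
  expect_equal(as.numeric(permutationFDR(obs3, perm3)), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("q-values are monotone along the omnibus ordering and capped at 1", {
  set.seed(31)
  for (rep in 1:5) {
    obs <- rchisq(40, df = 2)
    perm <- matrix(rchisq(40 * 25, df = 2), 40, 25)
    q <- permutationFDR(obs, perm)
    ord <- order(obs, decreasing = TRUE)
    expect_true(all(diff(q[ord]) >= -1e-12))
    expect_true(all(q <= 1))
    expect_true(all(attr(q, "raw") > 0))
    # brute-force count check of the pooled tail
    i <- sample(40, 1)
    rank_i <- which(ord == i)
    cnt <- sum(perm >= obs[i])
    expect_equal(attr(q, "raw")[i],
                 min(sapply(rank_i:40, function(j)
                   max(sum(perm >= obs[ord[j]]), 0.5) / (j * 25))))
  }
})

test_that("the hat-matrix F equals a nested-OLS oracle on random small designs", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(6:30, 1)
    p <- sample(1:2, 1)
    q <- sample(0:2, 1)
    Y <- matrix(rnorm(n * p), n, p)
    Z <- if (q > 0) matrix(rnorm(n * q), n, q) else NULL
    u <- rnorm(n)
    expect_equal(fStatistic(u, Y, Z), oracleF(u, Y, Z), tolerance = 1e-8)
  }
})

test_that("runDisc is deterministic, rank-stable in B, and catches collinearity", {
  sim <- generateDataset(M = 60, nSim = 10, nCell = 25, f = 1.5, density = 0.1, seed = 3)
  dds <- simData(sim); design <- simDesign(sim)
  r1 <- runDisc(dds, design, B = 49, seed = 5)
  r2 <- runDisc(dds, design, B = 49, seed = 5)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  # q-value ranking depends only on the omnibus F, hence not on B
  r3 <- runDisc(dds, design, B = 199, seed = 8)
  expect_equal(order(r1$q_value, -r1$F_omnibus), order(r3$q_value, -r3$F_omnibus))
  expect_equal(r1$F_omnibus, r3$F_omnibus)  # observed stats don't depend on the plan
  expect_equal(r1$F_omnibus, pmax(r1$F_zero_prop, r1$F_nonzero_mean, r1$F_nonzero_sd))
  # duplicating Y as a covariate is rejected already at design construction
  expect_error(DesignSpec(Y = design@Y, Z = cbind(design@Z, dup = design@Y[, 1]),
                          individualIds = design@individualIds),
               "span of the intercept and covariates")
})

test_that("smith and plain schemes agree without covariates at a shared seed", {
  sim <- generateDataset(M = 50, nSim = 12, nCell = 20, f = 1.3, density = 0.1, seed = 21)
  design0 <- DesignSpec(Y = simDesign(sim)@Y, Z = NULL,
                        individualIds = simDesign(sim)@individualIds)
  rp <- runDisc(simData(sim), design0, B = 99, seed = 17, scheme = "plain")
  suppressMessages(rs <- runDisc(simData(sim), design0, B = 99, seed = 17, scheme = "smith"))
  expect_equal(rp$F_omnibus, rs$F_omnibus, tolerance = 1e-10)
  # centering does not change the tested span, so permuted statistics are
  # mathematically identical; only exact ties (binary Y) may resolve
  # differently at floating-point precision, moving p by ~1/B
  expect_equal(rp$p_value, rs$p_value, tolerance = 0.03)
  expect_equal(which(rp$q_value <= 0.1), which(rs$q_value <= 0.1))
})

test_that("permutation p-values are calibrated under an exchangeable null", {
  sim <- generateDataset(M = 400, nSim = 16, nCell = 40, f = 1, seed = 99)
  res <- runDisc(simData(sim), simDesign(sim), B = 99, seed = 100)
  frac <- mean(res$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(res))
  expect_lt(abs(frac - 0.05), 3 * se + 0.01)  # genes are not fully independent
})

test_that("results serialize with their settings and reload consistently", {
  sim <- generateDataset(M = 30, nSim = 8, nCell = 15, f = 1, seed = 13)
  res <- runDisc(simData(sim), simDesign(sim), B = 19, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeResults(res, f)
  lines <- readLines(f)
  expect_match(lines[2], "B=19 seed=2")
  tab <- read.table(f, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(tab), 30)
  expect_equal(tab$p_value, res$p_value, tolerance = 1e-12)
})
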