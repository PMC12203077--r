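# Hierarchical ZINB simulator: parameter hierarchy, signal injection and
# count emission.

test_that("population parameter draws are reproducible and overridable", {
  p1 <- defaultPopulationParams(50, seed = 4)
  p2 <- defaultPopulationParams(50, seed = 4)
  expect_identical(p1@params, p2@params)
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(gene_id = paste0("g", 1:5), mu = 1:5 / 10,
                    phi = rep(0, 5), pi = rep(-2, 5), sigma = rep(log(0.5), 5))
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  pp <- populationParamsFromFile(f)
  expect_equal(pp@params$mu, tab$mu)
  expect_equal(pp@params$gene_id, tab$gene_id)
})

test_that("default parameters imply mostly analysable sparsity", {
  sim <- generateDataset(M = 400, nSim = 8, nCell = 80, f = 1, seed = 60)
  sparsity <- rowMeans(SummarizedExperiment::assay(simData(sim), "counts") == 0)
  expect_gt(mean(sparsity <= 0.8), 0.7)      # most genes pass the filter
  expect_gt(mean(sparsity >= 0.05), 0.5)     # and zeros are genuinely present
})

test_that("individual-level draws collapse to population means when Sigma = 0", {
  pp <- defaultPopulationParams(20, seed = 1, Sigma = matrix(0, 4, 4))
  z <- rnorm(6)
  ip <- sampleIndividualParams(pp, 6, z = z, seed = 2)
  expect_equal(ip$mu, outer(pp@params$mu, rep(1, 6)) + outer(rep(1, 20), 0.1 * z))
  expect_equal(ip$phi, matrix(pp@params$phi, 20, 6))
  # covBeta = 0 removes the covariate effect entirely
  pp0 <- defaultPopulationParams(20, seed = 1, Sigma = matrix(0, 4, 4), covBeta = 0)
  ip0 <- sampleIndividualParams(pp0, 6, z = z, seed = 2)
  expect_equal(ip0$mu, matrix(pp0@params$mu, 20, 6))
})

test_that("individual-level variance matches the requested Sigma (MC)", {
  pp <- defaultPopulationParams(500, seed = 3)
  ip <- sampleIndividualParams(pp, 40, z = rep(0, 40), seed = 9)
  dev <- ip$mu - matrix(pp@params$mu, 500, 40)
  pv <- apply(dev, 1, var)
  expect_lt(abs(mean(pv) - pp@Sigma[1, 1]), 3 * sd(pv) / sqrt(500))
})

test_that("DE injection selects disjoint sets of the right size and shifts cases only", {
  pp <- defaultPopulationParams(400, seed = 7)
  z <- rep(0, 8)
  ip <- sampleIndividualParams(pp, 8, z = z, seed = 8)
  cases <- rep(c(FALSE, TRUE), each = 4)
  inj <- injectDE(ip, cases, density = 0.05, f = 1.5, seed = 10)
  tt <- table(inj$truth$de_type)
  expect_equal(unname(tt[c("mean", "variance", "both")]), rep(20L, 3), ignore_attr = TRUE)
  expect_equal(sum(tt), 400)
  # mean-type up gene: case mu shifted by exactly log(1.5), controls untouched
  up <- which(inj$truth$de_type == "mean" & inj$truth$direction == "up")[1]
  expect_equal(inj$params$mu[up, cases], ip$mu[up, cases] + log(1.5))
  expect_equal(inj$params$mu[up, !cases], ip$mu[up, !cases])
  dn <- which(inj$truth$de_type == "variance" & inj$truth$direction == "down")[1]
  expect_equal(inj$params$sigma[dn, cases], ip$sigma[dn, cases] - log(1.5))
  # f = 1 is a global null: no labels, no shifts
  inj0 <- injectDE(ip, cases, density = 0.05, f = 1, seed = 10)
  expect_true(all(inj0$truth$de_type == "none"))
  expect_equal(inj0$params$mu, ip$mu)
  # sub-unit expected count per type warns
  ipSmall <- sampleIndividualParams(defaultPopulationParams(10, seed = 1), 8,
                                    z = z, seed = 2)
  expect_warning(injectDE(ipSmall, cases, density = 0.05, f = 2, seed = 1), "no DE genes")
})

test_that("ZINB moments and zero mass match closed forms (MC)", {
  n <- 1e5
  set.seed(42)
  x <- rzinb(n, mu = 5, size = 2, pi = 0)
  seMean <- sqrt(17.5 / n)
  expect_lt(abs(mean(x) - 5), 3 * seMean)
  # Var = m + m^2/phi = 17.5; allow 3 SEs of the variance estimator
  k <- mean(((x - 5) / sqrt(17.5))^4)
  seVar <- 17.5 * sqrt((k - 1) / n)
  expect_lt(abs(var(x) - 17.5), 3 * seVar)
  # zero mass with inflation: pi + (1-pi) (phi/(phi+m))^phi
  y <- rzinb(n, mu = 3, size = 1.5, pi = 0.2)
  p0 <- 0.2 + 0.8 * (1.5 / 4.5)^1.5
  expect_lt(abs(mean(y == 0) - p0), 3 * sqrt(p0 * (1 - p0) / n))
})

test_that("degenerate parameters behave: certain zero-inflation, zero sigma", {
  pp <- defaultPopulationParams(3, seed = 2, Sigma = matrix(0, 4, 4), covBeta = 0)
  ip <- sampleIndividualParams(pp, 4, z = rep(0, 4), seed = 3)
  ip$pi[] <- 50           # logit scale -> pi = 1
  dds <- generateCounts(ip, nCell = 30, seed = 5)
  expect_true(all(SummarizedExperiment::assay(dds, "counts") == 0))
  # sigma -> 0: all cells of one individual share one ZINB law, so the
  # per-individual zero fraction matches the NB zero-mass formula
  ip2 <- sampleIndividualParams(pp, 4, z = rep(0, 4), seed = 3)
  ip2$mu[] <- log(4); ip2$phi[] <- log(2); ip2$pi[] <- -1e3; ip2$sigma[] <- -1e3
  dds2 <- generateCounts(ip2, nCell = 4000, seed = 6)
  zf <- mean(SummarizedExperiment::assay(dds2, "counts")[1, ] == 0)
  p0 <- (2 / 6)^2
  expect_lt(abs(zf - p0), 3 * sqrt(p0 * (1 - p0) / 4000))
})

test_that("datasets are seed-deterministic and signals are local to DE cases", {
  s1 <- generateDataset(M = 200, nSim = 8, nCell = 30, f = 1, density = 0.05, seed = 31)
  s2 <- generateDataset(M = 200, nSim = 8, nCell = 30, f = 1.5, density = 0.05, seed = 31)
  s3 <- generateDataset(M = 200, nSim = 8, nCell = 30, f = 1.5, density = 0.05, seed = 31)
  c1 <- SummarizedExperiment::assay(simData(s1), "counts")
  c2 <- SummarizedExperiment::assay(simData(s2), "counts")
  expect_identical(c2, SummarizedExperiment::assay(simData(s3), "counts"))
  d <- c1 != c2
  tr <- simTruth(s2)
  expect_true(all(tr$de_type[rowSums(d) > 0] != "none"))
  caseCells <- individualOf(simData(s2)) %in% sprintf("ind%03d", 5:8)
  expect_true(all(!d[, !caseCells]))
  # case/control split is half and half, controls first
  expect_equal(unname(simDesign(s2)@Y[, 1]), rep(c(0, 1), each = 4))
})

test_that("mean-DE separation between cases and controls grows with the fold", {
  gaps <- sapply(c(1.1, 1.3, 1.5), function(f) {
    sim <- generateDataset(M = 150, nSim = 12, nCell = 50, f = f,
                           density = 0.1, seed = 77)
    dds <- normalizeTSS(simData(sim))
    fa <- extractFeatures(dds)
    up <- simTruth(sim)$de_type == "mean" & simTruth(sim)$direction == "up"
    mu <- fa@W[up, , "nonzero_mean", drop = FALSE][, , 1]
    cases <- simDesign(sim)@Y[, 1] == 1
    mean(rowMeans(mu[, cases]) - rowMeans(mu[, !cases]))
  })
  expect_true(all(diff(gaps) > 0))
})

test_that("simulated datasets round-trip through the text formats", {
  sim <- generateDataset(M = 25, nSim = 6, nCell = 10, f = 1.3, density = 0.1, seed = 12)
  d <- withr::local_tempdir()
  writeSimulatedDataset(sim, d)
  expect_true(all(file.exists(file.path(d, c("matrix.mtx", "genes.txt", "cells.txt",
                                             "cell_meta.tsv", "individual_meta.tsv",
                                             "truth.tsv")))))
  back <- attachIndividuals(
    readCounts(file.path(d, "matrix.mtx"), file.path(d, "genes.txt"),
               file.path(d, "cells.txt")),
    read.table(file.path(d, "cell_meta.tsv"), header = TRUE, sep = "\t"))
  expect_equal(as.matrix(SummarizedExperiment::assay(back, "counts")),
               as.matrix(SummarizedExperiment::assay(simData(sim), "counts")),
               ignore_attr = TRUE)
  truth <- read.table(file.path(d, "truth.tsv"), header = TRUE, sep = "\t")
  expect_equal(truth$de_type, simTruth(sim)$de_type)
})
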