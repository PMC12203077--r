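# Shared fixtures and cached simulation studies.

# A tiny deterministic data set: 4 genes, 6 cells, 3 individuals.
makeTinyDataSet <- function() {
  counts <- matrix(c(
    2L, 0L, 3L, 0L, 1L, 4L,
    0L, 0L, 0L, 0L, 0L, 0L,
    5L, 1L, 0L, 2L, 0L, 0L,
    1L, 1L, 1L, 1L, 1L, 1L), nrow = 4, byrow = TRUE)
  DiscDataSet(counts,
              geneIds = paste0("g", 1:4),
              cellIds = paste0("c", 1:6),
              individuals = c("A", "A", "B", "B", "C", "C"))
}

# Write a small Matrix Market fixture and return its paths.
writeMMFixture <- function(dir, entries, nrow, ncol, genes, cells) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(dir, "m.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow, ncol, nrow(entries)),
               apply(entries, 1, paste, collapse = " ")), mtx)
  gf <- file.path(dir, "genes.txt"); writeLines(genes, gf)
  cf <- file.path(dir, "cells.txt"); writeLines(cells, cf)
  list(mtx = mtx, genes = gf, cells = cf)
}

# Nested-OLS oracle for the F statistic: two independent lm() fits.
oracleF <- function(u, Y, Z = NULL) {
  df <- data.frame(u = u)
  Ym <- as.matrix(Y); colnames(Ym) <- paste0("y", seq_len(ncol(Ym)))
  full <- cbind(df, Ym)
  if (!is.null(Z) && ncol(as.matrix(Z)) > 0) {
    Zm <- as.matrix(Z); colnames(Zm) <- paste0("zc", seq_len(ncol(Zm)))
    full <- cbind(full, Zm)
    red <- stats::lm(u ~ ., data = cbind(df, as.data.frame(Zm)))
  } else {
    red <- stats::lm(u ~ 1, data = df)
  }
  fit <- stats::lm(u ~ ., data = full)
  rssF <- sum(stats::residuals(fit)^2)
  rssR <- sum(stats::residuals(red)^2)
  p <- ncol(Ym)
  dfRes <- stats::df.residual(fit)
  ((rssR - rssF) / p) / (rssF / dfRes)
}

# Cached heavyweight studies, shared by the acceptance tests (computed once
# per test session).
.studyCache <- new.env(parent = emptyenv())

cachedStudy <- function(key, expr) {
  if (!exists(key, envir = .studyCache)) assign(key, force(expr), envir = .studyCache)
  get(key, envir = .studyCache)
}

nullStudy <- function() cachedStudy("null", runStudy(
  studyPreset("global-null"), runs = 100L, seed = 20260920L, B = 99L, verbose = FALSE))

foldStudy <- function() cachedStudy("fold", runStudy(
  studyPreset("fold-sweep"), runs = 20L, seed = 4181L, B = 99L, verbose = FALSE))

cellStudy <- function() cachedStudy("cell", runStudy(
  studyPreset("cell-sweep"), runs = 20L, seed = 8231L, B = 99L, verbose = FALSE))
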