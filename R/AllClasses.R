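#' @import methods
#' @importFrom stats sd rnorm runif rnbinom plogis qlogis setNames complete.cases
#' @importFrom utils read.table write.table
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importClassesFrom S4Vectors DFrame
#' @importFrom S4Vectors DataFrame metadata 'metadata<-'
#' @importFrom SummarizedExperiment assay 'assay<-' assayNames colData 'colData<-'
#' @useDynLib DiSC, .registration = TRUE
NULL

#' DiscDataSet: genes-by-cells counts with individual assignment
#'
#' A thin extension of \linkS4class{SingleCellExperiment} holding a
#' non-negative integer count matrix (genes in rows, cells in columns) and,
#' in \code{colData()$individual}, the individual each cell was sampled
#' from.  All downstream feature extraction and testing operates at the
#' individual level, so the individual assignment is part of the data model
#' rather than optional metadata.
#'
#' Validity requires: finite, non-negative, integer-valued counts; unique
#' gene and cell identifiers; and, when individuals are assigned, no missing
#' labels (each individual then has at least one cell by construction).
#'
#' @export
setClass("DiscDataSet", contains = "SingleCellExperiment")

setValidity("DiscDataSet", function(object) {
  m <- SummarizedExperiment::assay(object, "counts")
  msg <- c(character(), .countValueIssues(m))
  if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicate gene identifiers")
  if (anyDuplicated(colnames(object))) msg <- c(msg, "duplicate cell identifiers")
  if ("individual" %in% colnames(SummarizedExperiment::colData(object))) {
    ind <- SummarizedExperiment::colData(object)$individual
    if (anyNA(ind)) msg <- c(msg, "missing individual labels")
  }
  if (length(msg)) msg else TRUE
})

#' DesignSpec: individual-level design for the association test
#'
#' Holds the N x p matrix \code{Y} of variables of interest (binary,
#' ordinal-coded or continuous), the N x q covariate matrix \code{Z}
#' (possibly with zero columns), and the individual identifiers aligned to
#' the rows.  An intercept is never stored here; the test adds one
#' internally.
#'
#' @export
setClass("DesignSpec",
  representation(Y = "matrix", Z = "matrix", individualIds = "character"))

setValidity("DesignSpec", function(object) {
  msg <- character()
  n <- length(object@individualIds)
  if (nrow(object@Y) != n) msg <- c(msg, "nrow(Y) does not match individualIds")
  if (nrow(object@Z) != n) msg <- c(msg, "nrow(Z) does not match individualIds")
  if (ncol(object@Y) < 1L) msg <- c(msg, "Y must have at least one column")
  if (anyDuplicated(object@individualIds)) msg <- c(msg, "duplicate individual ids")
  if (anyNA(object@Y) || anyNA(object@Z)) msg <- c(msg, "design matrices contain NA")
  p <- ncol(object@Y); q <- ncol(object@Z)
  if (n < p + q + 2L)
    msg <- c(msg, sprintf("need at least p + q + 2 = %d individuals, have %d", p + q + 2L, n))
  if (!length(msg)) {
    # every Y column must add rank beyond [1, Z]
    base <- cbind(rep(1, n), object@Z)
    r0 <- qr(base)$rank
    for (j in seq_len(p)) {
      if (qr(cbind(base, object@Y[, j]))$rank <= r0) {
        msg <- c(msg, sprintf("variable of interest '%s' lies in the span of the intercept and covariates",
                              colnames(object@Y)[j] %||% as.character(j)))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn DesignSpec-class Constructor.
#' @param Y,Z numeric matrices (or vectors/data.frames coerced to matrices);
#'   \code{Z} may be \code{NULL} for a covariate-free design.
#' @param individualIds character vector of individual identifiers aligned
#'   with the rows of \code{Y} and \code{Z}.
#' @export
DesignSpec <- function(Y, Z = NULL, individualIds) {
  toMat <- function(x, prefix) {
    if (is.null(x)) return(matrix(numeric(0), nrow = length(individualIds), ncol = 0))
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    if (is.null(colnames(x))) colnames(x) <- paste0(prefix, seq_len(ncol(x)))
    x
  }
  methods::new("DesignSpec", Y = toMat(Y, "y"), Z = toMat(Z, "z"),
               individualIds = as.character(individualIds))
}

setMethod("show", "DesignSpec", function(object) {
  cat(sprintf("DesignSpec: %d individuals, %d variable(s) of interest [%s], %d covariate(s)%s\n",
              length(object@individualIds), ncol(object@Y),
              paste(colnames(object@Y), collapse = ", "), ncol(object@Z),
              if (ncol(object@Z)) paste0(" [", paste(colnames(object@Z), collapse = ", "), "]") else ""))
})

#' FeatureArray: per-gene, per-individual distributional features
#'
#' \code{W} holds the raw features (genes x individuals x K) extracted from
#' the normalized expression; \code{U} the transformed features on which the
#' linear models are fitted.  \code{U} is empty until
#' \code{\link{transformFeatures}} is called.
#'
#' @export
setClass("FeatureArray",
  representation(W = "array", U = "array", featureNames = "character",
                 rho = "numeric", cap = "numeric"))

setValidity("FeatureArray", function(object) {
  msg <- character()
  if (length(dim(object@W)) != 3L) msg <- c(msg, "W must be a 3-d array")
  else if (dim(object@W)[3] != length(object@featureNames))
    msg <- c(msg, "third dimension of W must match featureNames")
  if (length(object@U) && !identical(dim(object@U), dim(object@W)))
    msg <- c(msg, "U must be empty or have the dimensions of W")
  if (anyNA(object@W)) msg <- c(msg, "W contains NA")
  if (length(object@U) && anyNA(object@U)) msg <- c(msg, "U contains NA")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FeatureArray", function(object) {
  d <- dim(object@W)
  cat(sprintf("FeatureArray: %d genes x %d individuals x %d features (%s); %s\n",
              d[1], d[2], d[3], paste(object@featureNames, collapse = ", "),
              if (length(object@U)) sprintf("transformed (rho = %g, cap = %g)", object@rho, object@cap)
              else "not yet transformed"))
})

#' PermutationPlan: the shared permutation layout
#'
#' One plan is shared across all genes and features: this sharing is what
#' makes the pooled permutation FDR well defined, and lets the N x N
#' projection matrices be computed once per permutation instead of once per
#' gene.
#'
#' @export
setClass("PermutationPlan",
  representation(perm = "matrix", B = "integer", scheme = "character",
                 seed = "integer"))

setValidity("PermutationPlan", function(object) {
  msg <- character()
  if (nrow(object@perm) != object@B) msg <- c(msg, "perm must have B rows")
  if (!object@scheme %in% c("plain", "smith")) msg <- c(msg, "scheme must be 'plain' or 'smith'")
  n <- ncol(object@perm)
  bad <- apply(object@perm, 1L, function(r) !identical(sort(r), seq_len(n)))
  if (any(bad)) msg <- c(msg, "each row of perm must be a permutation of 1..N")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PermutationPlan", function(object) {
  cat(sprintf("PermutationPlan: B = %d, N = %d, scheme = %s, seed = %d\n",
              object@B, ncol(object@perm), object@scheme, object@seed))
})

#' DiscResult: per-gene test results
#'
#' A \linkS4class{DFrame} with one row per tested gene: the observed F
#' statistic for each feature, the omnibus (max) F, the permutation p-value
#' and the pooled-permutation q-value (capped at 1; the uncapped values are
#' kept in \code{metadata()$qRaw}).  \code{metadata()} also records B, seed,
#' scheme, rho and cap.
#'
#' @export
setClass("DiscResult", contains = "DFrame")

setMethod("show", "DiscResult", function(object) {
  md <- S4Vectors::metadata(object)
  cat(sprintf("DiscResult: %d genes; B = %s, scheme = %s, seed = %s\n",
              nrow(object), md$B %||% "?", md$scheme %||% "?", md$seed %||% "?"))
  methods::callNextMethod()
})

#' PopulationParams: per-gene population parameters of the ZINB hierarchy
#'
#' \code{params} has one row per gene with columns \code{mu} (log scale mean
#' of cell log-means), \code{phi} (log dispersion), \code{pi} (logit zero
#' probability) and \code{sigma} (log of the between-cell SD of log-means).
#' \code{Sigma} is the 4 x 4 covariance of the individual-level draw around
#' these means, and \code{covBeta} the regression coefficient of the
#' continuous individual covariate on the log-mean.
#'
#' @export
setClass("PopulationParams",
  representation(params = "data.frame", Sigma = "matrix", covBeta = "numeric"))

setValidity("PopulationParams", function(object) {
  msg <- character()
  need <- c("gene_id", "mu", "phi", "pi", "sigma")
  if (!all(need %in% colnames(object@params)))
    msg <- c(msg, paste("params must have columns", paste(need, collapse = ", ")))
  if (!identical(dim(object@Sigma), c(4L, 4L))) msg <- c(msg, "Sigma must be 4 x 4")
  else {
    if (max(abs(object@Sigma - t(object@Sigma))) > 1e-8) msg <- c(msg, "Sigma must be symmetric")
    ev <- eigen(object@Sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) msg <- c(msg, "Sigma must be positive semi-definite")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PopulationParams", function(object) {
  cat(sprintf("PopulationParams: %d genes, covBeta = %g\n", nrow(object@params), object@covBeta))
})

#' SimulatedDataset: counts, design and ground truth from the simulator
#'
#' @export
setClass("SimulatedDataset",
  representation(data = "DiscDataSet", design = "DesignSpec",
                 truth = "data.frame", seed = "integer"))

setMethod("show", "SimulatedDataset", function(object) {
  tt <- table(object@truth$de_type)
  cat(sprintf("SimulatedDataset: %d genes x %d cells, %d individuals, seed %d\n",
              nrow(object@data), ncol(object@data),
              length(object@design@individualIds), object@seed))
  cat("  DE truth:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
})

#' @describeIn SimulatedDataset-class Count data as a \linkS4class{DiscDataSet}.
#' @param x a SimulatedDataset.
#' @export
simData <- function(x) x@data

#' @describeIn SimulatedDataset-class Individual-level design.
#' @export
simDesign <- function(x) x@design

#' @describeIn SimulatedDataset-class Ground-truth table (gene_id, de_type,
#'   direction, fold).
#' @export
simTruth <- function(x) x@truth
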