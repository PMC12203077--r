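# Distributional feature extraction.
#
# For every gene and individual, the cell-level distribution of normalized
# expression is summarised by K features.  The defaults are the zero
# proportion, the mean of the non-zero values and the sample standard
# deviation of the non-zero values; additional features can be registered
# and are picked up automatically by the omnibus test.

.featureRegistry <- new.env(parent = emptyenv())

.builtinFeatures <- function() {
  list(
    zero_prop = list(
      name = "zero_prop", builtin = TRUE,
      extractor = function(v) mean(v == 0),
      # capped logit; w = 0 and w = 1 map exactly to -cap / +cap
      transformer = function(w, rho, cap) pmin(pmax(log(w / (1 - w)), -cap), cap)),
    nonzero_mean = list(
      name = "nonzero_mean", builtin = TRUE,
      extractor = function(v) { nz <- v[v != 0]; if (length(nz)) mean(nz) else 0 },
      transformer = function(w, rho, cap) w^rho),
    nonzero_sd = list(
      name = "nonzero_sd", builtin = TRUE,
      extractor = function(v) { nz <- v[v != 0]; if (length(nz) >= 2L) stats::sd(nz) else 0 },
      transformer = function(w, rho, cap) w^rho)
  )
}

.initFeatureRegistry <- function() {
  assign("features", .builtinFeatures(), envir = .featureRegistry)
}

.getFeatures <- function() {
  if (!exists("features", envir = .featureRegistry)) .initFeatureRegistry()
  get("features", envir = .featureRegistry)
}

#' Register an additional distributional feature
#'
#' Registered features are included by all subsequent calls to
#' \code{\link{extractFeatures}} and \code{\link{transformFeatures}}, and
#' therefore automatically enter the omnibus test.
#'
#' @param name unique feature name.
#' @param extractor function mapping one individual's vector of normalized
#'   expression values to a single number.
#' @param transformer function of \code{(w, rho, cap)} mapping the raw
#'   feature to the model scale; defaults to the identity.  It is applied
#'   elementwise (vectorized input is fine but not required).
#' @return Invisibly, the new number of features K.
#' @export
registerFeature <- function(name, extractor,
                            transformer = function(w, rho, cap) w) {
  feats <- .getFeatures()
  if (name %in% names(feats))
    .discStop("validation", sprintf("feature '%s' is already registered", name))
  stopifnot(is.function(extractor), is.function(transformer))
  feats[[name]] <- list(name = name, builtin = FALSE,
                        extractor = extractor, transformer = transformer)
  assign("features", feats, envir = .featureRegistry)
  invisible(length(feats))
}

#' @describeIn registerFeature Restore the three default features,
#'   discarding any registered extras.
#' @export
resetFeatures <- function() {
  .initFeatureRegistry()
  invisible(3L)
}

#' @describeIn registerFeature Names of the currently registered features.
#' @export
listFeatures <- function() names(.getFeatures())

#' Extract per-gene, per-individual distributional features
#'
#' Computes, for each gene and individual, every registered feature from the
#' normalized expression values of that individual's cells.  For the default
#' features: zero proportion = (number of zero cells) / C_j; non-zero mean
#' (0 when the individual has no non-zero cell, which keeps the later power
#' transform at its fixed point); non-zero sample SD with denominator n - 1
#' (0 when fewer than two non-zero cells).
#'
#' @param dds a \linkS4class{DiscDataSet} that has been normalized with
#'   \code{\link{normalizeTSS}} and carries individual assignments.
#' @return A \linkS4class{FeatureArray} with raw features \code{W} filled
#'   and \code{U} empty.
#' @export
extractFeatures <- function(dds) {
  if (!"normcounts" %in% SummarizedExperiment::assayNames(dds))
    .discStop("validation", "no 'normcounts' assay; call normalizeTSS() first")
  ind <- individualOf(dds)
  if (is.null(ind))
    .discStop("validation", "no individual assignment; call attachIndividuals() first")
  if (any(table(ind) == 0L)) .discStop("validation", "individual with zero cells")
  X <- SummarizedExperiment::assay(dds, "normcounts")
  M <- nrow(X); N <- nlevels(ind)
  grp <- as.integer(ind)
  cj <- tabulate(grp, nbins = N)

  st <- if (methods::is(X, "CsparseMatrix")) {
    .group_stats_sparse(X@p, X@i, X@x, M, grp, N)
  } else {
    Xd <- as.matrix(X); storage.mode(Xd) <- "double"
    .group_stats_dense(Xd, grp, N)
  }
  nnz <- st$nnz
  zeroProp <- 1 - sweep(nnz, 2L, cj, "/")
  mu <- ifelse(nnz > 0, st$sum / pmax(nnz, 1), 0)
  ss <- st$sumsq - nnz * mu^2
  sdv <- ifelse(nnz >= 2, sqrt(pmax(ss, 0) / pmax(nnz - 1, 1)), 0)

  feats <- .getFeatures()
  K <- length(feats)
  W <- array(0, dim = c(M, N, K),
             dimnames = list(rownames(dds), levels(ind), names(feats)))
  for (k in seq_len(K)) {
    f <- feats[[k]]
    if (f$builtin) {
      W[, , k] <- switch(f$name,
                         zero_prop = zeroProp,
                         nonzero_mean = mu,
                         nonzero_sd = sdv)
    } else {
      W[, , k] <- .extractCustom(X, grp, N, f$extractor)
    }
  }
  methods::new("FeatureArray", W = W, U = array(numeric(0)),
               featureNames = names(feats), rho = NA_real_, cap = NA_real_)
}

# Transformers may take (w), (w, rho) or (w, rho, cap).
.applyTransformer <- function(tr, w, rho, cap) {
  nf <- length(formals(tr))
  if (nf >= 3L) tr(w, rho, cap) else if (nf == 2L) tr(w, rho) else tr(w)
}

# Slow generic path for user-registered features.
.extractCustom <- function(X, grp, N, extractor) {
  Xd <- as.matrix(X)
  idx <- split(seq_len(ncol(Xd)), grp)
  out <- matrix(0, nrow(Xd), N)
  for (i in seq_len(nrow(Xd))) {
    row <- Xd[i, ]
    out[i, ] <- vapply(idx, function(ix) as.numeric(extractor(row[ix])), numeric(1))
  }
  out
}

#' Transform distributional features to the model scale
#'
#' The zero proportion is logit-transformed and capped at \code{±cap}
#' (proportions of exactly 0 or 1 map to \code{-cap} / \code{+cap}, so no
#' infinite intermediates survive); the non-zero mean and SD get a power
#' transform \code{w^rho}.  Custom features use their registered
#' transformer.
#'
#' @param fa a \linkS4class{FeatureArray} from \code{\link{extractFeatures}}.
#' @param rho exponent of the power transform (must be > 0).
#' @param cap logit cap.
#' @return The array with \code{U} filled.
#' @export
transformFeatures <- function(fa, rho = 0.5, cap = 7) {
  if (!is.numeric(rho) || rho <= 0) .discStop("validation", "rho must be > 0")
  feats <- .getFeatures()
  if (!identical(names(feats), fa@featureNames))
    .discStop("validation", "feature registry changed since extraction; re-run extractFeatures()")
  U <- fa@W
  for (k in seq_along(feats)) {
    tr <- feats[[k]]$transformer
    w <- fa@W[, , k]
    u <- .applyTransformer(tr, w, rho, cap)
    if (length(u) != length(w)) { # non-vectorized user transformer
      u <- matrix(vapply(w, function(x) as.numeric(.applyTransformer(tr, x, rho, cap)),
                         numeric(1)), nrow(w), ncol(w))
    }
    U[, , k] <- u
  }
  if (anyNA(U)) .discStop("numerical", "feature transform produced NA")
  methods::initialize(fa, U = U, rho = rho, cap = cap)
}

#' Export features as a long-format table
#'
#' @param fa a \linkS4class{FeatureArray}.
#' @param path optional TSV path; when NULL the data.frame is returned only.
#' @return A data.frame with columns gene, individual, feature, raw and
#'   (when transformed) transformed values.
#' @export
featureTable <- function(fa, path = NULL) {
  dn <- dimnames(fa@W)
  df <- expand.grid(gene = dn[[1]], individual = dn[[2]], feature = dn[[3]],
                    stringsAsFactors = FALSE)
  df$value <- as.vector(fa@W)
  if (length(fa@U)) df$transformed <- as.vector(fa@U)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
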