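# Covariate-adjusted F statistics, the omnibus max-F, shared-plan
# permutation p-values and the pooled permutation FDR.

#' Projection (hat) matrix onto the column space of a design
#'
#' Uses a rank-revealing SVD, so rank-deficient designs (e.g. duplicated
#' columns) project onto their actual column space.  An empty design (zero
#' columns) yields the zero matrix.
#'
#' @param D numeric matrix with N rows (may have zero columns).
#' @param n number of rows, required only when \code{D} is NULL/empty.
#' @return N x N symmetric idempotent matrix.
#' @export
hatMatrix <- function(D, n = nrow(D)) {
  if (is.null(D) || ncol(D) == 0L) return(matrix(0, n, n))
  D <- as.matrix(D)
  s <- svd(D)
  tol <- max(dim(D)) * max(s$d, 0) * .Machine$double.eps * 100
  r <- sum(s$d > tol)
  if (r == 0L) return(matrix(0, nrow(D), nrow(D)))
  Ur <- s$u[, seq_len(r), drop = FALSE]
  tcrossprod(Ur)
}

# F statistics for all genes of one feature slab at once.
# U: M x N matrix, A = H_{YZ} - H_Z, R = I - H_{YZ}.
# Zero-variance genes (both quadratic forms below tolerance) get F = 0; a
# vanishing residual with non-vanishing numerator gets the +Inf sentinel.
.fStatMatrix <- function(U, A, R, p, dfRes) {
  qn <- rowSums((U %*% A) * U)
  qd <- rowSums((U %*% R) * U)
  eps <- 1e-10 * (rowSums(U * U) + .Machine$double.xmin)
  f <- (qn / p) / (qd / dfRes)
  f[qd <= eps & qn <= eps] <- 0
  f[qd <= eps & qn > eps] <- Inf
  pmax(f, 0)
}

#' Covariate-adjusted F statistic for one transformed feature
#'
#' Computes \deqn{F = \frac{U^T (H_{YZ} - H_Z) U / p}{U^T (I - H_{YZ}) U / df}}
#' where the hat matrices project onto the column spaces of the full design
#' (intercept, covariates, variables of interest) and the reduced design
#' (intercept, covariates), and \code{df} is N minus the rank of the full
#' design.  Equivalent to the classical nested-OLS F comparing the two
#' models.  A constant response returns 0; a perfectly fitted response with
#' remaining signal returns \code{Inf}.
#'
#' @param u length-N response (one gene's transformed feature across
#'   individuals).
#' @param Y N x p matrix (or vector) of variables of interest.
#' @param Z optional N x q covariate matrix.
#' @param includeIntercept add an intercept column to the reduced design
#'   (default; the residual degrees of freedom are rank-based either way).
#' @return The F statistic (scalar).
#' @export
fStatistic <- function(u, Y, Z = NULL, includeIntercept = TRUE) {
  u <- as.numeric(u)
  Y <- as.matrix(Y)
  n <- length(u)
  if (nrow(Y) != n) .discStop("validation", "length(u) must match nrow(Y)")
  Z0 <- if (is.null(Z)) matrix(numeric(0), n, 0) else as.matrix(Z)
  base <- if (includeIntercept) cbind(rep(1, n), Z0) else Z0
  .checkNotCollinear(Y, base)
  full <- cbind(base, Y)
  HZ <- hatMatrix(base, n = n)
  HF <- hatMatrix(full, n = n)
  dfRes <- n - .rankOf(full)
  if (dfRes < 1L) .discStop("validation", "no residual degrees of freedom")
  .fStatMatrix(matrix(u, nrow = 1), HF - HZ, diag(n) - HF, ncol(Y), dfRes)[1L]
}

.checkNotCollinear <- function(Y, base) {
  r0 <- .rankOf(base)
  for (j in seq_len(ncol(Y))) {
    if (.rankOf(cbind(base, Y[, j])) <= r0)
      .discStop("validation", sprintf(
        "variable of interest '%s' is collinear with the intercept/covariates",
        colnames(Y)[j] %||% as.character(j)))
  }
  invisible(TRUE)
}

#' Omnibus F statistic: the maximum across features
#'
#' @param fPerFeature numeric vector of per-feature F statistics (length K
#'   >= 1); \code{Inf} sentinels propagate.
#' @export
omnibusF <- function(fPerFeature) {
  if (!length(fPerFeature)) .discStop("validation", "empty F vector")
  max(fPerFeature)
}

#' Build the shared permutation plan
#'
#' B independent uniformly drawn permutations of 1..N (duplicates and the
#' identity permutation are possible, as in ordinary Monte Carlo
#' permutation testing).  The plan is shared by every gene and feature;
#' this is required for the pooled FDR and allows the projection matrices
#' to be reused across genes.
#'
#' @param N number of individuals (>= 3).
#' @param B number of permutations (>= 1); 999 by default, 99 is usually
#'   enough for exploratory runs.
#' @param scheme \code{"plain"} (permute rows of Y) or \code{"smith"}
#'   (permute covariate-adjusted residuals of Y).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @export
makePermutationPlan <- function(N, B = 999L, scheme = c("plain", "smith"), seed = 1L) {
  scheme <- match.arg(scheme)
  if (N < 3L) .discStop("validation", "need at least 3 individuals to permute")
  if (B < 1L) .discStop("validation", "B must be >= 1")
  perm <- .withSeed(seed, {
    t(vapply(seq_len(B), function(b) sample.int(N), integer(N)))
  })
  methods::new("PermutationPlan", perm = perm, B = as.integer(B),
               scheme = scheme, seed = as.integer(seed))
}

#' Permuted response under a permutation scheme
#'
#' \code{plain}: the rows of Y are reordered by the permutation.
#' \code{smith}: Y is first residualized column-wise on the intercept and
#' covariates Z, the residual rows are permuted, and the permuted residuals
#' are returned as the response of interest (the covariates stay in both
#' projections of the F statistic).  With no covariates the Smith scheme
#' reduces to permuting the centered Y, which is noted with a message.
#'
#' @param Y N x p matrix (or vector).
#' @param Z optional N x q covariate matrix.
#' @param permRow integer permutation of 1..N.
#' @param scheme \code{"plain"} or \code{"smith"}.
#' @export
permutedResponse <- function(Y, Z = NULL, permRow, scheme = c("plain", "smith")) {
  scheme <- match.arg(scheme)
  Y <- as.matrix(Y)
  if (scheme == "plain") return(Y[permRow, , drop = FALSE])
  if (is.null(Z) || ncol(as.matrix(Z)) == 0L)
    message("smith scheme without covariates: permuting centered Y")
  E <- .residualizeY(Y, Z)
  E[permRow, , drop = FALSE]
}

.residualizeY <- function(Y, Z) {
  n <- nrow(Y)
  base <- cbind(rep(1, n), if (is.null(Z)) NULL else as.matrix(Z))
  qr.resid(qr(base), Y)
}

#' Permutation p-values from the shared plan
#'
#' For gene i, \eqn{p_i = \sum_b I(F^b_{O,i} \ge F_{O,i}) / (B + 1)}, each
#' gene against its own permutation distribution.  As printed this can be
#' exactly zero; set \code{addOne = TRUE} for the conventional
#' \eqn{(1 + \sum_b I)/(B+1)} variant.
#'
#' @param fObs length-M observed omnibus statistics.
#' @param fPerm M x B matrix of permuted omnibus statistics.
#' @param addOne add the conventional pseudo-count to the numerator.
#' @export
permutationPvalues <- function(fObs, fPerm, addOne = FALSE) {
  fPerm <- as.matrix(fPerm)
  if (nrow(fPerm) != length(fObs)) .discStop("validation", "dimension mismatch")
  (rowSums(fPerm >= fObs) + as.numeric(addOne)) / (ncol(fPerm) + 1)
}

# number of values in sorted vector `pool` that are >= each element of v
.countGE <- function(v, pool) {
  # findInterval with left.open counts pool entries strictly below v
  length(pool) - findInterval(v, pool, left.open = TRUE)
}

#' Pooled permutation q-values
#'
#' All M x B permuted omnibus statistics are pooled into one empirical null.
#' With genes ordered by decreasing observed statistic (ties broken by
#' original gene order, stable),
#' \deqn{\tilde q_{(i)} = \max(\#\{(l,b): F^b_{O,l} \ge F_{O,(i)}\}, 0.5) / (i B)}
#' (the 0.5 pseudo-count guards the case where no permuted value reaches
#' the observed one) and \eqn{q_{(i)} = \min_{j \ge i} \tilde q_{(j)}}.
#' Values are mapped back to input order and capped at 1 for reporting; the
#' uncapped values are available as \code{attr(, "raw")}.
#'
#' @inheritParams permutationPvalues
#' @export
permutationFDR <- function(fObs, fPerm) {
  fPerm <- as.matrix(fPerm)
  M <- length(fObs)
  if (nrow(fPerm) != M) .discStop("validation", "dimension mismatch")
  B <- ncol(fPerm)
  ord <- order(fObs, decreasing = TRUE, method = "radix")  # stable in gene order
  pool <- sort(as.vector(fPerm), method = "radix")
  cnt <- .countGE(fObs[ord], pool)
  qtilde <- pmax(cnt, 0.5) / (seq_len(M) * B)
  qsorted <- rev(cummin(rev(qtilde)))
  raw <- numeric(M)
  raw[ord] <- qsorted
  q <- pmin(raw, 1)
  attr(q, "raw") <- raw
  q
}

#' Run the full DiSC test
#'
#' Pipeline: total-sum-scaling normalization (if not already done), feature
#' extraction, feature transforms, per-feature covariate-adjusted F
#' statistics on the observed design and on every permutation of the shared
#' plan, omnibus max-F, permutation p-values and pooled permutation
#' q-values.  The N x N projection matrices are computed once per
#' permutation and reused across all genes and features, so runtime scales
#' linearly in genes x permutations x features.
#'
#' @param dds a \linkS4class{DiscDataSet} with individuals attached.
#' @param design a \linkS4class{DesignSpec}; its individuals must be exactly
#'   those of \code{dds} (any order; rows are aligned internally).
#' @param B number of permutations.
#' @param seed seed for the permutation plan.
#' @param rho,cap transform parameters, see \code{\link{transformFeatures}}.
#' @param scheme permutation scheme; default \code{NULL} picks
#'   \code{"smith"} when covariates are present and \code{"plain"}
#'   otherwise.
#' @param pvalueAddOne use the \eqn{(1+\cdot)/(B+1)} p-value variant.
#' @param threads split the permutation loop over this many worker
#'   processes (unix fork); results are identical for any value.
#' @return A \linkS4class{DiscResult}.
#' @export
runDisc <- function(dds, design, B = 999L, seed = 1L, rho = 0.5, cap = 7,
                    scheme = NULL, pvalueAddOne = FALSE, threads = 1L) {
  ind <- individualOf(dds)
  if (is.null(ind)) .discStop("validation", "no individual assignment; call attachIndividuals() first")
  ids <- levels(ind)
  ord <- match(ids, design@individualIds)
  if (anyNA(ord))
    .discStop("validation", sprintf("design is missing individual(s): %s",
                                    paste(ids[is.na(ord)], collapse = ", ")))
  if (length(design@individualIds) != length(ids))
    .discStop("validation", "design contains individuals absent from the data")
  Y <- design@Y[ord, , drop = FALSE]
  Z <- design@Z[ord, , drop = FALSE]
  N <- length(ids)
  p <- ncol(Y)
  if (is.null(scheme)) scheme <- if (ncol(Z) > 0L) "smith" else "plain"
  scheme <- match.arg(scheme, c("plain", "smith"))

  if (!"normcounts" %in% SummarizedExperiment::assayNames(dds))
    dds <- normalizeTSS(dds)
  fa <- transformFeatures(extractFeatures(dds), rho = rho, cap = cap)
  K <- length(fa@featureNames)
  M <- nrow(dds)
  # stack the K feature slabs row-wise so each permutation costs two
  # matrix products instead of 2K
  Ustack <- do.call(rbind, lapply(seq_len(K), function(k) fa@U[, , k, drop = FALSE][, , 1L]))

  base <- cbind(`(Intercept)` = rep(1, N), Z)
  .checkNotCollinear(Y, base)
  HZ <- hatMatrix(base, n = N)
  I_N <- diag(N)
  if (scheme == "smith") {
    if (ncol(Z) == 0L) message("smith scheme without covariates: permuting centered Y")
    E <- .residualizeY(Y, if (ncol(Z)) Z else NULL)
  }
  plan <- makePermutationPlan(N, B = B, scheme = scheme, seed = seed)

  oneRep <- function(b) {
    Yb <- if (b == 0L) Y
          else if (scheme == "plain") Y[plan@perm[b, ], , drop = FALSE]
          else E[plan@perm[b, ], , drop = FALSE]
    full <- cbind(base, Yb)
    HF <- hatMatrix(full, n = N)
    dfRes <- N - .rankOf(full)
    if (dfRes < 1L) .discStop("numerical", "no residual degrees of freedom")
    A <- HF - HZ; R <- I_N - HF
    Fk <- matrix(.fStatMatrix(Ustack, A, R, p = p, dfRes = dfRes), M, K)
    list(Fk = Fk, FO = do.call(pmax, lapply(seq_len(K), function(k) Fk[, k])))
  }

  obs <- oneRep(0L)
  reps <- seq_len(B)
  threads <- max(1L, as.integer(threads))
  permOut <- if (threads > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(reps, oneRep, mc.cores = threads, mc.preschedule = TRUE)
  } else {
    lapply(reps, oneRep)
  }
  FOperm <- vapply(permOut, `[[`, numeric(M), "FO")
  if (M == 1L) FOperm <- matrix(FOperm, nrow = 1L)

  pv <- permutationPvalues(obs$FO, FOperm, addOne = pvalueAddOne)
  qv <- permutationFDR(obs$FO, FOperm)

  df <- S4Vectors::DataFrame(obs$Fk, row.names = rownames(dds))
  colnames(df) <- paste0("F_", fa@featureNames)
  df$F_omnibus <- obs$FO
  df$p_value <- pv
  df$q_value <- as.numeric(qv)
  res <- methods::new("DiscResult", df)
  S4Vectors::metadata(res) <- list(
    B = as.integer(B), seed = as.integer(seed), scheme = scheme,
    rho = rho, cap = cap, featureNames = fa@featureNames,
    nIndividuals = N, pvalueAddOne = pvalueAddOne,
    qRaw = attr(qv, "raw"))
  res
}

#' Write DiSC results as a TSV
#'
#' Comment lines at the top record B, seed, scheme, rho and cap, so a result
#' file is self-describing; the body has one row per gene.
#'
#' @param res a \linkS4class{DiscResult}.
#' @param path output file.
#' @export
writeResults <- function(res, path) {
  md <- S4Vectors::metadata(res)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# DiSC results",
               sprintf("# B=%d seed=%d scheme=%s rho=%g cap=%g",
                       md$B, md$seed, md$scheme, md$rho, md$cap)), con)
  df <- as.data.frame(res)
  out <- cbind(gene_id = rownames(df), df)
  utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
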