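# Internal helpers: classed errors, seed handling, small numerics.

# Conditions carry a class so the command-line front end can map them to
# distinct exit codes (io = 2, validation = 3, numerical = 4).
.discStop <- function(type = c("validation", "io", "numerical"), msg, call. = FALSE) {
  type <- match.arg(type)
  cond <- structure(
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL),
    class = c(paste0("disc_", type, "_error"), "discError", "error", "condition")
  )
  stop(cond)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Deterministic derivation of sub-seeds from a master seed.  A Lehmer-style
# map keeps derived seeds spread over (0, 2^31) and below R's integer limit.
.deriveSeed <- function(seed, k) {
  p <- 2147483629
  s <- (as.numeric(seed) %% p) * 48271 + as.numeric(k)
  as.integer(s %% p + 1)
}

.rankOf <- function(D) {
  if (is.null(D) || ncol(D) == 0L) return(0L)
  qr(D)$rank
}

# Row-wise count of non-zero entries, cheap for both dense and dgCMatrix.
.rowNonzero <- function(x) {
  if (methods::is(x, "CsparseMatrix")) {
    rows <- x@i[x@x != 0] + 1L
    tabulate(rows, nbins = nrow(x))
  } else {
    rowSums(x != 0)
  }
}

# Describe invalid count values, or character(0) when clean.  Integer
# storage needs only an NA and sign check; the element-wise finite/floor
# scans are reserved for double input.
.countValueIssues <- function(x, where = "counts") {
  v <- if (methods::is(x, "sparseMatrix")) x@x else x
  if (!length(v)) return(character(0))
  if (anyNA(v)) return(sprintf("%s contain missing values", where))
  if (is.integer(v)) {
    if (min(v) < 0L) return(sprintf("%s contain negative values", where))
    return(character(0))
  }
  rng <- range(v)
  if (!all(is.finite(rng)))
    return(sprintf("%s contain non-finite values", where))
  if (rng[1L] < 0)
    return(sprintf("%s contain negative values", where))
  if (any(v != floor(v)))
    return(sprintf("%s contain non-integer values", where))
  character(0)
}

.checkCounts <- function(x, where = "counts") {
  issues <- .countValueIssues(x, where)
  if (length(issues)) .discStop("validation", issues[1L])
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
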