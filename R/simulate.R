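# Hierarchical zero-inflated negative binomial simulator.
#
# Three levels: population (per-gene means of the transformed ZINB
# parameters), individuals (a multivariate-normal draw around the
# population means, plus a continuous covariate acting on the log-mean),
# and cells (per-cell log-means drawn normal around the individual
# log-mean; dispersion and zero probability inherited from the
# individual).  Counts are emitted from a ZINB law: an inflated zero with
# probability pi, otherwise negative binomial with mean m and size phi
# (variance m + m^2/phi).

#' Zero-inflated negative binomial random numbers
#'
#' With probability \code{pi} an inflated zero, otherwise NB with mean
#' \code{mu} and size (dispersion) \code{size}, so that the ZINB mean is
#' \eqn{(1-\pi) \mu} and the zero mass is
#' \eqn{\pi + (1-\pi)(\phi/(\phi+\mu))^{\phi}}.
#'
#' @param n number of draws.
#' @param mu NB mean (recycled).
#' @param size NB size/dispersion parameter (recycled).
#' @param pi zero-inflation probability (recycled).
#' @export
rzinb <- function(n, mu, size, pi = 0) {
  x <- rnbinom(n, mu = mu, size = size)
  z <- runif(n) < pi
  x[z] <- 0L
  x
}

#' Default per-gene population parameters
#'
#' In the absence of estimates from a reference data set, per-gene
#' parameters are drawn from documented distributions chosen to mimic a
#' moderately expressed UMI gene panel: most genes end up with sparsity
#' between roughly 0.2 and 0.8 (consistent with analysing data after an
#' 80\% sparsity filter), per-cell means around 1--2 counts, dispersion
#' near 1 and modest zero inflation.  All defaults can be overridden, or
#' replaced entirely by a parameter table
#' (\code{\link{populationParamsFromFile}}).
#'
#' @param M number of genes.
#' @param seed integer seed.
#' @param muMean,muSd population distribution of the log-scale mean of
#'   cell log-means.
#' @param phiMean,phiSd distribution of the log dispersion.
#' @param piMean,piSd distribution of the logit zero-inflation probability.
#' @param sigmaMean,sigmaSd distribution of the log between-cell SD of
#'   log-means.
#' @param Sigma 4 x 4 covariance of the individual-level draw
#'   (mu, phi, pi, sigma order); the default diagonal corresponds to
#'   between-individual SDs of about 0.15, 0.10, 0.20 and 0.15 on the
#'   transformed scales.
#' @param covBeta regression coefficient of the standard-normal individual
#'   covariate on the log-mean.
#' @return A \linkS4class{PopulationParams}.
#' @export
defaultPopulationParams <- function(M, seed = 1L,
                                    muMean = 0.5, muSd = 1,
                                    phiMean = 0, phiSd = 0.5,
                                    piMean = -2, piSd = 1,
                                    sigmaMean = log(0.7), sigmaSd = 0.25,
                                    Sigma = diag(c(0.0225, 0.01, 0.04, 0.0225)),
                                    covBeta = 0.1) {
  if (M < 1L) .discStop("validation", "M must be >= 1")
  params <- .withSeed(seed, data.frame(
    gene_id = sprintf("gene%05d", seq_len(M)),
    mu = rnorm(M, muMean, muSd),
    phi = rnorm(M, phiMean, phiSd),
    pi = rnorm(M, piMean, piSd),
    sigma = rnorm(M, sigmaMean, sigmaSd)))
  dimnames(Sigma) <- list(c("mu", "phi", "pi", "sigma"), c("mu", "phi", "pi", "sigma"))
  methods::new("PopulationParams", params = params, Sigma = Sigma, covBeta = covBeta)
}

#' Load population parameters from a TSV
#'
#' The table needs columns \code{mu}, \code{phi}, \code{pi}, \code{sigma}
#' (transformed scales) and optionally \code{gene_id}; it is used verbatim,
#' bypassing the defaults.
#'
#' @param path TSV file.
#' @param Sigma,covBeta as in \code{\link{defaultPopulationParams}}.
#' @export
populationParamsFromFile <- function(path,
                                     Sigma = diag(c(0.0225, 0.01, 0.04, 0.0225)),
                                     covBeta = 0.1) {
  if (!file.exists(path)) .discStop("io", sprintf("parameter file not found: %s", path))
  tab <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("mu", "phi", "pi", "sigma")
  if (!all(need %in% colnames(tab)))
    .discStop("validation", paste("parameter table must have columns", paste(need, collapse = ", ")))
  if (!"gene_id" %in% colnames(tab)) tab$gene_id <- sprintf("gene%05d", seq_len(nrow(tab)))
  dimnames(Sigma) <- list(c("mu", "phi", "pi", "sigma"), c("mu", "phi", "pi", "sigma"))
  methods::new("PopulationParams", params = tab[, c("gene_id", need)],
               Sigma = Sigma, covBeta = covBeta)
}

#' Draw individual-level parameters
#'
#' For each gene i and individual j, \eqn{(\mu_{ij}, \phi_{ij}, \pi_{ij},
#' \sigma_{ij})} is multivariate normal around the gene's population
#' parameters with covariance \code{Sigma}; the continuous covariate then
#' shifts the log-mean by \code{covBeta * z_j}.
#'
#' @param pp a \linkS4class{PopulationParams}.
#' @param N number of individuals (even, >= 4).
#' @param z length-N covariate values; standard normal draws by default.
#' @param seed integer seed.
#' @return List with M x N matrices \code{mu}, \code{phi}, \code{pi},
#'   \code{sigma} (transformed scales), the covariate \code{z} and
#'   \code{geneIds}.
#' @export
sampleIndividualParams <- function(pp, N, z = NULL, seed = 1L) {
  if (N < 4L || N %% 2L != 0L)
    .discStop("validation", "N must be an even number of individuals >= 4")
  M <- nrow(pp@params)
  .withSeed(seed, {
    if (is.null(z)) z <- rnorm(N)
    L <- if (all(pp@Sigma == 0)) NULL else chol(pp@Sigma, pivot = FALSE)
    shift <- if (is.null(L)) matrix(0, M * N, 4) else matrix(rnorm(M * N * 4), M * N, 4) %*% L
    mk <- function(k, base) matrix(base, M, N) + matrix(shift[, k], M, N)
    out <- list(
      mu = mk(1L, pp@params$mu) + matrix(pp@covBeta * z, M, N, byrow = TRUE),
      phi = mk(2L, pp@params$phi),
      pi = mk(3L, pp@params$pi),
      sigma = mk(4L, pp@params$sigma),
      z = z, geneIds = pp@params$gene_id)
    out
  })
}

#' Inject differential-expression signals
#'
#' Selects three disjoint random gene sets (mean, variance, both;
#' \code{density} of the genes each) and, for case individuals only, shifts
#' the individual parameters: mean-type genes get \eqn{\mu_{ij} \pm \log f},
#' variance-type genes get the between-cell SD multiplied by
#' \eqn{f^{\pm 1}} (an additive \eqn{\pm\log f} on the log-sigma scale),
#' and both-type genes get both shifts with one shared sign.  The sign
#' (up/down) is equally likely per gene.  With \code{f = 1} the injection
#' is a no-op and every gene is labelled \code{none} (the global null).
#'
#' @param ip individual-level parameters from
#'   \code{\link{sampleIndividualParams}}.
#' @param cases logical length-N case indicator.
#' @param density fraction of genes per signal type.
#' @param f fold change (>= 1).
#' @param seed integer seed.
#' @return List with the modified \code{params} and the \code{truth}
#'   data.frame (gene_id, de_type, direction, fold).
#' @export
injectDE <- function(ip, cases, density = 0.05, f = 1, seed = 1L) {
  M <- nrow(ip$mu)
  if (f < 1) .discStop("validation", "fold change f must be >= 1")
  if (3 * density * M > M) .discStop("validation", "3 * density must be <= 1")
  nPer <- floor(density * M)
  if (density > 0 && nPer < 1L && f > 1) {
    warning("density * M < 1: no DE genes of any type")
  }
  sel <- .withSeed(seed, {
    idx <- sample.int(M, 3L * nPer)
    dirs <- sample(c(-1, 1), 3L * nPer, replace = TRUE)
    list(idx = idx, dirs = dirs)
  })
  truth <- data.frame(gene_id = ip$geneIds, de_type = "none",
                      direction = NA_character_, fold = 1,
                      stringsAsFactors = FALSE)
  if (f > 1 && nPer >= 1L) {
    types <- rep(c("mean", "variance", "both"), each = nPer)
    truth$de_type[sel$idx] <- types
    truth$direction[sel$idx] <- ifelse(sel$dirs > 0, "up", "down")
    truth$fold[sel$idx] <- f
    shift <- sel$dirs * log(f)
    caseCols <- which(cases)
    meanRows <- sel$idx[types %in% c("mean", "both")]
    meanShift <- shift[types %in% c("mean", "both")]
    varRows <- sel$idx[types %in% c("variance", "both")]
    varShift <- shift[types %in% c("variance", "both")]
    ip$mu[meanRows, caseCols] <- ip$mu[meanRows, caseCols] + meanShift
    ip$sigma[varRows, caseCols] <- ip$sigma[varRows, caseCols] + varShift
  }
  list(params = ip, truth = truth)
}

#' Emit ZINB counts from individual-level parameters
#'
#' For each cell, a log-mean is drawn \eqn{N(\mu_{ij}, \sigma_{ij}^2)}
#' (plus an optional per-cell log size factor shared across genes), clipped
#' to [-30, 15] against overflow, and a ZINB count is emitted with mean
#' \eqn{e^{\cdot}}, dispersion \eqn{e^{\phi_{ij}}} and zero probability
#' \eqn{\mathrm{logit}^{-1}(\pi_{ij})}.  Each gene uses its own derived RNG
#' substream, so changing one gene's parameters (e.g. by signal injection)
#' perturbs only that gene's counts; cells are laid out control individuals
#' first, so case-only shifts leave control cells untouched.
#'
#' @param ip individual-level parameters (possibly after
#'   \code{\link{injectDE}}).
#' @param nCell cells per individual.
#' @param sizeFactorSd SD of the per-cell log size factor (0 disables).
#' @param seed integer seed.
#' @param individualIds optional identifiers (default ind001, ...).
#' @return A \linkS4class{DiscDataSet} with individuals attached.
#' @export
generateCounts <- function(ip, nCell, sizeFactorSd = 0, seed = 1L,
                           individualIds = NULL) {
  if (nCell < 1L) .discStop("validation", "nCell must be >= 1")
  M <- nrow(ip$mu); N <- ncol(ip$mu)
  C <- N * nCell
  if (is.null(individualIds)) individualIds <- sprintf("ind%03d", seq_len(N))
  sigmaNat <- exp(ip$sigma)
  phiNat <- exp(ip$phi)
  pz <- plogis(ip$pi)
  sf <- if (sizeFactorSd > 0) .withSeed(.deriveSeed(seed, 7L), rnorm(C, 0, sizeFactorSd))
        else numeric(C)
  counts <- matrix(0L, M, C)
  clipped <- 0L
  .withSeed(seed, {  # outer guard restores the caller's RNG state
    for (i in seq_len(M)) {
      set.seed(.deriveSeed(seed, 1000000 + i))
      row <- .zinb_emit_row(ip$mu[i, ], sigmaNat[i, ], phiNat[i, ], pz[i, ],
                            as.integer(nCell), sf, -30, 15)
      clipped <- clipped + attr(row, "clipped")
      counts[i, ] <- row
    }
  })
  if (clipped > 0L)
    warning(sprintf("%d cell log-mean(s) clipped to [-30, 15]", clipped))
  ind <- rep(individualIds, each = nCell)
  cellIds <- paste0(ind, "_c", rep(seq_len(nCell), times = N))
  DiscDataSet(counts, geneIds = ip$geneIds, cellIds = cellIds, individuals = ind)
}

#' Generate a complete simulated dataset
#'
#' End-to-end convenience wrapper: population parameters (defaults unless
#' supplied), a standard-normal individual covariate, individual-level
#' parameter draws, signal injection and count emission.  Individuals are
#' split half control / half case, controls first.  Deterministic given
#' \code{seed}.
#'
#' @param M number of genes.
#' @param nSim number of individuals (even).
#' @param nCell cells per individual.
#' @param f fold change (1 = global null).
#' @param density DE gene fraction per signal type.
#' @param seed master seed; all stage seeds derive from it.
#' @param popParams optional \linkS4class{PopulationParams}.
#' @param sizeFactorSd per-cell log size factor SD.
#' @return A \linkS4class{SimulatedDataset}.
#' @export
generateDataset <- function(M = 1000L, nSim = 24L, nCell = 375L, f = 1,
                            density = 0.05, seed = 1L, popParams = NULL,
                            sizeFactorSd = 0) {
  pp <- popParams %||% defaultPopulationParams(M, seed = .deriveSeed(seed, 1L))
  if (nrow(pp@params) != M && !is.null(popParams)) M <- nrow(pp@params)
  z <- .withSeed(.deriveSeed(seed, 2L), rnorm(nSim))
  ip <- sampleIndividualParams(pp, nSim, z = z, seed = .deriveSeed(seed, 3L))
  cases <- rep(c(FALSE, TRUE), each = nSim / 2L)
  inj <- injectDE(ip, cases, density = density, f = f, seed = .deriveSeed(seed, 4L))
  dds <- generateCounts(inj$params, nCell, sizeFactorSd = sizeFactorSd,
                        seed = .deriveSeed(seed, 5L))
  design <- DesignSpec(Y = matrix(as.numeric(cases), ncol = 1,
                                  dimnames = list(NULL, "group")),
                       Z = matrix(z, ncol = 1, dimnames = list(NULL, "z")),
                       individualIds = sprintf("ind%03d", seq_len(nSim)))
  methods::new("SimulatedDataset", data = dds, design = design,
               truth = inj$truth, seed = as.integer(seed))
}

#' Write a simulated dataset to disk
#'
#' Matrix Market counts plus gene/cell id files, cell metadata, individual
#' metadata (group and covariate) and the ground-truth table; readable by
#' \code{\link{readCounts}} / \code{\link{attachIndividuals}}.
#'
#' @param sim a \linkS4class{SimulatedDataset}.
#' @param dir output directory.
#' @export
writeSimulatedDataset <- function(sim, dir) {
  writeCounts(sim@data, dir)
  indMeta <- data.frame(individual = sim@design@individualIds,
                        sim@design@Y, sim@design@Z, check.names = FALSE)
  utils::write.table(indMeta, file.path(dir, "individual_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim@truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
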