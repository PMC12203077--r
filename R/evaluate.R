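# Scoring of a single analysis against simulation ground truth, and the
# multi-run simulation-study harness.

#' Score one DiSC run against ground truth
#'
#' Positives are genes with q-value at or below \code{fdrTarget}.  Genes
#' present in the truth table but absent from the result (e.g. removed by
#' the sparsity filter) count as negative calls, so TP + FP + FN + TN
#' always sums to the number of genes in \code{truth}.  The type I error
#' rate is the fraction of tested null genes with raw p below \code{alpha}.
#' FDP = FP / max(TP + FP, 1), so a run without positives scores 0.  TPR is
#' reported overall and per signal type; under a global null (no DE genes)
#' TPR is NA.
#'
#' @param result a \linkS4class{DiscResult}.
#' @param truth truth table with columns gene_id and de_type (from
#'   \code{\link{simTruth}}).
#' @param alpha nominal level for the type I error rate.
#' @param fdrTarget q-value threshold defining positives.
#' @return A one-row data.frame of metrics.
#' @export
scoreRun <- function(result, truth, alpha = 0.05, fdrTarget = 0.10) {
  if (!all(rownames(result) %in% truth$gene_id))
    .discStop("validation", "result contains genes absent from the truth table")
  m <- match(truth$gene_id, rownames(result))
  tested <- !is.na(m)
  pos <- logical(nrow(truth))
  pos[tested] <- result$q_value[m[tested]] <= fdrTarget
  isDE <- truth$de_type != "none"
  TP <- sum(pos & isDE); FP <- sum(pos & !isDE)
  FN <- sum(!pos & isDE); TN <- sum(!pos & !isDE)
  nullTested <- tested & !isDE
  typeI <- if (any(nullTested)) mean(result$p_value[m[nullTested]] < alpha) else NA_real_
  nNullTested <- sum(nullTested)
  tprBy <- function(type) {
    sel <- truth$de_type == type
    if (!any(sel)) return(NA_real_)
    sum(pos & sel) / sum(sel)
  }
  data.frame(
    type_I_error = typeI,
    FDP = FP / max(TP + FP, 1),
    TPR = if (any(isDE)) TP / (TP + FN) else NA_real_,
    TPR_mean = tprBy("mean"),
    TPR_variance = tprBy("variance"),
    TPR_both = tprBy("both"),
    TP = TP, FP = FP, FN = FN, TN = TN,
    n_null_tested = nNullTested,
    n_positive = TP + FP,
    any_positive = (TP + FP) > 0,
    alpha = alpha, fdr_target = fdrTarget)
}

#' Run a simulation study over a scenario grid
#'
#' For each scenario (a list of \code{\link{generateDataset}} arguments)
#' and each run: generate a dataset with a per-run derived seed, apply the
#' sparsity filter, run DiSC, and score against the truth.  Results are
#' aggregated into per-scenario means and standard errors
#' (SD / sqrt(runs)).  Under a global null the fraction of runs with any
#' positive finding equals the mean FDP exactly (each null run's FDP is 0
#' or 1) and is reported as \code{frac_any_positive}.  A failing run aborts
#' the study; nothing is skipped silently.
#'
#' @param scenarios named list of scenario configurations, each a list of
#'   arguments for \code{\link{generateDataset}} (a single flat list is
#'   treated as one scenario).
#' @param runs simulation runs per scenario (>= 2).
#' @param seed master seed; per-run seeds derive deterministically from it.
#' @param B permutations per analysis.
#' @param alpha,fdrTarget see \code{\link{scoreRun}}.
#' @param maxSparsity sparsity filter applied before testing.
#' @param threads passed to \code{\link{runDisc}}.
#' @param verbose print one line per scenario.
#' @return An object of class \code{"DiscStudy"}: a list with per-scenario
#'   \code{summary}, all per-run metric rows in \code{runs}, and the
#'   resolved \code{config}.
#' @export
runStudy <- function(scenarios, runs = 20L, seed = 1L, B = 99L,
                     alpha = 0.05, fdrTarget = 0.10, maxSparsity = 0.8,
                     threads = 1L, verbose = interactive()) {
  if (runs < 2L) .discStop("validation", "runs must be >= 2")
  if (!is.list(scenarios)) .discStop("validation", "scenarios must be a list")
  if (!all(vapply(scenarios, is.list, logical(1)))) scenarios <- list(scenario = scenarios)
  if (is.null(names(scenarios)) || any(!nzchar(names(scenarios))))
    names(scenarios) <- paste0("scenario", seq_along(scenarios))

  perRun <- list()
  for (s in seq_along(scenarios)) {
    cfg <- scenarios[[s]]
    for (r in seq_len(runs)) {
      runSeed <- .deriveSeed(seed, (s - 1L) * 100000L + r)
      sim <- do.call(generateDataset, c(cfg, list(seed = runSeed)))
      dds <- filterSparsity(simData(sim), maxSparsity)
      res <- runDisc(dds, simDesign(sim), B = B, seed = .deriveSeed(runSeed, 31L),
                     threads = threads)
      row <- scoreRun(res, simTruth(sim), alpha = alpha, fdrTarget = fdrTarget)
      row$scenario <- names(scenarios)[s]
      row$run <- r
      row$n_genes_tested <- nrow(res)
      perRun[[length(perRun) + 1L]] <- row
    }
    if (verbose) message(sprintf("scenario '%s': %d runs done", names(scenarios)[s], runs))
  }
  runsDf <- do.call(rbind, perRun)

  agg <- function(df) {
    se <- function(x) stats::sd(x) / sqrt(sum(!is.na(x)))
    data.frame(
      scenario = df$scenario[1], runs = nrow(df),
      # primary: averaged over runs; pooled over all gene-tests also reported
      type_I_error = mean(df$type_I_error), type_I_error_se = se(df$type_I_error),
      type_I_error_pooled = sum(df$type_I_error * df$n_null_tested, na.rm = TRUE) /
        max(sum(df$n_null_tested[!is.na(df$type_I_error)]), 1),
      FDR = mean(df$FDP), FDR_se = se(df$FDP),
      TPR = mean(df$TPR), TPR_se = se(df$TPR),
      TPR_mean = mean(df$TPR_mean), TPR_mean_se = se(df$TPR_mean),
      TPR_variance = mean(df$TPR_variance), TPR_variance_se = se(df$TPR_variance),
      TPR_both = mean(df$TPR_both), TPR_both_se = se(df$TPR_both),
      mean_false_positives = mean(df$FP),
      frac_any_positive = mean(df$any_positive))
  }
  summary <- do.call(rbind, lapply(split(runsDf, factor(runsDf$scenario, levels = names(scenarios))), agg))
  rownames(summary) <- NULL
  structure(list(summary = summary, runs = runsDf,
                 config = list(scenarios = scenarios, runs = runs, seed = seed, B = B,
                               alpha = alpha, fdrTarget = fdrTarget,
                               maxSparsity = maxSparsity)),
            class = "DiscStudy")
}

#' @export
print.DiscStudy <- function(x, ...) {
  cat(sprintf("DiSC simulation study: %d scenario(s) x %d runs, B = %d, seed = %d\n",
              nrow(x$summary), x$config$runs, x$config$B, x$config$seed))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Write a study summary as TSV
#'
#' @param study a \code{"DiscStudy"} object.
#' @param path output file.
#' @export
writeStudy <- function(study, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# DiSC study: runs=%d B=%d seed=%d alpha=%g fdr_target=%g",
                     study$config$runs, study$config$B, study$config$seed,
                     study$config$alpha, study$config$fdrTarget), con)
  utils::write.table(format(study$summary, digits = 10, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Built-in study presets
#'
#' \describe{
#'   \item{global-null}{f = 1, 24 individuals, 375 cells, 1000 genes: the
#'     null calibration scenario at desk scale.}
#'   \item{global-null-paper-scale}{the same conditions at 8000 genes.}
#'   \item{fold-sweep}{f in 1.1, 1.3, 1.5 with 5\% DE density per type.}
#'   \item{cell-sweep}{250 vs 500 cells per individual at f = 1.3.}
#'   \item{size-sweep}{10, 24, 50 individuals at f = 1.3.}
#' }
#'
#' @param name preset name.
#' @return A named list of scenario configurations for
#'   \code{\link{runStudy}}.
#' @export
studyPreset <- function(name) {
  presets <- list(
    "global-null" = list(null = list(M = 1000L, nSim = 24L, nCell = 375L, f = 1)),
    "global-null-paper-scale" = list(null = list(M = 8000L, nSim = 24L, nCell = 375L, f = 1)),
    "fold-sweep" = list(
      f1.1 = list(M = 1000L, nSim = 24L, nCell = 375L, f = 1.1, density = 0.05),
      f1.3 = list(M = 1000L, nSim = 24L, nCell = 375L, f = 1.3, density = 0.05),
      f1.5 = list(M = 1000L, nSim = 24L, nCell = 375L, f = 1.5, density = 0.05)),
    "cell-sweep" = list(
      cells250 = list(M = 1000L, nSim = 24L, nCell = 250L, f = 1.3, density = 0.05),
      cells500 = list(M = 1000L, nSim = 24L, nCell = 500L, f = 1.3, density = 0.05)),
    "size-sweep" = list(
      n10 = list(M = 1000L, nSim = 10L, nCell = 375L, f = 1.3, density = 0.05),
      n24 = list(M = 1000L, nSim = 24L, nCell = 375L, f = 1.3, density = 0.05),
      n50 = list(M = 1000L, nSim = 50L, nCell = 375L, f = 1.3, density = 0.05)))
  if (!name %in% names(presets))
    .discStop("validation", sprintf("unknown preset '%s'; available: %s",
                                    name, paste(names(presets), collapse = ", ")))
  presets[[name]]
}
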