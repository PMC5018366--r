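#' Full per-experiment analysis pipeline
#'
#' Read-to-metrics workflow for one experiment: fit both single-agent Hill
#' curves on all replicate points, derive each requested reference surface,
#' compute the synergy distribution against it, and summarize with
#' [computeMetrics()].
#'
#' @param exp a [CombinationExperiment-class].
#' @param models character vector of reference model ids (default all of
#'   `"LOEWE"`, `"BLISS"`, `"HSA"`).
#' @param direction sign convention, see [synergyDistribution()].
#' @param tol Loewe solver tolerance.
#' @return A list with elements `experiment`, `curves` (list `a`, `b`),
#'   `references` and `distributions` (named by model), and `metrics` (long
#'   `data.frame`, one row per model, with fit diagnostics appended).
#' @examples
#' ce <- simulateExperiment(
#'   HillCurve(0, 1, 1), HillCurve(10, 2, 1.5),
#'   model = "BLISS", seed = 7
#' )
#' res <- analyzeExperiment(ce, models = "BLISS")
#' res$metrics
#' @export
analyzeExperiment <- function(exp, models = REFERENCE_MODELS,
                              direction = "reference-minus-data",
                              tol = 1e-8) {
  models <- toupper(models)
  bad <- setdiff(models, REFERENCE_MODELS)
  if (length(bad)) stop("unknown reference model(s): ", paste(bad, collapse = ", "))
  curves <- fitSingleAgents(exp)
  refs <- lapply(models, function(m) {
    referenceSurface(m, curves$a, curves$b, dosesA(exp), dosesB(exp),
      tol = tol
    )
  })
  names(refs) <- models
  dists <- lapply(refs, synergyDistribution, exp = exp, direction = direction)
  metrics <- do.call(rbind, lapply(models, function(m) {
    rec <- computeMetrics(dists[[m]], exp)
    cbind(
      data.frame(experiment = experimentName(exp), stringsAsFactors = FALSE),
      rec,
      data.frame(
        rmse_a = curves$a@diagnostics$rmse, r2_a = curves$a@diagnostics$r2,
        rmse_b = curves$b@diagnostics$rmse, r2_b = curves$b@diagnostics$r2,
        inactive_a = curves$a@inactive, inactive_b = curves$b@inactive,
        n_warnings = length(qcWarnings(exp))
      )
    )
  }))
  rownames(metrics) <- NULL
  list(
    experiment = exp, curves = curves, references = refs,
    distributions = dists, metrics = metrics
  )
}

#' Batch-process a screen directory
#'
#' Processes every sub-folder of `root` (each holding one experiment's
#' files) sequentially in name order: read, fit, reference surfaces for each
#' requested model, synergy distribution, metrics. A failing experiment is
#' recorded in `failures` and does not abort the remaining ones. With
#' `outDir` set, the long and wide metrics tables are written as CSV.
#'
#' @param root directory of experiment sub-folders (loose experiment files
#'   directly under `root` are treated as one experiment per stem).
#' @param models reference model ids.
#' @param outDir optional output directory for `metrics_long.csv`,
#'   `metrics_wide.csv` and `failures.csv`.
#' @param rawNormalize passed to [readExperiment()].
#' @param direction,tol passed to [analyzeExperiment()].
#' @return A `BatchResult`: list with `metrics` (long `data.frame` ordered
#'   by experiment name), `failures` (`data.frame` of experiment/error) and
#'   `results` (per-experiment analysis lists, named).
#' @export
runBatch <- function(root, models = REFERENCE_MODELS, outDir = NULL,
                     rawNormalize = FALSE,
                     direction = "reference-minus-data", tol = 1e-8) {
  if (!dir.exists(root)) stop("screen directory not found: ", root)
  units <- sort(list.dirs(root, recursive = FALSE))
  if (!length(units)) {
    units <- sort(list.files(root, pattern = .DATA_FILE_RX, full.names = TRUE))
    units <- units[!duplicated(vapply(units, .stemOf, character(1)))]
  }
  if (!length(units)) stop("no experiment sub-folders or files in ", root)

  metrics <- list()
  results <- list()
  failures <- data.frame(
    experiment = character(0), error = character(0), stringsAsFactors = FALSE
  )
  for (u in units) {
    nameU <- if (dir.exists(u)) basename(u) else .stemOf(u)
    res <- tryCatch(
      {
        exp <- readExperiment(u, rawNormalize = rawNormalize)
        analyzeExperiment(exp,
          models = models, direction = direction, tol = tol
        )
      },
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <- rbind(failures, data.frame(
        experiment = nameU, error = conditionMessage(res),
        stringsAsFactors = FALSE
      ))
    } else {
      metrics[[nameU]] <- res$metrics
      results[[nameU]] <- res
    }
  }
  metrics <- if (length(metrics)) {
    m <- do.call(rbind, metrics[sort(names(metrics))])
    rownames(m) <- NULL
    m
  } else {
    NULL
  }
  out <- structure(
    list(metrics = metrics, failures = failures, results = results),
    class = "BatchResult"
  )
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(metrics)) {
      write.csv(metrics, file.path(outDir, "metrics_long.csv"),
        row.names = FALSE
      )
      writeMetricsTable(metrics, file.path(outDir, "metrics_wide.csv"))
    }
    if (nrow(failures)) {
      write.csv(failures, file.path(outDir, "failures.csv"), row.names = FALSE)
    }
  }
  out
}

#' @export
print.BatchResult <- function(x, ...) {
  nOK <- length(x$results)
  cat(sprintf(
    "BatchResult: %d experiment(s) analyzed, %d failure(s)\n",
    nOK, nrow(x$failures)
  ))
  if (!is.null(x$metrics)) {
    cat(sprintf(
      "  models: %s; %d metric rows\n",
      paste(unique(x$metrics$model), collapse = ", "), nrow(x$metrics)
    ))
  }
  if (nrow(x$failures)) {
    cat("  failed:", paste(x$failures$experiment, collapse = ", "), "\n")
  }
  invisible(x)
}
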