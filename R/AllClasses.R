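#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

REFERENCE_MODELS <- c("LOEWE", "BLISS", "HSA")

#' Three-parameter Hill dose-response curve
#'
#' Sigmoid model for percent-of-control viability,
#' \eqn{E(c) = E_0 + (E_{inf} - E_0) / (1 + (EC_{50}/c)^h)},
#' with the baseline pinned at \eqn{E_0 = 100} (the untreated control defines
#' 100% by construction), leaving three free parameters: the asymptotic
#' response `eInf`, the half-effect concentration `ec50` and the Hill
#' slope `h`.
#'
#' @slot eInf numeric(1), response at infinite dose (% control), in
#'   \[-20, 100\].
#' @slot ec50 numeric(1), concentration giving the response half-way between
#'   100 and `eInf`; strictly positive, same units as the dose grid.
#' @slot h numeric(1), Hill slope, strictly positive.
#' @slot e0 numeric(1), baseline response; fixed at 100.
#' @slot inactive logical(1), TRUE when the fit flagged the agent as having
#'   no usable dose response (flat curve or very poor fit).
#' @slot diagnostics list of fit diagnostics (`rmse`, `r2`, `converged`,
#'   `nPoints`); empty for curves constructed directly.
#'
#' @seealso [HillCurve()], [fitHill()], [hillResponse()]
#' @exportClass HillCurve
setClass("HillCurve",
  representation(
    eInf = "numeric",
    ec50 = "numeric",
    h = "numeric",
    e0 = "numeric",
    inactive = "logical",
    diagnostics = "list"
  ),
  prototype(e0 = 100, inactive = FALSE, diagnostics = list())
)

setValidity("HillCurve", function(object) {
  msg <- character()
  for (s in c("eInf", "ec50", "h", "e0")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v)) {
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
    }
  }
  if (length(msg)) return(msg)
  if (object@ec50 <= 0) msg <- c(msg, "'ec50' must be > 0")
  if (object@h <= 0) msg <- c(msg, "'h' must be > 0")
  if (object@e0 != 100) msg <- c(msg, "'e0' is fixed at 100 (% control)")
  if (object@eInf < -20 || object@eInf > 100) {
    msg <- c(msg, "'eInf' must lie in [-20, 100]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Hill curve
#'
#' @param eInf response at infinite dose (% control), in \[-20, 100\].
#' @param ec50 half-effect concentration (> 0).
#' @param h Hill slope (> 0).
#' @param inactive logical flag, see class description.
#' @param diagnostics optional list of fit diagnostics.
#' @return A [HillCurve-class] object.
#' @examples
#' hc <- HillCurve(eInf = 0, ec50 = 1, h = 1)
#' hillResponse(hc, 1) # 50
#' @export
HillCurve <- function(eInf, ec50, h, inactive = FALSE, diagnostics = list()) {
  new("HillCurve",
    eInf = as.numeric(eInf), ec50 = as.numeric(ec50), h = as.numeric(h),
    e0 = 100, inactive = isTRUE(inactive), diagnostics = diagnostics
  )
}

setMethod("show", "HillCurve", function(object) {
  cat(sprintf(
    "HillCurve: eInf = %.4g, ec50 = %.4g, h = %.4g (e0 fixed at 100)%s\n",
    object@eInf, object@ec50, object@h,
    if (object@inactive) " [inactive agent]" else ""
  ))
  d <- object@diagnostics
  if (length(d)) {
    cat(sprintf(
      "  fit: rmse = %.4g, r2 = %.4g, n = %d\n",
      d$rmse, d$r2, as.integer(d$nPoints)
    ))
  }
  invisible(NULL)
})

#' Checkerboard drug-combination experiment
#'
#' A `SummarizedExperiment` holding one combination experiment: columns are
#' the doses of drug A (laid out in columns of the source file), rows the
#' doses of drug B, and each assay one replicate response matrix in % of the
#' untreated control (100 = no effect, 0 = complete effect). Each dose grid
#' contains exactly one zero entry (the single-agent control row/column) and
#' is stored strictly increasing; the (0, 0) cell is the untreated control.
#'
#' Metadata fields: `name` (experiment identifier), `agentA`, `agentB`
#' (drug names) and `qcWarnings` (messages for values outside \[-20, 200\],
#' which are retained but flagged).
#'
#' @seealso [CombinationExperiment()], [readExperiment()],
#'   [simulateExperiment()]
#' @exportClass CombinationExperiment
setClass("CombinationExperiment", contains = "SummarizedExperiment")

.validDoseGrid <- function(d, what) {
  msg <- character()
  if (!is.numeric(d) || length(d) < 2L || any(!is.finite(d))) {
    return(sprintf("'%s' must be a finite numeric vector of length >= 2", what))
  }
  if (sum(d == 0) != 1L) {
    msg <- c(msg, sprintf("'%s' must contain exactly one zero dose", what))
  }
  if (any(d < 0)) msg <- c(msg, sprintf("'%s' must be non-negative", what))
  if (any(diff(d) <= 0)) {
    msg <- c(msg, sprintf("'%s' must be strictly increasing", what))
  }
  msg
}

setValidity("CombinationExperiment", function(object) {
  msg <- character()
  msg <- c(msg, .validDoseGrid(dosesA(object), "dosesA"))
  msg <- c(msg, .validDoseGrid(dosesB(object), "dosesB"))
  if (length(SummarizedExperiment::assays(object)) < 1L) {
    msg <- c(msg, "at least one replicate matrix is required")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a combination experiment
#'
#' Dose grids are sorted ascending and the replicate matrices permuted to
#' match, so the stored object is canonical regardless of the input ordering.
#' Values outside \[-20, 200\] % control are retained but recorded in the
#' `qcWarnings` metadata field.
#'
#' @param dosesA numeric vector of drug A concentrations (columns); must
#'   contain exactly one zero.
#' @param dosesB numeric vector of drug B concentrations (rows); must contain
#'   exactly one zero.
#' @param replicates a matrix, or list of matrices, of dimension
#'   `length(dosesB) x length(dosesA)`, values in % control.
#' @param name experiment identifier.
#' @param agentA,agentB drug names.
#' @return A [CombinationExperiment-class].
#' @examples
#' ce <- CombinationExperiment(
#'   dosesA = c(0, 1), dosesB = c(0, 1),
#'   replicates = matrix(c(100, 70, 60, 50), 2, 2)
#' )
#' meanResponse(ce)
#' @export
CombinationExperiment <- function(dosesA, dosesB, replicates,
                                  name = "experiment",
                                  agentA = "Drug A", agentB = "Drug B") {
  if (is.matrix(replicates)) replicates <- list(replicates)
  if (!length(replicates)) stop("at least one replicate matrix is required")
  dosesA <- as.numeric(dosesA)
  dosesB <- as.numeric(dosesB)
  dims <- vapply(replicates, dim, integer(2))
  if (any(dims[1, ] != length(dosesB)) || any(dims[2, ] != length(dosesA))) {
    stop(
      "replicate matrices must all be ", length(dosesB), " x ",
      length(dosesA), " (rows = dosesB, columns = dosesA)"
    )
  }
  oa <- order(dosesA)
  ob <- order(dosesB)
  replicates <- lapply(replicates, function(m) {
    m <- m[ob, oa, drop = FALSE]
    storage.mode(m) <- "double"
    dimnames(m) <- list(
      format(dosesB[ob], trim = TRUE),
      format(dosesA[oa], trim = TRUE)
    )
    m
  })
  names(replicates) <- paste0("rep", seq_along(replicates))
  warnings <- character()
  bad <- vapply(
    replicates,
    function(m) sum(m < -20 | m > 200, na.rm = TRUE),
    numeric(1)
  )
  if (any(bad > 0)) {
    warnings <- sprintf(
      "replicate %d: %d value(s) outside [-20, 200] %% control (retained)",
      which(bad > 0), bad[bad > 0]
    )
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = replicates,
    rowData = S4Vectors::DataFrame(dose = sort(dosesB)),
    colData = S4Vectors::DataFrame(dose = sort(dosesA)),
    metadata = list(
      name = as.character(name),
      agentA = as.character(agentA), agentB = as.character(agentB),
      qcWarnings = warnings
    )
  )
  new("CombinationExperiment", se)
}

setMethod("show", "CombinationExperiment", function(object) {
  cat(sprintf(
    "CombinationExperiment '%s': %s (columns) x %s (rows)\n",
    experimentName(object),
    metadata(object)$agentA, metadata(object)$agentB
  ))
  cat(sprintf(
    "  grid: %d x %d doses, %d replicate(s), values in %% control\n",
    length(dosesA(object)), length(dosesB(object)), nReplicates(object)
  ))
  w <- qcWarnings(object)
  if (length(w)) cat("  warnings:", paste(w, collapse = "; "), "\n")
  invisible(NULL)
})

#' Model-generated non-synergistic reference surface
#'
#' Predicted % control response for every dose pair under one classical
#' non-interaction model (`"LOEWE"`, `"BLISS"` or `"HSA"`), computed from the
#' two fitted single-agent Hill curves. Rows index `dosesB`, columns
#' `dosesA`; the zero-dose row and column equal the single-agent curve
#' predictions exactly under every model. `solverFlags` records, per cell,
#' how the value was obtained: `"exact"`, `"clamped"` (Bliss inputs clamped
#' to \[0, 100\]), `"capped"` (Loewe effect unreachable by the weaker agent,
#' value capped at its asymptote) or `"fallback_single_agent"` (Loewe with an
#' inactive agent).
#'
#' @slot model character(1), one of `"LOEWE"`, `"BLISS"`, `"HSA"`.
#' @slot dosesA,dosesB numeric dose grids.
#' @slot values numeric matrix of predicted % control.
#' @slot solverFlags character matrix, same shape as `values`.
#' @slot curveA,curveB the [HillCurve-class] objects used.
#' @seealso [referenceSurface()], [loeweSurface()], [blissSurface()],
#'   [hsaSurface()]
#' @exportClass ReferenceSurface
setClass("ReferenceSurface",
  representation(
    model = "character",
    dosesA = "numeric",
    dosesB = "numeric",
    values = "matrix",
    solverFlags = "matrix",
    curveA = "HillCurve",
    curveB = "HillCurve"
  )
)

setValidity("ReferenceSurface", function(object) {
  msg <- character()
  if (!(object@model %in% REFERENCE_MODELS)) {
    msg <- c(msg, sprintf(
      "'model' must be one of %s",
      paste(REFERENCE_MODELS, collapse = ", ")
    ))
  }
  if (!identical(
    dim(object@values),
    c(length(object@dosesB), length(object@dosesA))
  )) {
    msg <- c(msg, "'values' must be |dosesB| x |dosesA|")
  }
  if (!identical(dim(object@solverFlags), dim(object@values))) {
    msg <- c(msg, "'solverFlags' must match the shape of 'values'")
  }
  if (any(!is.finite(object@values))) {
    msg <- c(msg, "'values' must be finite")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReferenceSurface", function(object) {
  flg <- table(object@solverFlags)
  cat(sprintf(
    "ReferenceSurface (%s): %d x %d grid; cells: %s\n",
    object@model, length(object@dosesB), length(object@dosesA),
    paste(sprintf("%s=%d", names(flg), as.integer(flg)), collapse = ", ")
  ))
  invisible(NULL)
})

#' Synergy/antagonism distribution over concentration space
#'
#' Per-dose-pair difference between the reference surface and the mean
#' observed response, in % points. With the default sign convention,
#' positive values mean more effect than the non-interaction model predicts
#' (synergy), negative values antagonism. Cells on the zero-dose axes
#' measure single-agent fit residual rather than interaction and are
#' excluded from the scalar metrics by default.
#'
#' @slot model the reference model id.
#' @slot dosesA,dosesB numeric dose grids.
#' @slot values numeric matrix of synergy scores (% points).
#' @slot perCellSD numeric matrix of replicate standard deviations (all `NA`
#'   when fewer than 2 replicates).
#' @slot nReplicates integer(1).
#' @seealso [synergyDistribution()], [computeMetrics()]
#' @exportClass SynergyDistribution
setClass("SynergyDistribution",
  representation(
    model = "character",
    dosesA = "numeric",
    dosesB = "numeric",
    values = "matrix",
    perCellSD = "matrix",
    nReplicates = "integer"
  )
)

setValidity("SynergyDistribution", function(object) {
  msg <- character()
  if (!identical(
    dim(object@values),
    c(length(object@dosesB), length(object@dosesA))
  )) {
    msg <- c(msg, "'values' must be |dosesB| x |dosesA|")
  }
  if (!identical(dim(object@perCellSD), dim(object@values))) {
    msg <- c(msg, "'perCellSD' must match the shape of 'values'")
  }
  if (object@nReplicates < 1L) msg <- c(msg, "'nReplicates' must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SynergyDistribution", function(object) {
  v <- interiorValues(object)
  cat(sprintf(
    "SynergyDistribution (%s): %d x %d grid, %d replicate(s)\n",
    object@model, length(object@dosesB), length(object@dosesA),
    object@nReplicates
  ))
  cat(sprintf(
    "  interior synergy: max = %+.3g, min = %+.3g, mean = %+.3g %% points\n",
    max(v), min(v), mean(v)
  ))
  invisible(NULL)
})
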