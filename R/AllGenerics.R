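#' Accessors for combination-analysis objects
#'
#' `dosesA()` / `dosesB()` return the concentration grids (drug A = columns,
#' drug B = rows); `surfaceValues()` the value matrix of a surface or synergy
#' distribution; `modelName()` the reference model id; `solverFlags()` the
#' per-cell solver markers of a reference surface; `replicates()` the list of
#' replicate response matrices; `meanResponse()` their element-wise mean;
#' `nReplicates()` the replicate count; `experimentName()`, `agentNames()`
#' and `qcWarnings()` the experiment metadata.
#'
#' @param x a [CombinationExperiment-class], [ReferenceSurface-class] or
#'   [SynergyDistribution-class] as appropriate.
#' @return See each description above.
#' @name accessors
#' @examples
#' ce <- CombinationExperiment(
#'   dosesA = c(0, 1), dosesB = c(0, 1),
#'   replicates = matrix(c(100, 70, 60, 50), 2, 2)
#' )
#' dosesA(ce)
#' nReplicates(ce)
NULL

#' @rdname accessors
#' @export
setGeneric("dosesA", function(x) standardGeneric("dosesA"))

#' @rdname accessors
#' @export
setGeneric("dosesB", function(x) standardGeneric("dosesB"))

#' @rdname accessors
#' @export
setGeneric("surfaceValues", function(x) standardGeneric("surfaceValues"))

#' @rdname accessors
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))

#' @rdname accessors
#' @export
setGeneric("solverFlags", function(x) standardGeneric("solverFlags"))

#' @rdname accessors
#' @export
setGeneric("replicates", function(x) standardGeneric("replicates"))

#' @rdname accessors
#' @export
setGeneric("meanResponse", function(x) standardGeneric("meanResponse"))

#' @rdname accessors
#' @export
setGeneric("nReplicates", function(x) standardGeneric("nReplicates"))

#' @rdname accessors
#' @export
setGeneric("experimentName", function(x) standardGeneric("experimentName"))

#' @rdname accessors
#' @export
setGeneric("agentNames", function(x) standardGeneric("agentNames"))

#' @rdname accessors
#' @export
setGeneric("qcWarnings", function(x) standardGeneric("qcWarnings"))

#' @rdname accessors
#' @export
setMethod("dosesA", "CombinationExperiment", function(x) {
  SummarizedExperiment::colData(x)$dose
})

#' @rdname accessors
#' @export
setMethod("dosesB", "CombinationExperiment", function(x) {
  SummarizedExperiment::rowData(x)$dose
})

#' @rdname accessors
#' @export
setMethod("replicates", "CombinationExperiment", function(x) {
  as.list(SummarizedExperiment::assays(x))
})

#' @rdname accessors
#' @export
setMethod("nReplicates", "CombinationExperiment", function(x) {
  length(SummarizedExperiment::assays(x))
})

#' @rdname accessors
#' @export
setMethod("meanResponse", "CombinationExperiment", function(x) {
  reps <- replicates(x)
  Reduce(`+`, reps) / length(reps)
})

#' @rdname accessors
#' @export
setMethod("experimentName", "CombinationExperiment", function(x) {
  metadata(x)$name
})

#' @rdname accessors
#' @export
setMethod("agentNames", "CombinationExperiment", function(x) {
  c(a = metadata(x)$agentA, b = metadata(x)$agentB)
})

#' @rdname accessors
#' @export
setMethod("qcWarnings", "CombinationExperiment", function(x) {
  metadata(x)$qcWarnings
})

#' @rdname accessors
#' @export
setMethod("dosesA", "ReferenceSurface", function(x) x@dosesA)

#' @rdname accessors
#' @export
setMethod("dosesB", "ReferenceSurface", function(x) x@dosesB)

#' @rdname accessors
#' @export
setMethod("surfaceValues", "ReferenceSurface", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("modelName", "ReferenceSurface", function(x) x@model)

#' @rdname accessors
#' @export
setMethod("solverFlags", "ReferenceSurface", function(x) x@solverFlags)

#' @rdname accessors
#' @export
setMethod("dosesA", "SynergyDistribution", function(x) x@dosesA)

#' @rdname accessors
#' @export
setMethod("dosesB", "SynergyDistribution", function(x) x@dosesB)

#' @rdname accessors
#' @export
setMethod("surfaceValues", "SynergyDistribution", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("modelName", "SynergyDistribution", function(x) x@model)

#' @rdname accessors
#' @export
setMethod("nReplicates", "SynergyDistribution", function(x) x@nReplicates)

#' Interior (both-doses-positive) cells of a synergy distribution
#'
#' Axis cells (where either dose is zero) reflect single-agent fit residual,
#' not drug interaction, so metrics operate on the interior sub-matrix.
#'
#' @param x a [SynergyDistribution-class] (or [ReferenceSurface-class]).
#' @return `interiorValues()` returns the interior value matrix;
#'   `interiorMask()` a logical matrix marking interior cells.
#' @export
interiorValues <- function(x) {
  surfaceValues(x)[dosesB(x) > 0, dosesA(x) > 0, drop = FALSE]
}

#' @rdname interiorValues
#' @export
interiorMask <- function(x) {
  outer(dosesB(x) > 0, dosesA(x) > 0, `&`)
}
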