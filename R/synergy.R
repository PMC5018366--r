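#' Synergy/antagonism distribution over concentration space
#'
#' Compares the experimental surface to a model-generated reference surface
#' cell by cell. With the default `direction = "reference-minus-data"`, the
#' score is `reference - mean(data)`: observed response below the reference
#' (more kill than the non-interaction model predicts) scores positive
#' synergy, response above it negative antagonism. The literature is split
#' on this sign, so the convention is switchable. With two or more
#' replicates the per-cell replicate standard deviation is recorded.
#'
#' Because the mean is linear, computing the difference on the replicate
#' mean and averaging per-replicate differences give identical values.
#'
#' @param exp a [CombinationExperiment-class].
#' @param ref a [ReferenceSurface-class] on the same dose grids.
#' @param direction `"reference-minus-data"` (default; synergy positive) or
#'   `"data-minus-reference"`.
#' @return A [SynergyDistribution-class].
#' @examples
#' ce <- CombinationExperiment(
#'   dosesA = c(0, 1, 2, 4), dosesB = c(0, 1, 2, 4),
#'   replicates = matrix(50, 4, 4)
#' )
#' curves <- list(a = HillCurve(0, 1, 1), b = HillCurve(0, 1, 1))
#' ref <- blissSurface(curves$a, curves$b, dosesA(ce), dosesB(ce))
#' synergyDistribution(ce, ref)
#' @export
synergyDistribution <- function(exp, ref,
                                direction = c(
                                  "reference-minus-data",
                                  "data-minus-reference"
                                )) {
  stopifnot(is(exp, "CombinationExperiment"), is(ref, "ReferenceSurface"))
  direction <- match.arg(direction)
  if (!isTRUE(all.equal(dosesA(exp), dosesA(ref))) ||
    !isTRUE(all.equal(dosesB(exp), dosesB(ref)))) {
    stop("experiment and reference surface are on different dose grids")
  }
  sgn <- if (direction == "reference-minus-data") 1 else -1
  values <- sgn * (surfaceValues(ref) - meanResponse(exp))
  reps <- replicates(exp)
  if (length(reps) >= 2L) {
    m <- meanResponse(exp)
    ss <- Reduce(`+`, lapply(reps, function(r) (r - m)^2))
    sd <- sqrt(ss / (length(reps) - 1L))
  } else {
    sd <- matrix(NA_real_, nrow(values), ncol(values))
  }
  dimnames(sd) <- dimnames(values)
  new("SynergyDistribution",
    model = modelName(ref), dosesA = dosesA(exp), dosesB = dosesB(exp),
    values = values, perCellSD = sd, nReplicates = nReplicates(exp)
  )
}

#' Per-cell replicate standard deviation of a synergy distribution
#'
#' @param x a [SynergyDistribution-class].
#' @return Numeric matrix (all `NA` with fewer than 2 replicates).
#' @export
perCellSD <- function(x) {
  stopifnot(is(x, "SynergyDistribution"))
  x@perCellSD
}

#' Per-cell significance mask for synergy (extension)
#'
#' With at least 3 replicates, runs a two-sided one-sample t-test of each
#' interior cell's replicate deviations from the reference against zero,
#' Bonferroni-corrected over the interior cells. This testing layer is an
#' extension beyond the classical surface workflow and is not applied
#' anywhere by default.
#'
#' @inheritParams synergyDistribution
#' @param alpha family-wise significance level (default 0.05).
#' @return Logical matrix, `TRUE` where the interior deviation is
#'   significant; axis cells are `NA`.
#' @export
synergySignificance <- function(exp, ref, alpha = 0.05,
                                direction = c(
                                  "reference-minus-data",
                                  "data-minus-reference"
                                )) {
  stopifnot(is(exp, "CombinationExperiment"), is(ref, "ReferenceSurface"))
  direction <- match.arg(direction)
  if (nReplicates(exp) < 3L) {
    stop("significance testing requires at least 3 replicates")
  }
  sgn <- if (direction == "reference-minus-data") 1 else -1
  reps <- replicates(exp)
  refv <- surfaceValues(ref)
  mask <- interiorMask(exp)
  nTests <- sum(mask)
  out <- matrix(NA, nrow(refv), ncol(refv), dimnames = dimnames(refv))
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]
    j <- idx[k, 2]
    dev <- sgn * (refv[i, j] - vapply(reps, function(r) r[i, j], numeric(1)))
    # constant deviations make the t statistic undefined: a constant zero
    # deviation is clearly null, a constant non-zero one clearly not
    p <- if (stats::sd(dev) == 0) {
      if (all(dev == 0)) 1 else 0
    } else {
      stats::t.test(dev, mu = 0)$p.value
    }
    out[i, j] <- p < alpha / nTests
  }
  out
}
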