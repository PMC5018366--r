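# 3x3 uniform smoothing, kernel truncated at the borders (each cell is the
# mean of its in-bounds Moore neighbourhood including itself).
.smooth3x3 <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(0, nr, nc)
  cnt <- matrix(0L, nr, nc)
  for (di in -1:1) {
    for (dj in -1:1) {
      ri <- max(1, 1 + di):min(nr, nr + di)
      rj <- max(1, 1 + dj):min(nc, nc + dj)
      out[ri - di, rj - dj] <- out[ri - di, rj - dj] + m[ri, rj]
      cnt[ri - di, rj - dj] <- cnt[ri - di, rj - dj] + 1L
    }
  }
  out / cnt
}

#' Scalar metrics of a synergy distribution
#'
#' Summarizes the interior (both doses positive) of a synergy distribution
#' for ranking and batch comparison. Integrated metrics are means, not sums,
#' so screens mixing grid sizes stay comparable:
#'
#' * `max_synergy` / `max_antagonism`: largest and smallest interior value
#'   (% points; `max_antagonism` is reported as a value \eqn{\le} 0).
#' * `sum_synergy` / `sum_antagonism`: mean of the positive / negative parts,
#'   so `integrated_total = sum_synergy + sum_antagonism` is the plain
#'   interior mean.
#' * `weighted_integrated`: effect-weighted mean
#'   \eqn{\sum w s / \sum w} with weights
#'   \eqn{w = (100 - \bar{E})/100} clamped to \[0, 1\], where \eqn{\bar{E}}
#'   is the mean observed response — emphasizing synergy in high-effect
#'   regions. If every weight is zero (no observed effect anywhere) the
#'   unweighted mean is reported.
#' * `peak_dose_a` / `peak_dose_b`: the concentration pair where synergy is
#'   most dense — the argmax of the interior distribution after 3x3 uniform
#'   smoothing (truncated at borders), so a lone noisy cell cannot define
#'   the peak. Ties resolve to the lexicographically lowest
#'   `(dose_a, dose_b)` pair, preferring lower concentrations.
#'
#' @param dist a [SynergyDistribution-class].
#' @param exp the matching [CombinationExperiment-class] (supplies the
#'   observed responses used for weighting).
#' @return A one-row `data.frame` with columns `model`, `max_synergy`,
#'   `max_antagonism`, `sum_synergy`, `sum_antagonism`, `integrated_total`,
#'   `weighted_integrated`, `peak_dose_a`, `peak_dose_b`, `n_cells`.
#' @examples
#' ce <- simulateExperiment(
#'   HillCurve(0, 1, 1), HillCurve(0, 1, 1),
#'   model = "BLISS", seed = 1
#' )
#' curves <- fitSingleAgents(ce)
#' ref <- blissSurface(curves$a, curves$b, dosesA(ce), dosesB(ce))
#' computeMetrics(synergyDistribution(ce, ref), ce)
#' @export
computeMetrics <- function(dist, exp) {
  stopifnot(is(dist, "SynergyDistribution"), is(exp, "CombinationExperiment"))
  v <- interiorValues(dist)
  if (!length(v)) {
    stop("no interior cells: the grid has no positive-dose pairs")
  }
  da <- dosesA(dist)[dosesA(dist) > 0]
  db <- dosesB(dist)[dosesB(dist) > 0]

  w <- pmin(pmax((100 - meanResponse(exp)[
    dosesB(exp) > 0, dosesA(exp) > 0,
    drop = FALSE
  ]) / 100, 0), 1)
  weighted <- if (sum(w) > 0) sum(w * v) / sum(w) else mean(v)

  sm <- .smooth3x3(v)
  # column-major scan = ascending (dose_a, dose_b) lexicographic order, so
  # which.max's first-hit rule is exactly the documented tie-break
  k <- which.max(sm)
  peakB <- (k - 1) %% nrow(sm) + 1
  peakA <- (k - 1) %/% nrow(sm) + 1
  data.frame(
    model = modelName(dist),
    max_synergy = max(v),
    max_antagonism = min(v),
    sum_synergy = mean(pmax(v, 0)),
    sum_antagonism = mean(pmin(v, 0)),
    integrated_total = mean(v),
    weighted_integrated = weighted,
    peak_dose_a = da[peakA],
    peak_dose_b = db[peakB],
    n_cells = length(v),
    stringsAsFactors = FALSE
  )
}
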