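.newReference <- function(model, curveA, curveB, dosesA, dosesB,
                          values, flags) {
  dimnames(values) <- list(
    format(dosesB, trim = TRUE),
    format(dosesA, trim = TRUE)
  )
  dimnames(flags) <- dimnames(values)
  new("ReferenceSurface",
    model = model, dosesA = dosesA, dosesB = dosesB,
    values = values, solverFlags = flags, curveA = curveA, curveB = curveB
  )
}

# All three models agree with the single-agent curves on the axes; set those
# cells exactly rather than through each model's interior formula.
.applyAxes <- function(values, curveA, curveB, dosesA, dosesB) {
  values[dosesB == 0, ] <- hillResponse(curveA, dosesA)
  values[, dosesA == 0] <- hillResponse(curveB, dosesB)
  values[dosesB == 0, dosesA == 0] <- 100
  values
}

#' Bliss independence reference surface
#'
#' Treats the two % control responses as independent surviving fractions:
#' the predicted combination response is
#' \eqn{E_A E_B / 100}. This product law is only meaningful for fractions in
#' \[0, 1\], so curve predictions outside \[0, 100\] (possible when
#' `eInf < 0`) are clamped before multiplying and the cell flagged
#' `"clamped"`.
#'
#' @param curveA,curveB fitted [HillCurve-class] objects for the column
#'   (A) and row (B) drugs.
#' @param dosesA,dosesB the experiment dose grids (each containing 0).
#' @return A [ReferenceSurface-class] with `model = "BLISS"`.
#' @examples
#' hc <- HillCurve(0, 1, 1)
#' blissSurface(hc, hc, c(0, 1), c(0, 1))
#' @export
blissSurface <- function(curveA, curveB, dosesA, dosesB) {
  ea <- hillResponse(curveA, dosesA)
  eb <- hillResponse(curveB, dosesB)
  eaC <- pmin(pmax(ea, 0), 100)
  ebC <- pmin(pmax(eb, 0), 100)
  values <- outer(ebC, eaC) / 100
  flags <- matrix("exact", length(dosesB), length(dosesA))
  clamped <- outer(ebC != eb, eaC != ea, `|`)
  flags[clamped] <- "clamped"
  values <- .applyAxes(values, curveA, curveB, dosesA, dosesB)
  .newReference("BLISS", curveA, curveB, dosesA, dosesB, values, flags)
}

#' Highest Single Agent reference surface
#'
#' The predicted combination response at each dose pair is the stronger of
#' the two single-agent effects, i.e. the lower % control:
#' \eqn{\min(E_A(a), E_B(b))}.
#'
#' @inheritParams blissSurface
#' @return A [ReferenceSurface-class] with `model = "HSA"`.
#' @export
hsaSurface <- function(curveA, curveB, dosesA, dosesB) {
  ea <- hillResponse(curveA, dosesA)
  eb <- hillResponse(curveB, dosesB)
  values <- outer(eb, ea, pmin)
  flags <- matrix("exact", length(dosesB), length(dosesA))
  values <- .applyAxes(values, curveA, curveB, dosesA, dosesB)
  .newReference("HSA", curveA, curveB, dosesA, dosesB, values, flags)
}

# Loewe combination index a/A(E) + b/B(E) - 1, vectorized over effect E
# (with a, b fixed per cell). Monotone increasing in E on (max eInf, 100):
# higher E (less effect) needs smaller equivalent doses.
.loeweCI <- function(E, a, b, curveA, curveB) {
  a / inverseHill(curveA, E) + b / inverseHill(curveB, E) - 1
}

#' Loewe additivity reference surface
#'
#' Under dose equivalence, the non-interactive response \eqn{E^*} at dose
#' pair \eqn{(a, b)} satisfies \eqn{a/A(E^*) + b/B(E^*) = 1}, where
#' \eqn{A(E)} and \eqn{B(E)} are the single-agent doses producing effect
#' \eqn{E} (the combination index equals 1). The index is monotone in
#' \eqn{E}, so each interior cell is solved by bisection on the effect over
#' \eqn{(\max(E_{inf,A}, E_{inf,B}), 100)}, run until the index residual is
#' below `tol` or the bracket is narrower than 1e-10.
#'
#' Partial definition is handled explicitly rather than by extrapolating a
#' Hill curve beyond its asymptote: when the cell demands an effect deeper
#' than the weaker agent's asymptote (no root in the bracket), the index
#' equation degenerates to the stronger agent acting alone, so the value is
#' capped at `min(max(eInfA, eInfB), E_A(a), E_B(b)) + tol` — never above
#' what either drug achieves by itself, which keeps the surface monotone
#' and consistent with its own axes — and flagged `"capped"`; when an agent
#' is inactive (see [fitHill()]), the reference falls back to the active
#' agent's single-agent response, flagged `"fallback_single_agent"`.
#'
#' @inheritParams blissSurface
#' @param tol positive tolerance on the combination-index residual.
#' @return A [ReferenceSurface-class] with `model = "LOEWE"`.
#' @examples
#' hc <- HillCurve(0, 1, 1)
#' # sham combination: reference at (1, 1) equals the curve at dose 2
#' surfaceValues(loeweSurface(hc, hc, c(0, 1), c(0, 1)))[2, 2]
#' hillResponse(hc, 2)
#' @export
loeweSurface <- function(curveA, curveB, dosesA, dosesB, tol = 1e-8) {
  stopifnot(tol > 0)
  nb <- length(dosesB)
  na <- length(dosesA)
  values <- matrix(NA_real_, nb, na)
  flags <- matrix("exact", nb, na)

  interior <- which(outer(dosesB > 0, dosesA > 0, `&`), arr.ind = TRUE)
  a <- dosesA[interior[, 2]]
  b <- dosesB[interior[, 1]]

  if (curveA@inactive || curveB@inactive) {
    if (!curveB@inactive) {
      values[interior] <- hillResponse(curveB, b)
    } else if (!curveA@inactive) {
      values[interior] <- hillResponse(curveA, a)
    } else {
      values[interior] <- 100
    }
    flags[interior] <- "fallback_single_agent"
  } else if (nrow(interior)) {
    lowerE <- max(curveA@eInf, curveB@eInf)
    span <- 100 - lowerE
    lo <- rep(lowerE + 1e-12 * span, nrow(interior))
    hi <- rep(100 - 1e-12 * span, nrow(interior))
    # No root when even at the boundary asymptote the index is >= 0: the
    # cell demands an effect one agent cannot reach. In that limit the
    # index equation degenerates to the remaining agent acting alone, so
    # cap at the lesser of the boundary and the single-agent responses
    # (never above what either drug achieves by itself).
    capped <- .loeweCI(lo, a, b, curveA, curveB) >= 0
    solve <- !capped
    est <- pmin(lowerE, hillResponse(curveA, a), hillResponse(curveB, b)) +
      tol
    if (any(solve)) {
      loS <- lo[solve]
      hiS <- hi[solve]
      aS <- a[solve]
      bS <- b[solve]
      done <- rep(FALSE, length(loS))
      maxit <- ceiling(log2(span / 1e-11)) + 4L
      for (it in seq_len(maxit)) {
        mid <- (loS + hiS) / 2
        fm <- .loeweCI(mid, aS, bS, curveA, curveB)
        up <- fm < 0
        loS[up & !done] <- mid[up & !done]
        hiS[!up & !done] <- mid[!up & !done]
        # the residual alone is a poor stop where the index is flat in E,
        # so always narrow the effect bracket itself
        done <- done | (hiS - loS) < 1e-10 | fm == 0
        if (all(done)) break
      }
      est[solve] <- (loS + hiS) / 2
    }
    values[interior] <- est
    flags[interior][capped] <- "capped"
  }

  values <- .applyAxes(values, curveA, curveB, dosesA, dosesB)
  .newReference("LOEWE", curveA, curveB, dosesA, dosesB, values, flags)
}

#' Compute a reference surface under a named model
#'
#' Dispatcher over [loeweSurface()], [blissSurface()] and [hsaSurface()].
#'
#' @inheritParams loeweSurface
#' @param model one of `"LOEWE"`, `"BLISS"`, `"HSA"` (case-insensitive).
#' @return A [ReferenceSurface-class].
#' @export
referenceSurface <- function(model, curveA, curveB, dosesA, dosesB,
                             tol = 1e-8) {
  model <- toupper(model)
  switch(model,
    LOEWE = loeweSurface(curveA, curveB, dosesA, dosesB, tol = tol),
    BLISS = blissSurface(curveA, curveB, dosesA, dosesB),
    HSA = hsaSurface(curveA, curveB, dosesA, dosesB),
    stop(sprintf(
      "unknown reference model '%s' (expected one of %s)",
      model, paste(REFERENCE_MODELS, collapse = ", ")
    ))
  )
}

#' Reference-free brute-force Loewe solve (effect-grid scan)
#'
#' Independent cross-check for the bisection solver: scans the effect axis
#' with a staged uniform grid (coarse step 1 % point, refined twice by a
#' factor 100 around the running best, final step 1e-6 % points) for the
#' effect minimizing the absolute combination-index residual. Orders of
#' magnitude slower than [loeweSurface()]; intended for validation only.
#'
#' @inheritParams blissSurface
#' @param a,b positive doses of the cell to solve.
#' @return The scanned effect \eqn{E^*} in % control.
#' @export
loeweGridScan <- function(curveA, curveB, a, b) {
  lowerE <- max(curveA@eInf, curveB@eInf)
  span <- 100 - lowerE
  lo <- lowerE + 1e-9 * span
  hi <- 100 - 1e-9 * span
  step <- 1e-2 * span
  best <- NA_real_
  repeat {
    grid <- seq(lo, hi, by = step)
    ci <- abs(.loeweCI(grid, a, b, curveA, curveB))
    best <- grid[which.min(ci)]
    if (step <= 1e-6) break
    step <- step / 100
    lo <- max(lowerE + 1e-9 * span, best - 150 * step)
    hi <- min(100 - 1e-9 * span, best + 150 * step)
  }
  best
}
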