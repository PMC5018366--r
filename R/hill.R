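#' Predicted response of a Hill curve
#'
#' Evaluates \eqn{E(c) = E_0 + (E_{inf} - E_0)/(1 + (EC_{50}/c)^h)} with
#' \eqn{E_0 = 100}. Returns exactly 100 at dose 0; monotone non-increasing
#' in dose whenever `eInf <= 100`.
#'
#' @param curve a [HillCurve-class].
#' @param dose numeric vector of non-negative concentrations.
#' @return Numeric vector of responses in % control.
#' @examples
#' hillResponse(HillCurve(0, 1, 2), 3) # 100 / (1 + 9) = 10
#' @export
hillResponse <- function(curve, dose) {
  stopifnot(is(curve, "HillCurve"))
  if (any(dose < 0)) stop("'dose' must be non-negative")
  out <- rep(curve@e0, length(dose))
  pos <- dose > 0
  out[pos] <- curve@e0 +
    (curve@eInf - curve@e0) / (1 + (curve@ec50 / dose[pos])^curve@h)
  out
}

#' Dose producing a given response (inverse Hill)
#'
#' Unique dose `d` with `hillResponse(curve, d) == response`, via the closed
#' form \eqn{d = EC_{50} ((E_0 - E)/(E - E_{inf}))^{1/h}}. Defined only for
#' responses strictly between the asymptote `eInf` and the baseline 100; a
#' response outside that open interval is not achievable by the agent.
#'
#' @param curve a [HillCurve-class].
#' @param response numeric vector of responses in % control, each strictly
#'   inside `(eInf, 100)`.
#' @return Numeric vector of doses.
#' @examples
#' inverseHill(HillCurve(0, 2, 1), 20) # 2 * (80/20) = 8
#' @export
inverseHill <- function(curve, response) {
  stopifnot(is(curve, "HillCurve"))
  if (any(response <= curve@eInf | response >= curve@e0)) {
    stop(sprintf(
      "effect not achievable by this agent: response must lie strictly in (%g, %g)",
      curve@eInf, curve@e0
    ))
  }
  curve@ec50 *
    ((curve@e0 - response) / (response - curve@eInf))^(1 / curve@h)
}

#' Extract single-agent dose-response series from a checkerboard
#'
#' The row at dose B = 0 carries drug A alone; the column at dose A = 0
#' drug B alone. Replicate-wise values are retained alongside the mean so
#' the fit can use every point.
#'
#' @param exp a [CombinationExperiment-class].
#' @return A list with elements `a` and `b`, each a list of `doses` (numeric),
#'   `response` (mean across replicates) and `replicateResponses` (matrix,
#'   replicates in rows, doses in columns).
#' @export
extractSingleAgents <- function(exp) {
  stopifnot(is(exp, "CombinationExperiment"))
  reps <- replicates(exp)
  ia <- which(dosesB(exp) == 0) # row carrying drug A alone
  ib <- which(dosesA(exp) == 0) # column carrying drug B alone
  rowsA <- do.call(rbind, lapply(reps, function(m) m[ia, ]))
  colsB <- do.call(rbind, lapply(reps, function(m) m[, ib]))
  list(
    a = list(
      doses = dosesA(exp),
      response = colMeans(rowsA),
      replicateResponses = unname(rowsA)
    ),
    b = list(
      doses = dosesB(exp),
      response = colMeans(colsB),
      replicateResponses = unname(colsB)
    )
  )
}

# Sum of squared residuals of the Hill model, parameterized as
# (eInf, log ec50, h) for better-conditioned optimization.
.hillSSE <- function(par, dose, resp) {
  eInf <- par[1]
  ec50 <- exp(par[2])
  h <- par[3]
  pred <- ifelse(dose > 0, 100 + (eInf - 100) / (1 + (ec50 / dose)^h), 100)
  sum((resp - pred)^2)
}

.hillResiduals <- function(par, dose, resp) {
  eInf <- par[1]
  ec50 <- exp(par[2])
  h <- par[3]
  pred <- ifelse(dose > 0, 100 + (eInf - 100) / (1 + (ec50 / dose)^h), 100)
  resp - pred
}

#' Fit a three-parameter Hill curve
#'
#' Bounded least squares over `(eInf, log ec50, h)` on all replicate points
#' (unweighted), with the baseline pinned at 100. Optimization uses a
#' deterministic multi-start grid (5 `ec50` starts log-spaced over the dose
#' range crossed with slope starts 0.5, 1 and 3) of L-BFGS-B runs, followed
#' by a Levenberg-Marquardt polish of the best start, so the fit contains no
#' randomness and recovers noise-free model data to near machine precision.
#' Bounds: `eInf` in \[-20, 100\], `ec50` in
#' \[min positive dose / 100, max dose x 100\], `h` in \[0.1, 10\].
#'
#' An agent is flagged inactive when the fitted curve is essentially flat
#' (`|100 - eInf| < 5` % points) or explains almost none of the variance
#' (R-squared < 0.3); downstream Loewe/HSA handling falls back accordingly.
#'
#' @param doses numeric vector of concentrations (zero doses are kept as
#'   baseline anchors); at least 3 distinct positive doses are required.
#' @param responses responses in % control: a numeric vector parallel to
#'   `doses`, or a matrix/list with one replicate per row/element.
#' @return A [HillCurve-class] with `diagnostics` filled in (`rmse`, `r2`,
#'   `converged`, `nPoints`).
#' @examples
#' d <- c(0, 10^seq(-2, 2, length.out = 8))
#' fitHill(d, hillResponse(HillCurve(10, 1, 1.5), d))
#' @export
fitHill <- function(doses, responses) {
  doses <- as.numeric(doses)
  if (is.list(responses)) {
    responses <- do.call(rbind, lapply(responses, as.numeric))
  }
  if (is.matrix(responses)) {
    if (ncol(responses) != length(doses)) {
      stop("replicate response matrix must have one column per dose")
    }
    dose <- rep(doses, each = nrow(responses))
    resp <- as.numeric(responses)
  } else {
    if (length(responses) != length(doses)) {
      stop("'responses' must be parallel to 'doses'")
    }
    dose <- doses
    resp <- as.numeric(responses)
  }
  keep <- is.finite(resp)
  dose <- dose[keep]
  resp <- resp[keep]
  if (length(unique(dose[dose > 0])) < 3L) {
    stop("at least 3 distinct positive doses are required to fit 3 parameters")
  }

  dmin <- min(dose[dose > 0])
  dmax <- max(dose)
  lower <- c(-20, log(dmin / 100), 0.1)
  upper <- c(100, log(dmax * 100), 10)
  eInf0 <- min(max(min(resp), -20), 100)
  starts <- expand.grid(
    ec50 = exp(seq(log(dmin), log(dmax), length.out = 5)),
    h = c(0.5, 1, 3)
  )

  best <- NULL
  for (k in seq_len(nrow(starts))) {
    p0 <- c(eInf0, log(starts$ec50[k]), starts$h[k])
    fit <- tryCatch(
      stats::optim(p0, .hillSSE,
        dose = dose, resp = resp,
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(factr = 1e4, maxit = 500)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      fit <- list(par = p0, value = .hillSSE(p0, dose, resp), convergence = 99L)
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }

  polished <- tryCatch(
    minpack.lm::nls.lm(
      par = best$par, lower = lower, upper = upper,
      fn = .hillResiduals, dose = dose, resp = resp,
      control = minpack.lm::nls.lm.control(
        ftol = 1e-15, ptol = 1e-15, maxiter = 500
      )
    ),
    error = function(e) NULL
  )
  converged <- TRUE
  if (!is.null(polished) &&
    sum(polished$fvec^2) <= best$value + 1e-12) {
    par <- polished$par
    sse <- sum(polished$fvec^2)
  } else {
    par <- best$par
    sse <- best$value
    converged <- best$convergence == 0L
  }

  rmse <- sqrt(sse / length(resp))
  sst <- sum((resp - mean(resp))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1
  inactive <- abs(100 - par[1]) < 5 || r2 < 0.3
  HillCurve(
    eInf = par[1], ec50 = exp(par[2]), h = par[3],
    inactive = inactive,
    diagnostics = list(
      rmse = rmse, r2 = r2, converged = converged, nPoints = length(resp)
    )
  )
}

#' Fit both single-agent curves of an experiment
#'
#' Convenience wrapper: [extractSingleAgents()] then [fitHill()] on all
#' replicate points of each axis.
#'
#' @param exp a [CombinationExperiment-class].
#' @return List with [HillCurve-class] elements `a` and `b`.
#' @export
fitSingleAgents <- function(exp) {
  s <- extractSingleAgents(exp)
  list(
    a = fitHill(s$a$doses, s$a$replicateResponses),
    b = fitHill(s$b$doses, s$b$replicateResponses)
  )
}
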