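# Run code under a fixed RNG state without disturbing the caller's stream.
.withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.defaultDoseGrid <- function() c(0, 10^seq(-1.5, 1.5, length.out = 7))

#' Simulate a checkerboard experiment with known ground truth
#'
#' Generates replicate response matrices from two known Hill curves under a
#' chosen non-interaction model, with an optional planted synergy field and
#' i.i.d. Gaussian noise on the % control scale:
#' `response(i, j, rep) = reference(i, j) - synergyField(i, j) + N(0, noiseSD^2)`.
#' Subtracting the synergy field makes a positive planted value come out as
#' positive synergy under the default sign convention. Noise is drawn for
#' every cell of every replicate, the untreated control included — the
#' control well is as noisy as any other well.
#'
#' The default grid (8 doses per drug: 0 plus 7 log-spaced concentrations
#' over three decades) and defaults of 3 % points noise and 3 replicates
#' mirror a typical cell-viability checkerboard.
#'
#' @param curveA,curveB ground-truth [HillCurve-class] objects.
#' @param model reference model id (`"LOEWE"`, `"BLISS"`, `"HSA"`).
#' @param dosesA,dosesB dose grids, each containing 0.
#' @param synergyField numeric matrix (`|dosesB| x |dosesA|`) of planted
#'   interaction in % points (0 = non-synergistic), or a single 0.
#' @param noiseSD Gaussian noise standard deviation in % points.
#' @param nReplicates number of replicate matrices.
#' @param seed integer seed; mandatory so every simulated experiment is
#'   reproducible.
#' @param name experiment identifier.
#' @return A [CombinationExperiment-class].
#' @examples
#' ce <- simulateExperiment(
#'   HillCurve(5, 1, 1.2), HillCurve(20, 3, 2),
#'   model = "BLISS", noiseSD = 3, nReplicates = 3, seed = 42
#' )
#' ce
#' @export
simulateExperiment <- function(curveA, curveB, model = "LOEWE",
                               dosesA = .defaultDoseGrid(),
                               dosesB = .defaultDoseGrid(),
                               synergyField = 0,
                               noiseSD = 3, nReplicates = 3, seed,
                               name = "synthetic_experiment") {
  stopifnot(
    is(curveA, "HillCurve"), is(curveB, "HillCurve"),
    noiseSD >= 0, nReplicates >= 1
  )
  if (missing(seed)) stop("'seed' is mandatory for reproducible simulation")
  ref <- referenceSurface(model, curveA, curveB, dosesA, dosesB)
  truth <- surfaceValues(ref)
  if (length(synergyField) == 1L) {
    synergyField <- matrix(synergyField, nrow(truth), ncol(truth))
  }
  stopifnot(identical(dim(synergyField), dim(truth)))
  clean <- truth - synergyField
  reps <- .withSeed(seed, lapply(seq_len(nReplicates), function(k) {
    clean + matrix(
      stats::rnorm(length(clean), sd = noiseSD),
      nrow(clean), ncol(clean)
    )
  }))
  CombinationExperiment(
    dosesA = dosesA, dosesB = dosesB, replicates = reps, name = name
  )
}

#' Simulate a whole screen on disk
#'
#' Writes `n` experiments, each in its own sub-folder of `dir` with one
#' template CSV per replicate (via [writeExperiment()], so the files also
#' exercise the parser), ready for [runBatch()]. Ground-truth curves are
#' drawn per experiment: `eInf` uniform on \[0, 40\] % control, `ec50`
#' log-uniform over the positive dose range, slope `h` uniform on
#' \[0.5, 4\] — the parameter ranges of a realistically active oncology
#' screen.
#'
#' @param n number of experiments.
#' @param dir output directory.
#' @param model reference model used to generate each experiment.
#' @param dosesA,dosesB dose grids.
#' @param noiseSD,nReplicates as in [simulateExperiment()].
#' @param seed integer seed.
#' @return Invisibly, a `data.frame` of the ground-truth parameters per
#'   experiment.
#' @export
simulateScreen <- function(n, dir, model = "BLISS",
                           dosesA = .defaultDoseGrid(),
                           dosesB = .defaultDoseGrid(),
                           noiseSD = 3, nReplicates = 3, seed) {
  if (missing(seed)) stop("'seed' is mandatory for reproducible simulation")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pos <- range(dosesA[dosesA > 0])
  pars <- .withSeed(seed, data.frame(
    experiment = sprintf("experiment_%02d", seq_len(n)),
    eInfA = stats::runif(n, 0, 40),
    ec50A = exp(stats::runif(n, log(pos[1]), log(pos[2]))),
    hA = stats::runif(n, 0.5, 4),
    eInfB = stats::runif(n, 0, 40),
    ec50B = exp(stats::runif(n, log(pos[1]), log(pos[2]))),
    hB = stats::runif(n, 0.5, 4),
    seed = sample.int(.Machine$integer.max, n),
    stringsAsFactors = FALSE
  ))
  for (i in seq_len(n)) {
    ce <- simulateExperiment(
      HillCurve(pars$eInfA[i], pars$ec50A[i], pars$hA[i]),
      HillCurve(pars$eInfB[i], pars$ec50B[i], pars$hB[i]),
      model = model, dosesA = dosesA, dosesB = dosesB,
      noiseSD = noiseSD, nReplicates = nReplicates,
      seed = pars$seed[i], name = pars$experiment[i]
    )
    writeExperiment(ce, file.path(dir, pars$experiment[i]))
  }
  invisible(pars)
}
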