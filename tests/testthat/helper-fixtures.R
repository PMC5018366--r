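# Shared fixtures: everything is generated in code so the suite needs no
# stored data beyond the shipped CSV template.

# default synthetic dose grid: 0 plus 7 log-spaced doses over 3 decades
logGrid <- function(n = 8) c(0, 10^seq(-1.5, 1.5, length.out = n - 1))

# random active Hill curve within the screen-realistic parameter ranges
randomCurve <- function() {
  HillCurve(
    eInf = runif(1, 0, 40),
    ec50 = 10^runif(1, -1.5, 1.5),
    h = runif(1, 0.5, 4)
  )
}

# minimal 2x2 experiment used by the parsing/extraction examples
tinyExperiment <- function(values = matrix(c(100, 70, 60, 50), 2, 2),
                           nrep = 1) {
  CombinationExperiment(
    dosesA = c(0, 1), dosesB = c(0, 1),
    replicates = rep(list(values), nrep), name = "tiny"
  )
}

writeGridCSV <- function(path, dosesA, dosesB, values, corner = "") {
  rows <- c(
    paste(c(corner, dosesA), collapse = ","),
    vapply(seq_along(dosesB), function(i) {
      paste(c(dosesB[i], values[i, ]), collapse = ",")
    }, character(1))
  )
  writeLines(rows, path)
  path
}
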