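test_that("the same seed reproduces the experiment exactly", {
  ca <- HillCurve(5, 1, 1.2)
  cb <- HillCurve(20, 3, 2)
  ce1 <- simulateExperiment(ca, cb, model = "BLISS", seed = 42)
  ce2 <- simulateExperiment(ca, cb, model = "BLISS", seed = 42)
  expect_equal(replicates(ce1), replicates(ce2))
  ce3 <- simulateExperiment(ca, cb, model = "BLISS", seed = 43)
  expect_false(identical(replicates(ce1), replicates(ce3)))
  expect_error(simulateExperiment(ca, cb), "seed")
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(77)
  before <- runif(1)
  set.seed(77)
  invisible(simulateExperiment(
    HillCurve(0, 1, 1), HillCurve(0, 1, 1),
    model = "HSA", seed = 5
  ))
  expect_equal(runif(1), before)
})

test_that("noise-free simulation under each model round-trips to zero", {
  ca <- HillCurve(5, 0.8, 1.3)
  cb <- HillCurve(25, 2.5, 2.1)
  for (m in c("LOEWE", "BLISS", "HSA")) {
    ce <- simulateExperiment(ca, cb,
      model = m, noiseSD = 0, nReplicates = 1, seed = 1
    )
    res <- analyzeExperiment(ce, models = m)
    expect_lt(max(abs(interiorValues(res$distributions[[m]]))), 1e-5)
  }
})

test_that("scoring under a mismatched model shows the model gap", {
  ca <- HillCurve(0, 0.8, 1.3)
  cb <- HillCurve(0, 2.5, 2.1)
  ce <- simulateExperiment(ca, cb,
    model = "BLISS", noiseSD = 0, nReplicates = 1, seed = 2
  )
  res <- analyzeExperiment(ce, models = c("BLISS", "HSA"))
  # HSA reference >= Bliss reference, so Bliss-generated data scored under
  # HSA appears synergistic (non-negative) at every interior cell
  expect_gte(min(interiorValues(res$distributions$HSA)), -1e-6)
  expect_gt(max(interiorValues(res$distributions$HSA)), 1)
})

test_that("a planted synergy bump is recovered by the full pipeline", {
  ca <- HillCurve(5, 0.8, 1.3)
  cb <- HillCurve(25, 2.5, 2.1)
  g <- logGrid()
  field <- matrix(0, 8, 8)
  field[2, 2] <- 15 # lowest interior dose pair
  for (m in c("LOEWE", "BLISS", "HSA")) {
    ce <- simulateExperiment(ca, cb,
      model = m, synergyField = field,
      noiseSD = 0, nReplicates = 1, seed = 3
    )
    res <- analyzeExperiment(ce, models = m)
    met <- res$metrics
    expect_equal(met$max_synergy, 15, tolerance = 0.01)
    expect_equal(met$peak_dose_a, g[2])
    expect_equal(met$peak_dose_b, g[2])
  }
})

test_that("noise calibration: null synergy averages to zero at sd/sqrt(n)", {
  ca <- HillCurve(5, 0.8, 1.3)
  cb <- HillCurve(25, 2.5, 2.1)
  nrep <- 4
  sims <- lapply(1:30, function(k) {
    ce <- simulateExperiment(ca, cb,
      model = "BLISS", noiseSD = 3,
      nReplicates = nrep, seed = 1000 + k
    )
    ref <- blissSurface(ca, cb, dosesA(ce), dosesB(ce)) # true curves
    list(
      vals = interiorValues(synergyDistribution(ce, ref)),
      sd = perCellSD(synergyDistribution(ce, ref))[2, 2]
    )
  })
  allVals <- unlist(lapply(sims, `[[`, "vals"))
  # mean of interior synergy over simulations ~ 0 within Monte-Carlo error
  mcErr <- (3 / sqrt(nrep)) / sqrt(length(allVals))
  expect_lt(abs(mean(allVals)), 4 * mcErr)
  # per-cell spread of the synergy of a replicate-mean ~ sd/sqrt(n)
  expect_equal(sd(unlist(lapply(sims, function(s) s$vals[2, 2]))),
    3 / sqrt(nrep),
    tolerance = 0.35
  )
})

test_that("simulateScreen writes parseable per-experiment folders", {
  d <- withr::local_tempdir()
  pars <- simulateScreen(3, d, model = "HSA", seed = 9)
  folders <- list.dirs(d, recursive = FALSE)
  expect_length(folders, 3)
  ce <- readExperiment(folders[1])
  expect_equal(nReplicates(ce), 3L)
  expect_equal(experimentName(ce), "experiment_01")
})
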