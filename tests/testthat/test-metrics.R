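# build a synergy distribution with prescribed interior values on a grid
# with a full border of zero-dose axes
distWithInterior <- function(interior, data = 50) {
  nb <- nrow(interior) + 1L
  na <- ncol(interior) + 1L
  g <- function(n) c(0, seq_len(n - 1))
  values <- matrix(0, nb, na)
  values[-1, -1] <- interior
  dist <- new("SynergyDistribution",
    model = "BLISS", dosesA = g(na), dosesB = g(nb), values = values,
    perCellSD = matrix(NA_real_, nb, na), nReplicates = 1L
  )
  ce <- CombinationExperiment(g(na), g(nb), matrix(data, nb, na))
  list(dist = dist, ce = ce)
}

test_that("the zero distribution yields all-zero metrics, peak at low doses", {
  f <- distWithInterior(matrix(0, 3, 3))
  m <- computeMetrics(f$dist, f$ce)
  for (col in c(
    "max_synergy", "max_antagonism", "sum_synergy",
    "sum_antagonism", "integrated_total", "weighted_integrated"
  )) {
    expect_equal(m[[col]], 0)
  }
  expect_equal(m$peak_dose_a, 1) # lexicographic tie-break: lowest pair
  expect_equal(m$peak_dose_b, 1)
  expect_equal(m$n_cells, 9)
})

test_that("a single positive cell produces the direct arithmetic", {
  interior <- matrix(0, 3, 3)
  interior[2, 2] <- 10
  f <- distWithInterior(interior)
  m <- computeMetrics(f$dist, f$ce)
  expect_equal(m$max_synergy, 10)
  expect_equal(m$integrated_total, 10 / 9)
  expect_equal(m$sum_synergy, 10 / 9)
  expect_equal(m$sum_antagonism, 0)
  expect_equal(m$max_antagonism, 0)
})

test_that("a constant field is invariant to effect weighting", {
  f <- distWithInterior(matrix(5, 3, 3), data = 50)
  m <- computeMetrics(f$dist, f$ce)
  expect_equal(m$weighted_integrated, 5)
  # with no observed effect anywhere the weights vanish: unweighted mean
  f2 <- distWithInterior(matrix(5, 3, 3), data = 100)
  expect_equal(computeMetrics(f2$dist, f2$ce)$weighted_integrated, 5)
})

test_that("weighting emphasizes high-effect regions", {
  interior <- matrix(c(10, 0, 0, 0), 2, 2)
  nb <- 3L
  data <- matrix(100, nb, nb)
  data[2, 2] <- 10 # strong effect only where the synergy sits
  f <- distWithInterior(interior)
  ce <- CombinationExperiment(c(0, 1, 2), c(0, 1, 2), data)
  m <- computeMetrics(f$dist, ce)
  expect_gt(m$weighted_integrated, m$integrated_total)
  expect_lte(m$weighted_integrated, max(interior))
})

test_that("metrics scale linearly and the peak location does not move", {
  set.seed(30)
  interior <- matrix(rnorm(16, sd = 5), 4, 4)
  f <- distWithInterior(interior)
  f3 <- distWithInterior(3 * interior)
  m <- computeMetrics(f$dist, f$ce)
  m3 <- computeMetrics(f3$dist, f3$ce)
  for (col in c(
    "max_synergy", "max_antagonism", "sum_synergy",
    "sum_antagonism", "integrated_total", "weighted_integrated"
  )) {
    expect_equal(m3[[col]], 3 * m[[col]])
  }
  expect_equal(m3$peak_dose_a, m$peak_dose_a)
  expect_equal(m3$peak_dose_b, m$peak_dose_b)
  expect_true(m$max_synergy >= max(interior) - 1e-12)
  expect_true(m$max_antagonism <= min(interior) + 1e-12)
  expect_gte(m$weighted_integrated, min(interior))
  expect_lte(m$weighted_integrated, max(interior))
})

test_that("value metrics are permutation-invariant, the peak is not", {
  set.seed(31)
  interior <- matrix(rnorm(25, sd = 5), 5, 5)
  perm <- matrix(sample(interior), 5, 5)
  m <- computeMetrics(distWithInterior(interior)$dist,
    distWithInterior(interior)$ce
  )
  mp <- computeMetrics(distWithInterior(perm)$dist,
    distWithInterior(perm)$ce
  )
  for (col in c(
    "max_synergy", "max_antagonism", "sum_synergy",
    "sum_antagonism", "integrated_total"
  )) {
    expect_equal(mp[[col]], m[[col]])
  }
})

test_that("smoothing keeps a lone corner spike at its own dose pair", {
  interior <- matrix(0, 4, 4)
  interior[1, 1] <- 15 # lowest (dose_a, dose_b) interior cell
  f <- distWithInterior(interior)
  m <- computeMetrics(f$dist, f$ce)
  expect_equal(m$peak_dose_a, 1)
  expect_equal(m$peak_dose_b, 1)
  expect_equal(m$max_synergy, 15)
})

test_that("a grid without interior cells is refused", {
  bad <- new("SynergyDistribution",
    model = "HSA", dosesA = c(0, 1), dosesB = 0,
    values = matrix(0, 1, 2), perCellSD = matrix(NA_real_, 1, 2),
    nReplicates = 1L
  )
  ce <- tinyExperiment()
  expect_error(computeMetrics(bad, ce), "interior")
})
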