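test_that("hillResponse matches the closed form", {
  expect_equal(hillResponse(HillCurve(0, 1, 1), 1), 50) # midpoint at ec50
  expect_equal(hillResponse(HillCurve(0, 1, 2), 3), 10) # 100 / (1 + 9)
  expect_equal(hillResponse(HillCurve(37, 2, 1.3), 0), 100) # exact baseline
  # monotone non-increasing whenever eInf <= 100
  set.seed(1)
  for (k in 1:20) {
    cv <- randomCurve()
    r <- hillResponse(cv, sort(10^runif(50, -3, 3)))
    expect_true(all(diff(r) <= 0))
  }
})

test_that("inverseHill inverts hillResponse and guards its domain", {
  expect_equal(inverseHill(HillCurve(0, 1, 1), 50), 1)
  expect_equal(inverseHill(HillCurve(0, 2, 1), 20), 8) # ec50 * (80/20)
  expect_error(inverseHill(HillCurve(0, 1, 1), 100), "not achievable")
  expect_error(inverseHill(HillCurve(30, 1, 1), 20), "not achievable")
  set.seed(2)
  for (k in 1:20) {
    cv <- randomCurve()
    # doses around the ec50; far outside, the response is numerically
    # indistinguishable from its asymptotes and no inverse can recover it
    d <- cv@ec50 * 10^runif(20, -1.5, 1.5)
    expect_equal(inverseHill(cv, hillResponse(cv, d)), d, tolerance = 1e-9)
  }
})

test_that("single-agent series come from the zero-dose row and column", {
  ce <- tinyExperiment() # [[100, 60], [70, 50]], rows = dose_b
  s <- extractSingleAgents(ce)
  expect_equal(unname(s$a$response), c(100, 60))
  expect_equal(unname(s$b$response), c(100, 70))
  # replicate mean
  ce2 <- CombinationExperiment(c(0, 1), c(0, 1), list(
    matrix(c(100, 70, 60, 50), 2, 2), matrix(c(100, 74, 64, 50), 2, 2)
  ))
  expect_equal(unname(extractSingleAgents(ce2)$a$response), c(100, 62))
  # permuted input yields identical series
  ce3 <- CombinationExperiment(c(1, 0), c(0, 1),
    matrix(c(100, 70, 60, 50), 2, 2)[, 2:1]
  )
  expect_equal(extractSingleAgents(ce3)$a$response, s$a$response)
})

test_that("fitHill recovers noise-free parameters to high precision", {
  d <- c(0, 10^seq(-2, 2, length.out = 8))
  truth <- HillCurve(10, 1, 1.5)
  f <- fitHill(d, hillResponse(truth, d))
  expect_equal(f@eInf, 10, tolerance = 1e-4)
  expect_equal(f@ec50, 1, tolerance = 1e-4)
  expect_equal(f@h, 1.5, tolerance = 1e-4)
  expect_false(f@inactive)
  expect_lt(f@diagnostics$rmse, 1e-5)
  set.seed(3)
  for (k in 1:10) {
    cv <- randomCurve()
    f <- fitHill(d, hillResponse(cv, d))
    expect_lt(abs(f@eInf - cv@eInf) / max(abs(cv@eInf), 1), 1e-3)
    expect_lt(abs(f@ec50 - cv@ec50) / cv@ec50, 1e-3)
    expect_lt(abs(f@h - cv@h) / cv@h, 1e-3)
  }
})

test_that("fitHill is invariant to replicate and dose ordering", {
  d <- c(0, 10^seq(-1.5, 1.5, length.out = 7))
  set.seed(4)
  reps <- matrix(rep(hillResponse(HillCurve(5, 2, 1.2), d), each = 3), 3) +
    rnorm(3 * length(d), sd = 2)
  f1 <- fitHill(d, reps)
  f2 <- fitHill(d, reps[3:1, ])
  perm <- sample(length(d))
  f3 <- fitHill(d[perm], reps[, perm])
  expect_equal(f1@ec50, f2@ec50, tolerance = 1e-9)
  expect_equal(f1@ec50, f3@ec50, tolerance = 1e-9)
  expect_equal(f1@h, f3@h, tolerance = 1e-9)
})

test_that("flat responses flag an inactive agent", {
  d <- c(0, 10^seq(-1, 2, length.out = 6))
  f <- fitHill(d, rep(100, length(d)))
  expect_true(f@inactive)
  expect_gt(f@eInf, 95) # pinned near the baseline
})

test_that("fitHill refuses underdetermined designs", {
  expect_error(fitHill(c(0, 1, 2), c(100, 80, 60)), "3 distinct positive")
  expect_error(fitHill(c(0, 1, 1, 2), c(100, 80, 81, 60)), "3 distinct")
})

test_that("noisy ec50 recovery stays within the noise-scaled tolerance", {
  d <- c(0, 10^seq(-2, 2, length.out = 8))
  set.seed(5)
  errs <- replicate(30, {
    cv <- randomCurve()
    reps <- matrix(rep(hillResponse(cv, d), each = 3), 3) +
      rnorm(3 * length(d), sd = 2)
    abs(fitHill(d, reps)@ec50 - cv@ec50) / cv@ec50
  })
  expect_lt(median(errs), 0.15)
})
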