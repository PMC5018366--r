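test_that("Bliss surface is the product of surviving fractions", {
  # doses chosen so the curves hit the worked single-agent effects exactly
  ca <- HillCurve(0, 1, 1)
  cb <- HillCurve(0, 1, 1)
  g <- c(0, 1)
  ref <- blissSurface(ca, cb, g, g)
  expect_equal(surfaceValues(ref)[2, 2], 25) # 0.5 * 0.5 * 100
  # independence with a null agent: E_A = 100 leaves E_B unchanged
  inert <- HillCurve(100, 1, 1)
  ref2 <- blissSurface(inert, cb, g, g)
  expect_equal(surfaceValues(ref2)[2, 2], hillResponse(cb, 1))
  # E_A = 80, E_B = 30 -> 24
  ca3 <- HillCurve(0, 4, 1) # E(1) = 100/(1 + 1/4) = 80
  cb3 <- HillCurve(0, 1 / 7, 1) # E(1) = 100/(1 + 7) = 12.5 -> use dose for 30
  d30 <- inverseHill(cb3, 30)
  ref3 <- blissSurface(ca3, cb3, c(0, 1), c(0, d30))
  expect_equal(surfaceValues(ref3)[2, 2], 24)
})

test_that("Bliss clamps out-of-range fractions and flags them", {
  ca <- HillCurve(-20, 0.01, 4) # deep asymptote: E < 0 at high dose
  cb <- HillCurve(0, 1, 1)
  g <- c(0, 100)
  expect_lt(hillResponse(ca, 100), 0)
  ref <- blissSurface(ca, cb, g, g)
  expect_gte(min(interiorValues(ref)), 0)
  expect_equal(solverFlags(ref)[2, 2], "clamped")
})

test_that("HSA surface is the stronger single-agent effect", {
  ca <- HillCurve(0, 1, 1)
  cb <- HillCurve(40, 2, 2)
  g <- c(0, 0.5, 1, 4)
  ref <- hsaSurface(ca, cb, g, g)
  ea <- hillResponse(ca, g)
  eb <- hillResponse(cb, g)
  expect_equal(surfaceValues(ref), outer(eb, ea, pmin),
    ignore_attr = TRUE
  )
})

test_that("all three surfaces equal the single-agent curves on the axes", {
  set.seed(10)
  for (k in 1:5) {
    ca <- randomCurve()
    cb <- randomCurve()
    g <- logGrid()
    for (m in c("LOEWE", "BLISS", "HSA")) {
      ref <- referenceSurface(m, ca, cb, g, g)
      v <- surfaceValues(ref)
      expect_identical(unname(v[1, ]), hillResponse(ca, g))
      expect_identical(unname(v[, 1]), hillResponse(cb, g))
      expect_identical(v[1, 1], 100)
    }
  }
})

test_that("Loewe scores a sham combination as exactly additive", {
  hc <- HillCurve(0, 1, 1)
  g <- c(0, 1)
  ref <- loeweSurface(hc, hc, g, g)
  expect_equal(surfaceValues(ref)[2, 2], hillResponse(hc, 2),
    tolerance = 1e-8
  ) # 33.333...: curve at the summed dose
  set.seed(11)
  for (k in 1:10) {
    cv <- randomCurve()
    g <- logGrid()
    ref <- loeweSurface(cv, cv, g, g)
    expected <- outer(g, g, function(b, a) hillResponse(cv, a + b))
    interior <- outer(g > 0, g > 0, `&`)
    expect_lt(
      max(abs(surfaceValues(ref)[interior] - expected[interior])), 1e-6
    )
  }
})

test_that("Loewe respects dose equivalence between unequal curves", {
  # drug B at dose 2 is equivalent to drug A at dose 1 (double the ec50),
  # so the cell (a = 1, b = 2) behaves like drug A at dose 2
  ca <- HillCurve(0, 1, 1)
  cb <- HillCurve(0, 2, 1)
  ref <- loeweSurface(ca, cb, c(0, 1), c(0, 2))
  expect_equal(surfaceValues(ref)[2, 2], hillResponse(ca, 2),
    tolerance = 1e-7
  )
})

test_that("Loewe bisection agrees with the brute-force effect scan", {
  set.seed(12)
  g <- logGrid()
  for (k in 1:4) {
    ca <- randomCurve()
    cb <- randomCurve()
    ref <- loeweSurface(ca, cb, g, g)
    fl <- solverFlags(ref)
    for (i in c(2, 5, 8)) {
      for (j in c(3, 6, 8)) {
        if (fl[i, j] != "exact") next
        expect_equal(
          surfaceValues(ref)[i, j],
          loeweGridScan(ca, cb, g[j], g[i]),
          tolerance = 1e-5
        )
      }
    }
  }
})

test_that("unreachable Loewe effects are capped without exceeding HSA", {
  ca <- HillCurve(0, 1, 1) # can reach 0
  cb <- HillCurve(60, 1, 1) # cannot go below 60
  g <- c(0, 10^seq(-1, 3, length.out = 7))
  ref <- loeweSurface(ca, cb, g, g)
  fl <- solverFlags(ref)
  v <- surfaceValues(ref)
  # wherever the combination demands an effect below cb's asymptote the
  # solver caps instead of extrapolating the Hill curve
  expect_true(any(fl == "capped"))
  # capped cells sit at the lesser of the boundary and the single-agent
  # responses: here drug A keeps acting below 60, so they track E_A(a)
  capIdx <- which(fl == "capped", arr.ind = TRUE)
  capExp <- pmin(
    60,
    hillResponse(ca, g[capIdx[, 2]]),
    hillResponse(cb, g[capIdx[, 1]])
  )
  expect_equal(unname(v[capIdx]), capExp, tolerance = 1e-6)
  # the whole Loewe surface never exceeds the better single agent (HSA)
  hsa <- surfaceValues(hsaSurface(ca, cb, g, g))
  expect_true(all(v <= hsa + 1e-6))
})

test_that("an inactive agent makes Loewe fall back to the active one", {
  ca <- HillCurve(0, 1, 1)
  flat <- fitHill(logGrid(), rep(100, 8))
  expect_true(flat@inactive)
  g <- logGrid()
  ref <- loeweSurface(ca, flat, g, g)
  fl <- solverFlags(ref)
  expect_true(all(fl[-1, -1] == "fallback_single_agent"))
  expect_equal(unname(surfaceValues(ref)[5, -1]), hillResponse(ca, g[-1]))
})

test_that("Bliss never exceeds HSA and surfaces are monotone", {
  set.seed(13)
  g <- logGrid()
  for (k in 1:10) {
    ca <- randomCurve()
    cb <- randomCurve()
    bl <- surfaceValues(blissSurface(ca, cb, g, g))
    hs <- surfaceValues(hsaSurface(ca, cb, g, g))
    lw <- surfaceValues(loeweSurface(ca, cb, g, g))
    expect_true(all(bl <= hs + 1e-12))
    # tolerance covers the solver's capping margin at near-capped cells
    for (v in list(bl, hs, lw)) {
      expect_true(all(apply(v, 1, diff) <= 1e-7)) # along drug A
      expect_true(all(apply(v, 2, diff) <= 1e-7)) # along drug B
    }
  }
})

test_that("referenceSurface rejects unknown models", {
  hc <- HillCurve(0, 1, 1)
  expect_error(referenceSurface("ZIP", hc, hc, c(0, 1), c(0, 1)), "unknown")
})
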