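test_that("monoisotopic masses of the three reference strands match the printed values", {
  # printed formulas and monoisotopic masses of the proof-of-concept strands
  expect_equal(monoisotopicMass(parseFormula("C266H334N100O162P26")),
               8325.41, tolerance = 0.01 / 8325.41)
  expect_equal(monoisotopicMass(parseFormula("C221H282N82O137P22")),
               6957.18, tolerance = 0.01 / 6957.18)
  expect_equal(monoisotopicMass(parseFormula("C459H582N162O290P46")),
               14426.37, tolerance = 0.01 / 14426.37)
})

test_that("monoisotopic mass is additive and zero for the empty formula", {
  expect_identical(monoisotopicMass(molecularFormula()), 0)
  set.seed(11)
  for (i in 1:20) {
    f1 <- randomFormula(); f2 <- randomFormula()
    expect_equal(monoisotopicMass(f1 + f2),
                 monoisotopicMass(f1) + monoisotopicMass(f2))
  }
  expect_error(monoisotopicMass(molecularFormula(c(Xx = 1))),
               "unknown element")
})

test_that("formula arithmetic guards against negative counts", {
  f <- parseFormula("C2H6O")
  expect_equal(as.character(f - parseFormula("H2O")), "C2H4")
  expect_error(f - parseFormula("N1"), "negative")
  expect_equal(as.character(2 * parseFormula("CH2")), "C2H4")
})

test_that("a single atom's distribution equals its isotope table entries", {
  tab <- isotopeTable()
  cc <- tab[tab$element == "C", ]
  d <- aggregatedDistribution(molecularFormula(c(C = 1)), K = 2)
  expect_equal(probs(d), cc$abundance)
  expect_equal(centerMasses(d), cc$mass_da)
})

test_that("brute-force convolution reproduces closed forms", {
  tab <- isotopeTable()
  h <- tab[tab$element == "H", ]
  d <- bruteForceDistribution(molecularFormula(c(H = 2)), K = 3)
  a <- h$abundance
  expect_equal(probs(d), c(a[1]^2, 2 * a[1] * a[2], a[2]^2))
  # one-element formula: binomial in the heavy-isotope count
  d <- bruteForceDistribution(molecularFormula(c(C = 5)), K = 6)
  a <- tab[tab$element == "C", "abundance"]
  expect_equal(probs(d), dbinom(0:5, 5, a[2]))
  expect_error(bruteForceDistribution(molecularFormula(c(C = 10000))),
               "too large")
})

test_that("recurrence engine agrees with the brute-force oracle on random small formulas", {
  set.seed(101)
  for (i in 1:50) {
    f <- randomFormula()
    K <- sample(4:12, 1)
    da <- aggregatedDistribution(f, K)
    db <- bruteForceDistribution(f, K)
    expect_lt(max(abs(probs(da) - probs(db))), 1e-8)
    keep <- probs(db) > 1e-12        # center masses of vanishing peaks are fills
    expect_lt(max(abs(centerMasses(da)[keep] - centerMasses(db)[keep])), 1e-6)
  }
})

test_that("the vectorized batch kernel matches the single-formula path", {
  comps <- data.frame(A = c(1, 5, 0), C = c(2, 0, 10), G = c(0, 3, 2),
                      T = c(3, 1, 8))
  attr(comps, "chemistry") <- "DNA"
  tab <- suppressWarnings(buildMassTable(comps, K = 12))
  for (i in seq_len(nrow(comps))) {
    f <- formulaFromComposition(unlist(comps[i, ]), terminal = "phosphate")
    d <- aggregatedDistribution(f, K = 12)
    expect_equal(tab$mono[i], monoisotopicMass(f), tolerance = 1e-9)
    mp <- mostAbundantPeak(d)
    expect_identical(as.integer(tab$modeOffset[i]), mp$offset)
    expect_equal(tab$modeMass[i], mp$mass, tolerance = 1e-9)
    expect_equal(tab$am[i], averageMass(d), tolerance = 1e-9)
  }
})

test_that("aggregated peaks are about 1 Da apart and decay beyond the mode for small oligos", {
  f <- formulaFromComposition(c(A = 2, C = 1, G = 1, T = 1),
                              terminal = "phosphate")   # ~1.6 kDa
  d <- aggregatedDistribution(f, K = 15)
  expect_true(all(diff(centerMasses(d)) > 0.99 & diff(centerMasses(d)) < 1.01))
  q <- probs(d)
  m <- which.max(q)
  expect_true(all(diff(q[m:length(q)]) <= 0))
  expect_equal(centerMasses(d)[1], monoisotopicMass(f))
})

test_that("the 5-mer of dC has the monoisotopic peak as its mode", {
  f <- formulaFromComposition(c(C = 5), terminal = "phosphate")
  d <- aggregatedDistribution(f, K = 30)
  expect_identical(mostAbundantPeak(d)$offset, 0L)
})

test_that("at ~7 kDa the mode is no longer the monoisotopic peak", {
  d <- aggregatedDistribution(parseFormula("C221H282N82O137P22"), K = 30)
  mp <- mostAbundantPeak(d)
  expect_gt(mp$offset, 0L)
  expect_gt(mp$mass, 6957.18)
  expect_true(averageMass(d) - mp$mass >= 0.115 &&
              averageMass(d) - mp$mass <= 1.21)
})

test_that("mode ties break toward the lower offset", {
  d <- new("IsotopeDistribution", probs = c(0.4, 0.4, 0.2),
           masses = c(100, 101, 102))
  expect_identical(mostAbundantPeak(d)$offset, 0L)
  expect_identical(mostAbundantPeak(
    new("IsotopeDistribution", probs = c(0.5, 0.3, 0.2),
        masses = c(100, 101, 102)))$offset, 0L)
})

test_that("average mass is the intensity-weighted mean", {
  d1 <- new("IsotopeDistribution", probs = 1, masses = 123.4)
  expect_equal(averageMass(d1), 123.4)
  d2 <- new("IsotopeDistribution", probs = c(0.5, 0.5), masses = c(100, 101))
  expect_equal(averageMass(d2), 100.5)
})

test_that("degenerate isotope-engine inputs are rejected", {
  expect_error(aggregatedDistribution(molecularFormula(c(C = 1)), K = 0),
               "K must be")
  expect_error(aggregatedDistribution(molecularFormula()), "nonzero")
  expect_error(bruteForceDistribution(molecularFormula()), "nonzero")
})
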