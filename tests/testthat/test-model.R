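test_that("the global fit recovers exact lines and rejects degenerate input", {
  x <- seq(10, 100, by = 5)
  tab <- data.frame(modeMass = x, mono = 0.5 + 1.0 * x)
  g <- fitGlobal(tab)
  expect_equal(g$alpha, 0.5)
  expect_equal(g$beta, 1.0)
  two <- data.frame(modeMass = c(1, 3), mono = c(2, 8))
  g2 <- fitGlobal(two)
  expect_equal(g2$alpha + g2$beta * c(1, 3), c(2, 8))
  expect_error(fitGlobal(data.frame(modeMass = c(2, 2), mono = c(1, 5))),
               "degenerate")
  expect_error(fitGlobal(tab[1, ]), "at least 2")
  expect_equal(globalResiduals(tab, g), rep(0, nrow(tab)))
})

test_that("a synthetic two-branch table is recovered exactly", {
  tab <- syntheticTable()
  m <- fitMind(tab)
  ln <- residualLines(m)
  expect_identical(ln$branch, 0:1)
  expect_equal(ln$domainLo, c(0, 40))
  expect_equal(ln$domainHi, c(60, 100))
  # composite predictor is exact where the branch assignment is unambiguous
  xq <- c(5, 20, 35, 70, 90)
  truth <- ifelse(xq < 40, 0.5 + xq + 0.3 - 1e-3 * xq,
                  0.5 + xq - 0.7 - 1e-3 * xq)
  p <- predictMono(m, xq, warn = FALSE)
  expect_equal(p$mono, truth, tolerance = 1e-9)
  expect_identical(p$branch, c(0L, 0L, 0L, 1L, 1L))
  # symmetric overlap with equal member density cuts at the midpoint
  expect_equal(branchCuts(m), 50, tolerance = 0.5)
  expect_equal(unname(p$pError[xq == 5]), 0)
})

test_that("disjoint branch domains cut at the gap midpoint", {
  tab <- syntheticTable(lines = data.frame(branch = 0:1, c = c(0.3, -0.7),
                                           d = c(0, 0), lo = c(0, 60),
                                           hi = c(40, 100)))
  m <- fitMind(tab)
  expect_equal(branchCuts(m), 50)
  cv <- m@curves[[1]]
  expect_identical(cv$propUpper, c(1, 0))
})

test_that("a query exactly at a cut is assigned to the lower interval with 50% error risk", {
  m <- fitMind(syntheticTable())
  cut <- branchCuts(m)[1]
  p <- predictMono(m, cut, warn = FALSE)
  expect_identical(p$branch, 0L)
  expect_equal(p$pError, 0.5, tolerance = 0.05)
  pa <- predictMono(m, cut + 1e-6, warn = FALSE)
  expect_identical(pa$branch, 1L)
})

test_that("out-of-domain queries are flagged but still predicted", {
  m <- fitMind(syntheticTable())
  expect_warning(p <- predictMono(m, 250), "outside the trained")
  expect_false(p$inDomain)
  expect_true(is.finite(p$mono))
})

test_that("model serialization round-trips losslessly and deterministically", {
  m <- smallModel()
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  writeMindModel(m, f1)
  m2 <- readMindModel(f1)
  grid <- seq(modelDomain(m)[1], modelDomain(m)[2], length.out = 200)
  expect_identical(predictMono(m, grid, warn = FALSE),
                   predictMono(m2, grid, warn = FALSE))
  expect_identical(amMaInterval(m2), amMaInterval(m))
  # refit from the same table gives a byte-identical file
  writeMindModel(fitMind(smallTable()), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("corrupt model files are rejected", {
  f <- tempfile(fileext = ".json")
  writeMindModel(smallModel(), f)
  txt <- readLines(f)
  writeLines(txt[1:(length(txt) %/% 2)], f)
  expect_error(readMindModel(f))
  writeLines(sub("oligomind-model-1", "other-schema", txt, fixed = TRUE), f)
  expect_error(readMindModel(f), "schema")
})

test_that("the small-universe model has coherent structure", {
  m <- smallModel()
  ln <- residualLines(m)
  # adjacent residual-line intercepts are about 1 Da apart
  expect_true(all(abs(diff(ln$intercept) + 1) < 0.05))
  # cuts partition the domain: strictly increasing, inside the domain
  expect_true(all(diff(branchCuts(m)) > 0))
  expect_true(all(branchCuts(m) > modelDomain(m)[1] &
                  branchCuts(m) < modelDomain(m)[2]))
  expect_equal(m@beta, 1, tolerance = 0.01)
  expect_true(m@alpha > 0 && m@alpha < 2)
  # within every branch the residuals are collinear: the per-branch fit
  # leaves only sub-mDa scatter
  tab <- smallTable()
  e <- globalResiduals(tab, list(alpha = m@alpha, beta = m@beta))
  b <- detectBranches(tab)
  for (j in ln$branch) {
    i <- b == j
    res <- e[i] - (ln$intercept[match(j, ln$branch)] +
                     ln$slope[match(j, ln$branch)] * tab$modeMass[i])
    expect_lt(stats::sd(res), 0.05)
  }
})

test_that("small shifts of the input shift the prediction one-to-one", {
  # a mispicked most-abundant peak propagates to the predicted mass
  m <- smallModel()
  cuts <- branchCuts(m)
  x0 <- cuts[2] - 500           # comfortably inside one interval
  delta <- 0.2
  p <- predictMono(m, c(x0, x0 + delta), warn = FALSE)
  expect_equal(diff(p$mono), delta * m@beta, tolerance = 1e-3)
})
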