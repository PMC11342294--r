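test_that("envelope construction validates and sorts its peaks", {
  expect_warning(e <- envelope(c(101, 100), c(1, 2)), "sorted")
  expect_equal(e@mass, c(100, 101))
  expect_equal(e@intensity, c(2, 1))
  expect_error(envelope(numeric(), numeric()), "at least one peak")
  expect_error(envelope(c(100, 101), c(1, -1)), "nonnegative")
})

test_that("envelope average mass equals the distribution average mass", {
  expect_equal(averageMass(envelope(123.4, 7)), 123.4)
  expect_equal(averageMass(envelope(c(100, 101, 102), c(1, 1, 1))), 101)
  d <- aggregatedDistribution(parseFormula("C266H334N100O162P26"), K = 30)
  expect_equal(averageMass(asEnvelope(d)), averageMass(d), tolerance = 1e-12)
  expect_error(averageMass(envelope(c(100, 101), c(0, 0))), "zero")
})

test_that("clean theoretical envelopes need no correction", {
  tab <- smallTable()
  set.seed(5)
  for (j in sample(nrow(tab), 10)) {
    f <- formulaFromComposition(unlist(tab[j, c("A", "C", "G", "T")]),
                                terminal = "phosphate")
    d <- aggregatedDistribution(f, K = 30)
    sel <- selectMostAbundant(asEnvelope(d))
    expect_true(sel$ok)
    expect_identical(sel$steps, 0L)
    expect_equal(sel$mass, mostAbundantPeak(d)$mass)
  }
})

test_that("a noise-displaced mode is walked back to the true peak", {
  f <- formulaFromComposition(c(A = 10, C = 10, G = 10, T = 10),
                              terminal = "phosphate")
  d <- aggregatedDistribution(f, K = 30)
  q <- probs(d)
  j <- which.max(q)
  # dent the true mode by 10% so a neighbor wins the naive argmax
  q2 <- q; q2[j] <- q2[j] * 0.9
  e <- envelope(centerMasses(d), q2)
  expect_false(which.max(q2) == j)
  sel <- selectMostAbundant(e)
  expect_true(sel$ok)
  expect_identical(sel$index, j)
  expect_gt(sel$steps, 0L)
  # idempotence: selection from an already-correct start stays put
  again <- selectMostAbundant(e)
  expect_identical(again$index, sel$index)
})

test_that("a mixture of two envelopes whose average falls in the gap is uncorrectable", {
  # two short envelopes separated by a gap; the combined average mass sits
  # between them, so no peak's AM-candidate difference lands in the interval
  mix <- envelope(c(100, 101, 102, 105, 106, 107),
                  c(1, 2, 1.5, 1.5, 2, 1))
  expect_equal(averageMass(mix), 103.5)
  expect_warning(sel <- selectMostAbundant(mix, c(0.115, 1.21)),
                 "uncorrectable")
  expect_false(sel$ok)
  expect_true(is.na(sel$mass))
})

test_that("the correction walk is bounded", {
  e <- envelope(c(100, 101, 102), c(1, 2, 1))
  # impossible interval far from any AM - candidate difference
  expect_warning(sel <- selectMostAbundant(e, c(50, 60)), "uncorrectable")
  expect_lte(sel$steps, 2L * 3L)
})

test_that("envelope files round-trip losslessly", {
  tab <- smallTable()
  set.seed(9)
  idx <- sample(nrow(tab), 75)
  envs <- lapply(idx, function(j) {
    f <- formulaFromComposition(unlist(tab[j, c("A", "C", "G", "T")]),
                                terminal = "phosphate")
    noisyEnvelope(aggregatedDistribution(f, K = 30), width = 0.1)
  })
  names(envs) <- paste0("scan", seq_along(envs))
  for (ext in c(".tsv", ".csv")) {
    path <- tempfile(fileext = ext)
    writeEnvelopes(path, envs)
    back <- readEnvelopes(path)
    expect_length(back, 75)
    expect_identical(names(back), names(envs))
    expect_equal(back[["scan40"]]@mass, envs[["scan40"]]@mass,
                 tolerance = 1e-12)
    expect_equal(back[["scan40"]]@intensity, envs[["scan40"]]@intensity,
                 tolerance = 1e-12)
  }
})

test_that("envelope reading reports malformed and unsorted input", {
  p <- tempfile(fileext = ".tsv")
  writeLines("envelope_id\tneutral_mass\tintensity", p)
  expect_length(readEnvelopes(p), 0)
  writeLines(c("envelope_id\tneutral_mass\tintensity",
               "a\t100.0\t1", "a\tnot-a-number\t2"), p)
  expect_error(readEnvelopes(p), "line")
  writeLines(c("envelope_id\tneutral_mass\tintensity",
               "a\t101.0\t1", "a\t100.0\t2"), p)
  expect_warning(e <- readEnvelopes(p), "sorted")
  expect_equal(e[["a"]]@mass, c(100, 101))
})

test_that("batch annotation predicts clean envelopes correctly", {
  m <- smallModel()
  tab <- smallTable()
  set.seed(3)
  idx <- sample(which(tab$mono > 3000), 5)
  envs <- lapply(idx, function(j) {
    f <- formulaFromComposition(unlist(tab[j, c("A", "C", "G", "T")]),
                                terminal = "phosphate")
    asEnvelope(aggregatedDistribution(f, K = 30))
  })
  names(envs) <- paste0("e", idx)
  ann <- annotateEnvelopes(m, envs)
  expect_identical(nrow(ann), 5L)
  expect_true(all(ann$flag == ""))
  # most envelopes predict within 0.5 Da; allow overlap-zone off-by-ones
  expect_gt(mean(abs(ann$mono - tab$mono[idx]) < 0.5), 0.5)
})
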