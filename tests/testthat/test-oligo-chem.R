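test_that("the three reference sequences give the printed formulas", {
  expect_identical(
    as.character(formulaFromSequence("GCC ACA TAT GAG AGT GGA TTT GTC ATT")),
    "C266H334N100O162P26")
  expect_identical(
    as.character(formulaFromSequence("GGT GCC CCA GAA TCT CTC AGC CT")),
    "C221H282N82O137P22")
  expect_identical(
    as.character(formulaFromSequence(
      "GAG ATC TCT GCT TCT GAT GGC TCT CTG GTT ACT GCC AGT TGA ATC TG")),
    "C459H582N162O290P46")
})

test_that("sequence parsing is case-insensitive and rejects bad input", {
  expect_identical(as.character(formulaFromSequence("acgt")),
                   as.character(formulaFromSequence("ACGT")))
  expect_error(formulaFromSequence(""), "empty")
  expect_error(formulaFromSequence("ACGU", chemistry = "DNA"), "invalid")
  expect_error(formulaFromSequence("ACGT", chemistry = "RNA"), "invalid")
  expect_error(formulaFromComposition(c(A = 0)), "at least one base")
})

test_that("a single nucleoside has no linkage terms", {
  expect_identical(as.character(formulaFromComposition(c(A = 1))),
                   "C10H13N5O3")
})

test_that("terminal conventions differ by exactly one HPO3", {
  fOH <- formulaFromComposition(c(C = 5), terminal = "OH")
  fP <- formulaFromComposition(c(C = 5), terminal = "phosphate")
  expect_identical(as.character(fP - fOH), "HO3P")
  expect_equal(monoisotopicMass(fP), 1463.24, tolerance = 0.01 / 1463.24)
})

test_that("RNA chemistry adds one oxygen per residue and swaps T for U", {
  fd <- formulaFromComposition(c(A = 2, C = 1, G = 1, T = 1), "DNA")
  fr <- formulaFromComposition(c(A = 2, C = 1, G = 1, U = 1), "RNA")
  d <- elementCounts(fr) - elementCounts(fd)[names(elementCounts(fr))]
  # 5 extra O (one per sugar) and one T->U means one CH2 fewer
  expect_equal(d[["O"]], 5L)
  expect_equal(d[["C"]], -1L)
  expect_equal(d[["H"]], -2L)
})

test_that("poly-dC and poly-dG bound the mass of fixed-length DNA oligos", {
  comp <- enumerateCompositions(8, 8)
  tab <- suppressWarnings(buildMassTable(comp, K = 5))
  expect_identical(unlist(comp[which.min(tab$mono), ]),
                   c(A = 0L, C = 8L, G = 0L, T = 0L))
  expect_identical(unlist(comp[which.max(tab$mono), ]),
                   c(A = 0L, C = 0L, G = 8L, T = 0L))
})

test_that("the modification registry reproduces the study deltas", {
  reg <- modificationRegistry()
  expect_true(all(c("table3", "impurity") %in% reg$scope))
  f <- formulaFromSequence("ACGTACGT")
  expect_identical(as.character(applyModification(f, "methylation", 2)),
                   as.character(f + parseFormula("C2H4")))
  fs <- applyModification(f, "o_to_s", 1)
  d <- elementCounts(fs)
  expect_equal(d[["S"]], 1L)
  expect_equal(d[["O"]], elementCounts(f)[["O"]] - 1L)
  ff <- applyModification(f, "fluoride", 1)
  expect_equal(elementCounts(ff)[["F"]], 1L)
  expect_equal(monoisotopicMass(applyModification(f, "na_adduct", 1)) -
                 monoisotopicMass(f), 22.98977 - 1.00783, tolerance = 1e-4)
})

test_that("inapplicable modifications signal a classed condition", {
  f3g <- formulaFromSequence("GGGTTT")
  expect_error(applyModification(f3g, "guanine_depurination", times = 4,
                                 composition = c(G = 3, T = 3)),
               class = "oligomind_inapplicable")
  # formula-level guard: stripping more nitrogen than present
  tiny <- formulaFromSequence("TTTTT")
  expect_error(applyModification(tiny, "guanine_depurination", times = 5),
               class = "oligomind_inapplicable")
  expect_error(applyModification(f3g, "methylation", times = 0), "at least 1")
})

test_that("sequences read from FASTA and plain text", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">probe 1", "ACGT", "ACGT", ">probe 2", "GGTT"), fa)
  s <- readSequences(fa)
  expect_identical(unname(s), c("ACGTACGT", "GGTT"))
  expect_identical(names(s), c("probe 1", "probe 2"))
  txt <- tempfile(fileext = ".txt")
  writeLines(c("ACGT", "GGTT"), txt)
  expect_identical(unname(readSequences(txt)), c("ACGT", "GGTT"))
})
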