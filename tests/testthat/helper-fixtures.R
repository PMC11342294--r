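# shared fixtures, built lazily and cached for the whole test run

.fixtures <- new.env(parent = emptyenv())

# small DNA universe (lengths 5-30) and a model fitted on it: large enough
# to have several residual branches and overlaps, small enough to build in
# about a second
smallTable <- function() {
  if (is.null(.fixtures$smallTab)) {
    comp <- enumerateCompositions(5, 30)
    .fixtures$smallTab <- suppressWarnings(buildMassTable(comp))
  }
  .fixtures$smallTab
}

smallModel <- function() {
  if (is.null(.fixtures$smallModel))
    .fixtures$smallModel <- fitMind(smallTable())
  .fixtures$smallModel
}

# full enumerated DNA universe (lengths 5-92) and the training/validation
# split and fitted model used by the acceptance checks; built once
dnaTable <- function() {
  if (is.null(.fixtures$dnaTab)) {
    comp <- enumerateCompositions(5, 92)
    .fixtures$dnaTab <- suppressWarnings(buildMassTable(comp))
  }
  .fixtures$dnaTab
}

dnaSplit <- function() {
  if (is.null(.fixtures$dnaSplit))
    .fixtures$dnaSplit <- splitMassTable(dnaTable(), 10000L, seed = 42)
  .fixtures$dnaSplit
}

dnaModel <- function() {
  if (is.null(.fixtures$dnaModel))
    .fixtures$dnaModel <- fitMind(dnaSplit()$training)
  .fixtures$dnaModel
}

# random small molecular formula for oracle-equivalence properties
randomFormula <- function(maxAtoms = 60) {
  els <- c("C", "H", "N", "O", "P", "S")
  n <- sample(2:4, 1)
  pick <- sample(els, n)
  cnt <- sapply(pick, function(e) sample.int(maxAtoms %/% n, 1))
  molecularFormula(cnt)
}

# synthetic mass table with known piecewise-linear structure:
# branch b has residual e = c_b + d_b * x over its domain
syntheticTable <- function(alpha = 0.5, beta = 1.0,
                           lines = data.frame(branch = 0:1,
                                              c = c(0.3, -0.7),
                                              d = c(-1e-3, -1e-3),
                                              lo = c(0, 40), hi = c(60, 100)),
                           perBranch = 200) {
  rows <- lapply(seq_len(nrow(lines)), function(i) {
    x <- seq(lines$lo[i], lines$hi[i], length.out = perBranch)
    e <- lines$c[i] + lines$d[i] * x
    data.frame(modeMass = x, mono = alpha + beta * x + e,
               modeOffset = lines$branch[i],
               am = alpha + beta * x)   # placeholder, unused by the fit
  })
  out <- do.call(rbind, rows)
  attr(out, "chemistry") <- "DNA"
  attr(out, "k") <- 30L
  out
}
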