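#' Global linear model of monoisotopic mass on most-abundant mass
#'
#' Ordinary least squares fit of `mono ~ modeMass` over a mass table,
#' computed in closed form on centered variables.
#'
#' @param table Mass table with columns `mono` and `modeMass`.
#' @return List with elements `alpha` (intercept, Da) and `beta` (slope).
#' @export
fitGlobal <- function(table) {
  x <- table$modeMass; y <- table$mono
  if (length(x) < 2L) stop("need at least 2 records")
  xm <- mean(x); ym <- mean(y)
  sxx <- sum((x - xm)^2)
  if (sxx == 0) stop("degenerate design: all most-abundant masses equal")
  beta <- sum((x - xm) * (y - ym)) / sxx
  list(alpha = ym - beta * xm, beta = beta)
}

#' Residuals of the global linear model
#' @param table Mass table.
#' @param fit List from [fitGlobal()].
#' @return Numeric vector `e = mono - (alpha + beta * modeMass)`.
#' @export
globalResiduals <- function(table, fit)
  table$mono - (fit$alpha + fit$beta * table$modeMass)

#' Branch labels of a mass table
#'
#' The residuals of the global model fall on distinct straight lines, one
#' per integer offset between the most-abundant and the monoisotopic
#' aggregated peak; the branch label is that offset.
#'
#' @param table Mass table with a `modeOffset` column.
#' @return Integer vector of branch labels.
#' @export
detectBranches <- function(table) as.integer(table$modeOffset)

#' Per-branch residual lines
#'
#' Fits, separately for each branch, an ordinary least squares line of the
#' global-model residuals on the most-abundant mass, and records the mass
#' domain (min/max most-abundant mass) of the branch.
#'
#' @param table Mass table.
#' @param e Residual vector from [globalResiduals()].
#' @param branch Branch labels from [detectBranches()].
#' @return data.frame with columns `branch`, `intercept`, `slope`,
#'   `domainLo`, `domainHi`, `n`, ordered by branch.
#' @export
fitResidualLines <- function(table, e, branch = detectBranches(table)) {
  x <- table$modeMass
  xm <- mean(x); em <- mean(e)          # center for numerical stability
  xc <- x - xm; ec <- e - em
  f <- factor(branch)
  n <- as.vector(table(f))
  if (any(n < 2L))
    stop("branch(es) with fewer than 2 records: ",
         paste(levels(f)[n < 2L], collapse = ", "))
  sx <- as.vector(rowsum(xc, f)); se <- as.vector(rowsum(ec, f))
  sxx <- as.vector(rowsum(xc * xc, f)); sxe <- as.vector(rowsum(xc * ec, f))
  slope <- (sxe - sx * se / n) / (sxx - sx^2 / n)
  # centered model: e - em = interceptC + slope * (x - xm)
  interceptC <- se / n - slope * sx / n
  intercept <- em + interceptC - slope * xm
  dom <- vapply(split(x, f), range, numeric(2))
  out <- data.frame(branch = as.integer(levels(f)),
                    intercept = intercept, slope = slope,
                    domainLo = dom[1, ], domainHi = dom[2, ], n = n)
  rownames(out) <- NULL
  out[order(out$branch), , drop = FALSE]
}

#' Optimal-Bayes branch boundaries by sliding-window proportions
#'
#' For each pair of adjacent branches, slides a window of width `window`
#' Da in steps of `step` Da across the region where the two branch
#' domains overlap, computes at each grid point the proportion of
#' molecules belonging to the lower-offset ("upper") residual line among
#' the members of the two branches inside the window, and places the cut
#' mass where the interpolated proportion crosses 50%. Outside the
#' overlap regions the proportions are 0 or 1. Disjoint adjacent domains
#' get the midpoint of the gap; an overlap narrower than one step falls
#' back to its midpoint (with a message).
#'
#' @param table Mass table.
#' @param branch Branch labels.
#' @param window Sliding window width in Da (default 50).
#' @param step Grid step in Da (default 10).
#' @return List with `cuts` (numeric, one per adjacent pair) and `curves`
#'   (list of data.frames `mass`, `propUpper`).
#' @export
computeBoundaries <- function(table, branch = detectBranches(table),
                              window = 50, step = 10) {
  x <- table$modeMass
  labs <- sort(unique(branch))
  half <- window / 2
  cuts <- numeric(length(labs) - 1L)
  curves <- vector("list", length(labs) - 1L)
  for (i in seq_len(length(labs) - 1L)) {
    xu <- sort(x[branch == labs[i]])        # upper line (lower offset)
    xd <- sort(x[branch == labs[i + 1L]])   # lower line (next offset)
    lo <- xd[1]; hi <- xu[length(xu)]
    if (lo > hi) {                          # disjoint domains: gap midpoint
      cuts[i] <- (lo + hi) / 2
      curves[[i]] <- data.frame(mass = c(hi, lo), propUpper = c(1, 0))
      next
    }
    grid <- seq(lo, hi, by = step)
    if (grid[length(grid)] < hi) grid <- c(grid, hi)
    if (length(grid) < 2L) {                # narrower than one step
      message("overlap of branches ", labs[i], "/", labs[i + 1L],
              " narrower than one step; using its midpoint")
      cuts[i] <- (lo + hi) / 2
      curves[[i]] <- data.frame(mass = c(lo, hi), propUpper = c(1, 0))
      next
    }
    nUp <- findInterval(grid + half, xu) - findInterval(grid - half, xu)
    nDn <- findInterval(grid + half, xd) - findInterval(grid - half, xd)
    prop <- nUp / (nUp + nDn)
    ok <- is.finite(prop)
    grid <- grid[ok]; prop <- prop[ok]
    cross <- which(prop[-length(prop)] >= 0.5 & prop[-1] < 0.5)
    if (length(cross)) {                    # first crossing if several
      j <- cross[1]
      cuts[i] <- grid[j] + (prop[j] - 0.5) / (prop[j] - prop[j + 1L]) *
        (grid[j + 1L] - grid[j])
    } else cuts[i] <- if (all(prop < 0.5)) lo else hi
    curves[[i]] <- data.frame(mass = grid, propUpper = prop)
  }
  names(curves) <- paste(labs[-length(labs)], labs[-1], sep = "-")
  list(cuts = cuts, curves = curves)
}

#' Fit the two-stage monoisotopic-mass predictor
#'
#' Fits the global linear model, labels the residual branches by
#' most-abundant peak offset, fits one residual line per branch, computes
#' the optimal-Bayes cut masses between adjacent branches, and records the
#' empirical interval of (average mass - most-abundant mass) used by the
#' peak-selection correction.
#'
#' @param table Training mass table from [buildMassTable()].
#' @param window,step Sliding-window parameters in Da (defaults 50 and 10).
#' @return A [MindModel-class].
#' @export
fitMind <- function(table, window = 50, step = 10) {
  chemistry <- attr(table, "chemistry"); if (is.null(chemistry)) chemistry <- "DNA"
  k <- attr(table, "k"); if (is.null(k)) k <- 30L
  g <- fitGlobal(table)
  e <- globalResiduals(table, g)
  branch <- detectBranches(table)
  lines <- fitResidualLines(table, e, branch)
  bd <- computeBoundaries(table, branch, window = window, step = step)
  amMa <- range(table$am - table$modeMass)
  new("MindModel", chemistry = chemistry, alpha = g$alpha, beta = g$beta,
      lines = lines, cuts = bd$cuts, curves = bd$curves, amMa = amMa,
      k = as.integer(k),
      provenance = list(nTraining = nrow(table),
                        terminal = attr(table, "terminal"),
                        isotopeTable = attr(isotopeTable(), "version"),
                        window = window, step = step,
                        package = as.character(utils::packageVersion("oligomind"))))
}

#' Predict monoisotopic mass from most-abundant mass
#'
#' Evaluates the two-stage predictor: the global linear model plus the
#' residual line of the branch selected by the cut-mass partition. The
#' partition is lower-open/upper-closed, so a query exactly at a cut mass
#' is assigned to the lower interval. The off-by-one error probability is
#' one minus the (interpolated) sliding-window proportion of the assigned
#' line at the query mass; it is 0 outside overlap regions.
#'
#' @param model A [MindModel-class].
#' @param mostAbundantMass Numeric vector of neutral most-abundant masses
#'   (Da).
#' @param warn Warn when queries fall outside the trained mass domain
#'   (default TRUE); predictions are still returned, flagged
#'   `inDomain = FALSE`.
#' @return data.frame with columns `mostAbundantMass`, `branch`, `mono`,
#'   `pError`, `inDomain`.
#' @examples
#' \dontrun{
#' predictMono(model, 6963.19)
#' }
#' @export
predictMono <- function(model, mostAbundantMass, warn = TRUE) {
  stopifnot(is(model, "MindModel"))
  ma <- as.numeric(mostAbundantMass)
  if (any(!is.finite(ma))) stop("most-abundant masses must be finite")
  ln <- model@lines
  bi <- findInterval(ma, model@cuts, left.open = TRUE) + 1L
  pred <- model@alpha + model@beta * ma + ln$intercept[bi] + ln$slope[bi] * ma
  dom <- c(min(ln$domainLo), max(ln$domainHi))
  inDomain <- ma >= dom[1] & ma <= dom[2]
  if (warn && any(!inDomain))
    warning(sum(!inDomain), " quer", if (sum(!inDomain) == 1) "y" else "ies",
            " outside the trained mass domain [",
            round(dom[1], 2), ", ", round(dom[2], 2), "] Da; ",
            "extrapolated predictions are unreliable")
  pErr <- numeric(length(ma))
  for (i in seq_along(model@curves)) {
    cv <- model@curves[[i]]
    rng <- range(cv$mass)
    # pair i: upper line = branch row i, lower line = branch row i + 1
    sel <- bi == i & ma >= rng[1] & ma <= rng[2]
    if (any(sel)) {
      p <- approx(cv$mass, cv$propUpper, xout = ma[sel])$y
      pErr[sel] <- pmax(pErr[sel], 1 - p)
    }
    sel <- bi == i + 1L & ma >= rng[1] & ma <= rng[2]
    if (any(sel)) {
      p <- approx(cv$mass, cv$propUpper, xout = ma[sel])$y
      pErr[sel] <- pmax(pErr[sel], p)
    }
  }
  data.frame(mostAbundantMass = ma, branch = ln$branch[bi], mono = pred,
             pError = pmin(pmax(pErr, 0), 1), inDomain = inDomain)
}

#' @describeIn predictMono `predict` method for fitted models;
#'   `newdata` is the vector of most-abundant masses.
#' @param object A [MindModel-class].
#' @param newdata Numeric vector of most-abundant masses (Da).
#' @param ... Passed on to `predictMono`.
#' @export
setMethod("predict", "MindModel",
          function(object, newdata, ...) predictMono(object, newdata, ...))

#' Trained mass domain of a model
#' @param model A [MindModel-class].
#' @return Length-2 numeric: the most-abundant mass range seen in training.
#' @export
modelDomain <- function(model)
  c(min(model@lines$domainLo), max(model@lines$domainHi))

#' AM-MA interval of a model
#' @param model A [MindModel-class].
#' @return Length-2 numeric: empirical range of (average mass -
#'   most-abundant mass) over the training universe.
#' @export
amMaInterval <- function(model) model@amMa

#' Residual lines of a model
#' @param model A [MindModel-class].
#' @return data.frame of per-branch lines.
#' @export
residualLines <- function(model) model@lines

#' Cut masses of a model
#' @param model A [MindModel-class].
#' @return Numeric vector of interior cut masses (Da).
#' @export
branchCuts <- function(model) model@cuts

setMethod("show", "MindModel", function(object) {
  cat("MindModel (", object@chemistry, ", K = ", object@k, ")\n", sep = "")
  cat("  global fit: mono =", format(object@alpha, digits = 6), "+",
      format(object@beta, digits = 8), "x mostAbundant\n")
  cat("  ", nrow(object@lines), " residual branches, ",
      length(object@cuts), " cuts\n", sep = "")
  dom <- modelDomain(object)
  cat("  domain: [", round(dom[1], 2), ", ", round(dom[2], 2), "] Da\n",
      sep = "")
  cat("  AM-MA interval: [", round(object@amMa[1], 4), ", ",
      round(object@amMa[2], 4), "] Da\n", sep = "")
})
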