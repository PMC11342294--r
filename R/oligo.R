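#' @name oligoChemistry
#' @title Oligonucleotide chemistry
#'
#' @description Translation of base compositions and sequences into
#' molecular formulas. A linear oligonucleotide of length n is assembled
#' from nucleosides joined by n-1 phosphodiester links, each link adding
#' HPO3 and removing H2O. Two terminal conventions are supported:
#' `terminal = "OH"` (5'-OH/3'-OH, n-1 phosphate groups - the usual state
#' of synthesized and measured oligonucleotides) and
#' `terminal = "phosphate"` (one additional terminal phosphate, n
#' phosphate groups in total - the nucleotide-monophosphate polymer
#' convention used for the enumerated training universe, whose lightest
#' member, the dC 5-mer, then has monoisotopic mass 1463.24 Da).
#' DNA uses 2'-deoxyribose and thymine; RNA uses ribose and uracil.
NULL

# nucleoside elemental compositions, elements C,H,N,O
.NUCLEOSIDES <- list(
  DNA = list(A = c(C = 10, H = 13, N = 5, O = 3),
             C = c(C = 9,  H = 13, N = 3, O = 4),
             G = c(C = 10, H = 13, N = 5, O = 4),
             T = c(C = 10, H = 14, N = 2, O = 5)),
  RNA = list(A = c(C = 10, H = 13, N = 5, O = 4),
             C = c(C = 9,  H = 13, N = 3, O = 5),
             G = c(C = 10, H = 13, N = 5, O = 5),
             U = c(C = 9,  H = 12, N = 2, O = 6))
)

.H2O  <- c(C = 0, H = 2, N = 0, O = 1)
.HPO3 <- c(C = 0, H = 1, N = 0, O = 3)  # plus one P, handled separately

.baseLetters <- function(chemistry)
  if (chemistry == "DNA") c("A", "C", "G", "T") else c("A", "C", "G", "U")

# Element-count matrix (columns C,H,N,O,P) for a base-count matrix with
# columns A,C,G,T(or U). Vectorized over rows.
.elementCountsFromBases <- function(bases, chemistry, terminal) {
  nuc <- .NUCLEOSIDES[[chemistry]]
  letters <- .baseLetters(chemistry)
  bases <- as.matrix(bases[, letters, drop = FALSE])
  nucmat <- do.call(rbind, nuc[letters])          # 4 x 4 (C,H,N,O)
  ec <- bases %*% nucmat
  n <- rowSums(bases)
  nP <- n - 1L + (terminal == "phosphate")
  ec <- cbind(ec, P = 0)
  ec[, "H"] <- ec[, "H"] + nP - 2 * (n - 1L)
  ec[, "O"] <- ec[, "O"] + 3 * nP - (n - 1L)
  ec[, "P"] <- nP
  storage.mode(ec) <- "integer"
  ec
}

#' Molecular formula of an oligonucleotide composition
#'
#' @param composition Named vector of base counts: names among A, C, G, T
#'   (DNA) or A, C, G, U (RNA); missing bases count 0.
#' @param chemistry `"DNA"` or `"RNA"`.
#' @param terminal `"OH"` (5'-OH/3'-OH; n-1 phosphates) or `"phosphate"`
#'   (terminal phosphate; n phosphates). See [oligoChemistry].
#' @return A [MolecularFormula-class].
#' @examples
#' # the 23-mer of Table-style composition G5 A4 T5 C9
#' f <- formulaFromComposition(c(A = 4, C = 9, G = 5, T = 5))
#' as.character(f)  # "C221H282N82O137P22"
#' @export
formulaFromComposition <- function(composition, chemistry = c("DNA", "RNA"),
                                   terminal = c("OH", "phosphate")) {
  chemistry <- match.arg(chemistry)
  terminal <- match.arg(terminal)
  letters <- .baseLetters(chemistry)
  bad <- setdiff(names(composition), letters)
  if (length(bad))
    stop("invalid base(s) for ", chemistry, " chemistry: ",
         paste(bad, collapse = ", "))
  cnt <- setNames(integer(4), letters)
  cnt[names(composition)] <- as.integer(composition)
  if (any(cnt < 0L)) stop("base counts must be nonnegative")
  if (sum(cnt) < 1L) stop("composition must contain at least one base")
  ec <- .elementCountsFromBases(t(cnt), chemistry, terminal)
  molecularFormula(ec[1, ])
}

#' Molecular formula of an oligonucleotide sequence
#'
#' Counts the bases of a sequence string (case-insensitive, whitespace
#' ignored) and delegates to [formulaFromComposition()].
#'
#' @param seq Base string over A/C/G/T (DNA) or A/C/G/U (RNA).
#' @inheritParams formulaFromComposition
#' @return A [MolecularFormula-class].
#' @examples
#' formulaFromSequence("GGT GCC CCA GAA TCT CTC AGC CT")
#' @export
formulaFromSequence <- function(seq, chemistry = c("DNA", "RNA"),
                                terminal = c("OH", "phosphate")) {
  chemistry <- match.arg(chemistry)
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(gsub("[[:space:]]", "", seq))
  if (!nzchar(s)) stop("empty sequence")
  ch <- strsplit(s, "")[[1]]
  letters <- .baseLetters(chemistry)
  bad <- unique(ch[!ch %in% letters])
  if (length(bad))
    stop("invalid character(s) in ", chemistry, " sequence: ",
         paste(bad, collapse = ", "))
  formulaFromComposition(table(factor(ch, levels = letters)),
                         chemistry = chemistry, terminal = terminal)
}

#' Read sequences from FASTA or plain text
#'
#' Single- or multi-record FASTA (description lines preserved as names) or
#' one bare sequence per line.
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
readSequences <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(setNames(character(), character()))
  if (startsWith(trimws(lines[1]), ">")) {
    idx <- cumsum(startsWith(trimws(lines), ">"))
    recs <- split(lines, idx)
    seqs <- vapply(recs, function(r) paste(r[-1], collapse = ""), "")
    names(seqs) <- vapply(recs, function(r) sub("^>\\s*", "", trimws(r[1])), "")
    seqs
  } else setNames(lines, paste0("seq", seq_along(lines)))
}

#' Modification registry
#'
#' Built-in registry of formula deltas for common oligonucleotide
#' modifications, degradants and adducts. The `table3` scope carries the
#' chemical/artificial modification set used by the in-silico robustness
#' study (guanine depurination, guanine shortmer, methylation, fluoride,
#' GalNAc conjugation, oxygen-to-sulfur conversion); the `impurity` scope
#' carries standard synthesis impurities and adducts (A/C shortmer,
#' adenine depurination, Na/K adducts). Note the registry's guanine
#' shortmer delta (-C11H14N5O7P) is kept verbatim from its source study
#' even though it differs by CH2O from the standard dG residue
#' (-C10H12N5O6P), which is available as `shortmer_*` in the impurity
#' scope.
#'
#' @param path Optional CSV with columns name, plus, minus, requires_base,
#'   scope; `NULL` uses the packaged registry.
#' @return data.frame, one row per modification.
#' @examples
#' modificationRegistry()
#' @export
modificationRegistry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "modifications.csv", package = "oligomind")
  reg <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character")
  need <- c("name", "plus", "minus", "requires_base", "scope")
  if (!all(need %in% names(reg)))
    stop("modification registry must have columns ",
         paste(need, collapse = ", "))
  reg
}

.getModification <- function(m) {
  if (is.data.frame(m)) return(m[1, , drop = FALSE])
  reg <- modificationRegistry()
  hit <- reg[reg$name == m, , drop = FALSE]
  if (!nrow(hit)) stop("unknown modification: ", m)
  hit[1, , drop = FALSE]
}

# net element-count delta of one application, named numeric (can be < 0)
.modificationDelta <- function(mod) {
  plus <- elementCounts(parseFormula(mod$plus))
  minus <- elementCounts(parseFormula(mod$minus))
  els <- union(names(plus), names(minus))
  d <- setNames(numeric(length(els)), els)
  d[names(plus)] <- plus
  d[names(minus)] <- d[names(minus)] - minus
  d
}

#' Apply a modification to a molecular formula
#'
#' Adds `times` copies of a modification's formula delta. A modification
#' that cannot be applied - because it would drive an element count
#' negative, or because the composition lacks the required base (e.g.
#' depurination of more guanines than are present) - signals a classed
#' error (`oligomind_inapplicable`); such molecules are reported as
#' "missing" by the robustness study rather than predicted.
#'
#' @param f A [MolecularFormula-class].
#' @param modification Registry name (see [modificationRegistry()]) or a
#'   one-row registry data.frame.
#' @param times Number of applications (>= 1).
#' @param composition Optional named base-count vector; if supplied and
#'   the modification requires a base, `composition[base] >= times` is
#'   enforced.
#' @return The modified [MolecularFormula-class].
#' @examples
#' f <- formulaFromSequence("ACGT")
#' as.character(applyModification(f, "methylation", times = 2))
#' @export
applyModification <- function(f, modification, times = 1L,
                              composition = NULL) {
  stopifnot(is(f, "MolecularFormula"))
  times <- as.integer(times)
  if (times < 1L) stop("times must be at least 1")
  mod <- .getModification(modification)
  inapplicable <- function(why)
    stop(structure(class = c("oligomind_inapplicable", "error", "condition"),
                   list(message = paste0("modification '", mod$name,
                                         "' is inapplicable: ", why),
                        call = sys.call(-1))))
  if (nzchar(mod$requires_base) && !is.null(composition)) {
    have <- composition[[mod$requires_base]]
    if (is.null(have) || is.na(have) || have < times)
      inapplicable(paste0("requires ", times, " x base ",
                          mod$requires_base))
  }
  d <- .modificationDelta(mod) * times
  cnt <- elementCounts(f)
  els <- union(names(cnt), names(d))
  full <- setNames(numeric(length(els)), els)
  full[names(cnt)] <- cnt
  full[names(d)] <- full[names(d)] + d
  if (any(full < 0))
    inapplicable(paste0("element count would become negative: ",
                        paste(els[full < 0], collapse = ", ")))
  molecularFormula(full)
}
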