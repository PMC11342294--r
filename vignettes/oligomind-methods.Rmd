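---
title: "Predicting monoisotopic masses of oligonucleotides from the most-abundant isotopic peak"
author: "oligomind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting monoisotopic masses of oligonucleotides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Annotating deconvoluted mass spectra of DNA and RNA oligonucleotides —
therapeutic antisense oligonucleotides, their impurities, degradants and
adducts — requires the monoisotopic mass of each analyte. Beyond roughly
10 kDa the monoisotopic variant of a nucleic acid is usually below the
detection limit: the isotope envelope is wide and the all-light-isotope
species carries a vanishing fraction of the signal. The most-abundant
(mode) peak of the aggregated isotopic distribution, in contrast, is the
easiest feature to read off the spectrum. `oligomind` learns the mapping
from the most-abundant neutral mass back to the monoisotopic mass from an
exhaustively enumerated in-silico universe of oligonucleotide
compositions, and applies it to experimental envelopes.

## The model

Let $M_{\text{mono}}$ be the monoisotopic mass and $M_{\text{MostAb}}$
the center mass of the most-abundant aggregated isotope peak. Over the
enumerated universe the two are almost perfectly linearly related, so the
first stage is an ordinary least squares fit

$$M_{\text{mono}} = \alpha + \beta\, M_{\text{MostAb}} + \varepsilon .$$

On the DNA training universe $\hat\alpha \approx 0.6624$ Da and
$\hat\beta \approx 0.99952$. The residuals $e_i$ are not noise: they fall
on 14 parallel, slightly sloped straight lines, one per integer offset
$j$ between the mode peak and the monoisotopic peak
($j = 0, \dots, 13$ over this universe). Neighbouring lines are spaced by
about 1.003 Da — the average aggregated-peak spacing — which is why a
branch mix-up produces a characteristic "off-by-one" (±1 Da) error. The
second stage therefore fits, per branch, a line
$e = c_j + d_j\,M_{\text{MostAb}}$ by OLS and records the branch's
most-abundant-mass domain $[a_j, b_j]$.

Adjacent branch domains overlap (about 20% of the mass range and 34% of
the molecules over the DNA universe; never more than two branches at one
mass). To decide which branch a query belongs to, the package follows an
optimal-Bayes rule estimated with a sliding window: a 50 Da window moves
in 10 Da steps across each overlap, the proportion of molecules
belonging to the lower-offset branch among the two is recorded at each
grid point, and the cut mass is placed by linear interpolation where the
proportion crosses 50%. The 13 cuts partition the domain into half-open
intervals, lower-open and upper-closed, so a query exactly at a cut
belongs to the lower interval. The full predictor is

$$\hat M_{\text{mono}} = (\hat\alpha + \hat\beta\,M) + (c_j + d_j\,M),
\qquad j \text{ chosen by the cut partition},$$

and each prediction carries an off-by-one error probability: one minus
the interpolated sliding-window proportion of the assigned branch at the
query mass (zero outside overlaps, 0.5 exactly at a cut).

## The training universe

`enumerateCompositions(5, 92)` produces every multiset of the four bases
with length 5–92: 3,321,890 DNA compositions. Unlike peptides, base
*combinations* (not permutations) already determine the elemental
composition, so every record has a distinct mass. Formulas are assembled
as nucleoside monophosphate polymers: $n$ nucleotides joined by $n-1$
phosphodiester links, each link removing one water — equivalently a
5′-phosphate terminus, $n$ phosphate groups in total. Under this
convention the universe spans 1463.242 Da (the dC 5-mer) to 30,290.84 Da
(the dG 92-mer); the most-abundant-mass input domain extends to
30,303.87 Da. Synthesized and measured oligonucleotides are usually
5′-OH/3′-OH, which is the default of `formulaFromSequence()` (a 23-mer
then has 22 phosphates); the mapping from most-abundant to monoisotopic
mass is insensitive to which convention a query molecule uses, because
the predictor only sees its most-abundant mass.

Aggregated isotope distributions (the first $K = 30$ peaks: probabilities
and intensity-weighted exact center masses) are computed from the
elemental composition with power-sum recurrences: the series logarithm of
the isotope-pattern generating polynomial is linear in the element
counts, so per-element coefficient tables are precomputed once and the
per-molecule work is a short exponentiation recurrence — the whole
universe is evaluated in seconds by a small C++ kernel. A brute-force
convolution oracle (`bruteForceDistribution()`) verifies the engine to
1e-8 in probability and 1e-6 Da in center mass on small formulas in the
test suite. The 30-peak truncation retains at least 99.9% of the
probability mass everywhere (99.955% for the heaviest, ~30 kDa
molecules, whose expected nucleon shift is ≈ 13.3).

Isotope masses and abundances are pinned in an editable, versioned CSV
(`inst/extdata/isotopes.csv`). The packaged values are the classic
NIST/IUPAC numbers conventionally used by isotope-pattern calculators.
The sulfur abundances matter only for phosphorothioate-style studies;
the DNA/RNA results are driven by C, H, N, O, P.

## Most-abundant peak selection correction

Noise, poor ion statistics and wide envelopes can displace the raw
argmax of an experimental envelope by ±1 Da or more, and any error on
the model input propagates one-to-one to the prediction. The correction
exploits a stable envelope statistic: over the whole enumerated
universe, the intensity-weighted average mass minus the true
most-abundant mass lies in the interval $[0.115, 1.210]$ Da. Presented
with an envelope, the package computes the experimental average mass AM
over the full peak list, starts from the most intense peak and walks:
if AM − candidate exceeds the upper bound the candidate is too light
(take the next heavier peak); below the lower bound, too heavy. The walk
stops when the difference enters the interval; it is bounded (at most
two passes, with revisit detection), and an envelope on which no peak
satisfies the interval — typically a mixture of overlapping envelopes —
is flagged uncorrectable rather than guessed at. AM is computed once and
never updated during the walk: the working assumption is that zero-mean
intensity noise largely cancels in the average, so AM is the robust
anchor while the argmax is the fragile feature being repaired.

## Synthetic validation data

Two simulators emulate the degradations the correction is meant to
survive:

* `noisyEnvelope()` adds zero-centered uniform noise to each peak
  height, with support width a fraction $w$ of that peak's own height
  (default $w = 0.10$), clipped at zero. Masses are never perturbed —
  mass noise would shift predictions one-to-one and reveal nothing about
  the model. Intensities are not renormalized afterwards: both the
  argmax and the weighted mean are scale-free.
* `sampledEnvelope()` draws a fixed total ion count from the
  multinomial over the normalized peak probabilities, emulating poor ion
  statistics.

What these simulations do **not** emulate: mass-axis miscalibration,
baseline drift, profile-mode peak shapes, co-eluting mixtures and
deconvolution artifacts. Passing the in-silico studies therefore
demonstrates the statistical soundness of the branch classification and
the correction, not robustness to every failure mode of real LC-MS data;
uncorrectable-envelope flagging and the in-domain flag are the designed
escape hatches for such cases.

With a 10,000-molecule hold-out (validation masses distributed like the
training masses), 10% uniform noise and the correction on, about 92–93%
of molecules are predicted within ±0.5 Da, with the remaining errors
almost exactly −1/+1 Da — and never ±2 Da, which the test suite asserts.
Intrinsic (noise-free) classification accuracy is ≈ 94.3%: within
overlap regions roughly one molecule in six is closer in probability to
the neighbouring branch than any single cut can resolve, and averaged
over the universe (34% of molecules sit in overlaps) this bounds what
any threshold rule can achieve; the per-prediction `pError` quantifies
exactly this risk.

## Modification robustness

`modificationRobustness()` re-runs the pipeline after applying an
elemental delta (methylation +CH2, guanine depurination −C5H5N5O +H2O,
2′-fluoro −OH +F, GalNAc conjugation +C87H140O41N, phosphorothioate
O→S, shortmers, Na/K adducts; see `modificationRegistry()`) to every
validation molecule, predicting from the theoretical most-abundant mass
without noise or correction so that only the model's transferability is
measured. Applicability is checked at the formula level (a delta that
would drive an element count negative marks the molecule missing, as
does a modified most-abundant mass outside the trained domain);
percentages are reported over the non-missing molecules. The user-facing
`applyModification()` additionally enforces base-count requirements
(e.g. depurinating four guanines requires four guanines) when a
composition is supplied.

Mono-isotopic deltas (CH2, F) leave accuracy at the unmodified ≈ 94%.
Each oxygen-to-sulfur conversion distorts the isotope pattern further
away from the training chemistry and accuracy degrades monotonically,
from ≈ 91% at one sulfur to ≈ 21% at ten; beyond about three sulfurs the
predictions should not be trusted, and refitting on a sulfur-containing
universe would be the right tool (out of scope here).

## Numerical choices and edge cases

* Global and per-branch OLS run on centered variables in closed form;
  sums accumulate in long double.
* Mode ties (two equal peak probabilities) break toward the lower
  nucleon shift; the raw-argmax tie in envelopes breaks toward the lower
  mass.
* Boundary search takes the first 50% crossing if noise produces
  several; adjacent branches with disjoint domains cut at the gap
  midpoint; an overlap narrower than one grid step falls back to its
  midpoint (logged).
* Off-by-one probabilities are linear interpolations of the stored
  proportion curves, clipped to [0, 1].
* Queries outside the trained most-abundant-mass domain are still
  answered but flagged `inDomain = FALSE` with a warning — extrapolation
  beyond the enumerated mass range is explicitly cautioned against.
* Models serialize to JSON with 17 significant digits, so save/load
  round trips reproduce predictions bit for bit; refitting the same
  table yields a byte-identical file.
* Far-tail aggregated peaks whose probabilities fall below the
  recurrence's roundoff floor (1e-13 relative to the mode) are reported
  as zero with interpolated center masses.

## Problem sizes used by the tests

The test suite builds the full 3.3M-composition DNA universe once
(seconds) for the end-to-end checks, and a lengths-5–30 universe
(~46,000 compositions) for unit tests. The hold-out split uses seed 42
and the noise study seed 7; `scripts/acceptance.R` derives all seeds
from its `--seed` argument. Fitting, validation and the robustness grid
all complete within a few seconds on one CPU.

## Limitations

* The predictor is chemistry-specific: use a DNA model for DNA and an
  RNA model (same pipeline, `chemistry = "RNA"`) for RNA.
* Inputs are neutral monoisotopic-ladder envelopes after charge
  deconvolution; m/z handling and deconvolution are upstream concerns.
* Heavily sulfurized backbones (>3 O→S) need a dedicated training
  universe.
* The correction assumes a single analyte per envelope; mixtures are
  flagged, not resolved.
* Systematic mass-axis errors pass through to the prediction untouched;
  calibration remains the spectrometrist's responsibility.
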