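---
title: "Measuring mRNA end-to-end separation from the exterior loop"
author: "endloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring mRNA end-to-end separation from the exterior loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endloop)
has_engine <- Sys.which("RNAfold") != ""
```

## The statistic

A folded mRNA leaves its 5' and 3' termini on the *exterior loop*: the
set of nucleotides not enclosed by any base pair, plus the closing pairs
of the outermost (depth-0) helices. The backbone path along that loop
connects the two ends, so its length — the contour length

$$C_L = L \times d, \qquad d = 0.59\ \text{nm per link}$$

— indexes the intrinsic end-to-end separation of the molecule, the
distance that matters for the circularization step of cap-dependent
translation initiation. $L$ is the number of links along the loop.
`exteriorSummary()` computes $L$ by walking the backbone at nesting
depth 0: each unpaired exterior nucleotide is a node, and each depth-0
helix contributes its two closing nucleotides as nodes joined by one
bridging base-pair link, giving

$$L = u + 2h - 1$$

for $u$ exterior-unpaired nucleotides and $h$ outermost helices.

**Why this convention.** The smallest observable separation in a survey
of folded mRNAs is one link, 0.59 nm — a molecule whose termini are
directly base-paired ($u = 0$, $h = 1$). Counting helices as zero-width
nodes ($L = u + h - 1$) or ignoring them ($L = u$) would make that
minimum 0 nm, which is physically wrong for a bridged loop and does not
match observed distribution minima. Both alternatives remain selectable
(`convention = "helixNode"` / `"unpairedOnly"`) so their effect can be
audited. A single-nucleotide input gives $u = 1$, $h = 0$, $L = 0$,
$C_L = 0$: a degenerate but well-defined edge case. $d$ is a parameter,
not a constant baked into call sites, because the per-link distance is
itself an empirical value.

## Structures

Structure prediction is delegated to the ViennaRNA command-line
programs behind a pinned, auditable engine configuration
(`viennaEngine()` records program, version and temperature into every
structure's provenance). The package deliberately implements no folding
algorithm: the statistic is engine-agnostic, and published comparisons
show mfold and ViennaRNA produce closely similar contour lengths even
when whole structures differ. Golden-file tests are keyed to the pinned
engine version so an engine upgrade fails loudly instead of silently
shifting $C_L$ values.

* `foldMFE()` returns the single minimum-free-energy structure at the
  engine default 37 °C (configurable; the temperature is recorded
  because no published value exists to pin against).
* `foldSuboptimal(k)` returns the $k$ lowest-free-energy structures,
  MFE first. They are enumerated with `RNAsubopt` inside an energy
  window above the MFE, starting at 0.1 kcal/mol and doubling until
  $k$ structures exist; this retrieves the lowest-energy structures in
  seconds even for 1600-nt molecules, where exhaustive Zuker-style
  enumeration is orders of magnitude slower.
* `parseDotBracket()` / `parseCT()` read Vienna and mfold interchange
  formats into the same `SecondaryStructure` container, which enforces
  the pairing involution and rejects pseudoknots (neither engine emits
  them, and the depth-0 walk is only defined for nested structures).

```{r structure-example}
s <- parseDotBracket(c("AAGCAAAGCAA", "..((...)).."))
exteriorSummary(s)
```

## Eligible molecules

The survey is restricted to full-length transcriptional units, filtered
by `checkEligibility()`: both UTRs annotated, total length in
[200, 7000] nt, and a 3' region containing a polyadenylation signal and
the start of the poly-A tail. All failures are accumulated (no
short-circuiting) so a filter report explains every exclusion.

Two details of the 3'-end checks are genuinely open choices, exposed as
configuration rather than hidden defaults:

* **PAS motif set** — defaults to AAUAAA plus the common variant
  AUUAAA. These canonical hexamers cover the vertebrate, plant and
  invertebrate species ranges surveyed; species with divergent signals
  can extend the list via `filterCriteria(pasMotifs = ...)`.
* **Poly-A start** — a run of ≥ 8 consecutive A ending at the 3'
  terminus. Eight is long enough that a chance run is rare
  ($4^{-8} \approx 1.5\times10^{-5}$ per position) yet shorter than the
  12-nt footprint a poly(A)-binding protein requires.

Before folding, `runSurvey()` trims the terminal poly-A run
(`trimPolyA = TRUE`): a homopolymer tail cannot pair internally and
would only add its own length to the exterior loop, and the tail is
bound by PABP in vivo, making its full extent irrelevant to the
end-to-end geometry of interest. The untrimmed behaviour is available
for sensitivity checks.

Coordinates are 1-based closed intervals throughout, matching the
GenBank feature convention; sequences are sense-strand mRNA, so no
reverse-complement handling exists.

## The random-sequence null

`generateRandomSequences()` draws i.i.d. nucleotides with equal
probabilities — the null model for "no biology, only thermodynamics".
The defaults (50 sequences × 1600 nt, uniform composition) are the
published control conditions, and `runRandomControl()` reruns the whole
chain: generate → fold → measure → fit. The generator is seeded
explicitly and restores the caller's RNG state; no attempt is made to
reproduce any particular historical RNG stream, only the distribution.

What the synthetic data deliberately does *not* emulate: codon
structure, UTR grammar, or realistic base composition. Passing tests on
these fixtures therefore validate the *machinery* (parsing, counting,
fitting), and the null comparison; they cannot certify the native-mRNA
numbers, which require the real GenBank records.

`generateStructure()` builds dot-bracket fixtures with an exactly known
exterior composition $(u, h)$, which gives every downstream stage a
ground truth: the link count of a generated structure is $u + 2h - 1$
by construction, and tests require triple agreement between that, the
implementation, and an independent brute-force backbone walk.

## Statistics

**Histogram fit.** `fitGaussianCL()` bins the contour lengths (default
bin width 2 nm, the granularity of the published histograms; always
reported so fits are auditable) and least-squares fits

$$y = A\,e^{-(x - c)^2 / w^2}$$

to bin centers and counts, using Levenberg–Marquardt with moment-based
starting values ($c_0 = \bar x$, $w_0 = \sqrt{2}\,s$, $A_0$ = tallest
bin; at most 200 iterations). $w$ is the **1/e half-width**, related to
the standard deviation by $w = \sqrt{2}\sigma$. This convention is the
one under which the published bounds are reproducible:
$9.0 + \sqrt{2} \times 6.03 = 17.53$ and
$7.7 + \sqrt{2} \times 2.6 = 11.38$ match the printed 17.5 and 11.4 nm,
which is why `upperBound95()` computes $c + \sqrt{2} w = \mu + 2\sigma$
by default. The alternative reading ($w = \sigma$, one-sided
$\mu + 1.645\sigma$) is selectable and documented as *not* matching
those values. Parameter uncertainties come from the fit covariance;
degenerate inputs (all values equal, fewer than 10 points) raise errors
rather than returning silent answers.

**Width comparison.** A wider native distribution could be a trivial
consequence of a larger center, so `scaleWidth()` rescales the control
width by the center ratio (and an optional GC factor, default 1, kept
explicit because composition also shifts widths), with uncertainties
propagated in quadrature. `sigmaConfidence()` then expresses the native
excess in units of the scaled width's uncertainty. With the published
inputs: `scaleWidth(2.6, 9.0, 7.7)` → 3.04 nm and
`sigmaConfidence(6.03, 3.03, 0.81)` → 3.7 σ.

**Tests and fits.** Group comparisons use Welch's unequal-variance $t$
(two-tailed, Satterthwaite degrees of freedom) via `welchTest()`;
dispersion is reported as mean ± SEM; `pearsonLinfit()` provides the
Pearson $r$ with its two-tailed $t$-transform p-value, the OLS line
$y = a + bx$, and a 95% confidence band for the mean response. No
multiple-testing correction is applied: comparisons are interpreted
per-test at $P < 0.05$, matching the analysis this package reproduces.

```{r worked}
sigmaConfidence(6.03, 3.03, 0.81)
upperBound95(GaussianFit(center = 9.0, width = 6.03))
upperBound95(GaussianFit(center = 7.7, width = 2.6))
```

**Numerical notes.** `sampleGaussianCL()` rejects and redraws negative
values (a contour length is non-negative); for the parameter regimes
used here the truncation shifts the mean by well under a bin width, and
tests account for it with the closed-form truncated-normal moments.
Histogram bins are aligned to multiples of the bin width, so fits are
invariant to the sample ordering. Welch and Gaussian-fit error paths
require nonzero variance; the survey handles the one legitimate
degenerate case (two identical groups) by reporting $t = 0$, $p = 1$
instead of failing.

## The pipeline

```{r survey, eval = has_engine}
set.seed(7)
recs <- c(lapply(1:5, function(i) {
    rnd <- function(n) paste(sample(c("A","C","G","U"), n, TRUE), collapse = "")
    seq <- paste0(rnd(50), rnd(160), rnd(40), "AAUAAA", rnd(12), strrep("A", 12))
    mrnaRecord(paste0("m", i), seq, speciesCode = "XX",
               utr5 = c(1, 50), cds = c(51, 210), utr3 = c(211, nchar(seq)))
}))
rep <- runSurvey(recs, minFit = 1000)
rep@perMolecule[, c("id", "length", "gc", "u", "h", "L", "CL")]
```

`runSurvey()` never drops a record silently: everything appears either
in the per-molecule table or in the skipped table with a reason.
Per-species aggregation is the mean contour length with SEM; clade and
gene-class labels are carried as annotations only (no phylogenetic
computation), and homologous-versus-heterologous contrasts are
expressed as configured group comparisons over those labels, since
homology calls are upstream annotation, not something this package
infers. `writeSurveyReport()` serializes the tables as TSV and the fits
and comparisons as JSON, deterministically for fixed inputs.

## Problem sizes and limitations

The test suite exercises the full random control at its native scale
(50 × 1600 nt) and the MFE-versus-suboptimal stability property at 20
sequences × 5 suboptimals, sizes chosen so the whole suite folds in a
few minutes on one CPU while keeping the control at the published
sample size. Parameter-recovery grids run at $n = 500$ per cell over
centers 5–12 nm and widths 2–7 nm.

Known limitations:

* Native-mRNA results (per-species means, native fit parameters, GC
  correlations) require the curated GenBank record set they were
  derived from, which is not redistributable here; the pipeline emits
  those tables verbatim-formatted when such records are supplied, but
  cannot regenerate them from thin air.
* $C_L$ is a contour length along the loop, not a Euclidean (FRET-style)
  end-to-end distance; no 3D inference is attempted.
* MFE prediction accuracy degrades with sequence length; the package
  treats the engine as a replaceable, versioned dependency and records
  provenance rather than claiming structural truth.
* A fitted $w$ from a 50-molecule histogram carries substantial
  uncertainty; downstream bounds inherit it, which is why every fit
  reports parameter SDs and its bin width.
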