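---
title: "Methods: response element scanning, promoter enrichment, and binding fits"
author: "trescan"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: response element scanning, promoter enrichment, and binding fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the models, the
conventions that had to be fixed where the underlying biology or common
practice leaves them open, the numerical choices, and what the synthetic
data generator does and does not emulate.

## The scanning model

Thyroid hormone response elements are direct repeats of an AGGTCA-type
hexamer halfsite, bound by the TR/RXR receptor pair, with the spacer
length between the repeats selecting among nuclear receptors (4 bases is
the canonical thyroid geometry, DR4). Because real elements diverge from
the consensus, scanning is consensus-with-degeneracy rather than exact
matching. Three built-in patterns cover the practical range:

| name | pattern | mismatches |
|------|---------|-----------|
| `halfsite` | `[AG]-G-G-N-C-A` | 0 |
| `dr4` | halfsite `-N(4,4)-` halfsite | 0 |
| `dr0_6` | `[AG]-[G]-G-[AT]-C-A-N(0,6)-[AG]-[G]-G-[AT]-C-A` | 2 |

Conventions the scanner fixes, each exposed as an argument where a user
could reasonably want the other choice:

* **Mismatch budget is joint.** For direct repeats the allowance (2 for
  `dr0_6`) is spent across both halfsites together, not per halfsite:
  "two allowed mismatches" most naturally modifies the whole search
  sequence, and a per-halfsite budget would accept elements with four
  total deviations, which is no longer a recognizable consensus match.
  Spacer bases and any-base (`N`) pattern positions never contribute.
* **`dr4` is scanned at zero mismatches.** The permissive search is the
  one that carries the mismatch allowance; the canonical-geometry search
  is kept strict. `compile_pattern(..., max_mismatches =)` overrides.
* **Both strands are scanned** (`both_strands = FALSE` disables).
  Response elements act on either strand; minus-strand matching runs on
  the reverse complement with coordinates reported on the forward
  sequence. A locus matching on both strands yields two hits, one per
  strand; only placements identical in (sequence, interval, strand,
  pattern) are merged, keeping the lowest mismatch count. All distinct
  placements — e.g. the same locus at spacers 3 and 4 — are retained, and
  the counting granularity is decided once, downstream, by the
  association rule.
* **The unknown residue `N` in the subject never satisfies an informative
  position.** Assembly gaps should not generate hits.

Coordinates are 0-based half-open everywhere inside the package; GFF3 I/O
converts to and from that format's 1-based inclusive convention, and hit
tables export as CSV or BED6 unchanged. The per-position mismatch sweep
is compiled (Rcpp), with an R-level brute-force enumeration kept in the
test suite as the independent oracle.

## Promoter windows and association

Each mRNA locus is treated as a gene object with a strand-aware
transcription start: the GFF3 `start` on the plus strand, `end` on the
minus strand (both converted to 0-based). The promoter window runs 500
bases upstream through 20 bases downstream of the TSS and includes the
TSS base itself, so an unclamped window is 521 bases wide; windows are
clamped at sequence boundaries but never dropped, keeping the gene
universe (the denominator of every enrichment) fixed.

A hit is credited to a gene when the **hit's start coordinate** lies in
the window. Start-in-window is the simplest deterministic rule; full
containment would make the effective window pattern-length dependent, and
midpoint rules are equivalent up to a shift. A hit inside two overlapping
windows is credited to both genes, and no collapsing of mRNA loci into
parent genes is performed — each locus keeps its own tally. Signed
TSS distances (negative = upstream in the gene's own orientation) are
recorded per hit, but all enrichment statistics use only the window
counts.

## Enrichment statistics

Two complementary analyses link counts to a differential-expression table
(`gene_id`, `contrast`, `log2fc`, `padj`):

1. **Regulation strength by element class** (`lfc_by_tre_class`): genes
   with at least `K` elements versus genes with none, compared on
   |log2FC|. The threshold `K` is data-chosen by `choose_threshold` as
   the largest integer for which at least 50 DEGs still carry ≥ K
   elements — as selective as the DEG sample size allows while keeping
   the high group interpretable. The headline statistic is the ratio of
   group mean |log2FC| (the "fold-ratio" of regulation strength).
2. **Element load near DEGs** (`deg_tre_enrichment`): mean element count
   and presence (≥ 1 element) in DEGs versus all other genes.

Fixed conventions, and why:

* **Magnitudes, not signed changes.** Response elements both activate
  and repress, so the natural direction-free question is "how strongly",
  i.e. |log2FC|. `use_abs = FALSE` switches to signed comparison.
* **DEG definition**: `padj < 0.05` and |log2FC| ≥ 1 (at least 2-fold).
  0.05 is the conventional DESeq2-style cutoff; both knobs (`alpha`,
  `fold_cut`) are arguments.
* **Welch, not Student.** Group sizes and variances are wildly unequal
  (tens versus thousands of genes); the unequal-variance statistic with
  Welch–Satterthwaite degrees of freedom is the defensible default. When
  both groups are constant and equal the comparison is degenerate and is
  reported as t = 0, p = 1 with a warning.
* **Presence is compared with a t test on 0/1 indicators** to keep one
  uniform test family; a two-proportion z test is available
  (`prop_test = "z"`).
* **No multiple-testing correction by default** across patterns and
  contrasts — each comparison answers its own question; `run_pipeline`
  adds Benjamini–Hochberg columns with `adjust_p = TRUE`.

## Binding models

Saturation assays follow the one-site total binding model

$$ B(c) = \frac{B_{max}\, c}{K_d + c} + ns \cdot c + bg $$

(specific hyperbola, linear nonspecific component, constant background),
and competition assays the one-site displacement model, a unit-slope
logistic in $\log_{10}$ concentration whose midpoint is tied to the
inhibition constant by the Cheng–Prusoff correction:

$$ S(c) = bottom + \frac{top - bottom}{1 + 10^{\log_{10} c - \log_{10} IC_{50}}},
\qquad IC_{50} = K_i \left(1 + \frac{[hot]}{K_{d,hot}}\right). $$

Numerical choices:

* Fits run Levenberg–Marquardt least squares (`minpack.lm::nls.lm`) on
  explicit residual functions. $K_d$ and $K_i$ are estimated as
  $\log_{10}$ parameters, which enforces positivity and makes their
  sampling distribution closer to normal; confidence intervals are
  asymptotic (t quantile on the standard errors from
  $\hat\sigma^2 (J^\top J)^{-1}$) and back-transformed, so the reported
  Ki interval is asymmetric, as binding intervals usually are.
* The nonspecific slope is fitted per fraction of the top concentration;
  with concentrations spanning eight orders of magnitude the raw slope's
  gradient column is otherwise so small that the Jacobian is numerically
  rank-deficient.
* Replicates are pooled into one residual vector rather than averaged
  first, so points with three observations weigh three times as much and
  the residual degrees of freedom are honest.
* Starting values come from the data: plateaus from the extreme
  concentration triplets, the midpoint from the observation nearest the
  half-range, background from the minimum signal.
* **No-displacement detection**: after the competition fit, the span
  (top − bottom) must be positive and significantly nonzero (t test at
  0.05); otherwise the fit aborts with "no displacement detected" — flat
  series (non-binding competitors) are a result, not a parameter
  estimate.
* Millipolarization normalization to 0–100 uses observed per-series
  extremes by default; a fitted-plateau mode (free logistic per series)
  is available when the extremes are noisy. Whether to normalize before
  fitting is the caller's choice; fits are scale-equivariant so the Ki is
  unaffected.

The dilution design used throughout is the assay's own: 18 points,
3-fold serial dilution from 2.7e-4 M (bottoming out near 2.1e-12 M),
three replicates.

## The synthetic-data generator

Every stage is testable against data whose truth is known, generated
under fixed study conditions:

* **Genome**: one chromosome of i.i.d. bases, GC = 0.5, 2000 genes placed
  one per 1000-base block with alternating strands, each promoter window
  wholly inside its own block. Uniform composition keeps occurrence
  probabilities analytic — the halfsite matches 8 of 4096 hexamers per
  strand, so a 521-base window expects 521 · (8/4096) · 2 ≈ 2.03
  background hits, a prediction the tests check directly.
* **Planting**: 10% of genes receive 11 non-overlapping zero-mismatch
  halfsite instances at random offsets of an equal-block partition of
  their window, on random strands. Re-scanning is guaranteed to recover
  at least the planted count (background can add more).
* **Expression**: affected genes draw log2FC from Normal(±δ, σ) with
  random sign, null genes from Normal(0, σ), with δ = 1 and σ = 0.5;
  p values come from a two-sided normal test of log2FC against a
  per-gene standard error of 0.25, BH-adjusted. σ = 0.5 and se = 0.25
  are realistic dispersions for a well-powered RNA-seq contrast; with
  them the expected fold-ratio between planted and empty promoters is
  the folded-normal ratio E|N(1, 0.5)| / E|N(0, 0.5)| ≈ 2.53, of the
  same order as enrichment ratios reported in hormone-response studies.
* **Binding**: model curves over the 18-point design plus Gaussian noise
  with sd equal to 5% of the curve's dynamic range, three replicates.

All generators require an explicit seed; nothing draws from the global
RNG silently.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: genomic repeat structure and
composition bias (which inflate background hit counts non-uniformly),
overlapping and nested gene models, correlated expression noise and
count-level mean–variance structure (the generator produces log2FC
summaries, not reads), distal enhancers, and any sequence conservation
signal. The tests establish that the machinery is correct and calibrated,
not that a particular biological effect size is expected.

## Problem sizes and calibration checks

The test suite validates the scanner against brute-force enumeration on
dozens of random sequences up to 20 kb; calibration of the enrichment
test uses 200 null replicates (expression noise redrawn over independently
generated genomes), requiring the fraction of p < 0.05 to fall inside the
exact binomial 99% band around 0.05; power and recovery use 100
replicates at the study conditions above; Ki recovery uses 100 simulated
plates, requiring a median |log10 error| under 0.15 and the Cheng–Prusoff
identity to machine precision. `scripts/acceptance.R` re-runs the same
computations from scratch and writes the resulting numbers as JSON.

## Known limitations

* Consensus-with-mismatch scanning has no statistical calibration per
  hit (no PWM scores or p values); counts are comparable across genes
  within one pattern, not across patterns.
* The largest-K threshold rule conditions on the DEG set; K is therefore
  a data-dependent quantity and should be reported alongside results.
* Presence-indicator t tests are anticonservative for very rare motifs;
  use the z-test option (or exact tests outside the package) when
  presence proportions are near 0 or 1.
* Asymptotic confidence intervals for Kd/Ki undercover when the dilution
  series barely spans the transition; profile-likelihood intervals are a
  possible extension.
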