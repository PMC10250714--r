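# trescan

Genome-wide scanning for thyroid hormone response elements (TREs),
promoter-window enrichment statistics against differential expression, and
one-site ligand-binding curve fits — with a seeded synthetic-data generator
so the whole pipeline is testable without external data.

## Who this is for

Researchers asking whether a transcriptomic response to thyroid hormones
(or another nuclear-receptor ligand) is plausibly mediated by genomic
response elements: given a genome (FASTA), gene models (GFF3) and a
finished differential-expression table, the package locates candidate
response elements, tallies them near each gene's transcription start, and
tests whether element-rich genes respond more strongly. A companion module
fits the membrane binding assays that usually accompany such studies.

## What it computes

**Motif scanning.** Three degenerate search patterns are built in, in
bracket notation:

* `halfsite` — `[AG]-G-G-N-C-A`, no mismatches (the canonical AGGTCA-type
  hexamer bound by one receptor of the TR/RXR pair);
* `dr4` — two halfsites separated by exactly 4 bases (Direct Repeat 4, the
  canonical TRE geometry), no mismatches;
* `dr0_6` — `[AG]-[G]-G-[AT]-C-A-N(0,6)-[AG]-[G]-G-[AT]-C-A`, a permissive
  direct repeat with a 0–6 base spacer and a joint budget of two
  mismatches across both halfsites.

`scan_sequence()` slides a pattern over every start, every spacer length
and both strands, reporting 0-based half-open hits; custom patterns come
from `compile_pattern()`.

**Gene association.** Each gene object (one per mRNA locus) gets a
strand-aware promoter window from 500 bp upstream to 20 bp downstream of
its predicted transcription start; a hit is credited to a gene when the
hit's start falls inside the window (`promoter_windows()`, `associate()`).

**Enrichment.** For a chosen pattern and contrast,
`choose_threshold()` picks the largest count `K` keeping at least 50
differentially expressed genes (DEGs), `lfc_by_tre_class()` compares
|log2 fold change| between genes with ≥ K elements and genes with none
(reporting the fold-ratio and a two-tailed Welch t test), and
`deg_tre_enrichment()` compares element counts and element presence
between DEGs (padj < 0.05, ≥ 2-fold) and unregulated genes.

**Binding fits.** `fit_saturation()` fits the one-site total binding model
`B(c) = Bmax·c/(Kd + c) + ns·c + bg`; `fit_competition()` fits one-site
competitive displacement, a unit-slope logistic in log10 concentration
whose midpoint is tied to the inhibition constant by the Cheng–Prusoff
correction `IC50 = Ki·(1 + [hot]/Kd_hot)`. Both use Levenberg–Marquardt
least squares with the affinity parameter estimated on the log10 scale,
and report asymptotic 95% confidence intervals.

## Worked example

Simulate a dataset under the package's standard study conditions (2000
genes; 11 halfsites planted in the promoters of a random 10%; an additive
|log2FC| effect of 1 on those genes) and run the analysis:

```r
library(trescan)

dir <- tempfile()
files <- simulate_preset("enrichment", seed = 3, out_dir = dir)

genome  <- read_genome(files[["genome"]])
sl      <- setNames(Biostrings::width(genome), names(genome))
genes   <- read_gene_models(files[["genes"]], seq_lengths = sl)
windows <- promoter_windows(genes, sl)            # 500 up / 20 down
hits    <- scan_sequence(genome, tre_patterns()$halfsite)
counts  <- associate(hits, windows, seq_ids = names(genome))

expr <- read.delim(files[["expression"]])
degs <- deg_set(expr, "T4_27d")
K    <- choose_threshold(counts, degs)            # >= 50 DEGs kept
lfc_by_tre_class(counts, expr, "T4_27d", "halfsite", K)
```

```
   pattern contrast threshold_k n_high n_zero mean_abs_lfc_high
1 halfsite   T4_27d          13    112    209          1.037431
  mean_abs_lfc_zero fold_ratio   t_stat      p_value
1         0.4055032    2.55838 11.50267 3.151297e-22
```

Genes with ≥ 13 nearby halfsites (112 of them) changed expression 2.56-fold
more strongly than the 209 genes with none — close to the analytic
expectation ≈ 2.53 for a folded-normal effect of 1 over a background
spread of 0.5, and decisively non-null (Welch p ≈ 3e-22).

The same stages run from the shell via the thin CLI in
`inst/scripts/tre.R` (`simulate`, `scan`, `associate`, `enrich`,
`fit-binding`, `pipeline` subcommands), or in one step through
`run_pipeline()`.

A binding example:

```r
b <- simulate_preset("binding", seed = 3, out_dir = tempfile())
fit_competition(read.csv(b[["competition"]]), hot_conc = 1e-7, hot_kd = 9.5e-8)
```

```
<one-site competition fit (Cheng-Prusoff)>
  Ki   = 1.02e-09 M  (95% CI 8.67e-10 - 1.21e-09)
  IC50 = 2.1e-09 M, top = 99.46, bottom = 1.738, RSS = 1021
```

The simulation used Ki = 1e-9 M with 5% noise on the 18-point 3-fold
dilution series; the fit recovers it within its confidence interval.

## Scope notes

The package consumes a finished differential-expression table (e.g. from
DESeq2); it does not trim, align, quantify, or test counts itself. Motif
scanning is consensus-based with mismatches — no position-weight-matrix
scoring — and no distal-enhancer association is attempted.
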