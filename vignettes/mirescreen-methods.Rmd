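---
title: "Scoring pooled inducible-knockdown dropout screens with mirescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring pooled inducible-knockdown dropout screens with mirescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The assay and its readout

A pooled competitive growth (dropout) screen transduces a library of
inducible knockdown constructs — here miR-E shRNAs, one construct per
target transcript variant — into a cell population at single-copy
integration and fixed representation (about 1,000 cells per construct).
The population is grown for 14 days with or without doxycycline (Dox);
Dox switches the knockdown on. Constructs whose target supports
proliferation or survival deplete from the induced arm. The readout is the
number of sequencing reads (NOR) per construct in three arms per replicate:

* **Day0** — baseline, right after selection;
* **Day14** — 14 days untreated (reference for growth drift);
* **Day14Dox** — 14 days with induction.

Replicates are independent transductions sharing the same library and
biology. The library is split into pools (~hundreds of constructs each);
every pool is cultured and sequenced as its own sample, so all
normalization is strictly within (pool, sample).

Each pool additionally carries four spiked controls: two *stability*
controls against transcripts absent from murine cells (shRenilla,
shLuciferase), which should behave neutrally, and two *depletion* controls
against the essential replication factor Rpa3, which should drop out
strongly once induced.

## Normalization and trimming

Counts are converted per sample to log2 reads-per-million with a
pseudocount:

$$v_{is} = \log_2\!\left(\frac{c_{is}}{\sum_{j \in \mathrm{pool}(s)} c_{js}}
\cdot 10^6 + 1\right).$$

Adding the pseudocount *after* scaling makes the transform exactly
invariant to sequencing depth (a property the tests assert bitwise).
Two trimming rules mask unreliable cells before scoring, recorded but never
deleted:

* a construct with a raw Day0 count below `min_day0_count` (default 30) in
  a replicate is masked throughout that replicate — too few baseline cells
  for a meaningful ratio;
* a day-14 cell whose |log2 change versus its replicate's Day0| exceeds
  `ratio_cap` (default 8) is masked as an outlier.

Both defaults are package choices, exposed in configuration and echoed in
the run manifest; tightening either threshold can only grow the masked set
(also tested). Masked cells propagate as missing values into scoring, where
they drive the single-replicate fallbacks, rather than being zero-filled.

## The effect statistic

On the log2 scale, per construct and replicate:

$$\mathrm{FGR}_r = v(\mathrm{Day14Dox}) - v(\mathrm{Day14}), \qquad
  \mathrm{BGR}_r = v(\mathrm{Day0}) - v(\mathrm{Day14}).$$

FGR is the induction effect; BGR is the Dox-independent drift of a clone,
pooled across all constructs and both replicates to estimate the screen's
noise:

$$\mathrm{medianBGR} = \mathrm{median}(\mathrm{BGR}), \qquad
  \mathrm{MAD} = 1.4826 \cdot \mathrm{median}\,|\mathrm{BGR} -
  \mathrm{medianBGR}|.$$

The per-replicate robust strictly standardized mean difference and its
replicate average are

$$\mathrm{SSMD}^*_r = \frac{\mathrm{FGR}_r - \mathrm{medianBGR}}
  {\sqrt{2}\,\mathrm{MAD}}, \qquad
  \mathrm{AvSSMD}^* = \mathrm{mean}_r\,\mathrm{SSMD}^*_r,$$

and the gene-level score is the unweighted mean of the gene's scored
constructs (AvSSMD\*/protease). If a replicate's untreated Day14 value is
masked, FGR falls back to $v(\mathrm{Day14Dox}) - v(\mathrm{Day0})$ and
that replicate contributes no BGR; a construct with one usable replicate
keeps that replicate's score.

### Design choices that were genuinely open

* **Placement of $\sqrt{2}$.** The source formula, written inline as
  "(FGR − medianBGR)/MAD · √2", is ambiguous between dividing or
  multiplying by $\sqrt 2$. We divide — the standard scaling for a paired
  difference against a robust background — and expose the literal
  left-to-right reading as `convention = "multiply"`. The two differ by the
  exact factor 2; because the hit cutoff is itself one standard deviation
  of the scores, hit sets are provably identical under either convention,
  and a test asserts this on simulated screens.
* **Global background.** medianBGR and MAD are computed per screen, pooled
  over all constructs, pools and replicates. A per-construct MAD from at
  most two BGR values would be degenerate; a per-pool background is
  possible but the pooled form matches "from all constructs in both
  replicates" and is what we implement (flagged in output metadata).
* **Controls in the background.** Control constructs enter the pooled
  background and the SD of scores like any other construct by default
  (`include_controls = FALSE` excludes them).
* **No second log2.** Axis labels of the form "log2 AvSSMD*" in screen
  figures are read as "AvSSMD* computed on log2 data", not as a transform
  of the score itself; the score distribution is signed and roughly
  centered at zero, where a log would be undefined.

## Hit selection

`SD_AvSSMD*` is the sample standard deviation (n−1) of all constructs'
AvSSMD\* in a screen; ±1 SD is the intrinsic-variability band. Selection
proceeds in two filters:

1. **Frequency filter:** a gene is a hit iff at least `min_frequency = 2`
   of its constructs score strictly outside the band (|AvSSMD\*| > SD,
   either sign). Two independent constructs guard against single-construct
   off-target artifacts. Direction comes from the sign of the gene-level
   score.
2. **Expression filter:** a hit is kept only if its target mRNA is
   strictly above the configured threshold in *every* cell line's
   expression table (e.g. RNA-seq FPKM > 0.5, microarray log2 > 6.2). A
   gene absent from a table fails — absence of evidence of expression is
   not sufficient expression.

Cross-screen accounting tabulates every Venn region of the per-screen hit
sets and classifies union genes as *depletion* (negative score wherever
hit), *mixed* (negative in one screen, positive in another) or
*enrichment-only*; enrichment-only genes are excluded at the final
reporting (heat-map) stage, not at the first filter, matching the
narrative order of the original analysis.

## The synthetic-screen generator

The generator makes every stage testable without sequencing data. Its
defaults are the study conditions: 658 genes × 4–7 constructs in 16 pools,
four controls per pool, 1,000× representation, 14-day window, two
replicates, $10^6$ reads per sample.

* Day0 clone abundances are
  $a_i = \mathrm{representation} \cdot \mathrm{LogNormal}(0, \sigma)$,
  redrawn independently per replicate (independent transductions); the
  default $\sigma = 0.5$ is a generic choice for the clone-size spread
  after pooled transduction, since the source reports no empirical Day0
  distribution.
* Growth is deterministic and exponential in log2 units: a construct with
  effect $e$ (total log2 fold-change over the window under full induction)
  multiplies its abundance by $2^{ek}$, with $k = 1$ under Dox,
  $k = \lambda$ (the leakiness) untreated, $k = 0$ at Day0.
* Sequencing draws each sample as a multinomial of `depth` reads over its
  pool's relative abundances; an optional Dirichlet-multinomial
  overdispersion is available for stress tests.
* FASTQ emission writes `barcode + miR-30 5' flank + guide + 3' flank`
  reads at constant quality; demultiplexing at zero mismatches is its exact
  inverse (tested bit-exactly at $10^6$ reads).

**What the generator does not emulate.** Real replicates share the skew of
the plasmid pool, so their Day14 profiles correlate (the study saw Pearson
R 0.56–0.79 between replicates); with independently redrawn baselines the
between-replicate correlation is near zero here, while within-replicate
correlations are, if anything, cleaner than real data (R ≥ 0.95 at the
simulated depths versus ≥ 0.79 reported). There is no stochastic clone
extinction, no PCR amplification bias, no sequencing error in the reads,
and conditions (hypoxia/normoxia) are modeled only as distinct screens with
distinct effect maps. Passing tests therefore validate the *scoring
machinery and its calibration*, not the biology of any particular screen.

**Leakiness is a scale, not a switch.** Modeling Dox-independent promoter
activity as a multiplicative factor $\lambda$ on the effect means FGR
scales by $(1-\lambda)$ for every affected construct — and so does the SD
of scores. The depletion-control detection fraction (controls below
−1 SD) is therefore invariant over moderate $\lambda$ at screen-realistic
depth and collapses only as $\lambda \to 1$, when the untreated reference
arm has already lost the clones. The leakiness property is accordingly
asserted as a weak monotonicity (the fraction never increases along
$\lambda \in \{0, 0.25, 0.5, 1\}$), with the visible collapse at
$\lambda = 1$ mirroring the qualitative behavior of the leaky screen in
the study.

## Numerical and degenerate-input behavior

* MAD = 0 (constant background) is an error advising a review of trimming
  and depth, since the score divides by it; SD_AvSSMD\* = 0 is flagged
  degenerate.
* A gene score of exactly 0 has undefined direction (logged, not dropped).
* Demultiplexing refuses barcode sets whose pairwise Hamming distance is
  ≤ 2 × the allowed mismatches (assignment would be ambiguous by
  construction); ambiguous reads — ties at the minimum distance — are
  discarded into a tally, never fractionally assigned.
* Reads shorter than the layout count as unassigned; the four demux
  tallies always sum to the number of reads processed (asserted
  internally).
* All randomness flows from one integer seed; identical configuration and
  seed reproduce library tables, count matrices and FASTQ files
  byte-identically.

## Problem sizes used in the tests

Unit tests run on screens of 10–40 genes at depths of $10^3$–$5 \cdot
10^5$ reads per sample. The end-to-end calibration and recovery checks use
300 genes × 5 constructs in 5 pools at $3 \cdot 10^6$ reads per sample —
20 null simulations for calibration (median AvSSMD\* within ±0.2; genes
passing the first filter within the binomial 99th percentile implied by
the empirical outside-band mass, pooled over simulations) and 10
simulations with 10% of genes planted at $e = -4$ for recovery
(sensitivity ≥ 0.9, neutral-gene call rate ≤ 5%). These sizes were chosen
so the suite exercises the study-scale statistics while remaining quick to
run routinely. Note that under a pure null the ±1 SD band marks ~32% of
constructs as outliers and roughly half the genes pass the frequency
filter — the filter derives its specificity from real screens' sparse,
large effects inflating SD_AvSSMD\*, which the recovery simulations
reproduce.

## Limitations

The trimming criteria of the original pipeline are not public; ours are
explicit stand-ins with the same intent. The generator's independence
assumptions (between replicates, between constructs of a gene) make the
null calibration slightly cleaner than real screens. Expression filtering
consumes per-gene expression tables as given and applies fixed thresholds;
it does not model expression measurement error. No p-values or FDR are
attached to hits — the method is a cutoff on a robust effect size with a
reproducibility requirement, as in the original analysis.
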