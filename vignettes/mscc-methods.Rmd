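---
title: "MSCC methylome analysis: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MSCC methylome analysis: model, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msccr)
```

## The measurement model

Methyl-sensitive cut counting reads out CpG methylation at CCGG sites
through differential restriction digestion. HpaII cuts C^CGG only when
the internal CpG is unmethylated; MspI cuts regardless of methylation.
Two libraries are built from the same DNA: the **HpaII library**, whose
tags witness *unmethylated* sites, and the **inverse library** (HpaII
ends deactivated first, then MspI digestion), whose tags witness
*methylated* sites, 5mC and 5hmC alike — the assay cannot distinguish
the two, and this package does not try. MmeI releases a fixed-length
genomic tag adjacent to each cut; we collapse MmeI's 18/20-bp cut
heterogeneity to exactly 18 bp. Adaptor index sequences identify the
(sample, library) stream of each read.

### Tag coordinates

For a CCGG whose first C sits at 0-based position $p$, the cut C^CGG
leaves a fragment starting at $p+1$, so the forward-side tag is
$[p+1, p+19)$; by palindromy of CCGG the opposite-side tag is the
reverse complement of $[p-15, p+3)$. Both begin with `CGG`. The
protocol literature does not print tag coordinates, so this convention
is fixed here and used identically by the simulator and the matcher:
correctness of the mapping stage is internal consistency, verified by an
exact read-level round trip, not a claim about the chemistry's basepair
offsets. Tags that would cross a chromosome end are omitted for that
side; a tag seen at more than one (site, side) is removed entirely
(both occurrences), mirroring a uniquely-mappable requirement.

### Tag matching

Reads are demultiplexed by **exact** index match (the protocol describes
no mismatch-tolerant demultiplexing), then the 18-bp tag is searched
against the library at mismatch tiers 0, 1, … in order; a read is
accepted only if exactly one library tag matches at the lowest non-empty
tier. The published rule "fewer than 2 mismatches" is read literally as
`max_mismatch = 1`; the flag accepts 2 for the permissive reading.
Whether uniqueness was judged per tier or across tiers is not stated in
the protocol literature; per-tier is used (a unique exact hit wins even
if 1-mismatch hits exist elsewhere), which is the behaviour of standard
best-hit mappers. At toy-genome scale the search is a hash lookup plus
single-substitution neighbour enumeration — exact, with no aligner
heuristics to calibrate.

## Quantification

Per library $L$ and sample, the spike-in standard count defines a scale
factor $f_L = K/\text{spike}_L$ with an arbitrary constant $K$ that
cancels; the level estimate for a site with HpaII count $u$ and inverse
count $m$ is

$$\hat p = \frac{m f_I}{m f_I + u f_H}.$$

The exact normalization formula is not fixed by the published MSCC protocol descriptions;
this ratio-of-scaled-counts form is the minimal estimator consistent
with "normalize both libraries by the standard counts", and it is
unbiased by construction when the spike-ins carry the same
library-efficiency distortion as the genomic reads (verified in the
tests at efficiencies 1.0/0.8).

Sites require **depth ≥ 30 raw reads** (`min_depth = 30`,
configurable). Two details are deliberate:

* the filter uses *raw* $u+m$, not normalized counts — sampling noise is
  governed by the number of physical reads;
* a site with exactly 30 reads is kept; where the prose ("more than
  30") and the label ("30+ reads") of published MSCC analyses differ,
  the "30+" convention wins because it is the operative form on every
  downstream analysis.

Spike-ins scale each (sample, library) independently; no cross-sample
quantile or global normalization is added, because the assay describes
none.

## Differential methylation

Analysis units are 200-bp non-overlapping windows (trailing partial
windows kept) and CpG islands. A unit enters a comparison only with
**≥ 4 sites** quantified in *both* samples — "> 3 sequenced CpGs" —
and its means use exactly that shared site set, otherwise coverage
differences would masquerade as methylation differences. The test
statistic is Fisher's exact test (two-sided, conditional on margins,
with a $10^{-7}$ relative tolerance on the probability-ordering
comparison) applied to the pooled raw counts
$(m_a, u_a; m_b, u_b)$ over the shared sites. Raw counts enter the
table — not spike-in-scaled ones — because the hypergeometric sampling
model is count-based and scale factors are constant within a comparison;
this is a reconstruction, flagged as such.

The headline criterion is a **25% absolute difference** in unit means.
Published MSCC analyses assign p-values alongside this cutoff without
stating a threshold or multiple-testing rule, so the default DMR definition here requires both
$|\Delta| > 0.25$ and BH $q < 0.05$ within each comparison
(`mode = "delta_q"`), with `mode = "delta_only"` reproducing the
literal delta-only criterion; both flags are always reported. A unit is
a *consistent* DMR only if it passes in **every** treated-vs-baseline
comparison (S4h, S12h, S24h, S96h vs S0h under the default design).
Site-level consistency is analogous per site; by default the absolute
change matters, not its direction (`same_sign = TRUE` tightens this, a
choice the published criterion leaves open).

## Context profiles

* **Metagene axis**: each quantified site maps to its *nearest* gene
  (deterministic tie-break), at relative coordinate 0 = TSS, 1 = TES,
  with flanks of half the gene length per side (−50%…150%); 20 flank
  bins per side, 40 body bins. "Latter half of the gene body" means
  relative 0.5–1. The moving-average smoother uses an 11-bin centered
  window that truncates at the series ends (the first smoothed value of
  a window-3 smooth is the mean of the first two bins); published metagene
  figures name a moving average but not its window. Nearest-gene
  assignment (rather than all overlapping genes) is likewise an
  unstated-detail decision.
* **CGI shores** are the 2 kb flanking each island — the field's
  standard width; MSCC protocol descriptions never define "shore". Distances are to
  the nearest contained base, boundary inclusive.
* **Gene context** uses six classes with fixed precedence
  tss_region (±1 kb of the strand-aware TSS) > exon > intron >
  upstream > downstream (2 kb flanks) > intergenic, so sites hit by
  several genes are deterministic.
* **Expression tertiles** are equal-count thirds by rank, ordered
  deterministically by (expression, gene name), so boundary ties fall
  into the lower group while all-tied inputs still split evenly.
* **Histone peaks / short RNA**: within-vs-without means per mark;
  within / near (≤ 2 kb, inclusive) / without classes for short-RNA
  loci.

All coordinates are 0-based half-open throughout (BED-native), in files
and in memory.

## What the simulator emulates

The synthetic module is the package's evidence base: it generates the
*conditions* the analyses assume, with a known truth per site and
sample.

* **Genome**: AT-rich background (30/20/20/30) with CpG islands of
  600–1200 bp re-sampled GC-rich. CCGG sites are planted at a mean
  spacing of ~45 bp in the background and ~12 bp inside CGIs, keeping
  the CGI/background CCGG density ratio above 3. The background spacing
  is deliberately ~20× denser than a mammalian genome: it puts a
  desk-scale genome (3 × 100 kb) into the analysis' operating regime of
  >1000 eligible 200-bp windows with ≥ 4 sites, the scaled-down
  analogue of a genome-wide scan over >10,000 windows. Genes
  (2–5 kb, 2–4 exons, strand random), one peak track per histone mark,
  short-RNA loci and a log-normal expression table are placed
  non-overlapping with pads.
* **Methylome**: background levels from the bimodal mixture
  0.7 Beta(8,2) + 0.3 Beta(2,8) (mammalian methylomes are bimodal);
  CGI sites Beta(1,12); shore sites ×0.5; ±1 kb of a TSS ×0.2;
  active-mark peaks ×0.3; repressive-mark peaks +0.2; short-RNA loci
  ×0.25 and their 2-kb neighbourhoods ×0.45. No distributional forms are
  prescribed by the assay, so these are fixed constants chosen to make
  the qualitative orderings (CGI < shore < open sea; TSS dip;
  active-within < without; repressive-within > without;
  short-RNA within < near < without) hold with clear margins in the
  truth; they are stated here so every test is reproducible. Under the
  `expression_coupled` scenario, latter-gene-body levels are
  Normal(0.35/0.45/0.55, 0.05) by expression tertile (a 0.2 offset) and
  the TSS dip deepens with expression.
* **Counts**: per (sample, site), depth ~ Poisson(mean_depth); the
  inverse-library count is Binomial(depth, $q$) with
  $q = p e_I / (p e_I + (1-p) e_H)$; spike-ins are
  Poisson(spike_in_mean · $e_L$), so a biased efficiency leaves the
  same trace in the standards as in the genomic reads — which is
  precisely what makes the normalization identifiable. One standard tag
  set per library is the minimal model: protocol descriptions say only
  that standard DNA is co-digested, so this is an assumption, flagged.
* **Reads**: one read per count, index ⊕ tag, side chosen uniformly
  (whether both sides are sequenced at equal rates is unstated;
  symmetric is assumed at both ends of the pipeline). Substitution
  errors apply to the tag only — demultiplexing is exact-match by
  design, so index errors would only shuffle reads into the unassigned
  bin; indels are out of scope because MmeI fixes the tag length.
* **Planted DMRs** shift all treated samples by `delta` (clipped to
  [0,1]) inside disjoint windows holding ≥ 4 sites. By default only
  windows where *no* member site clips are eligible: a "planted 40%
  effect" on a site at level 0.9 would really be a 10% effect, and a
  power statement about Δ = 0.4 must plant Δ = 0.4.
  `allow_clipping = TRUE` removes the restriction.

What the simulator does **not** emulate: PCR duplicates, quality-score
structure, indels, chimeric reads, copy-number variation, biological
replicate dispersion (the emulated design pools dishes per timepoint and
has no replicates), or realistic genomic CCGG sparsity. Passing tests
therefore demonstrate correctness of the estimators and decision rules
under the stated sampling model — not robustness to artefacts the model
excludes.

## Numerical choices and degenerate inputs

* Fisher: zero-margin tables return $p = 1$; tie comparison uses a
  $1+10^{-7}$ relative factor; p is capped at 1.
* `normalize_and_call` rejects non-positive spike-ins naming the
  sample/library; $u = m = 0$ sites are dropped regardless of
  `min_depth`.
* `depth_accuracy_curve` skips thresholds with fewer than 10 shared
  sites (with a warning). Depth contrast in the validation is created
  by simulating site subsets at 12× and 150× and binding them, since a
  single Poisson mean populates only one depth stratum.
* Windows: trailing partial windows are kept; `unit_stats` reports
  ineligibility as a value (`reason = "min_sites"`), not an error.
* Chromosomes with no surviving calls appear in summaries with `NA`
  mean and count 0 rather than being dropped.
* Determinism: every stochastic function takes a seed; identical
  config + seed reproduces byte-identical files (the run manifest
  records md5 checksums, and a re-run with unchanged config and intact
  outputs is skipped).

## Problem sizes

The bundled validation uses 3 × 100 kb genomes (~8,500 CCGG sites,
~1,500 eligible units, five samples at 50×), 2,000-site mixtures for
estimator calibration, and an exhaustive Fisher sweep over all 2×2
tables with total ≤ 40 — sizes chosen so the full suite and the
acceptance script each run in well under a minute on one core while
keeping Monte-Carlo margins comfortable.

## Known limitations

* MSCC counts 5mC and 5hmC together; no deconvolution is attempted.
* No per-site confidence intervals; depth filtering is the only
  uncertainty control, as in the emulated analysis.
* The window/CGI Fisher test has no dispersion term; with biological
  replicates a beta-binomial model would be preferable, but the
  emulated design has none.
* The exact-match hash search scales to toy genomes; a genome-scale
  reimplementation would need an indexed matcher, which is out of scope
  here.
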