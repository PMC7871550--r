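---
title: "Bulk-segregant X-QTL mapping and backcross introgression analysis"
author: "xqtlmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bulk-segregant X-QTL mapping and backcross introgression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The experiment this package models

Two haploid yeast strains that differ in neutral-lipid (NL) storage — a
laboratory strain of the BY/S288C background and a wine strain of the
AWRI background — are crossed, and the haploid F1 segregants of the
hybrid are screened for NL content with a Nile Red fluorescence (FI)
microplate assay.  Two complementary mapping strategies follow:

* **X-QTL (extreme-QTL) bulk segregant analysis.**  A very large pool of
  segregants is sorted by FACS, collecting the brightest ~2 %.  The
  selected subpopulation and the unselected (average) population are
  whole-genome sequenced as pools; at every SNV distinguishing the
  parents the parental allele read counts are compared.  Regions where
  the selected pool is enriched for one parent's alleles harbour
  candidate QTLs.
* **Recurrent backcrossing with selection.**  The best F1 segregant is
  backcrossed to a parent for several generations, each round selecting
  the highest-FI segregant of ~190 screened.  Donor-parent genome that
  survives seven generations of backcrossing far in excess of the
  \((1/2)^g\) drift expectation implicates linked causal alleles.

The package implements the analysis end of both strategies — allele
ratios, windowed medians, pool differences, peak calling, haplotype-block
inference, donor-fraction quantification, depth-based duplication
flagging, and the plate-reader phenotype processing — together with a
synthetic generator for every input (SNV maps, meioses, trait values,
FACS gates, pooled read counts, per-segregant calls, microplates), so the
whole pipeline is exercisable and testable with no external data.

## The generative model

**Genome and markers.**  The default genome is the 16 nuclear
chromosomes of the S288C reference (12,071,326 bp).  `buildParentalMap()`
scatters 68,000 SNVs uniformly, proportional to chromosome length — one
marker per ~178 bp, matching the density of the real inter-parent
variant catalogue.

**Meiosis.**  Per chromosome, the crossover count on a gamete is
Poisson-distributed with mean equal to the genetic length in Morgans;
breakpoints fall uniformly on the genetic scale and are mapped to
physical coordinates through the genetic map (`GeneticMap`, uniform by
default, piecewise if desired).  There is no crossover interference and
no obligate chiasma; under this model the recombination fraction between
two loci follows Haldane's map function
\(r = \tfrac12\,(1 - e^{-2d/100})\) of their distance \(d\) in cM.  The
default rate of 0.345 cM/kbp reproduces the published physical–genetic
correspondence of the cross (26.2 kbp ≈ 9 cM near *CAN1*) and gives a
genome-wide map length of ~4,165 cM, in the range usually quoted for
*S. cerevisiae*.

**Selection markers.**  Haploid-selection systems force the marker loci
(by default stand-ins for *CAN1* on chrV and *LYP1* on chrXIV, both
required from the BY parent) to one parental origin in every surviving
segregant.  Linked loci hitchhike with Haldane decay — the package
reproduces both the distortion within each pool and its cancellation in
the selected-minus-average subtraction, which is exactly why a
marker-linked allele (the *RML2* situation) can only be resolved by
individual genotyping.

**Trait model.**  A trait value is
`baseline + Σ locus effects (chosen by parental origin) + Σ epistasis
terms + N(0, noiseSD)`.  Biological and instrument noise are folded into
one `noiseSD`; the FACS gate is applied to the same values, since no
separate instrument-error model is published for the assay.
`defaultTraitModel()` places five additive loci at the approximate
positions of the mapped lipid QTLs (four AWRI-beneficial, one
BY-beneficial near the *CAN1* marker) plus one interaction term, and is
calibrated so the parental FI ratio is \(2^{0.66}\) and roughly a fifth
of F1 segregants falls outside the parental range in each direction —
the transgressive pattern characteristic of this cross.  `noiseSD = 33`
FI units was fixed once to reproduce that spread; it is deliberately
large relative to single-locus effects, as in the real assay.

**Pool sequencing.**  At each SNV the true AWRI frequency *f* is the
fraction of pool genomes with AWRI origin there.  Sequencing draws
`depth ~ Poisson(meanDepth)` and
`nAWRI ~ Binomial(depth, f(1−e)+(1−f)e)` for error rate *e*.  Read-level
simulation (FASTQ, alignment, base quality) is deliberately out of
scope: the pipeline starts at allele counts.

## The mapping statistics

* `alleleRatio()` — per SNV, `(nAWRI + c)/(nBY + c)` with pseudocount
  `c = 0.5` (Haldane–Anscombe), plus the AWRI frequency.  The canonical
  orientation is AWRI:BY; the literature uses both phrasings, so the
  reciprocal is one division away and the orientation is written into
  output headers.
* `windowMedian()` — medians per non-overlapping 10,000 bp window.
  Windows with no SNV are omitted: gaps in the track are informative
  (regions identical to the reference parent).  The last window of a
  chromosome may be shorter and is flagged.
* `poolDelta()` — per window present in both tracks,
  `selected − average`.  The default scale is the AWRI *frequency*
  (symmetric around 0); a ratio-scale delta is available for figure
  parity.  Positive delta = AWRI-enriched, negative = BY-enriched.
* `nullThreshold()` — the published analysis states no explicit
  significance rule for promoting loci, so the package simulates
  selection-free pool pairs at the study's pool sizes and depths, runs
  the identical pipeline, and uses a genome-wide quantile (default 0.99)
  of |delta| as the calling threshold.
* `callPeaks()` — maximal runs of ≥ 2 adjacent windows beyond the
  threshold with constant sign; the apex window gives the peak position
  and the enriched parent.

## Backcross analysis

`runBackcross()` counts generations by index: F\(_g\) is reached after
\(g-1\) backcross rounds from an F1 founder, so a random founder gives
the drift expectation \(100\cdot(1/2)^g\) % donor genome at F\(_g\)
(0.78125 % at F7, printed as 0.8 %).  The published description of the
seventh generation is consistent with \((1/2)^7\) rather than the
six meioses of a strict F1→F7 pedigree; the package adopts the printed
convention and documents the discrepancy here.

`inferBlocks()` applies the consecutive-SNV rule literally: at least
`minRun = 5` consecutive same-parent calls assign the interval between
the furthest two SNVs of the run; shorter runs and inter-block intervals
stay `unassigned` rather than being merged into neighbours (merging
would manufacture precision the data do not contain).  Block boundaries
sit at SNV coordinates, not midpoints.  `donorFraction()` uses the total
genome length as its default denominator so the \((1/2)^g\) comparison
is well defined; an assigned-only denominator is available because the
published retained-genome percentages do not state how unassigned
intervals were counted.  Regions flagged as duplicated can be excluded
from both numerator and denominator.

`detectDuplication()` normalizes windowed depth by the genome-wide
median window depth and reports runs of fold ≥ 1.5 spanning ≥ 50 kb —
only a depth-gain view of events like the VIII-t-XVI translocation-borne
duplication; breakpoint-level characterization is out of scope.

## Phenotype processing

`nlProxy()` is `(FI_post − FI_pre)/OD600`.  Negative values (post-stain
below pre-stain) are retained and flagged, but excluded from log2
binning.  `plateNormalize()` divides by the mean of the on-plate
reference replicates (four per plate in the study design), making plates
comparable; `binDistribution()` builds the 100-class histogram on the
log2 scale.  Classes are 1-based; a value on an interior right edge
belongs to the bin on its right, the top edge to the last bin.  The
binning range defaults to the data range of whatever set is
histogrammed; for cross-panel comparisons (F1 vs F7 panels) pass a
common `limits`, which is the default mode of comparison because the
class↔log2 anchors of different panels only align on a shared range.
An all-equal sample has no well-defined equal-width binning and is an
error rather than a single-bin histogram.  The t-test helper defaults to
the equal-variance Student test (the common spreadsheet default for such
assays), with Welch behind a flag.

## Numerical and design choices

* Coordinates: `GRanges` 1-based closed in memory; BED/bedGraph 0-based
  half-open on disk; SNV positions 1-based (VCF convention).  File
  headers state the convention.
* Ties in FACS gating and top-k selection break toward the lower index
  (stable sort), so results are reproducible across runs.
* `facsSort()` takes `ceiling(gateFraction · n)` values — a ~2 % gate on
  1.5×10⁸ cells collects 3×10⁶.
* Pseudocount 0.5 keeps ratios finite at zero counts; with
  `pseudocount = 0`, zero-denominator sites are dropped with a logged
  count instead.
* Every stochastic entry point takes one integer seed; the pipeline
  derives per-stage seeds from it and records them in the manifest, so
  identical config + seed gives byte-identical text outputs.
* Pool allele frequencies are computed by breakpoint event accumulation
  (a difference array over SNV indices), so cost scales with crossover
  count rather than pool size × SNV count; a 10,000-segregant,
  68,000-SNV pool evaluates in well under a second.

## What the tests do and do not show

The test suite checks the in-text arithmetic of the study at printed
precision, verifies the windowed-median and block-inference operations
against brute-force oracles on a thousand random instances, and runs the
full pipeline under the study's design conditions: 10,000 segregants, a
top-2 % gate, pool depths of 738× and 1407×, three planted causal loci
of effect 0.5·noiseSD (two AWRI-beneficial, one BY-beneficial), with
peak intervals required to contain every true locus with the correct
enrichment sign in ≥ 90 % of 20 replicates.  Drift backcrossing is
checked over 200 replicate lineages (5 phenotyped segregants per round —
the donor-fraction distribution under pure drift does not depend on the
per-round sample size); marker hitchhiking is checked against Haldane's
map function at 9 cM; a planted 2× depth segment must be recovered
almost fully.

Synthetic data are idealized: SNVs are uniform rather than clustered,
the genetic map is uniform (no hot/cold spots or interference),
sequencing errors are symmetric and independent, there is no mapping
bias toward the reference parent, and pools contain exactly the sampled
genomes (no growth competition between sorting and sequencing).  Passing
tests therefore demonstrate the correctness of the *analysis* under its
stated model, not the biological calibration of any particular real
cross.  The wet-lab numbers of the study (lipid mg/g in deletion
mutants, the exact Table-style SNV percentages, the 3.2–6.5 % retained
genome of the real lineages) derive from measurements this desk-scale
model cannot reproduce and are not asserted anywhere.

## Worked example

```{r example}
library(xqtlmap)

cfg <- runConfig(n_segregants = 2000, seed = 7)
res <- runPipeline(cfg, outdir = "xqtl-run")
res$peaks
plotDeltaTrack(res$delta, res$threshold)
```
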