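---
title: "Predicting and evaluating CpG islands: clustering vs sliding windows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and evaluating CpG islands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgiscan)
```

## The problem

CpG dinucleotides are depleted in mammalian genomes and mostly methylated;
the exceptions are short CpG-rich, predominantly unmethylated stretches —
CpG islands (CGIs) — that concentrate in promoters and other regulatory
regions. Two families of detectors exist. Sliding-window approaches (SWA)
declare a region an island when it clears fixed thresholds on length, GC
content, observed/expected CpG ratio and CpG count. Clustering approaches
instead treat the island as a statistical property of the CpG positions
themselves: CpGs closer together than expected under a null model form
clusters, and each cluster receives a p-value, so statistical significance
replaces the length threshold. `cgiscan` implements one detector of each
family plus the evaluation battery needed to compare them: overlap
statistics against annotation sets, sensitivity and lower-bound positive
predictive value against gold standards, matched-set-size calibration,
islet extraction, methylation-state classification, within-island
methylation heterogeneity, and promoter coexpression analysis.

## The clustering detector

For each chromosome independently, `predict_islands()`:

1. extracts the 0-based start positions of all CG dimers (`N` never
   matches);
2. takes the consecutive start-to-start distances $d_i$ and sets the
   clustering threshold to a percentile of their distribution — the median
   by default, the classic choice for this detector family. With an even
   number of distances the floor of the midpoint average is used, so the
   threshold is always an achievable integer distance;
3. clusters consecutive CpGs with $d_i \le$ threshold (equality clusters;
   a strict mode is exposed because the tie rule changes island counts);
   runs with fewer than 2 CpGs have no distance and are dropped;
4. assigns each cluster of $N$ CpGs spanning $S$ bp (first to last start)
   the lower tail $P(\sum_{i=1}^{N-1} D_i \le S)$ where the $D_i$ are
   i.i.d. geometric on $\{1, 2, \dots\}$ with success probability
   $\hat p = n_{\mathrm{CpG}} / (L - 1)$, the chromosome's own per-position
   CpG start rate. The sum of $N-1$ geometrics is a shifted negative
   binomial, so the tail is evaluated through `stats::pnbinom`, i.e. the
   regularized incomplete beta function — no explicit summation, but the
   result agrees with naive summation to machine precision on small cases;
5. reports clusters with $p \le$ threshold ($10^{-5}$ for the relaxed set,
   $10^{-20}$ for the strict set) as islands running from the C of the
   first CpG to just past the G of the last ($S + 2$ bp), annotated with
   GC%, O/E ratio $n_{\mathrm{CpG}} L / (n_C n_G)$ and CpG density.

Real DNA cannot place two CpG starts 1 bp apart, while the geometric null
has support starting at 1. We keep the full support: the p-value is
internally consistent with the null used to derive it, and the enumeration
oracle in the test suite checks exactly that contract. Whether p-values
should be corrected for multiple testing is left as printed thresholds
(no correction), matching the two standard cutoffs.

The p-value is deliberately *not* a reparameterisation of island length:
for a fixed span it decreases with CpG count, so two islands of equal
length and different density get different significance. The test suite
asserts this non-degeneracy.

## The sliding-window detector

`tj_predict()` implements the stringent window scan: windows of 500 bp
must reach GC $\ge$ 55%, O/E $\ge$ 0.65 and at least $0.6 \cdot L / 16$
CpGs (the guard against "mathematical" islands). The scan has five steps
per chromosome: slide 1 bp until a window qualifies; jump window-by-window
while criteria hold; on failure roll the last window back 1 bp at a time
until it qualifies, closing a candidate; trim the candidate 1 bp per side,
with both ends snapped onto CpGs (the C of the first, the G of the last),
until the whole segment meets all criteria; merge islands separated by at
most 100 bp when the merged segment still meets every criterion (never
across an N run at least as long as the merge gap), and report segments of
at least 500 bp. Island counts are sensitive to the step size, window and
merge gap, so all are exposed as parameters and recorded in outputs.

Two consequences of this procedure matter for interpretation. First, every
reported island satisfies all thresholds over its full extent — the
self-consistency oracle in the tests re-scores each island from raw
sequence. Second, the ends-on-CpG rule means the only reportable part of
any region is its CpG-bounded core (first CpG start to last CpG end). A
505-bp island whose outermost CpGs are 490 bp apart is unreportable *by
construction*, not by implementation accident. The recovery experiments
therefore define a "TJ-qualifying" planted block as one whose CpG-bounded
core is at least 500 bp and itself meets all criteria
(`tj_block_qualifies()`); against that definition recovery is complete,
while against whole-extent qualification it hovers around 0.8–0.9 — the
shortfall is exactly the blocks with short cores.

The trim shrinks both sides symmetrically. An asymmetric search could
rescue a few more marginal segments, but the symmetric rule is the
documented procedure and keeps counts comparable with the classic
implementation.

## Evaluation battery

All coordinates, in files and in memory, are 0-based half-open (BED
convention), and overlap always means at least one shared base: touching
intervals do not overlap. Overlap and coverage arithmetic runs on IRanges
behind the tidy interfaces, and every statistic is checked against a
per-base brute-force oracle on random instances.

* `overlap_summary()` — mean coverage (mean over islands of the fraction
  of island bases covered by the union of elements) and overlap fraction
  (islands touching any element / all islands).
* `benchmark_vs_gold()` — TP = predictions overlapping the gold standard,
  FN = gold intervals untouched by any prediction, SN = TP/(TP+FN),
  PPV = TP/predictions. The TP is prediction-side while FN is gold-side;
  this heterogeneous-unit reading is the one that reproduces every
  published SN cell from its count quadruple, and the PPV is a lower bound
  because an incomplete gold standard can only turn FPs into TPs.
* `calibrate_pvalue_threshold()` — matched set sizes: the most significant
  `target_count` islands, with all cutoff ties included and reported, so
  p-value-selected sets can be compared with window-length-selected sets
  of equal size.
* `extract_islets()` — significant clusters shorter than 200 bp, the
  islands that length-thresholded detectors cannot represent;
  `exclusive_islands()` finds those untouched by any competing prediction.
* `nesting_counts()` and `tss_specificity()` — how many cluster islands a
  window island hosts, and whether islands contain one or several
  transcription start sites. "Included within" is read as >= 1 bp overlap,
  with strict containment behind a flag.
* `promoters_from_tss()` — strand-aware windows from 1500 bp upstream to
  500 bp downstream of the TSS.

## Methylation and expression rules

Per-CpG classification follows the bisulfite-amplicon rules: records with
fewer than 2 clones are discarded; measurements are averaged within tissue
(multiple samples per tissue are averaged first — the aggregation the
source data requires but does not spell out); a CpG needs at least 6
tissues; per-tissue labels use mean $\ge 80$ methylated, $< 20$
unmethylated, otherwise intermediate (so exactly 80 is methylated and
exactly 20 intermediate, from the half-open phrasing of the rules); and
cross-tissue calls need a strict majority with the "never the opposite
extreme" veto applied literally. The cross-tissue rules name only
methylated, unmethylated and differential; an all-intermediate CpG is
labeled intermediate here so that island coverage (which needs classified
states for a strict majority of island CpGs) counts CpGs that *have* data
but sit between the cutoffs. Island labels then need a strict majority of
classified CpGs and obey the same vetoes.

Two-tissue array regions are unmethylated in a tissue when the scaled 5mC
log2 ratio is below 0.3; the methylated side of the differential call is
the complement (ratio $\ge 0.3$), which the source rules imply but do not
state. Read-based island means use cytosines with at least 10 reads, both
strands averaged per CpG, and need covered CpGs for a strict majority of
the island.

`swa_heterogeneity()` aggregates the maximum over both tissues and
inner-island pairs of the difference in mean methylation between cluster
islands hosted by the same window island — "maximal difference over the
different tissues" admits several readings, so the per-tissue breakdown is
also computable from the returned table. `compare_island_pair()` is a
two-sided Mann-Whitney test on per-CpG methylation values with exact
enumeration below 8 values per side (ties handled through midranks;
`stats::wilcox.test` cannot do exact ties, which is why the test is
implemented here and wilcox.test serves as the independent cross-check in
the suite) and a tie-corrected, continuity-corrected normal approximation
otherwise.

Coexpression of a promoter-sharing gene pair is the fraction of tissues in
which both genes are on the same side of the signal-200 expression cutoff,
over tissues with data for both; at most 0.2 is divergent, exactly 1
coexpressed.

## What the simulator emulates — and what it does not

`simulate_genome()` draws i.i.d. filler sequence (background GC 38%,
island GC 60%) and injects CpG dinucleotides by a Bernoulli process:
0.002 per position in the background — the characteristic CpG depletion of
mammalian DNA — and 0.08 inside the 100 planted islands (mean 500 bp,
SD 75, at least 2 kb apart on a 2-Mb chromosome). Accidental CG dimers
arising in the filler are broken, so the realised CpG positions are
exactly the planted ones and inter-CpG distances follow the geometric null
the p-value assumes — this is what makes the analytic recovery checks
clean, and it is also the model's main idealisation. Real genomes have
isochore structure, repeats (Alu elements are themselves CpG-rich),
neighbour-dependent substitution and CpG clustering beyond geometric
spacing; passing the recovery tests therefore shows correctness of the
machinery under its own null, not field performance on a real assembly.
Genome-scale published counts (tens of thousands of islands, mean lengths,
table rows) are whole-genome quantities that require the actual assembly
and annotation tracks; the formula-level checks against published count
quadruples are the desk-scale counterpart used here.

Methylation tracks give every CpG one record per tissue across 12 tissues
(the amplicon resource the classification rules come from spans 12):
unmethylated islands draw per-tissue means from 5–15%, methylated islands
and background from 85–95%, differential islands are low in half the
tissues and high in the other half, all with Gaussian noise (SD 5
percentage points) and 5% deliberately under-supported records to exercise
the clone filter. 70% of islands are planted unmethylated, 20%
differential, 10% methylated — the unmethylated majority reflects what is
expected of true islands, with enough of the other classes to test every
label. Expression uses a 73-tissue healthy panel with planted coexpressed
(identical expressed-tissue sets), divergent (complementary sets) and
intermediate (~30% of tissues flipped) pairs.

The demonstration that cluster islands can fall below 55% GC — even 50% —
while window islands pile up against their thresholds uses an explicit
AT-leaning island configuration (`gc_island = 0.45`, CpG rate unchanged):
CpG clustering does not require high GC, which is precisely the property
being demonstrated; the default configuration keeps 60% GC islands, the
realistic value for mammalian CGIs.

## Numerical choices and degenerate inputs

* Distance thresholds are floored integers and never below 2 (CG dimers
  cannot overlap).
* `negbin_pvalue()` errors on impossible geometry (span < CpGs − 1);
  chromosomes with fewer than 2 CpGs yield no islands rather than an
  error, while `compute_distance_threshold()` itself requires 2 positions.
* O/E ratios report 0 when $n_C n_G = 0$.
* Empty island sets make overlap statistics undefined (error), and the
  benchmark requires non-empty inputs on both sides.
* Ambiguity codes collapse to N on input; whether repeat-masked lowercase
  sequence should be excluded is not specified by the sources this package
  follows, so case is normalised and all bases used.
* Percentages in TSS-specificity tables are rounded to 2 decimals;
  everything else is full precision, with island BED output printing
  p-values at 6 significant digits.

## Problem sizes

The recovery experiments run on one simulated 2-Mb chromosome with 100
planted islands (about 7,700 CpGs); the brute-force oracles use up to
10-kb instances with up to 50 intervals, 200 instances per run; exact
rank-sum enumeration covers up to 6 values per side; the p-value
enumeration grid covers 2–4 CpGs, spans up to 12 and three null rates.
These sizes keep the full suite within a couple of minutes on one core
while leaving the statistics nowhere near their asymptotic regimes — the
regime where the implementations must be exact.

## Known limitations

* The simulator's i.i.d. background understates the correlation structure
  of real genomes (see above); recovery rates on simulation are upper
  bounds on real-data behavior.
* The window detector's symmetric trim can drop marginal candidates whose
  qualifying subsegment sits asymmetrically inside the candidate.
* Read-based (bisulfite sequencing) methylation input is consumed as a
  per-cytosine table; alignment and methylation calling from raw reads are
  out of scope.
* Competing window-based predictions (UCSC-style, promoter-oriented
  finders) are consumed as external BED files, not reimplemented.
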