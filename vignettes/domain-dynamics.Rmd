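---
title: "Calling and comparing broad H3K27me3 domains with k27domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and comparing broad H3K27me3 domains with k27domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(k27domains)
```

## The problem

H3K27me3, the repressive mark written by PRC2, occupies broad
multi-kilobase domains (facultative heterochromatin) rather than sharp
peaks. When cells are perturbed — the G1 phase lengthened, PRC2 activity
modulated, an oncohistone expressed — these domains do not simply rise
or fall in place: their *boundaries* move. Quantifying that requires a
pipeline that (i) makes fragment-level chromatin-profiling samples
(CUT&RUN, CUT&Tag, ChIP-seq) comparable across global occupancy shifts,
(ii) calls broad domains robustly, and (iii) decomposes multi-condition
domain sets into comparable units whose changes can be classified and
clustered. `k27domains` implements that workflow end to end, together
with a synthetic-data generator that plants domains with known dynamics
so every stage is testable without sequencing data.

## Normalization and coverage

Fragments are length-filtered to the assay's retention window (120–500
bp for CUT&RUN; 120–1000 bp for CUT&Tag, after discarding
coordinate-duplicates; single-end ChIP reads are extended from their 5'
end to 250 bp). Coverage is counted in fixed 100-bp windows: a fragment
adds its normalization weight to every window it overlaps by at least
1 bp. The weight is either

* spike-in: \(N = 10{,}000 / (\text{fragments mapped to the spike-in
  genome})\), appropriate when an exogenous genome (e.g. *Drosophila*)
  was spiked in, so that global gains or losses of the mark are
  preserved; or
* depth: \(N = 2.8\times 10^9 / (\text{total mapped reads})\), a
  constant in the range of mammalian mapped base pairs, when no spike-in
  exists.

The 10,000 and 2.8e9 constants are arbitrary scale anchors; only ratios
between samples matter. Replicates are combined by summation of
already-normalized tracks, and the combined track is smoothed with a
running average spanning ±1,000 bp around each 100-bp bin. At chromosome
ends the window is truncated and the mean taken over the bins actually
present, which avoids artificial signal decay at the edges.

## Domain calling

The *domain cutoff* is the smallest bin value strictly greater than the
values of \(F\)% of all genome-wide bins (nearest rank, zeros included,
no interpolation — interpolated percentiles would shift cutoffs on
sparse data). \(F = 95\) by default; datasets with globally depleted
signal (e.g. H3K27M-mutant lines) use \(F = 75\). Domains are maximal
runs of bins at or above the cutoff; to tolerate short mappability
dropouts, two runs are linked across a gap iff the gap is at most 750 bp
*and* every gap bin still reaches 0.75 × cutoff (the condition is
per-bin, not a gap mean; "up to 750 bp" is inclusive, i.e. up to 7 full
bins). Putative domains are then filtered on their enrichment over an
IgG control: only domains with

\[\log_2\frac{\bar s + \varepsilon}{\bar g + \varepsilon} > 2\]

(4-fold over IgG; \(\bar s\), \(\bar g\) the mean normalized signal and
IgG over the domain, \(\varepsilon = 0.01\) a symmetric pseudocount) are
kept. External chromatin-state annotations (e.g. "FacultativeHet"
segments of a genome segmentation) are made comparable by transitively
coalescing same-state segments whose ends lie within 500 bp.

### Where the percentile cutoff works — a design constraint

A percentile threshold presumes the enriched fraction of the genome is
close to \(100 - F\) percent. Writing \(h\) for the smoothing half-span
(1,000 bp) and \(r\) for the cutoff expressed as a multiple of
background, a domain of length \(L\) with fold-enrichment \(f\)
contributes \(L - 2h + 4h\,(f - r)/(f - 1)\) bp above the cutoff, so the
cutoff bisects the boundary ramps — where boundary estimates are most
accurate — exactly when total domain bp equals \((100-F)\%\) of the
genome. Below that fraction the cutoff falls into the background noise
tail (boundaries overshoot by up to one half-span and noise runs get
linked); far above it the cutoff climbs into the domain plateau and
splits domains at noise dips. H3K27me3 in mESCs genuinely occupies
roughly a tenth of the genome, comfortably in the workable regime for
\(F = 95\); the synthetic generator's defaults are chosen to match it.

## Unique segments, classification, clustering

Domain sets from multiple conditions are compared on the atomic
intervals induced by all their boundaries (`disjoin`): each unique
segment lies fully inside or fully outside every condition's domains,
the segments are pairwise disjoint, and their union equals the union of
the inputs bp-exactly (asserted on every call). Interval algebra is
delegated to GenomicRanges; the test suite checks it against an
independent per-bp label-vector oracle.

Boundary changes of a treated condition against a reference follow a
four-way taxonomy: segments covered in both conditions are **same**;
treated-only segments of a domain that touches a reference domain are
**spreading**; segments of treated domains with no reference overlap at
all are **new**; reference-only segments are **shrinking** — covering
both partial retraction and complete loss (complete loss is a
convention: the schematic taxonomy does not depict that case). "Same"
is strict bp-identity on the bin grid; a one-bin boundary shift already
counts as a change (a bp-slack tolerance flag exists, default 0). A
domain may retract one boundary and extend the other, yielding both
shrinking and spreading segments; no single domain-level label is
forced.

Per-segment trajectories (log2 of pseudocounted mean signal per
condition, row z-scored by default so shape dominates scale) are
clustered with k-means. For reproducibility — which plain k-means does
not provide — the features are clustered in a canonical
(lexicographic) order under a fixed seed with 50 restarts, every row is
then assigned to its nearest converged center (ties to the lowest
index), and clusters are relabeled 1..k by ascending mean change
between the last and first conditions, so cluster 1 collects the
strongest losses and cluster k the strongest gains. Input row order
therefore cannot affect the labels. Raw (non-z-scored) features are
available behind a flag; with only two conditions z-scoring collapses
all trajectories to two shapes, so raw mode is the sensible choice
there.

## The bimodal log2-ratio model

Per-segment log2 ratios between two conditions are summarized by
fitting the explicit two-Gaussian curve

\[y = A_0 e^{-\left(\frac{x - A_1}{A_2}\right)^2}
    + A_3 e^{-\left(\frac{x - A_4}{A_5}\right)^2}\]

to the histogram density (60 equal-width bins by default) by nonlinear
least squares — deliberately a curve fit to the density, not
maximum-likelihood EM, mirroring the interactive curve-fitting workflow
the formula comes from. \(A_1, A_4\) are the component means and
\(A_2, A_5\) the component widths (the width \(w\) corresponds to a
Gaussian standard deviation \(w/\sqrt{2}\); component areas are
proportional to \(A_0 A_2\) and \(A_3 A_5\)). Initialization takes the
two strongest separated kernel-density peaks (falling back to the
25th/75th percentiles), widths from half the inter-peak distance, and
amplitudes from the peak densities; ten deterministically jittered
restarts are run and the lowest residual sum of squares wins, making
the fit a deterministic function of the data. Components are
canonically ordered so \(A_1 \le A_4\).

Segments are partitioned into three groups: `cut_high` is the x between
the means where the two fitted component curves cross (midpoint of the
means if they do not cross in the open interval), `cut_low` is
\(A_1 - A_2\), one width below the left mean; CL1 = x < cut_low
(strong loss), CL2 in between, CL3 = x ≥ cut_high (gain). The source
material never prints its shaded-region cut points, so these two rules
are explicit, configurable conventions of this package.

## Statistics

Overlap between two clusterings of two different segmentations is
tested per cluster pair with the hypergeometric distribution over a
common universe of atomic intersection pieces (each piece inherits both
parents' labels; counting pieces avoids double counting, and a
bp-weighted variant exists). Both enrichment (upper tail) and depletion
(lower tail) are tested; all pairs × directions form one
Benjamini–Hochberg family and the smaller tail is reported with its
direction. Group comparisons use the two-sided Mann–Whitney rank-sum
test: exact by complete enumeration of group assignments (midranks for
ties) when the combined sample size is ≤ 20, otherwise the normal
approximation with tie and continuity correction. Gene-expression
comparisons assign genes to clusters by ≥ 1 bp gene-body overlap
(multi-cluster genes join all their clusters), keep significantly
changing genes (|log2FC| > 1, FDR < 0.05 by default), and compare
clusters pairwise with rank-sum + BH.

## The synthetic-data generator

The generator emulates the *data regime* of spike-in chromatin
profiling, not its sequence-level detail. A truth set plants
non-overlapping domains on a toy genome, each assigned a scenario —
`same`, `shrinking`, `spreading`, `new`, or `lost` — with per-condition
intervals (linear interpolation of moving boundaries across more than
two conditions, rounded to the bin grid). Target fragment midpoints are
drawn from a piecewise-constant density with weight `enrichment_fold`
inside condition-present domains and 1 outside, so the expected
in-domain midpoint fraction has the closed form
\(fp/(fp + 1 - p)\) for planted fraction \(p\) and fold \(f\), and the
in/out density ratio converges to \(f\). An optional `background_rate`
mixes in a fraction of purely uniform midpoints (default 0, keeping the
closed forms exact). Fragment lengths are normal (mean 180, sd 40)
clipped to [50, 600] bp — spanning the assays' retention windows so
length filters exercise both keep and drop branches. Spike-in fragments
are uniform over dedicated `spike_`-prefixed chromosomes; IgG fragments
are uniform over the target genome. One root seed yields derived
per-stream seeds (truth / fragments per condition and replicate /
mixture), so adding a stream never perturbs another, and identical
configurations produce byte-identical BED output.

Default study conditions: 10–30 kb domains (the scale of broad
facultative-heterochromatin domains), enrichment fold 8, three
replicates, ~2.6% of fragments on the spike genome, and planted domain
bp tuned to the \((100-F)\%\) rule above. Demo scenarios keep the
*total* enriched fraction comparable between conditions by balancing de
novo domains with fully lost ones — real chromatin satisfies this
because domain turnover is bidirectional (the bimodal log2-ratio
distributions show gains and losses simultaneously), and a shared
percentile cutoff presumes it.

What the generator does *not* emulate: mappability and GC structure,
fragment-length dependence on position, PCR-duplicate family structure
(only exact-coordinate duplication), inter-replicate variability beyond
sampling noise, and any sequence-level effect. Passing the planted
recovery suite therefore demonstrates correctness of the computational
method under its stated assumptions, not robustness to artifacts of
real libraries.

## Numerical choices and degenerate inputs

* Coordinates are BED convention (0-based, half-open) everywhere;
  GenomicRanges' 1-based closed intervals are converted at the
  boundary.
* Length-filter bounds are inclusive on both ends ("120–500" read as a
  closed interval).
* The percentile is nearest-rank with strict inequality; a constant
  track has no qualifying value and raises a "degenerate distribution"
  error rather than returning an arbitrary cutoff.
* Pseudocounts (`0.01` normalized units) are applied symmetrically to
  numerator and denominator so ratio ordering is preserved; zero-IgG
  bins stay finite.
* Double smoothing is an error: reproducibility of the published
  procedure depends on smoothing exactly once.
* k-means requires at least k distinct feature rows and fails loudly
  otherwise; relabeling ties break by cluster index.
* The mixture fit requires ≥ 100 values and ≥ 20 bins; non-convergence
  from every restart raises an error rather than returning garbage.
* Empty inputs (no fragments, no domains, empty clusters) flow through
  with empty outputs or flagged zero rows, never NA arithmetic.

## Problem sizes in the test suite

The verification suite runs entirely from generated data: 1,000 random
multi-condition interval sets against a per-bp disjoin oracle, 1,000
random tracks against an exhaustive gap-linking oracle, an end-to-end
planted-scenario run (22 domains on a 6.8 Mb toy chromosome, 3
replicates × 100,000 fragments per condition), a full sweep of all
hypergeometric configurations with universe ≤ 12 against subset
enumeration, 60 mixture fits at n = 10,000, and 10,000 simulated null
pairs for rank-sum calibration. These sizes give each check enough
resolution to fail loudly while keeping a complete run on one CPU
within a few minutes.

## Known limitations

* The percentile cutoff degrades gracefully but measurably outside its
  operating regime (enriched fraction far from \(100-F\)%); F must be
  rechosen for globally depleted samples, as the SU-DIPG-IV setting
  (F = 75) illustrates.
* "Same" at zero tolerance is stricter than visual judgement of a
  genome browser; users comparing noisy replicates may prefer a 1–2 bin
  slack.
* The three-group cut points are conventions; absolute group
  memberships near the cuts are sensitive to the fit.
* No statistical test is attached to per-segment enrichment differences
  (by design; the workflow clusters and classifies rather than testing
  each segment).
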