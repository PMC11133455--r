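---
title: "Scoring chromatin-architecture changes caused by TAD boundary deletions"
author: "tadfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring chromatin-architecture changes caused by TAD boundary deletions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadfusion)
```

## The problem

Topologically associating domains (TADs) partition chromosomes into
self-interacting blocks separated by insulating boundaries, typically
anchored by clustered CTCF binding sites. Deleting a boundary can fuse the
two flanking TADs, exposing a gene to enhancers it normally never contacts
("enhancer hijacking"). Capture Hi-C over a locus of interest gives deep
contact maps for wild-type and boundary-deletion cells, but the two maps are
not directly comparable: the deletion changes genomic distances, and contact
frequency decays steeply with distance, so even a deletion with *no* effect
on folding mechanics reshuffles the map.

`tadfusion` separates these two effects. It builds, from the wild-type map
alone, the contact map expected if the deletion acted **only** through
genomic distance, and then scores where the observed mutant map departs from
that distance-only null.

## The distance-only null

Let $V_{ij}$ be the (VC_SQRT-normalized) wild-type contact value between
5-kb bins $i$ and $j$, and let $P(s)$ be the locus's distance-decay profile:
the mean normalized contact over all valid bin pairs at separation $s$ bins
(`estimate_expected()`; exact on any map whose values depend only on
$|i-j|$).

A deletion $[a, b)$ induces a two-block synteny map between the reference
and the deleted genome (`deletion_to_synteny()`). Two liftover models move
contacts through such a map:

* **easy** (`liftover_easy()`): coordinates only. Each bin's signal is
  reassigned through its synteny block with overlap-fraction weighting;
  values are untouched, so contact mass over mapped pairs is conserved.
* **balanced** (`liftover_balanced()`): in addition, every remapped pair
  whose separation changes from $s$ to $s'$ is rescaled by $P(s')/P(s)$ —
  the map is re-expressed as if each pair had always sat at its new genomic
  distance. This is the only reading under which a deletion affects
  architecture purely by changing distances.

The null prediction $V^*$ (`simulate_wt_under_deletion()`) composes the two:
wild type $\to$ balanced liftover onto the deleted genome $\to$ easy
liftover back to reference coordinates. The round trip leaves same-side
pairs (both bins on one side of the deletion) exactly unchanged and rescales
pairs straddling the deletion; the deleted interval itself is masked. On a
perfectly distance-only map, $V^*_{ij} = P(s')$ at every surviving pair —
the unit tests assert this as an equality, not an approximation.

## The differential contact-enrichment statistic

With the observed mutant map $V$ (mapped to reference coordinates, as
aligners produce it) and the null $V^*$ on the same grid,

$$D(k, f) = \operatorname{mean}\bigl\{\log(V_{ij}/V^*_{ij}) :
  i \in [k-f, k),\; j \in (k, k+f],\; V_{ij} > 0,\; V^*_{ij} > 0\bigr\}$$

averages the log-enrichment of observed over expected contacts across bin
$k$, over a window of $f$ bins on each side (`d_score()`). $D$ is then
Z-transformed across all defined $k$. A boundary that lost insulation shows
a positive Z peak at its position; `call_insulation_changes()` merges
contiguous bins with $|Z|$ above a threshold (default 2) into BED intervals
with their peak Z.

Conventions, all chosen where the statistic's definition leaves room:

* **Log base**: natural. Only Z is interpreted downstream and the Z
  transform is base-invariant.
* **Zeros**: pairs with $V = 0$ or $V^* = 0$ are excluded; a bin with no
  valid pair has undefined $D$ (not zero). On identical inputs the Z track
  is reported as all-zero rather than NaN (zero-variance convention).
* **Depth matching**: before taking ratios both maps are scaled to the mean
  of their totals over jointly positive pairs. The symmetric target keeps
  $D$ exactly antisymmetric under swapping the inputs; any common scale
  cancels in Z regardless.
* **Window `f`**: default 20 bins (100 kb at 5 kb resolution) — wide enough
  to average tens to hundreds of pairs per position, narrow enough to
  localize a single boundary; it is a tunable argument and is echoed into
  every exported track and manifest.
* **Edges**: windows are truncated at the chromosome ends rather than
  dropped.

## Normalization and subtraction maps

`vc_sqrt_normalize()` implements vanilla-coverage square-root balancing:
$W_{ij} = V_{ij}/\sqrt{r_i r_j}$ with $r_i$ the row sum over unmasked bins,
followed by one global rescale. The rescale convention — preserve the total
matrix sum — keeps normalized maps in count-like units so that subtraction
maps remain interpretable. Bins with zero marginal are masked and stay
masked downstream. Note that this half-balancing attenuates but does not
remove multiplicative per-bin coverage structure: a rank-one matrix
$c_i c_j$ becomes $\sqrt{c_i c_j}$-structured, not flat (flattening it would
require full vanilla coverage, division by $r_i r_j$). The D statistic is
robust to this because the same normalization is applied to both maps being
compared.

`subtraction_map()` renders gains and losses directly: both maps are scaled
to the mean of their totals over jointly valid bins, optionally aggregated
to a coarser grid (e.g. 10 kb for display, summing 5-kb values), and
differenced. The result negates exactly under swapping the inputs.

## Allele-specific expression

In F1 *M. musculus* × *M. castaneus* hybrids, allele-distinguishing SNPs
assign reads to parental alleles. Per SNP, the normalized allele expression
is $(\text{mus} + 1)/(\text{cast} + 1)$ — the pseudocount keeps ratios
finite and makes a coverage-0 SNP score exactly 1. Per gene and genotype,
`gene_allelic_summary()` reports mean ± sample SD over SNPs (SD 0 by
convention at $n = 1$); `compare_alleles()` runs a two-tailed Mann–Whitney U
test between genotypes with SNPs as the sampling unit — exact null
distribution when the smaller group has ≤ 8 observations and no ties, else
a normal approximation with tie-corrected variance. `allele_fraction()`
converts a ratio $r$ to the musculus transcript fraction $r/(1+r)$; the
published mutant *Kdr* ratio of 49.71 converts to 98%.

## What the synthetic generator emulates — and what it does not

`kit_locus_model()` mirrors the study design the package targets: a
~2.275 Mb capture region at 5 kb resolution (455 bins) holding three
adjacent TADs, with main boundaries at bins 150 and 290 (insulation
multiplier $\delta = 0.2$) and two weaker nested sub-TAD boundaries (bins
200 and 245, $\delta = 0.6$) inside the middle TAD. Expected contacts are
$A(1+s)^{-\alpha}$ ($\alpha = 1$, the canonical intra-TAD decay slope)
times $\prod \delta_b$ over boundaries between the two bins, optionally
times Gaussian loop bumps; counts are independent Poisson per unordered
pair, globally scaled to an expected total of $5 \times 10^6$ — a realistic
capture Hi-C depth over a region this size. `simulate_deletion_experiment()`
simulates the mutant on the deleted genome (distances recomputed after
collapse; the overlapped boundary dropped when `fused = TRUE`, re-anchored
at the fusion point otherwise) and re-expresses it in reference coordinates,
as mutant reads mapped to the reference assembly would appear.

The generator reproduces the *statistical* structure the analysis relies on
— distance decay, block insulation, Poisson counting noise, the coordinate
collapse of a deletion — and deliberately omits features of real capture
Hi-C: overdispersion beyond Poisson (a knob exists in principle but tests
run without it), restriction-fragment and probe-density bias along the
locus, unmappable bins away from the deletion, loop-extrusion stripes and
corner peaks, and trans contacts. Passing tests therefore demonstrate the
*method's* correctness and calibration under its own assumptions, not that
real libraries are free of artifacts; on real data the VC_SQRT step and the
joint-positivity filter carry the weight the generator's idealizations
leave out.

Under these conditions the end-to-end suite checks two properties at study
scale (455 bins, depth $5 \times 10^6$, 20 replicates each): with the
boundary retained, the per-replicate mean Z lies in $[-0.2, 0.2]$ and at
most 10% of bins exceed $|Z| > 2$; with the boundary fused
($\delta: 0.2 \to 1$), an insulation-gain call with peak $Z \ge 3$ overlaps
the deleted boundary (±2 bins) in at least 18 of 20 replicates.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally (BED-compatible);
  browser region strings are read as 1-based inclusive and converted.
* Contact maps are symmetrized on construction; symmetric inputs are
  required to ~1e-8 relative and enforced exactly thereafter.
* A bin partially overlapping a block or deletion edge is redistributed by
  overlap fraction, not dropped — deletions need not be bin-aligned.
* $P(s)$ ratios with undefined or zero denominator (or a target separation
  outside the source profile's support) drop the pair rather than
  extrapolate; the per-bin mask cannot express pair-level holes, so these
  appear as zeros and are excluded downstream by the positivity filter.
* A zero-length deletion yields the identity synteny map; liftover through
  it is the exact identity.
* Zero-variance Z tracks and fully tied Mann–Whitney inputs return 0 and
  p = 1 respectively, never NaN.
* Genome labels travel with every map and synteny object; composing a
  liftover against a map from the wrong genome is an error, not a silent
  misuse.
* Expected-profile smoothing (log-spaced pooling for sparse maps) exists
  but is off by default and flagged in the output when used.

## Problem sizes in the test suite

Unit tests run on 2–30-bin toys where brute-force oracles (base-pair-level
liftover enumeration, double-loop D scoring, full Mann–Whitney arrangement
enumeration) are exact and fast; the calibration and power studies run the
full 455-bin locus at depth $5 \times 10^6$ for 20 seeds per scenario, which
completes in well under a minute. These sizes were chosen to make every
stochastic claim reproducible at fixed seeds while keeping the suite quick
to iterate on.

## Known limitations

* Only deletions (and, through `synteny_map`, inversions) are modeled;
  duplications and translocations are out of scope.
* Balancing is VC_SQRT only — the method the targeted workflow uses — not
  KR/ICE.
* The statistic is one-dimensional in $k$; it localizes insulation changes
  but does not call loops or compartments.
* Inter-sample scaling (mean-total matching over the joint support) is a
  declared convention; with very large architectural changes the joint
  support itself shifts, which is why Z, not raw D, is the reported score.
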