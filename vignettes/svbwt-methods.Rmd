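---
title: "Breakpoint detection from the BWT of reads: model and methods"
author: "svbwt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breakpoint detection from the BWT of reads: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Somatic genomic rearrangements — deletions, duplications, inversions,
translocations and dispersed insertions — join two distant reference
positions $x_0 < y_0$ into a novel adjacency (a *junction*). In
paired-end whole-genome sequencing of a heterogeneous tumor with a
matched normal, the evidence for a junction is indirect: read pairs whose
insert spans it violate the paired-end mapping condition (inward
orientation at roughly one insert length) and become *discordant pairs*.
Discordant pairs localize a junction only to within an insert length;
split-read approaches recover base precision but lose sensitivity because
reads are much shorter than inserts. `svbwt` takes a third route: it
keeps the complete read collection in a lossless FM-index dictionary and
interrogates it directly around candidate regions, so junction-crossing
*fragments* of reads contribute evidence even when no aligner could have
placed them.

The pipeline has three stages:

1. discordant pairs are clustered in the plane $G \times G$ of global
   genome coordinates;
2. per cluster, the adjoint of the insert-length diffusion operator is
   applied to the empirical pair distribution and *breakpoint regions*
   are read off where the result is large;
3. the regions are scanned with unique anchor queries against the read
   dictionary, and junctions are called at drastic changes of the
   multivalued edit-distance functions of the leftward read extensions.

## Discordant geometry and orientation classes

All chromosomes are concatenated (separated by `$`) so every base has one
global coordinate. A pair becomes the point $(x, y)$, $x < y$, of the
global coordinates of the first sequenced bases of its two reads. The two
strands (after the swap) determine one of four *orientation classes*,
each the signature of one junction geometry:

| class      | strands | displacement of pairs from $(x_0, y_0)$ | spread direction |
|------------|---------|------------------------------------------|------------------|
| `del_like` | `+ -`   | $(-, +)$                                 | diagonal         |
| `dup_like` | `- +`   | $(+, -)$                                 | diagonal         |
| `inv_pp`   | `+ +`   | $(-, -)$                                 | anti-diagonal    |
| `inv_mm`   | `- -`   | $(+, +)$                                 | anti-diagonal    |

The mapping from strands to geometry is validated in the test suite by
forward simulation: donor genomes with one junction of each type are
sequenced error-free, mapped, and the resulting points are checked to lie
in the predicted quadrant with the predicted class.

Clustering uses the alternating sort–partition scheme: sort by the first
coordinate, split at gaps of at least the insert length $L$, re-sort each
group by the second coordinate, split again, and repeat until the
partition is stable. On well-separated data this coincides with
single-linkage connected components under "both axis gaps $< L$", which
the tests verify. Tumor and normal pairs are pooled for clustering; a
cluster is *somatic* when at least 90% of its pairs are tumor-derived
(`somatic_rate`). Clusters with fewer than `min_cluster_support = 3`
pairs are discarded as noise.

## The forward operator and its conjugate

For sonicated libraries the insert length is modeled as Gaussian
$N(L, \sigma)$ (defaults $L = 760$, $\sigma = 45$, or a median/MAD
estimate from accordant pairs). Given a junction at $(x_0, y_0)$ of class
`del_like`, a spanning insert of length $\ell$ with junction offset $u$
uniform in $(0, \ell)$ (no sonication bias) produces the pair

$$x = x_0 - u, \qquad y = y_0 + (\ell - u).$$

Equivalently, the density of pairs is the image of a point mass under a
composition of three commuting operators: a translation $T_L$ by $L/2$
into the class quadrant, a uniform diffusion $U_L$ of half-width $L/2$
along the class's spread diagonal, and a Gaussian diffusion $G_\sigma$.
For the other classes the displacement direction is rotated by 90, 180 or
270 degrees. The package discretizes the factors on per-cluster grids
(`bin` bases per cell, default 1 for the operator API and 2 in the
pipeline configuration):

* $T_L$: integer shift by $\mathrm{round}(L/2/\mathrm{bin})$ cells in
  each axis, signed per class;
* $U_L$: a uniform kernel over $2h+1$ diagonal (or anti-diagonal) steps,
  $h = \mathrm{round}(L/2/\mathrm{bin})$ — length $L + 1$ cells at 1-bp
  bins;
* $G_\sigma$: a separable per-axis Gaussian with per-axis scale
  $\sigma/\sqrt{2}$, truncated at four standard deviations and
  renormalized.

The per-axis scale $\sigma/\sqrt 2$ is a deliberate choice: the
generative law puts the Gaussian fluctuation $\ell - L$ into the
anti-diagonal coordinate $y - x$ exactly once, so the $y - x$ marginal of
the operator must have standard deviation $\sigma$. A separable kernel
with per-axis scale $\sigma/\sqrt 2$ achieves that (its small extra
diagonal smoothing is negligible against the width-$2L$ uniform factor);
a per-axis scale of $\sigma$ would inflate the insert-length marginal by
$\sqrt 2$. The test suite checks the discretized operator against direct
Monte-Carlo sampling of the two-step rule ($10^5$ pairs; marginal means
within sampling error, standard deviations within 2%).

The *conjugate* $A^{*}$ reverses the translation and reuses the two
self-adjoint diffusions. Applied to the empirical pair counts $y$ it
yields $z = A^{*}y$: for a single pair, $z$ peaks at the pair displaced
by $L/2$ against the class direction — the locus where its junction most
likely sits — and for many pairs the peaks reinforce at the consensus
overlap. Regions where $z \ge \tau \cdot \max z$ (relative threshold,
default $\tau = 0.5$; scale-free across coverages) are extracted as
8-connected components; each component's bounding box projects to region
A (first axis) and region B (second axis). The normal operator
$A^{*}A$ — the two translations cancel, $U_L$ acts twice, the Gaussians
compose to scale $\sqrt 2\,\sigma$ — is symmetric in both diagonal
directions, self-adjoint and positive semi-definite; all three properties
are verified numerically (adjointness to $10^{-8}$ relative error;
composite-form agreement limited only by the inexact composition of
*discrete* Gaussian kernels, about $10^{-4}$ of the peak at a scale of
two cells and far smaller at realistic scales). Only the single
application $z = A^{*}y$ is used for prediction; no iterative solve of
the normal equation is needed, and the normalizing constant of the
forward relation never has to be evaluated.

Grid padding of at least $L + 4\sigma$ on every side keeps the operator
mass on the grid; the operators verify this and refuse inputs whose mass
would leak by more than $10^{-3}$.

## Anchors, extensions and the scan

The reference (both strands, chromosomes split at runs of N) is indexed
in a suffix array with LCP structure, from which the package stores, for
every position, the *minimum length for uniqueness* (MLU): the shortest
rightward substring occurring exactly once in both strands. A scan query
at position $x$ is the genomic window of length $\mathrm{MLU}^+(x) +
\alpha$ (slack $\alpha = 3$ keeps spurious dictionary hits out);
positions with undefined MLU, or whose window would cross a segment
boundary, are skipped.

Reads of each sample (and their reverse complements, so sequencing strand
never matters) are indexed in a BWT/FM dictionary built by SA-IS suffix
sorting, with occurrence checkpoints every 64 symbols. The scan walks a
region side right to left, extended by `margin` (default one insert
length, mirroring the prediction uncertainty): each query is located by
backward search, and all leftward extensions up to $e = 20$ bases are
enumerated by recursive examination of the four possible bases, each
branch carrying its exact occurrence count (*support*). Besides maximal
branches, the scan also records prefixes at which read occurrences
terminate, so a junction crossed by reads that extend only 12 of 20
bases still yields a well-supported branch; branches shorter than
`min_branch_len = 14` are not accepted as junction evidence. The length
floor is a sequence-specificity bound: a candidate branch may carry
`low_thresh * len` edits against the partner, and an 11-mer with one
edit matches somewhere in a kilobase of partner sequence (both strands)
a few percent of the time, while a 14-mer with one edit does so at the
$10^{-4}$ level; 14 still leaves a 50-plus-base read window supporting
true junction branches at 40x coverage.

Each branch is scored by the minimum semi-global edit distance (Myers
bit-parallel dynamic program, verified against the classic DP) against
(i) its local reference context on the scanned side and (ii) both strands
of the partner region sequence, each normalized by the branch length.
Per scan position this yields the *multivalued edit-distance functions*
of the two regions. Reference-derived branches track their own region at
distance $\approx 0$ (SNPs and sequencing errors contribute at most a few
hundredths) and sit at the chance level ($\approx 0.25$–$0.3$) against
the partner; a junction-crossing branch drops below `low_thresh = 0.1`
against the partner while its own-region distance grows linearly past
`high_thresh = 0.3` — the drastic change. A call requires support
$\ge$ `min_support = 2` and a candidate run spanning at least
`min_positions = 2` scan positions: a real junction supports candidate
branches at every position within `low_thresh * e` bases to its right
(about three), whereas an isolated chance match cannot span a run.
Within a maximal run of candidate positions the
breakpoint is placed where the partner distance is smallest (ties towards
the deepest scanned position), and the partner coordinate is the branch's
best alignment end. The partner sequence is padded by
$e + \alpha + 4\sigma$ so junction-proximal extensions align fully even
when the predicted projection is slightly off-center.

A junction adjacency is crossed by leftward extensions in exactly two
scan geometries — one per side, using either the forward or the
reverse-complement strand entry of the region (the reverse passes reuse
the MLU table of the reverse-strand half of the genome index). Running
precisely those two passes per orientation class realizes the
"repeat with regions A and B swapped" confirmation: calls agreeing within
$2\alpha$ on both coordinates are merged and flagged `confirmed`. The
achieving partner strand must match the class expectation
(`strand_agrees`). A call is *somatic* when the matched normal's profiles
show no junction branch (at any support) within 5 bp of the same locus.
Short templated insertions at a junction are tolerated implicitly while
they keep the partner-distance floor below `low_thresh` (about
$0.1 \times e = 2$ bases); longer intervening sequence suppresses the
partner match and the junction is not called.

## The simulator

`sim_genome`, `add_snps`, `apply_rearrangements`, `sim_reads` and
`mix_purity` generate fully ground-truthed inputs: an i.i.d.-uniform
random reference; a normal genome with SNPs at 0.1%; a cancer genome with
a configurable number of events of each of six types, affected lengths
uniform in 300 bp–30 kb by default; 90-bp pairs read inward from
fragments with $N(760, 45)$ inserts, uniform fragment starts, i.i.d.
substitution errors at 0.1%; and purity mixing that draws an exact
fraction of pairs from the cancer read set without replacement. Junction
counts per event follow the adjacency bookkeeping: insertion 2,
deletion 1, inversion 2, tandem duplication 1, translocations 3
(cut-and-paste: one junction at the excision site, two at the
integration site) — 40 events of each type introduce exactly 480
junctions.

Insertions are *copied* from a distant genomic segment (dispersed
duplications). This is a deliberate design choice: material absent from
the reference cannot anchor the mate of any spanning pair once the event
is longer than the insert minus two read lengths, so fully novel
insertions are invisible to any discordant-pair method — and per-junction
accounting then also lacks a reference partner coordinate. Copied
insertions keep both junction partners on the reference and make the
inserted material mappable, which matches the detectability the method is
expected to show on this event class.

An internal exact-seed paired-end mapper (`map_read_pairs`) removes any
dependence on an external aligner: the first 30 bases are matched exactly
by backward search against both strands (with a pigeonhole split rescue
for a single seed mismatch), candidates are scored by full-length
mismatch count, a unique best placement gets MAPQ 60 and ties get 0, and
the proper-pair flag follows the standard inward-orientation test with a
$4\sigma$ template-length window.

What the simulator deliberately does not emulate: real repeat structure
and segmental duplications (the dominant source of ambiguous anchors on
real genomes), GC and sonication bias, indel sequencing errors, PCR and
optical duplicates, and library chimeras. Passing the simulation suite
therefore demonstrates the correctness and calibration of the method
under its own model assumptions — not its performance on a real tumor
genome, where MAPQ filtering, MLU-undefined regions and the somatic rule
carry much more of the burden.

## Problem sizes and numerical choices

The bundled study (`run_purity_study`, also driven by
`scripts/acceptance.R` and the acceptance tests) uses a 1-Mbp
two-chromosome genome, four events of each type with lengths 300 bp–5 kb,
40x coverage per sample, and tumor purities 100/20/10% mixed from a
separately drawn normal-genome read pool; the cancer genome and all read
pools are generated once and shared across purities. These sizes keep a
full sweep in the minutes range on one core while leaving roughly 20
inserts spanning each junction at full purity — the same physical-
coverage regime as a 40x human-scale run. Other fixed numerical choices:
grid bin 2 bp in the pipeline (operator parameters rescale with the bin;
prediction only needs region-level accuracy, and the scan re-derives
base-precise coordinates); Gaussian kernels truncated at $4\sigma$;
cluster and call deduplication tolerance 5 bp; truth matching for
evaluation within 10 bp on both coordinates; insert-sd estimates floored
at 1 bp. Sensitivity is the fraction of truth junctions matched by a call
within tolerance; the false-detection rate is the fraction of calls
matching no truth junction.

## Limitations

* Junctions whose anchors fall where the MLU is undefined (long exact
  repeats spanning a whole segment) cannot be queried; on random genomes
  this is negligible, on real genomes it tracks repeat content.
* Partner alignment is required for a call, so junctions into sequence
  absent from the reference (true novel insertions, viral integration)
  are not called.
* Tandem duplications shorter than the insert length merge both
  projections into one region; calls still resolve, but region
  accounting becomes conservative.
* The conjugate-operator prediction assumes the configured insert model;
  grossly misestimated $L$ or $\sigma$ displaces regions, which the scan
  margin (one insert length) absorbs only partially.
* Coverage below roughly 10 spanning inserts per junction (purity times
  depth) degrades branch support faster than cluster support; the
  10%-purity regime is near the method's sensitivity edge by design.
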