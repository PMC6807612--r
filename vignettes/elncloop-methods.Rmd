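---
title: "elncloop: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{elncloop: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`elncloop` studies enhancer lncRNAs (elncRNAs) — lncRNA genes
transcribed from active enhancers — and their relationship with
chromatin architecture: chromatin loops, enhancer–promoter (EP)
contacts, structuring-factor binding and G-quadruplex (G4) signal.
This vignette records the models, the tunable parameters and the design
decisions, in the spirit of the methods sections of mature omics
packages.

## Coordinate conventions

All plain tables (BED, BEDPE, contact lists, the gene-model table) use
0-based half-open coordinates; `GRanges` objects use the 1-based closed
Bioconductor convention. Conversion happens exactly once, at the
parser/writer boundary (`granges0()`, `granges_to_table()`), so no
module ever mixes conventions. Overlap means ≥ 1 shared bp; no
minimum-fraction option is offered because every rule in the analysis
is stated as bare overlap. `gap_distance()` is 0 for overlapping or
abutting intervals and `NA` across chromosomes (the undefined-distance
signal).

## Element definitions

* **Promoters**: `upstream = 2000`, `downstream = 500` bp around each
  TSS, strand-aware and clamped at position 0. One promoter per gene
  row; tables with several TSSs per gene simply repeat the gene id on
  several rows, and gene-level statements use the union of that gene's
  promoters.
* **Enhancer filtering** removes enhancers overlapping a protein-coding
  gene body or promoter. "Located in" is read as any overlap rather
  than full containment — the conservative choice, since partial
  overlap already places part of the element under coding regulation.
* **Active enhancers**: within `max_gap = 1000` bp of a GRO-seq-derived
  transcriptional-regulatory peak (gap 0 when overlapping/abutting; the
  1001-bp gap is inactive — the boundary is inclusive at 1000).
* **elncRNAs**: lncRNA gene spans (not just TSSs) overlapping ≥ 1
  active enhancer; each active enhancer back-links the elncRNA ids it
  overlaps.
* **Expression classes**: FPKM ≥ 0.21 (inclusive; the threshold is
  stated without strictness, and `≥` keeps the boundary value
  expressed) defines expressed lncRNAs; the expressed set is split at
  its median into low/high halves. Ties at the median go to the low
  half until the halves balance, so the rule is deterministic and
  seedless; `|low| − |high| ≤ 1` always.

## EP pairs and the distance-decay null

The interaction frequency of an (enhancer, promoter) pair is the summed
count of contact records with one end inside each element, in either
end order. Candidate pairs are all same-chromosome enhancer × promoter
combinations; pair distance is midpoint-to-midpoint (elements have
unequal widths and no convention is forced by the data).

Significance uses a simplified, one-pass form of the fit-HiC idea:

1. sort candidate pairs by distance and cut them into `n_bins = 100`
   **equal-occupancy** bins, each holding about the same total contact
   count (resolution concentrates where the data are);
2. estimate the per-pair expected contact probability in bin *b* as
   `p̂_b = (total count in b) / (N × pairs in b)` with *N* the total
   contact count;
3. enforce monotone non-increasing `p̂(d)` with weighted
   pool-adjacent-violators (weights = pairs per bin), which preserves
   the calibration identity `Σ pairs p̂ × N = Σ observed` exactly;
4. per pair, `p = P(X ≥ k)` with `X ~ Binomial(N, p̂(d))`; distances
   outside the modeled range use the nearest bin;
5. Benjamini–Hochberg over all pairs with `k ≥ 1`; retain `q < 0.001`
   (strict, matching the stated cutoff).

The original fit-HiC refits after removing outlier pairs; the one-pass
model keeps the contract (distance-corrected significance) at the
scale this package targets, and the simplification is stated here and
in the README. Raw counts (not matrix-balanced values) are the
contract: the frequency is defined as a read count. Group comparisons
use the two-sided pooled-variance Student's t-test (`compare_groups()`;
Welch behind a flag), reported always with group sizes.

## Loop-anchor analyses

Loops vary in span, so the relative-density profile maps each in-loop
feature point — TSS for stranded genes, midpoint otherwise — to
`(point − loop start)/(loop span)` and histograms it over
`n_rel_bins = 40` bins; values are rescaled to a per-10 kb density
using the mean loop span so profiles of unequal loops are comparable.
Bin counts always sum to the number of in-loop feature points.

Anchor fold-enrichment compares the mean number of anchors overlapped
per feature against the same statistic over length- and
chromosome-matched random intervals (default `n_random = 1000` draws,
seeded). Random starts are uniform over the positions at which the
interval fits the chromosome — equivalent to uniform placement with
rejection of out-of-bounds draws, without the rejection loop. Features
are put in canonical genomic order before drawing so the fold is
bit-reproducible and invariant under permutation of the input list.

Peak metaprofiles count peak midpoints per `binsize = 1000` bp bin in
±`flank = 50000` bp windows around anchor midpoints; the window size is
a package default, chosen to cover the anchor and its immediate
neighborhood at loop scale. Anchors are partitioned upstream of the
call (e.g. elncRNA-containing vs other, by gene-span overlap).
elncRNA-target anchors are anchors with ≥ 1 retained significant
contact to an elncRNA gene, using exactly the EP-pair machinery with
anchors in the enhancer role.

## Factor signals and clustering

Signal assignment modes: `max_value` (maximum overlapping MACS peak
value — ChIP-seq factors), `count` (number of overlapping peaks —
merged-TF panel) and `signal_track` (maximum overlapping track value —
G4-seq). Absent signal is 0, never missing. Each pair contributes two
columns per factor (enhancer side, promoter side), matching two-sided
heatmap displays.

Z-normalization is per column with the population (divide-by-*n*)
standard deviation — the plain Z-score formula carries no Bessel
correction; constant columns map to all-zero with a warning.
Clustering is agglomerative with distance `1 − Pearson r` between row
vectors and **average linkage**, cut to exactly *k* clusters (*k* is a
required parameter: 10 for elncRNA-associated pairs and 6 for others
in the default pipeline; no automatic selection). Average linkage is
the standard hierarchical mode of the classic Cluster software
tradition this analysis style follows; the linkage is a knob. Rows
with zero variance have undefined correlation and are placed at
distance 1 from all other rows. Pearson distance makes the clustering
invariant to positive affine transforms of rows — a property the tests
assert.

Cross-panel robustness: pairs are re-clustered on the 6-factor subset
(CTCF, RAD21, SMC3, RNA POLII, merged TFs, G4) and compared with the
10-factor labels by greedy maximal-overlap matching on the contingency
table; agreement is the percentage of rows whose matched cluster is
unchanged. Random labelings agree at ≈ 1/k.

## G4 classification

Profiles report, per bin, either the count of G4 interval midpoints
per element (interval input) or the mean per-bp signal (bedGraph
input), in ±2 kb windows (100-bp bins) around midpoints or TSSs;
TSS-referenced windows are strand-flipped so upstream is negative.
"Density" for the promoter/body comparison is total signal mass per bp
— the formula is not forced by the data, and mass-per-bp makes the two
regions comparable despite very different lengths. The gene body is
the gene span minus its promoter overlap; genes whose body vanishes
are excluded with a warning. A gene is promoter-biased iff promoter
density strictly exceeds body density; ties (including the zero–zero
case) fall to body-biased and are counted — this affects only
degenerate synthetic inputs. The two-group split is a direct density
comparison rather than a 2-means on the density pair: the rule is
deterministic, parameter-free and matches the verbal definition.

## Synthetic data: what it emulates, what it does not

`generate()` emits a toy genome (default 2 × 20 Mb chromosomes, 120
coding genes, 400 lncRNAs, 260 enhancers, 60 loops) with:

* enhancers rejection-sampled to respect the coding-region exclusion,
  plus ~10% planted-invalid enhancers inside coding regions so the
  filter stage has known casualties;
* GRO-seq peaks at a configurable fraction (default 0.5) of enhancers;
  planted elncRNAs (default 25% of lncRNAs) each overlap one active
  enhancer, and other active enhancers avoid lncRNAs so truth labels
  stay clean;
* contacts per candidate EP pair drawn Poisson with expectation
  `∝ d^−α` (α = 1, the classic intra-TAD decay scale), normalized to
  `total_contacts = 2 × 10⁵`, and multiplied by
  `elnc_pair_multiplier = 1.3` for elncRNA-associated pairs — the
  planted analogue of the higher interaction frequency of
  elncRNA-associated pairs;
* 60% of lncRNAs placed within 10% relative distance of a loop anchor
  (anchor-proximal enrichment), and higher anchor read counts for
  loops whose anchors hold an elncRNA;
* six planted factor signatures (architectural-only, RNAPII+YY1,
  merged-TF-rich, G4-rich, promoter-only, low-signal) with Gaussian
  noise on the raw scale. The low-signal cluster keeps a weak residual
  baseline on the enhancer-side TF columns no other signature
  occupies: a perfectly flat mean profile has no correlation structure
  and cannot constitute a cluster under a Pearson metric, while
  quiescent pairs in real data retain weak dispersed binding;
* G4 signal biased to promoters for half of the elncRNAs
  (`g4_promoter_bias_frac = 0.5`), with higher lognormal FPKM for the
  promoter-biased group.

`generate_null()` removes every planted effect (multiplier 1, no
signatures, no G4 bias, anchor-independent lncRNA placement, one
expression law) under the identical generative process, for type-I
error and calibration checks. Output is byte-deterministic for a fixed
config; truth tables record all planted labels.

What the generator does **not** emulate: read-level noise, replicate
structure, matrix-balancing artifacts, interchromosomal contacts,
chromatin-domain structure beyond the planted loops, and genome-scale
element counts. Passing tests therefore demonstrate that the machinery
recovers known structure under the stated statistical model, not that
real-data estimates are unbiased.

`simulate_class_counts()` deliberately shares one distance set between
the two pair classes so the realized mean-count ratio isolates the
planted multiplier from distance composition; with distances drawn
independently per class, distance-sampling noise alone would dominate
the ratio at a few thousand pairs.

## Numerical choices and problem sizes

* Equal-occupancy binning assigns zero-count pairs to the bin open at
  their distance rank; bins are forced contiguous in distance order.
* The PAVA smoother is weighted by pairs-per-bin, so the model's
  expected total equals the observed total exactly (calibration is a
  tested invariant, within 1%).
* Binomial p-values are exact upper tails; calibration tests use
  per-pair expectations around 700 counts so the discrete tail is
  effectively continuous — at shallow depth, exact-test p-values are
  conservative (super-uniform), which a two-sided uniformity test
  would flag as a discreteness artifact rather than a defect.
* Default test/acceptance problem sizes — 500–2000 candidate pairs,
  1200-row signal matrices, 10–50 replicate seeds — keep the whole
  suite around a minute while leaving Monte-Carlo noise well inside
  the asserted tolerances.
* All randomness flows through R's RNG from explicit seeds;
  `anchor_enrichment()` and the generator save and restore the global
  RNG state so library calls do not perturb user code.

## Known limitations

* The decay model is one-pass; no outlier-pair refinement pass.
* The binomial null ignores overdispersion between replicates (counts
  are pooled by contract).
* Anchor random-region matching controls length and chromosome but not
  GC content or mappability, which have no meaning in the synthetic
  genome but matter on real data.
* The clustering exposes exactly the distance the analysis names
  (centered Pearson); uncentered variants used by some legacy tools
  are not implemented.
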