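# elncloop

Enhancer long non-coding RNAs (elncRNAs) are lncRNA genes transcribed
from active enhancers. `elncloop` implements a genome-wide analysis of
how elncRNAs relate to chromatin architecture in a single cell type:

* **Element calling** — promoters as the 2 kb upstream / 0.5 kb
  downstream window around each TSS; enhancers filtered against coding
  promoters and gene bodies; *active* enhancers as those within 1 kb of
  a GRO-seq transcriptional-regulatory peak; *elncRNAs* as lncRNA genes
  overlapping an active enhancer; expressed lncRNAs (FPKM ≥ 0.21) split
  at the median into high/low halves.
* **Enhancer–promoter (EP) pairs from Hi-C** — the interaction frequency
  of a pair is the count of contact read pairs with one end in each
  element. Significance comes from a distance-decay binomial null: for a
  pair at distance *d* with count *k*,
  `p = P(X ≥ k), X ~ Binomial(N, p̂(d))`, where *N* is the total contact
  count and `p̂(d)` the expected per-pair contact probability estimated
  by equal-occupancy distance binning with monotone (pool-adjacent
  violators) smoothing — a simplified one-pass form of the fit-HiC idea.
  Pairs are kept at Benjamini–Hochberg `FDR < 0.001` and labelled
  elncRNA-associated when the enhancer overlaps an elncRNA.
* **Loop-anchor profiling** — relative lncRNA density across chromatin
  loops, fold enrichment of loop-anchor overlap against length- and
  chromosome-matched random regions, peak-count metaprofiles around
  anchors, and elncRNA-target anchors (anchors with a significant
  contact to an elncRNA gene).
* **Structuring-factor clustering** — per-pair signal of 10 factors
  (CTCF, RAD21, SMC3, RNA POLII, YY1, HDGF, GATAD2B, GABPA, G4-seq
  signal, merged TFs) on both elements, Z-score normalized per column
  (`Z_ij = (x_ij − μ_i)/δ_i`, population δ), hierarchically clustered
  with distance `1 − Pearson r` and average linkage; cross-panel
  agreement quantifies clustering robustness.
* **G-quadruplex classification** — G4 signal profiles around enhancers
  and TSSs, and a two-group split of elncRNAs by promoter vs gene-body
  G4 density (signal mass per bp).

A seeded synthetic-data generator (`sim_config()` / `generate()` /
`generate_null()`) emits all input formats with planted effects and
truth tables, so the whole pipeline is testable offline.

## Worked example

```r
library(elncloop)

bundle <- generate(sim_config(seed = 7))   # synthetic toy genome
rep <- run_all(bundle, seed = 3)
rep$summary[key %in% c("elncRNA_fraction", "pairs_retained",
                       "mean_if_elnc", "mean_if_other",
                       "anchor_enrichment_fold")]
#>                       key       value
#>                    <char>       <num>
#> 1:       elncRNA_fraction   0.2800000
#> 2:         pairs_retained 196.0000000
#> 3:           mean_if_elnc 274.4146341
#> 4:          mean_if_other 100.5000000
#> 5: anchor_enrichment_fold   5.7503246
```

28% of the simulated lncRNAs are called elncRNAs; 196 EP pairs survive
the FDR filter; the mean interaction frequency of elncRNA-associated
pairs (274.4) exceeds that of other pairs (100.5), reflecting the
planted contact-frequency multiplier amplified by the significance
filter; and elncRNAs overlap loop anchors ~5.8× more often than
length-matched random regions, reflecting anchor-proximal placement.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/elncloop.R simulate --out sim --seed 7
Rscript inst/scripts/elncloop.R run-all --in sim --out results --seed 3
```

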