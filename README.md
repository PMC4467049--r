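# regmut

Analysis of somatic *cis*-regulatory mutations in cancer genomes and
their impact on gene expression.

Tumor whole-genome sequencing reveals thousands of somatic mutations
outside protein-coding exons. `regmut` implements a pipeline for the
subset of the non-coding genome with the best functional annotation:
transcription factor binding sites (TFBSs) predicted within ChIP-seq peak
regions. It is aimed at cancer-genomics analysts who have per-sample
somatic VCFs, ChIP-seq peaks, JASPAR-style binding profiles and matched
expression, and want to know **which genes are dysregulated by mutations
in their regulatory elements**.

The pipeline stages, each exposed as package functions:

1. **TFBS prediction** — log-odds PWM scanning of both strands of every
   peak, keeping hits with relative score
   `(s − s_min)/(s_max − s_min) ≥ 0.85`.
2. **Mutation rates** — per-sample rates in TFBSs, protein-coding exons
   and their 1-kb flanks (feature-subtracted), with uniform
   shuffled-genome null replicates.
3. **Frequently targeted regions** — 1-kb sliding windows (500-bp step)
   with ≥ 3 TFBS-overlapping mutations; closest-TSS assignment (promoter
   = within 2 kb); hypergeometric promoter enrichment `P(X ≥ k)`.
4. **TFBS alteration scoring** — best-hit re-scan of the
   mutation-bearing alternative sequence (windows `2n−1` / `2n−2+i` /
   `2(n−1)` for SNV / insertion / deletion); deleterious when the
   alternative relative score is below 0.80; a queryable catalog of all
   possible SNV alterations per site.
5. **Mutation–expression integration** — a hierarchical-Bayes model
   coupling a per-gene variable `D` (gene influences expression when
   mutated) to per-patient variables `F` (this patient's mutation acts),
   with the μ ± 1σ expression states of the gene and its network
   neighbors as evidence, solved exactly by sum-product belief
   propagation on the per-gene tree.

A synthetic-cohort generator (`simulate_cohort()`) produces every input —
genome, annotations, motifs, peaks with planted sites, per-sample VCFs,
expression, network — with planted ground truth, so the whole pipeline is
testable without restricted-access patient data.

## Worked example

The `analysis/` directory holds the numbered workflow. From the
repository root:

```sh
Rscript analysis/01_simulate.R 1      # write the synthetic cohort
Rscript analysis/02_scan_tfbs.R       # predict TFBSs in the peaks
Rscript analysis/03_mutation_rates.R 1
Rscript analysis/04_hotspots.R
Rscript analysis/05_alterations.R
Rscript analysis/06_xseq.R
```

With seed 1 this prints, among other lines:

```
predicted 393 TFBS hits covering 4127 bp (11.46% of peak bp)
planted consensus site recovery at 85% threshold: 100.0%
...
shuffled null (200 replicates): TFBS > exon in 55% (expected ~50%)
...
cohort-1 example: 135/273 promoter (49%), p = 1.16e-75
cohort-2 example: 348/534 promoter (65%), p = 3.28e-156
...
predicted genes (Pr(D) >= 0.5, >= 2 samples at Pr(F) >= 0.5): gene021, gene029, gene057, gene058
planted drivers: gene058, gene057, gene021
recovery: recall 1.00, precision 0.75
```

Reading: the scan recovers every planted consensus site at the 0.85
threshold; under the shuffled null the TFBS and exon rates are
exchangeable (≈ 50%); the two promoter-enrichment worked examples
recompute the published hypergeometric p-values from their printed
counts; and the expression model recovers the three planted driver genes
(here with one false positive, a gene whose coding mutations coincide
with chance expression tails). Stage outputs land as TSV/BED under
`results/`.

In code, the same end-to-end run is:

```r
library(regmut)
sim <- simulate_cohort(sim_config(seed = 1))
res <- run_pipeline(sim, pipeline_config(seed = 1))
res$xseq$predictions$genes
```

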