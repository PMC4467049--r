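---
title: "Methods: cis-regulatory somatic mutations and expression dysregulation"
author: "regmut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cis-regulatory somatic mutations and expression dysregulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

Whole-genome sequencing of tumor–normal pairs yields somatic single
nucleotide variants (SNVs) and small insertions/deletions (indels) across
the whole genome, but most interpretation effort has gone into the ~2% of
the genome that codes for protein. `regmut` implements an analysis of the
complementary *cis*-regulatory space: transcription factor binding sites
(TFBSs) predicted within ChIP-seq peak regions. The pipeline

1. predicts TFBSs by position weight matrix (PWM) scanning of peaks,
2. compares somatic mutation rates in TFBSs, protein-coding exons and
   their 1-kb flanks against shuffled-genome nulls,
3. finds *frequently targeted regions* — 1-kb windows holding three or
   more TFBS-overlapping mutations — assigns each mutation to its closest
   transcription start site (TSS), and tests promoter enrichment with the
   hypergeometric distribution,
4. scores each mutation's impact on its TFBS by re-scanning the
   mutation-bearing alternative sequence, and
5. integrates the mutation matrix with matched RNA-seq expression over a
   gene-interaction network in a hierarchical-Bayes model solved by belief
   propagation, yielding `Pr(D)` per gene (the gene influences expression
   when mutated) and `Pr(F)` per gene–patient (that patient's mutation
   acts).

A synthetic-data generator produces every input with planted ground truth,
so each stage is testable end to end without access to patient data.

# TFBS prediction

A position frequency matrix (PFM) with columns $i$ and base counts
$c_{b,i}$ is converted to a log-odds PWM with a background-proportional
pseudocount $p$ over background $q_b$:

$$w_{b,i} = \log_2 \frac{(c_{b,i} + p\,q_b) / (\sum_b c_{b,i} + p)}{q_b}.$$

Defaults are a uniform background and $p = 0.8$, the convention of the
standard PFM-to-PWM lineage; both are configurable because published scans
rarely state them, and exact reproduction of any particular external TFBS
set is not attempted. Each PWM stores its minimal and maximal attainable
scores, and a window's *relative score* is
$(s - s_\min) / (s_\max - s_\min)$, which normalizes thresholds across
motifs of different lengths and information content; hits are windows on
either strand with relative score at least 0.85, the conventional cutoff.
Windows containing `N` are penalized with the column minimum by default (a
conservative choice; a skip policy is available). Best-hit ties break to
the lowest start coordinate, then the forward strand, so outputs are
deterministic.

# Mutation rates and nulls

A mutation's reference footprint is the mutated base (SNV), the deleted
bases (deletion), or the single VCF anchor base (insertion) — a zero-length
event between bases needs a convention, and the anchor base keeps overlap
semantics consistent through VCF round trips. Rates divide the number of
mutations whose footprint intersects a feature set by the *merged* length
of that set, so duplicated or overlapping features never inflate the
denominator. Flanks are the 1-kb intervals on each side of every feature,
clipped to the chromosome, with the feature union subtracted. The null
model repositions every mutation uniformly over the genome, preserving
per-sample counts and indel lengths; replicates are indexed so any single
shuffled genome can be regenerated in isolation from the base seed.

# Hotspots and promoter enrichment

Windows of 1 kb advance in 500-bp steps (`bedtools makewindows`
arithmetic: one window per step start below the chromosome length,
truncated at the end), and windows with at least three TFBS-overlapping
mutations are retained; with step < size a mutation can support two
windows. Each mutation is assigned the gene whose TSS is closest to its
footprint midpoint (midpoint is symmetric for indels; ties break to the
lexicographically smaller gene identifier, with a warning), and it counts
as a promoter mutation when that distance is at most 2 kb. Enrichment of
promoters among hotspot mutations uses the upper tail
$P(X \ge k)$ of the hypergeometric distribution, computed in log space;
the strict tail $P(X > k)$ is available behind a flag, but the
at-least-observed convention is the default because it reproduces the
published worked examples exactly.

# Alteration scoring

For a motif of length $n$, the shortest sequence containing every motif
placement that overlaps a variant has length $2n-1$ for an SNV (centered),
$2n-2+i$ for an insertion of $i$ bp (inserted bases centered) and
$2(n-1)$ for a deletion (deletion point centered). Reference and
alternative windows are scanned in best-hit mode on both strands; a
mutation is deleterious for a TFBS when the alternative best relative
score falls strictly below 0.80. The reference window for an indel spans
the same reference coordinates as the alternative construction implies
(the insertion locus treated as zero-length; the deletion span included),
so both windows carry comparable context — the symmetric-context
convention is ours and is documented rather than asserted as universal.
One record is emitted per (mutation, TF) pair, and a catalog precomputing
all $3n$ possible SNV alterations per site supports point queries by
(chromosome, position, alternative allele); it is an indexed in-memory
table with a TSV round trip, standing in for a document database backend.

# The expression model

Preprocessing flags a gene in a sample as up- (down-) regulated when its
log-scale expression exceeds $\mu + \sigma$ (falls below $\mu - \sigma$),
with $\mu, \sigma$ taken over all tumor samples including the tested one
(a leave-one-out variant is available but off by default, matching the
stated preprocessing of the source analyses). The mutation matrix sets
entry (patient, gene) to 1 for any qualifying coding mutation
(default classes: nonsense, missense, frameshift, splice-site,
start/stop-altering; expression is *not* filtered for coding entries), or
for a TFBS-overlapping mutation whose closest gene is dysregulated in
that patient. Provenance (`coding` / `cis` / `both`) and supporting
alteration records are retained per entry.

The probabilistic model couples, per gene, a population-level variable
$D$ to per-patient variables $F^p$, which in turn explain the expression
states $E$ of the gene and its network neighbors in that patient:

* $D \in \{\text{null}, \text{down}, \text{up}\}$. The direction component
  is a design choice: recurrently predicted cancer genes are typically
  dysregulated the same way in every affected sample (an oncogene is up
  wherever its mutation acts), and carrying the direction lets concordant
  patients reinforce each other while chance flags, which split between
  directions, do not. `Pr(D)` is the probability of the non-null states,
  so the Bernoulli reading is preserved.
* $P(F^p \ne \text{null} \mid D \ne \text{null}) = \beta$ and
  $P(F^p \ne \text{null} \mid D = \text{null}) = \varepsilon$, with an
  acting $F^p$ following $D$'s direction with probability 0.9. The
  penetrance is provenance-aware: $\beta_{cis} = 0.9$ for cis entries —
  they reach the matrix only after the expression-concordance filter and
  carry TFBS-alteration support, so conditional on inclusion they very
  likely act — versus $\beta_{coding} = 0.5$ for unfiltered coding entries,
  which include passengers. $\varepsilon = 0.05$, prior
  $P(D \ne \text{null}) = 0.1$ split equally between directions.
* Expression evidence enters, by default, as the observed
  $\mu \pm 1\sigma$ flag state of the gene and each neighbor
  (`evidence = "flag"`). The conditional tables are calibrated against
  that rule's Gaussian null exceedance $2(1 - \Phi(1)) \approx 0.317$:
  under $F = \text{null}$ a flag appears at exactly that rate, so chance
  tails neither mimic evidence nor, crucially, dilute it — a patient with
  neutral expression is close to evidence-neutral for $D$. When the
  mutation acts, the gene itself flags with probability 0.7 (a 2-sd shift
  under the $\mu\pm\sigma$ rule, after the shift itself inflates
  $\hat\sigma$) and a neighbor with probability 0.45 (≈ 60% response
  × detection). A soft-emission mode (`evidence = "mixture"`) attaches the
  per-gene mixture densities instead; it is kept as an option because the
  mixture's tail components absorb the very signal being tested, which
  weakens the likelihood ratios on cohorts of this size.

The per-gene graph (D at the root, one $F^p$ per mutated patient, one
$E$ per patient × {gene, neighbors}) is a tree, so sum-product belief
propagation is exact; the engine is a generic flooding-schedule
implementation with a convergence flag so loopy extensions degrade
gracefully. Tests verify BP marginals against exhaustive enumeration on
graphs up to 12 variables at $10^{-6}$.

Post-processing reports genes with `Pr(D)` at or above a threshold
(fixed, default 0.5, or read off the `Pr(D)` histogram at the first local
minimum above the largest low-probability peak — the peak is formed by
genes mutated in single samples, for which the all-samples probability is
poorly determined) and with `Pr(F)` at least 0.5 in at least two samples,
which guards against single-sample false positives. Each reported
(gene, sample) carries its mutation category (coding / TFBS / both, with
a deleterious variant annotated).

## Expression mixtures

The three-state Gaussian location mixture per gene (down / neutral / up)
is fit by EM with ordered means. A plain maximum-likelihood fit is poorly
identified at cohort scale: on unimodal data a tail component drifts into
the bulk, and a ~20% shifted subpopulation is happily merged into a
widened neutral component (an unconstrained equal-variance fit shows the
same behavior). The estimator is therefore regularized: two starts
(moment-based at $\mu \pm 2\sigma$, and quantile-anchored at the mean of
the outer 7.5% tails), component scales tied within
$[0.5, 1.1] \times$ a robust core scale (the smaller of the two
side-specific mads, so a shifted subpopulation does not widen its own
gate), tail means kept at least 1.7 core-sds from the median, a 2%
weight floor so no component dies irrecoverably, and the
better-likelihood start reported. Constant genes collapse to a single
neutral component. The regularization trades a modest downward bias in
the recovered tail weight for stability.

# The synthetic cohort

The generator's defaults are the benchmark conditions used throughout the
tests: one 1-Mb chromosome at GC 0.41 (human-like), 60 genes (three
200-bp exons each, promoter = TSS ± 2 kb), 8 motifs of 8–12 bp with at
least half their columns dominated (≥ 70% of counts on one base), 120
non-overlapping 300-bp peaks — half anchored in promoters — each with two
embedded motif instances (consensus, or one mismatch with probability
0.1), 50 samples with background SNVs at $10^{-4}$/bp and indels
(1–10 bp) at $10^{-5}$/bp placed uniformly, 3 driver genes each receiving
one SNV at the highest-information-content column of a planted promoter
site in 5 samples (substituting the lowest-weight base — mutations at
high-information-content positions are the most disruptive to binding),
expression shifts of 2 gene-sds in driver-mutated samples with 60% of
each driver's network neighbors responding in consistent per-neighbor
directions, and an Erdős–Rényi gene graph of mean degree 4.

What it emulates: the coordinate plumbing, cohort structure, planted
effect sizes and the uniform-mutation null of the study design. What it
does not: mutational signatures and sequence-context rate variation,
mappability, linked germline variation, realistic regulatory grammar
(motif co-occurrence, competition), distal enhancer–promoter wiring, and
scale-free network topology. Passing recovery tests therefore show the
machinery is correct and calibrated under the stated assumptions — not
that real cohorts behave this benignly. Real-cohort aggregate counts
(genome-wide TFBS coverage, per-cohort mutation totals, specific gene
lists) depend on restricted-access data and external resources and are
out of scope.

Every random draw flows from one seed through named substreams (one per
generator stage, one per shuffle replicate), so whole cohorts and single
replicates are reproducible in isolation, and two runs from one seed are
byte-identical.

# Numerical and design notes

* Intervals use `GenomicRanges` (1-based, closed) internally — the native
  currency of the Bioconductor stack this package builds on; conversions
  are confined to the BED (0-based half-open, handled by `rtracklayer`)
  and VCF boundaries. All interval arithmetic (unions, subtraction,
  overlap) is delegated to `IRanges`.
* Sliding-window construction follows `bedtools makewindows`: a window at
  every step start below the chromosome length, truncated at the end —
  i.e. `ceiling(L / step)` windows for a chromosome of length `L`.
* The hypergeometric tail is computed via `phyper(..., log.p = TRUE)`;
  p-values around $10^{-156}$ are well inside double range but the
  log-space path keeps the monotonicity tests exact.
* The EM, BP and selection thresholds, and every stage cutoff (0.85 scan,
  0.80 deleterious, 1 kb/500 bp windows, 3-mutation minimum, 2-kb
  promoter, 1-kb flanks) sit in one `pipeline_config()` object.
* Problem sizes in the test-suite: oracle comparisons use motifs ≤ 6 bp on
  sequences ≤ 50 bp and factor graphs ≤ 12 variables; null calibration
  uses 200 shuffled replicates of a ~5,000-mutation cohort; recovery runs
  three 50-sample cohorts. These sizes give stable statistics while
  keeping the whole suite to a few minutes.

# Known limitations

* The closest-TSS rule ignores distal regulation; the enhancer analysis is
  a generic overlap against a user-supplied BED.
* The expression model's conditional tables are calibrated to the
  generator's effect sizes; on real cohorts β, ε and the flag
  probabilities should be treated as tunable and ideally learned.
* Indel alterations are scored on demand but not precomputed in the
  catalog (which enumerates SNVs only).
* The germline-repeat labeling heuristic implements one documented reading
  of an ambiguous rule (repeat end minus indel start versus distance to
  the nearest normal-sample indel); it is exposed as a pure function so
  alternative readings are easy to test.
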