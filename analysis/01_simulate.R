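#!/usr/bin/env Rscript
# Generate the synthetic study cohort: a 1-Mb genome with 60 annotated
# genes, 8 TF motifs, 120 ChIP-seq peaks with planted binding sites,
# 50 tumor samples with background SNVs/indels plus promoter-TFBS driver
# mutations in 3 genes, and matched expression over a gene network.
# All downstream analysis scripts read the files written here.

suppressMessages(library(regmut))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

cfg <- sim_config(seed = seed)
sim <- simulate_cohort(cfg)
dir <- "results/sim"
write_simulation(sim, dir)

cat(sprintf("cohort written to %s\n", dir))
cat(sprintf("  genome: %d chromosome(s) x %d bp, GC %.3f\n",
            cfg$n_chroms, cfg$chrom_length,
            as.numeric(Biostrings::letterFrequency(sim$genome[[1]], "GC")) /
              cfg$chrom_length))
cat(sprintf("  genes: %d (drivers: %s)\n", cfg$n_genes,
            paste(sim$truth$driver_genes, collapse = ", ")))
cat(sprintf("  peaks: %d with %d planted sites (%d consensus)\n",
            length(sim$peaks), nrow(sim$truth$sites),
            sum(sim$truth$sites$is_consensus)))
cat(sprintf("  mutations: %d (%d SNV, %d indel) across %d samples\n",
            nrow(sim$mutations), sum(sim$mutations$kind == "SNV"),
            sum(sim$mutations$kind != "SNV"), cfg$n_samples))
cat(sprintf("  planted driver mutations: %d; planted expression shifts: %d\n",
            nrow(sim$truth$driver_mutations),
            nrow(sim$truth$expression_shifts)))
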