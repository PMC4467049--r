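#!/usr/bin/env Rscript
# Score the impact of cis-regulatory mutations on their TFBSs by
# re-scanning mutation-bearing alternative sequences (best hit on both
# strands), flag deleterious alterations (alternative relative score below
# 80%), and demonstrate the precomputed SNV alteration catalog on one peak.

suppressMessages(library(regmut))

dir <- "results/sim"
genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
hits <- read_hits_bed("results/tfbs_hits.bed")
pwms <- lapply(read_jaspar(file.path(dir, "motifs.pfm")), pfm_to_pwm)
muts <- read_somatic_vcf_dir(file.path(dir, "vcf"))

cis <- overlap_count(muts, hits)$overlapping
alt <- score_alterations(cis, hits, genome, pwms,
                         deleterious_threshold = 0.80)
utils::write.table(alt, "results/alterations.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("scored %d (mutation, TF) pairs from %d cis mutations\n",
            nrow(alt), nrow(cis)))
cat(sprintf("deleterious (alt relative score < 0.80): %d (%.0f%%)\n",
            sum(alt$deleterious, na.rm = TRUE),
            100 * mean(alt$deleterious, na.rm = TRUE)))
cat(sprintf("mean score loss among deleterious: %.2f bits\n",
            mean(alt$delta_score[alt$deleterious], na.rm = TRUE)))

# catalog of every possible SNV in the TFBSs of the first peak
peak1 <- rtracklayer::import(file.path(dir, "peaks.bed"))[1]
h1 <- hits[IRanges::overlapsAny(hits, peak1)]
cat_dt <- build_catalog(h1, genome, pwms)
write_catalog(cat_dt, "results/catalog_peak1.tsv")
cat(sprintf("catalog for peak 1: %d records over %d TFBSs (3 per site bp)\n",
            nrow(cat_dt), length(h1)))
q <- catalog_query(cat_dt, cat_dt$chrom[1], cat_dt$pos[1], cat_dt$alt[1])
cat(sprintf("example query %s:%d>%s -> alt relative score %.3f\n",
            q$chrom[1], q$pos[1], q$alt[1], q$alt_relative_score[1]))
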