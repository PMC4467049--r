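#!/usr/bin/env Rscript
# Predict TFBSs inside the ChIP-seq peaks by scanning both strands with the
# log-odds PWMs at the 85% relative-score threshold, and measure how many
# planted consensus sites the scan recovers.

suppressMessages(library(regmut))

dir <- "results/sim"
genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
peaks <- rtracklayer::import(file.path(dir, "peaks.bed"))
pwms <- lapply(read_jaspar(file.path(dir, "motifs.pfm")), pfm_to_pwm)

sc <- scan_peaks(peaks, genome, pwms, threshold = 0.85)
write_hits_bed(sc$hits, "results/tfbs_hits.bed")

truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                             simplifyVector = TRUE)
cons <- truth$sites[truth$sites$is_consensus, ]
gr <- GenomicRanges::GRanges(cons$chrom,
                             IRanges::IRanges(cons$start, cons$end))
rec <- mean(IRanges::overlapsAny(gr, sc$hits, type = "equal"))

cat(sprintf("predicted %d TFBS hits covering %d bp (%.2f%% of peak bp)\n",
            length(sc$hits), sc$coverage_bp,
            100 * sc$coverage_bp / sum(GenomicRanges::width(peaks))))
cat(sprintf("planted consensus site recovery at 85%% threshold: %.1f%%\n",
            100 * rec))
cat("hits written to results/tfbs_hits.bed\n")
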