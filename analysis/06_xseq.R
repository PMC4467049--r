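#!/usr/bin/env Rscript
# Integrate mutations with expression over the gene network: build the
# patient-gene mutation matrix (coding mutations plus expression-concordant
# cis mutations), infer Pr(D) per gene and Pr(F) per gene-sample by belief
# propagation, select predictions, and compare with the planted drivers.

suppressMessages(library(regmut))

dir <- "results/sim"
genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
hits <- read_hits_bed("results/tfbs_hits.bed")
pwms <- lapply(read_jaspar(file.path(dir, "motifs.pfm")), pfm_to_pwm)
muts <- read_somatic_vcf_dir(file.path(dir, "vcf"))
tss <- read_tss(file.path(dir, "tss.tsv"))
expr <- filter_null_expression(read_expression(file.path(dir, "expression.tsv")))
network <- read_network(file.path(dir, "network.tsv"))
coding <- utils::read.table(file.path(dir, "coding.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)

cis <- overlap_count(muts, hits)$overlapping
alt <- score_alterations(cis, hits, genome, pwms)
alt <- assign_closest_tss(alt, tss)

mm <- suppressWarnings(build_mutation_matrix(alt, coding, expr))
post <- infer_posteriors(mm, expr, network)
sel <- select_predictions(post, mm, pr_d_threshold = 0.5,
                          pr_f_threshold = 0.5, min_samples = 2)

utils::write.table(
  data.frame(gene = names(post$pr_d), pr_d = unname(post$pr_d)),
  "results/xseq_pr_d.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(sel$cells, "results/xseq_predictions.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("mutation matrix: %d genes x %d samples, %d entries (%d cis-supported)\n",
            ncol(mm$matrix), nrow(mm$matrix), sum(mm$matrix),
            sum(mm$provenance %in% c("cis", "both"))))
cat(sprintf("predicted genes (Pr(D) >= 0.5, >= 2 samples at Pr(F) >= 0.5): %s\n",
            paste(sel$genes$gene, collapse = ", ")))

truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                             simplifyVector = TRUE)
drivers <- truth$driver_genes
recall <- mean(drivers %in% sel$genes$gene)
precision <- if (nrow(sel$genes)) mean(sel$genes$gene %in% drivers) else NA
cat(sprintf("planted drivers: %s\n", paste(drivers, collapse = ", ")))
cat(sprintf("recovery: recall %.2f, precision %.2f\n", recall, precision))
cat(sprintf("category breakdown: %s\n",
            paste(names(table(sel$cells$category)),
                  table(sel$cells$category), sep = "=", collapse = ", ")))
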