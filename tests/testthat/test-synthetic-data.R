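# Generator contracts: counts, determinism, planted-truth integrity.

test_that("genome generation honours the configuration", {
  cfg <- sim_config(seed = 2, chrom_length = 1e5, n_genes = 10,
                    n_peaks = 10, n_samples = 4, n_driver_genes = 2,
                    driver_hit_samples = 2)
  g <- simulate_genome(cfg)
  expect_equal(length(g$genome), 1L)
  expect_equal(Biostrings::width(g$genome)[[1]], 1e5)
  expect_equal(nrow(g$tss), 10L)
  # determinism: same config, same seed, byte-identical
  g2 <- simulate_genome(cfg)
  expect_identical(as.character(g$genome), as.character(g2$genome))
  expect_identical(g$genes, g2$genes)
  # sizing error
  expect_error(simulate_genome(sim_config(chrom_length = 1e4, n_genes = 50)),
               "too small")
})

test_that("generated G+C fraction is within 3 binomial sd of the target", {
  cfg <- sim_config(seed = 4, gc_fraction = 0.5, chrom_length = 1e6,
                    n_genes = 10)
  g <- simulate_genome(cfg)
  gc <- Biostrings::letterFrequency(g$genome[[1]], "GC") / 1e6
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 1e6))
})

test_that("motifs are detectable: dominated columns, equal sums, consensus scores 1", {
  cfg <- sim_config(seed = 5, n_tfs = 5)
  pfms <- simulate_motifs(cfg)
  expect_length(pfms, 5L)
  for (pf in pfms) {
    cs <- colSums(pf$counts)
    expect_true(all(cs == cs[1]))
    dom_frac <- mean(apply(pf$counts, 2, max) >= 0.7 * cs[1])
    expect_gte(dom_frac, 0.5)
    pw <- pfm_to_pwm(pf)
    best <- scan_sequence(consensus(pf), pw, mode = "best")
    expect_equal(best$relative_score, 1)
  }
})

test_that("peaks carry the configured number of planted sites within bounds", {
  sim <- small_sim()
  cfg <- sim$config
  expect_equal(length(sim$peaks), cfg$n_peaks)
  expect_equal(nrow(sim$truth$sites), cfg$n_peaks * cfg$sites_per_peak)
  # all planted sites inside their peak and on the chromosome
  s <- sim$truth$sites
  expect_true(all(s$start >= 1 & s$end <= cfg$chrom_length))
  pk <- sim$peaks[s$peak]
  expect_true(all(s$start >= GenomicRanges::start(pk) &
                  s$end <= GenomicRanges::end(pk)))
  # every planted consensus instance scores >= 0.85 under its own PWM
  for (i in which(s$is_consensus)[1:10]) {
    seq_i <- as.character(Biostrings::subseq(sim$genome[[s$chrom[i]]],
                                             s$start[i], s$end[i]))
    pw <- pfm_to_pwm(sim$pfms[[s$tf_name[i]]])
    best <- scan_sequence(seq_i, pw, mode = "best")
    expect_gte(best$relative_score, 0.85)
  }
})

test_that("per-sample SNV counts follow the configured Poisson background", {
  cfg <- sim_config(seed = 8, chrom_length = 1e6, n_genes = 20,
                    background_snv_rate = 1e-4, n_samples = 10,
                    n_driver_genes = 1, driver_hit_samples = 1)
  sim <- simulate_cohort(cfg)
  counts <- table(sim$mutations$sample_id[sim$mutations$kind == "SNV"])
  # Poisson mean 100, sd 10; driver SNVs add at most 1
  expect_true(all(abs(counts - 100) <= 4 * 10 + 1))
})

test_that("planted driver mutations are exact products and lie inside planted sites", {
  sim <- small_sim()
  dm <- sim$truth$driver_mutations
  cfg <- sim$config
  expect_equal(nrow(dm), cfg$n_driver_genes * cfg$driver_hit_samples)
  sites <- sim$truth$sites
  for (i in seq_len(nrow(dm))) {
    inside <- any(sites$chrom == dm$chrom[i] & sites$start <= dm$pos[i] &
                  sites$end >= dm$pos[i])
    expect_true(inside)
    # ref allele matches the genome
    expect_identical(as.character(Biostrings::subseq(
      sim$genome[[dm$chrom[i]]], dm$pos[i], dm$pos[i])), dm$ref[i])
    expect_false(dm$ref[i] == dm$alt[i])
  }
})

test_that("expression shifts are planted at the configured magnitude and flagged", {
  cfg <- sim_config(seed = 13)
  sim <- simulate_cohort(cfg)
  sh <- sim$truth$expression_shifts
  expect_gt(nrow(sh), 0)
  dys <- dysregulation_matrix(sim$expression)
  flagged <- mapply(function(s, g) dys[g, s] != "none",
                    sh$sample_id, sh$gene_id)
  # 2-sd directional shifts exceed the mu +/- 1 sigma rule in most cases
  # (sigma is inflated by the planted shifts themselves)
  expect_gte(mean(flagged), 0.6)
  # direction agrees where flagged
  dir_ok <- mapply(function(s, g, d) dys[g, s] %in% c("none", d),
                   sh$sample_id, sh$gene_id, sh$direction)
  expect_true(all(dir_ok))
  expect_equal(dim(sim$expression),
               c(cfg$n_genes, cfg$n_samples))
  expect_false(anyNA(sim$expression))
})

test_that("two cohort runs from one seed are identical, different seeds differ", {
  a <- small_sim(seed = 6)
  b <- small_sim(seed = 6)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$expression, b$expression)
  expect_identical(a$network, b$network)
  c_ <- small_sim(seed = 7)
  expect_false(identical(a$mutations, c_$mutations))
})

test_that("all emitted intervals lie on their chromosomes", {
  sim <- small_sim()
  L <- sim$config$chrom_length
  for (gr in list(sim$peaks, sim$exons, sim$promoters)) {
    expect_true(all(GenomicRanges::start(gr) >= 1))
    expect_true(all(GenomicRanges::end(gr) <= L))
    expect_true(all(GenomicRanges::start(gr) <= GenomicRanges::end(gr)))
  }
})

test_that("a simulated cohort round-trips through the on-disk formats", {
  sim <- small_sim(seed = 9)
  dir <- tempfile("simdir")
  write_simulation(sim, dir)
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_identical(as.character(genome[[1]]), as.character(sim$genome[[1]]))
  peaks <- rtracklayer::import(file.path(dir, "peaks.bed"))
  expect_equal(GenomicRanges::start(peaks), GenomicRanges::start(sim$peaks))
  muts <- read_somatic_vcf_dir(file.path(dir, "vcf"))
  expect_equal(nrow(muts), nrow(sim$mutations))
  m0 <- sim$mutations[order(sim$mutations$sample_id, sim$mutations$chrom,
                            sim$mutations$pos, sim$mutations$alt), ]
  m1 <- muts[order(muts$sample_id, muts$chrom, muts$pos, muts$alt), ]
  rownames(m0) <- rownames(m1) <- NULL
  expect_equal(m0, m1)
  expr <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(expr, sim$expression)
  tss <- read_tss(file.path(dir, "tss.tsv"))
  expect_equal(tss$gene_id, sim$tss$gene_id)
})
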