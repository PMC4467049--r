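# Overlap counting, mutation rates, flanks, shuffled nulls, and the indel
# germline-repeat heuristic.

snv_at <- function(pos, chrom = "chr1", sample = "s1") {
  mutation_table(sample, chrom, pos, rep("A", length(pos)),
                 rep("C", length(pos)))
}

test_that("overlap counting matches hand examples and the all-pairs oracle", {
  feat <- GenomicRanges::GRanges("chr1", IRanges::IRanges(16, 25))
  m <- snv_at(c(11, 21, 31))
  expect_equal(overlap_count(m, feat)$count, 1L)
  expect_equal(overlap_count(m, GenomicRanges::GRanges())$count, 0L)
  set.seed(31)
  m2 <- snv_at(sample.int(1e4, 1000, replace = TRUE))
  fs <- sort(sample.int(1e4, 100))
  feats <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(fs, fs + sample.int(50, 100, TRUE)))
  got <- overlap_count(m2, feats)$count
  fp <- mutation_footprint(m2)
  expect_equal(got, bf_overlap_count(GenomicRanges::start(fp),
                                     GenomicRanges::end(fp),
                                     GenomicRanges::start(feats),
                                     GenomicRanges::end(feats)))
})

test_that("indel footprints follow the VCF anchor convention", {
  m <- mutation_table(c("s", "s", "s"), "chr1", c(10, 20, 30),
                      c("A", "A", "ACGT"), c("C", "ACC", "A"))
  expect_equal(m$kind, c("SNV", "insertion", "deletion"))
  fp <- mutation_footprint(m)
  expect_equal(GenomicRanges::start(fp), c(10, 20, 31))
  expect_equal(GenomicRanges::end(fp), c(10, 20, 33))
})

test_that("mutation rate uses the merged feature length", {
  feat <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(1, 101, 101), c(200, 300, 300)))
  m <- snv_at(c(50, 150))
  r <- mutation_rate(m, feat)
  expect_equal(r$feature_bp, 300)  # duplicates and overlaps merged
  expect_equal(r$n_mutations, 2L)
  expect_equal(r$rate, 2 / 300)
  r2 <- mutation_rate(snv_at(c(10, 20)),
                      GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 400)))
  expect_equal(r2$rate, 0.005)
  expect_error(mutation_rate(m, GenomicRanges::GRanges()), "zero")
})

test_that("TFBS mutation rate on uniform synthetic data matches the genome rate", {
  sim <- simulate_cohort(sim_config(
    seed = 12, chrom_length = 5e5, n_genes = 30, n_peaks = 60,
    n_samples = 20, n_driver_genes = 2, driver_hit_samples = 3))
  hits <- scan_peaks(sim$peaks, sim$genome,
                     lapply(sim$pfms, pfm_to_pwm))$hits
  # background only: planted driver SNVs are deliberately inside TFBSs
  dm <- sim$truth$driver_mutations
  bg <- sim$mutations[sim$mutations$kind == "SNV" &
                        !paste(sim$mutations$sample_id, sim$mutations$pos) %in%
                          paste(dm$sample_id, dm$pos), ]
  n <- overlap_count(bg, hits)$count
  lambda <- nrow(bg) * feature_bp(hits) / sim$config$chrom_length
  expect_lt(abs(n - lambda), 4 * sqrt(lambda) + 1)
})

test_that("flanking regions are clipped, subtracted, and disjoint from features", {
  lens <- c(chr1 = 10000L)
  f1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1100))
  fl <- flanking_regions(f1, 1000, lens)
  expect_equal(GenomicRanges::start(fl), c(1, 1101))
  expect_equal(GenomicRanges::end(fl), c(1000, 2100))
  # a second feature carves a hole in the right flank
  f2 <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(1001, 1151), c(1100, 1200)))
  fl2 <- flanking_regions(f2, 1000, lens)
  expect_true(all(GenomicRanges::countOverlaps(fl2, f2) == 0))
  expect_true(any(GenomicRanges::start(fl2) == 1101 &
                  GenomicRanges::end(fl2) == 1150))
  # boundary clip at the chromosome start
  f3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 300))
  fl3 <- flanking_regions(f3, 1000, lens)
  expect_equal(GenomicRanges::start(fl3)[1], 1)
  expect_equal(GenomicRanges::end(fl3)[1], 200)
  # property: flanks never intersect the features, for random features
  set.seed(17)
  fs <- sort(sample.int(9000, 50))
  fr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(fs, fs + sample.int(200, 50, TRUE)))
  flr <- flanking_regions(fr, 1000, lens)
  expect_equal(sum(GenomicRanges::countOverlaps(flr, fr)), 0L)
})

test_that("shuffled genomes preserve counts, are seed-reproducible, and uniform", {
  sim <- small_sim(seed = 15)
  m <- sim$mutations
  lens <- sim$chrom_lengths
  s1 <- shuffle_mutations(m, lens, seed = 5, index = 1)
  expect_equal(nrow(s1), nrow(m))
  expect_equal(table(s1$sample_id), table(m$sample_id))
  expect_equal(nchar(s1$ref), nchar(m$ref))  # indel lengths preserved
  expect_identical(shuffle_mutations(m, lens, seed = 5, index = 1), s1)
  expect_false(identical(shuffle_mutations(m, lens, seed = 5, index = 2), s1))
  # deletions stay fully on-chromosome
  fp <- mutation_footprint(s1)
  expect_true(all(GenomicRanges::end(fp) <= lens["chr1"]))
  # uniformity: fraction landing in a fixed tenth of the genome
  feat <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, lens[[1]] / 10))
  frac <- overlap_count(s1, feat)$count / nrow(m)
  expect_lt(abs(frac - 0.1), 4 * sqrt(0.1 * 0.9 / nrow(m)))
})

test_that("rate comparison reproduces exact regression cases", {
  r <- suppressWarnings(compare_rates(data.frame(
    sample_id = c("a", "b"), exon_rate = c(1, 2), tfbs_rate = c(2, 4))))
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 0)
  expect_equal(r$r_squared, 1)
  same <- suppressWarnings(compare_rates(data.frame(
    sample_id = c("a", "b", "c"), exon_rate = c(1, 2, 3),
    tfbs_rate = c(1, 2, 3))))
  expect_equal(same$fraction_tfbs_gt_exon, 0)
  expect_equal(same$slope, 1)
  expect_error(compare_rates(data.frame(sample_id = c("a", "b"),
                                        exon_rate = c(1, 1),
                                        tfbs_rate = c(1, 2))), "constant")
})

test_that("tandem repeats spanning an indel are found with unit lengths 1-6", {
  seq <- paste0(paste(rep("G", 20), collapse = ""),
                paste(rep("AT", 6), collapse = ""),
                paste(rep("C", 20), collapse = ""))
  rr <- find_repeat_region(seq, 25, max_unit = 6)
  expect_equal(rr$start, 21)
  expect_equal(rr$end, 32)
  expect_null(find_repeat_region("ACGTGCATTGCA", 5))
  hp <- find_repeat_region(paste(rep("A", 10), collapse = ""), 4)
  expect_equal(hp$start, 1)
  expect_equal(hp$end, 10)
})

test_that("indels are labelled germline only when the repeat outreaches the normal indel", {
  # repeat spanning [96,110], indel start 100, normal indel 3 bp away:
  # distance 10 > 3 -> germline
  rr <- list(start = 96, end = 110)
  expect_equal(label_indel_germline(100, rr, 3), "germline")
  expect_equal(label_indel_germline(100, rr, 15), "somatic")
  expect_equal(label_indel_germline(100, NULL, 3), "somatic")
  expect_equal(label_indel_germline(100, rr, NA), "somatic")
})
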