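# Synthetic cohort generator with planted ground truth. Every input the
# pipeline consumes (genome, annotations, motifs, peaks with embedded
# sites, per-sample mutations, expression, network) is generated from one
# seed, with the planted truth recorded so downstream recall/precision can
# be computed without re-reading generator internals.

#' Simulation configuration
#'
#' Defaults encode the benchmark conditions used throughout the package's
#' tests: a 1-Mb genome, 50 tumor samples, 3 planted driver genes each with
#' a promoter-TFBS mutation in 5 samples, 2-sd expression shifts in the
#' driver-mutated samples and directional shifts in 60% of each driver's
#' network neighbors.
#'
#' @param seed Integer master seed; every stage derives a named substream.
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param gc_fraction G+C fraction of the background sequence.
#' @param n_genes,exons_per_gene Gene count and exons per gene.
#' @param n_tfs Number of transcription factor motifs.
#' @param motif_length_range Motif length range in bp (min >= 4).
#' @param n_peaks,peak_length ChIP-seq peak count and width (bp).
#' @param sites_per_peak Planted motif instances per peak.
#' @param promoter_peak_fraction Fraction of peaks placed inside promoters.
#' @param site_mismatch_prob Probability a planted (non-driver) site carries
#'   one mismatch from the consensus.
#' @param n_samples Number of tumor samples.
#' @param background_snv_rate,background_indel_rate Background mutation
#'   rates (mutations/bp).
#' @param n_driver_genes Number of planted driver genes.
#' @param driver_hit_samples Samples carrying a planted promoter-TFBS
#'   mutation per driver.
#' @param expression_shift_sd_units Planted expression shift, in units of
#'   the gene's own standard deviation.
#' @param network_mean_degree Mean degree of the random gene graph.
#' @param neighbor_shift_fraction Probability each driver neighbor responds
#'   (shifts) in the driver-mutated samples.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 1L, chrom_length = 1e6,
                       gc_fraction = 0.41,
                       n_genes = 60L, exons_per_gene = 3L,
                       n_tfs = 8L, motif_length_range = c(8L, 12L),
                       n_peaks = 120L, peak_length = 300L,
                       sites_per_peak = 2L,
                       promoter_peak_fraction = 0.5,
                       site_mismatch_prob = 0.1,
                       n_samples = 50L,
                       background_snv_rate = 1e-4,
                       background_indel_rate = 1e-5,
                       n_driver_genes = 3L, driver_hit_samples = 5L,
                       expression_shift_sd_units = 2,
                       network_mean_degree = 4,
                       neighbor_shift_fraction = 0.6) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              gc_fraction = gc_fraction, n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              n_tfs = as.integer(n_tfs),
              motif_length_range = as.integer(motif_length_range),
              n_peaks = as.integer(n_peaks),
              peak_length = as.integer(peak_length),
              sites_per_peak = as.integer(sites_per_peak),
              promoter_peak_fraction = promoter_peak_fraction,
              site_mismatch_prob = site_mismatch_prob,
              n_samples = as.integer(n_samples),
              background_snv_rate = background_snv_rate,
              background_indel_rate = background_indel_rate,
              n_driver_genes = as.integer(n_driver_genes),
              driver_hit_samples = as.integer(driver_hit_samples),
              expression_shift_sd_units = expression_shift_sd_units,
              network_mean_degree = network_mean_degree,
              neighbor_shift_fraction = neighbor_shift_fraction)
  stopifnot(cfg$background_snv_rate >= 0, cfg$background_indel_rate >= 0,
            cfg$motif_length_range[1L] >= 4L,
            cfg$motif_length_range[1L] <= cfg$motif_length_range[2L],
            cfg$driver_hit_samples <= cfg$n_samples,
            cfg$gc_fraction > 0, cfg$gc_fraction < 1,
            cfg$n_driver_genes <= cfg$n_genes,
            cfg$promoter_peak_fraction >= 0,
            cfg$promoter_peak_fraction <= 1,
            cfg$neighbor_shift_fraction >= 0,
            cfg$neighbor_shift_fraction <= 1)
  structure(cfg, class = "sim_config")
}

# Gene body layout constants (bp).
EXON_WIDTH <- 200L
INTRON_WIDTH <- 300L
PROMOTER_HALF <- 2000L

#' Generate a random genome with gene annotations
#'
#' Chromosome sequences are i.i.d. bases at the configured G+C fraction.
#' Genes are placed non-overlapping (with promoter-sized margins), each with
#' a strand, a TSS and `exons_per_gene` exons laid out in transcription
#' direction; the promoter is TSS +/- 2 kb clipped to the chromosome.
#'
#' @param config A [sim_config()].
#' @return A list: `genome` (named `DNAStringSet`), `chrom_lengths`, `genes`
#'   (data.frame `gene_id`, `chrom`, `start`, `end`, `strand`, `tss_pos`),
#'   `tss` (TSS table for [assign_closest_tss()]), `exons` (`GRanges`),
#'   `promoters` (`GRanges` with `gene_id`).
#' @export
simulate_genome <- function(config) {
  body_len <- config$exons_per_gene * EXON_WIDTH +
    (config$exons_per_gene - 1L) * INTRON_WIDTH
  slot <- body_len + 2L * PROMOTER_HALF + 500L
  per_chrom <- ceiling(config$n_genes / config$n_chroms)
  if (per_chrom * slot > config$chrom_length) {
    stop("chrom_length too small to place ", config$n_genes,
         " genes (need >= ", per_chrom * slot, " bp per chromosome)")
  }
  with_seed(substream_seed(config$seed, 11L), {
    probs <- c((1 - config$gc_fraction) / 2, config$gc_fraction / 2,
               config$gc_fraction / 2, (1 - config$gc_fraction) / 2)
    seqs <- vapply(seq_len(config$n_chroms), function(i) {
      paste(sample(BASES, config$chrom_length, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1L))
    names(seqs) <- paste0("chr", seq_len(config$n_chroms))
    genome <- Biostrings::DNAStringSet(seqs)
    chrom_lengths <- stats::setNames(rep(config$chrom_length,
                                         config$n_chroms), names(seqs))
    # round-robin gene placement in jittered slots
    chrom_of <- rep(names(seqs), length.out = config$n_genes)
    idx_on_chrom <- stats::ave(seq_len(config$n_genes), chrom_of,
                               FUN = seq_along)
    slot_width <- config$chrom_length %/% per_chrom
    jitter_max <- slot_width - body_len - 2L * PROMOTER_HALF
    starts <- (idx_on_chrom - 1L) * slot_width + PROMOTER_HALF + 1L +
      floor(stats::runif(config$n_genes) * max(1L, jitter_max))
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    genes <- data.frame(
      gene_id = sprintf("gene%03d", seq_len(config$n_genes)),
      chrom = chrom_of,
      start = as.integer(starts),
      end = as.integer(starts + body_len - 1L),
      strand = strand,
      stringsAsFactors = FALSE)
    genes$tss_pos <- ifelse(genes$strand == "+", genes$start, genes$end)
    ex <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
      off <- (seq_len(config$exons_per_gene) - 1L) *
        (EXON_WIDTH + INTRON_WIDTH)
      es <- if (genes$strand[i] == "+") genes$start[i] + off
            else genes$end[i] - off - EXON_WIDTH + 1L
      data.frame(chrom = genes$chrom[i], start = es,
                 end = es + EXON_WIDTH - 1L, gene_id = genes$gene_id[i],
                 stringsAsFactors = FALSE)
    }))
    exons <- GenomicRanges::GRanges(ex$chrom,
                                    IRanges::IRanges(ex$start, ex$end),
                                    gene_id = ex$gene_id)
    promoters <- GenomicRanges::GRanges(
      genes$chrom,
      IRanges::IRanges(pmax(1L, genes$tss_pos - PROMOTER_HALF),
                       pmin(config$chrom_length,
                            genes$tss_pos + PROMOTER_HALF)),
      gene_id = genes$gene_id)
    list(genome = genome, chrom_lengths = chrom_lengths, genes = genes,
         tss = genes[, c("gene_id", "chrom", "tss_pos", "strand")],
         exons = exons, promoters = promoters)
  })
}

#' Generate detectable random motifs
#'
#' Each PFM has equal column sums (100 counts) and at least half of its
#' columns dominated by one base holding at least 70% of the counts, so
#' planted consensus instances stand out against the background.
#'
#' @param config A [sim_config()].
#' @return A named list of `pfm` objects (`TF1`, `TF2`, ...).
#' @export
simulate_motifs <- function(config) {
  stopifnot(config$n_tfs >= 1L)
  with_seed(substream_seed(config$seed, 23L), {
    pfms <- lapply(seq_len(config$n_tfs), function(t) {
      n <- sample(seq(config$motif_length_range[1L],
                      config$motif_length_range[2L]), 1L)
      dominated <- rep(FALSE, n)
      dominated[sample.int(n, ceiling(n / 2))] <- TRUE
      dominated <- dominated | stats::runif(n) < 0.3
      counts <- vapply(seq_len(n), function(i) {
        col <- numeric(4L)
        if (dominated[i]) {
          dom <- sample.int(4L, 1L)
          col[dom] <- 85
          col[-dom] <- sample(c(7, 5, 3))
        } else {
          col <- sample(c(40, 30, 20, 10))
        }
        col
      }, numeric(4L))
      pfm(counts, tf_name = sprintf("TF%d", t))
    })
    names(pfms) <- vapply(pfms, function(p) p$tf_name, character(1L))
    pfms
  })
}

# One-mismatch variant of a consensus string (random column, random
# non-consensus base).
mismatch_site <- function(site_seq) {
  i <- sample.int(nchar(site_seq), 1L)
  b <- sample(setdiff(BASES, substr(site_seq, i, i)), 1L)
  substr(site_seq, i, i) <- b
  site_seq
}

#' Generate ChIP-seq peaks with planted motif instances
#'
#' Picks `n_driver_genes` driver genes, anchors one peak inside each
#' driver's promoter, places the remaining peaks half in random promoters
#' and half in intergenic background (all peaks non-overlapping), and embeds
#' `sites_per_peak` motif instances per peak into the genome sequence:
#' consensus, or one mismatch with probability `site_mismatch_prob` (driver
#' promoter sites are always consensus so the disruption signal is
#' guaranteed). The returned genome carries the embedded sites.
#'
#' @param config A [sim_config()].
#' @param gen Output of [simulate_genome()].
#' @param pfms Output of [simulate_motifs()].
#' @return A list: `genome` (modified), `peaks` (`GRanges`), `sites`
#'   (data.frame: `chrom`, `start`, `end`, `strand`, `tf_name`,
#'   `is_consensus`, `peak`, `gene_id` of the promoter if any),
#'   `driver_genes` (character), `driver_sites` (rows of `sites`, one per
#'   driver).
#' @export
simulate_peaks <- function(config, gen, pfms) {
  with_seed(substream_seed(config$seed, 37L), {
    max_n <- max(vapply(pfms, function(p) p$n, integer(1L)))
    chunk <- config$peak_length %/% config$sites_per_peak
    if (chunk < max_n + 2L) {
      stop("peak_length too small for ", config$sites_per_peak,
           " sites of up to ", max_n, " bp")
    }
    genes <- gen$genes
    drivers <- sample(genes$gene_id, config$n_driver_genes)
    n_promoter <- max(config$n_driver_genes,
                      round(config$promoter_peak_fraction * config$n_peaks))
    other_prom_genes <- sample(setdiff(genes$gene_id, drivers),
                               min(n_promoter - config$n_driver_genes,
                                   nrow(genes) - config$n_driver_genes))
    prom_genes <- c(drivers, other_prom_genes)
    occupied <- GenomicRanges::GRanges()
    peaks <- list()
    place_in_promoter <- function(g) {
      row <- genes[genes$gene_id == g, ]
      lo <- max(1L, row$tss_pos - PROMOTER_HALF)
      hi <- min(config$chrom_length,
                row$tss_pos + PROMOTER_HALF) - config$peak_length
      for (try in 1:50) {
        st <- lo + floor(stats::runif(1L) * max(1L, hi - lo))
        cand <- GenomicRanges::GRanges(row$chrom,
                                       IRanges::IRanges(st, st + config$peak_length - 1L))
        if (!any(IRanges::overlapsAny(cand, occupied))) return(cand)
      }
      stop("could not place a promoter peak for ", g)
    }
    for (g in prom_genes) {
      p <- place_in_promoter(g)
      p$gene_id <- g
      occupied <- c(occupied, GenomicRanges::granges(p))
      peaks[[length(peaks) + 1L]] <- p
    }
    n_bg <- config$n_peaks - length(peaks)
    gene_space <- GenomicRanges::reduce(c(
      GenomicRanges::GRanges(genes$chrom,
                             IRanges::IRanges(pmax(1L, genes$start - PROMOTER_HALF),
                                              pmin(config$chrom_length,
                                                   genes$end + PROMOTER_HALF)))))
    tries <- 0L
    while (n_bg > 0L) {
      tries <- tries + 1L
      if (tries > 200L * config$n_peaks) {
        stop("overlap-free peak placement impossible at this density")
      }
      chrom <- sample(names(gen$chrom_lengths), 1L)
      st <- 1L + floor(stats::runif(1L) *
                         (gen$chrom_lengths[[chrom]] - config$peak_length))
      cand <- GenomicRanges::GRanges(chrom,
                                     IRanges::IRanges(st, st + config$peak_length - 1L))
      if (any(IRanges::overlapsAny(cand, occupied)) ||
          any(IRanges::overlapsAny(cand, gene_space))) next
      cand$gene_id <- NA_character_
      occupied <- c(occupied, GenomicRanges::granges(cand))
      peaks[[length(peaks) + 1L]] <- cand
      n_bg <- n_bg - 1L
    }
    peaks <- do.call(c, peaks)
    # embed sites
    genome <- gen$genome
    sites <- list()
    for (i in seq_along(peaks)) {
      chrom <- as.character(GenomicRanges::seqnames(peaks))[i]
      pstart <- GenomicRanges::start(peaks)[i]
      is_driver_peak <- !is.na(peaks$gene_id[i]) &&
        peaks$gene_id[i] %in% drivers
      for (k in seq_len(config$sites_per_peak)) {
        tf <- sample(names(pfms), 1L)
        n <- pfms[[tf]]$n
        off <- (k - 1L) * chunk + 1L +
          floor(stats::runif(1L) * (chunk - n))
        st <- pstart + off - 1L
        strand <- sample(c("+", "-"), 1L)
        cons <- consensus(pfms[[tf]])
        keep_consensus <- (is_driver_peak && k == 1L) ||
          stats::runif(1L) >= config$site_mismatch_prob
        site_seq <- if (keep_consensus) cons else mismatch_site(cons)
        emb <- if (strand == "+") site_seq else
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(site_seq)))
        genome[[chrom]] <- Biostrings::replaceAt(
          genome[[chrom]], IRanges::IRanges(st, st + n - 1L),
          Biostrings::DNAString(emb))
        sites[[length(sites) + 1L]] <- data.frame(
          chrom = chrom, start = st, end = st + n - 1L, strand = strand,
          tf_name = tf, is_consensus = keep_consensus, peak = i,
          gene_id = peaks$gene_id[i], stringsAsFactors = FALSE)
      }
    }
    sites <- do.call(rbind, sites)
    driver_sites <- do.call(rbind, lapply(drivers, function(g) {
      cand <- sites[!is.na(sites$gene_id) & sites$gene_id == g &
                      sites$is_consensus, ]
      cand[1L, ]
    }))
    list(genome = genome, peaks = peaks, sites = sites,
         driver_genes = drivers, driver_sites = driver_sites)
  })
}

# Per-column information content (bits) of a PFM.
pfm_ic <- function(x) {
  p <- sweep(x$counts, 2L, colSums(x$counts), "/")
  2 + colSums(ifelse(p > 0, p * log2(p), 0))
}

#' Generate per-sample somatic mutations with planted drivers
#'
#' Background SNVs and indels are Poisson-distributed per sample and placed
#' uniformly over the genome (the shuffled-null assumption). Each planted
#' driver gene additionally receives, in `driver_hit_samples` samples, one
#' SNV at the highest-information-content column of its planted promoter
#' site, substituting the base with the lowest weight at that column — the
#' most disruptive possible change.
#'
#' @param config A [sim_config()].
#' @param genome The (site-embedded) genome from [simulate_peaks()].
#' @param chrom_lengths Named chromosome lengths.
#' @param pfms Motif list.
#' @param driver_sites Data.frame of one planted consensus site per driver
#'   (from [simulate_peaks()]).
#' @return A list: `mutations` (mutation table over all samples),
#'   `driver_mutations` (data.frame: `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `gene_id`, `tf_name`).
#' @export
simulate_mutations <- function(config, genome, chrom_lengths, pfms,
                               driver_sites) {
  with_seed(substream_seed(config$seed, 53L), {
    total_bp <- sum(as.numeric(chrom_lengths))
    chroms <- names(chrom_lengths)
    samples <- sprintf("S%02d", seq_len(config$n_samples))
    draw_positions <- function(n, span = 1L) {
      ci <- sample.int(length(chroms), n, replace = TRUE,
                       prob = as.numeric(chrom_lengths) / total_bp)
      maxp <- as.numeric(chrom_lengths)[ci] - span + 1
      data.frame(chrom = chroms[ci],
                 pos = as.integer(1 + floor(stats::runif(n) * maxp)))
    }
    base_at <- function(chrom, pos, len = 1L) {
      vapply(seq_along(chrom), function(i) {
        as.character(Biostrings::subseq(genome[[chrom[i]]], pos[i],
                                        pos[i] + len - 1L))
      }, character(1L))
    }
    muts <- list()
    for (s in samples) {
      n_snv <- stats::rpois(1L, config$background_snv_rate * total_bp)
      if (n_snv > 0L) {
        loc <- draw_positions(n_snv)
        ref <- base_at(loc$chrom, loc$pos)
        alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L),
                      character(1L), USE.NAMES = FALSE)
        muts[[length(muts) + 1L]] <- mutation_table(s, loc$chrom, loc$pos,
                                                    ref, alt)
      }
      n_ind <- stats::rpois(1L, config$background_indel_rate * total_bp)
      if (n_ind > 0L) {
        len <- sample(1:10, n_ind, replace = TRUE)
        is_ins <- stats::runif(n_ind) < 0.5
        loc <- draw_positions(n_ind, span = len + 1L)
        ref <- character(n_ind); alt <- character(n_ind)
        for (j in seq_len(n_ind)) {
          anchor <- base_at(loc$chrom[j], loc$pos[j])
          if (is_ins[j]) {
            ref[j] <- anchor
            alt[j] <- paste0(anchor, paste(sample(BASES, len[j],
                                                  replace = TRUE),
                                           collapse = ""))
          } else {
            ref[j] <- base_at(loc$chrom[j], loc$pos[j], len[j] + 1L)
            alt[j] <- anchor
          }
        }
        muts[[length(muts) + 1L]] <- mutation_table(s, loc$chrom, loc$pos,
                                                    ref, alt)
      }
    }
    # planted driver SNVs at the max-IC column of the driver promoter site
    driver_recs <- list()
    for (d in seq_len(nrow(driver_sites))) {
      site <- driver_sites[d, ]
      pw <- pfm_to_pwm(pfms[[site$tf_name]])
      ic <- pfm_ic(pfms[[site$tf_name]])
      col <- which.max(ic)
      pos <- if (site$strand == "+") site$start + col - 1L
             else site$end - col + 1L
      ref <- base_at(site$chrom, pos)
      worst <- BASES[which.min(pw$weights[, col])]
      alt <- if (site$strand == "+") worst else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(worst)))
      if (alt == ref) {  # consensus already worst? pick next-lowest base
        ord <- BASES[order(pw$weights[, col])]
        alt_site <- setdiff(ord, if (site$strand == "+") ref else
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(ref))))[1L]
        alt <- if (site$strand == "+") alt_site else
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(alt_site)))
      }
      hit_samples <- sample(samples, config$driver_hit_samples)
      for (s in hit_samples) {
        muts[[length(muts) + 1L]] <- mutation_table(s, site$chrom, pos,
                                                    ref, alt)
        driver_recs[[length(driver_recs) + 1L]] <- data.frame(
          sample_id = s, chrom = site$chrom, pos = pos, ref = ref,
          alt = alt, gene_id = site$gene_id, tf_name = site$tf_name,
          stringsAsFactors = FALSE)
      }
    }
    list(mutations = do.call(rbind, muts),
         driver_mutations = do.call(rbind, driver_recs))
  })
}

#' Generate expression and a gene-interaction network with planted shifts
#'
#' Baseline log-scale expression is Normal per gene across samples. In each
#' sample carrying a planted driver mutation, the driver gene is shifted by
#' `expression_shift_sd_units` gene-sds in a per-driver direction, and each
#' of its network neighbors responds (is shifted in its own consistent
#' direction) independently with probability `neighbor_shift_fraction`. The
#' network is an Erdos-Renyi graph over all genes at the configured mean
#' degree.
#'
#' @param config A [sim_config()].
#' @param genes Gene table from [simulate_genome()].
#' @param driver_mutations Data.frame from [simulate_mutations()].
#' @return A list: `expression` (genes x samples matrix), `network`
#'   (data.frame `gene_a`, `gene_b`, `weight`), `graph` (`igraph`),
#'   `shifts` (data.frame `sample_id`, `gene_id`, `direction`).
#' @export
simulate_expression <- function(config, genes, driver_mutations) {
  with_seed(substream_seed(config$seed, 71L), {
    gid <- genes$gene_id
    samples <- sprintf("S%02d", seq_len(config$n_samples))
    g <- igraph::sample_gnp(length(gid),
                            p = min(1, config$network_mean_degree /
                                      (length(gid) - 1L)))
    igraph::V(g)$name <- gid
    mu <- stats::rnorm(length(gid), 6, 1)
    sdv <- stats::runif(length(gid), 0.8, 1.2)
    expr <- matrix(stats::rnorm(length(gid) * length(samples)),
                   length(gid), length(samples),
                   dimnames = list(gid, samples))
    expr <- expr * sdv + mu
    shifts <- list()
    drivers <- unique(driver_mutations$gene_id)
    for (d in drivers) {
      dir_d <- sample(c(-1, 1), 1L)
      hit <- driver_mutations$sample_id[driver_mutations$gene_id == d]
      nbrs <- names(igraph::neighbors(g, d))
      responsive <- nbrs[stats::runif(length(nbrs)) <
                           config$neighbor_shift_fraction]
      dir_nb <- stats::setNames(sample(c(-1, 1), length(responsive),
                                       replace = TRUE), responsive)
      for (s in hit) {
        expr[d, s] <- expr[d, s] +
          dir_d * config$expression_shift_sd_units * sdv[match(d, gid)]
        shifts[[length(shifts) + 1L]] <- data.frame(
          sample_id = s, gene_id = d,
          direction = ifelse(dir_d > 0, "up", "down"),
          stringsAsFactors = FALSE)
        for (nb in responsive) {
          expr[nb, s] <- expr[nb, s] +
            dir_nb[nb] * config$expression_shift_sd_units *
            sdv[match(nb, gid)]
          shifts[[length(shifts) + 1L]] <- data.frame(
            sample_id = s, gene_id = nb,
            direction = ifelse(dir_nb[nb] > 0, "up", "down"),
            stringsAsFactors = FALSE)
        }
      }
    }
    edges <- igraph::as_data_frame(g, what = "edges")
    network <- data.frame(gene_a = edges$from, gene_b = edges$to,
                          weight = 1, stringsAsFactors = FALSE)
    list(expression = expr, network = network, graph = g,
         shifts = if (length(shifts)) do.call(rbind, shifts) else
           data.frame(sample_id = character(0), gene_id = character(0),
                      direction = character(0)))
  })
}

#' Generate a full synthetic cohort with planted truth
#'
#' Runs all generator stages from one seed and assembles the planted truth
#' (driver genes, site intervals, disrupting mutations, expression shifts).
#' A coding-annotation table (background mutations overlapping exons,
#' labelled `missense`) emulates the output of an external variant
#' annotator.
#'
#' @param config A [sim_config()].
#' @return A list with `config`, `genome`, `chrom_lengths`, `genes`, `tss`,
#'   `exons`, `promoters`, `pfms`, `peaks`, `mutations`, `coding`,
#'   `expression`, `network`, `graph`, and `truth` (list: `driver_genes`,
#'   `sites`, `driver_mutations`, `expression_shifts`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  gen <- simulate_genome(config)
  pfms <- simulate_motifs(config)
  pk <- simulate_peaks(config, gen, pfms)
  mu <- simulate_mutations(config, pk$genome, gen$chrom_lengths, pfms,
                           pk$driver_sites)
  ex <- simulate_expression(config, gen$genes, mu$driver_mutations)
  fp <- mutation_footprint(mu$mutations)
  ov <- GenomicRanges::findOverlaps(fp, gen$exons, ignore.strand = TRUE)
  coding <- unique(data.frame(
    sample_id = mu$mutations$sample_id[S4Vectors::queryHits(ov)],
    gene_id = gen$exons$gene_id[S4Vectors::subjectHits(ov)],
    impact = "missense", stringsAsFactors = FALSE))
  list(config = config, genome = pk$genome,
       chrom_lengths = gen$chrom_lengths, genes = gen$genes, tss = gen$tss,
       exons = gen$exons, promoters = gen$promoters, pfms = pfms,
       peaks = pk$peaks, mutations = mu$mutations, coding = coding,
       expression = ex$expression, network = ex$network, graph = ex$graph,
       truth = list(driver_genes = pk$driver_genes, sites = pk$sites,
                    driver_sites = pk$driver_sites,
                    driver_mutations = mu$driver_mutations,
                    expression_shifts = ex$shifts))
}

#' Write a simulated cohort to a directory of standard-format files
#'
#' FASTA genome, BED6 peaks/planted sites/exons, TSS TSV, JASPAR motifs,
#' one VCF per sample, expression TSV, edge-list TSV, and a JSON truth file.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  rtracklayer::export(sim$peaks, file.path(dir, "peaks.bed"))
  sites_gr <- GenomicRanges::GRanges(
    sim$truth$sites$chrom,
    IRanges::IRanges(sim$truth$sites$start, sim$truth$sites$end),
    strand = sim$truth$sites$strand, name = sim$truth$sites$tf_name)
  rtracklayer::export(sites_gr, file.path(dir, "planted_sites.bed"))
  rtracklayer::export(sim$exons, file.path(dir, "exons.bed"))
  utils::write.table(sim$tss, file.path(dir, "tss.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_jaspar(sim$pfms, file.path(dir, "motifs.pfm"))
  vcf_dir <- file.path(dir, "vcf")
  dir.create(vcf_dir, showWarnings = FALSE)
  for (s in unique(sim$mutations$sample_id)) {
    write_somatic_vcf(sim$mutations[sim$mutations$sample_id == s, ],
                      file.path(vcf_dir, paste0(s, ".vcf")),
                      sim$chrom_lengths)
  }
  utils::write.table(
    data.frame(gene_id = rownames(sim$expression), sim$expression,
               check.names = FALSE),
    file.path(dir, "expression.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(sim$network, file.path(dir, "network.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$coding, file.path(dir, "coding.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(driver_genes = sim$truth$driver_genes,
                sites = sim$truth$sites,
                driver_mutations = sim$truth$driver_mutations,
                expression_shifts = sim$truth$expression_shifts)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(sim$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
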