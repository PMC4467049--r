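# Frequently targeted regions: sliding windows, closest-TSS assignment, and
# promoter hypergeometric enrichment.

#' Sliding windows over a genome
#'
#' Windows of `size` bp start at every multiple of `step` below the
#' chromosome length (bedtools `makewindows` semantics); the last windows
#' are truncated at the chromosome end.
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param size Window size in bp (default 1000).
#' @param step Step in bp (default 500).
#' @return A `GRanges` of windows.
#' @export
make_windows <- function(chrom_lengths, size = 1000, step = 500) {
  stopifnot(size > 0, step > 0)
  per_chrom <- lapply(names(chrom_lengths), function(chr) {
    L <- as.integer(chrom_lengths[[chr]])
    starts0 <- seq.int(0L, L - 1L, by = step)  # 0-based starts
    data.frame(chr = chr, start = starts0 + 1L,
               end = pmin(starts0 + size, L))
  })
  df <- do.call(rbind, per_chrom)
  GenomicRanges::GRanges(df$chr, IRanges::IRanges(df$start, df$end))
}

#' Detect frequently targeted windows
#'
#' Windows containing at least `min_count` cis-regulatory mutations
#' (mutations whose footprint overlaps a predicted TFBS). With step < size a
#' mutation can contribute to two overlapping windows.
#'
#' @param cis_mut A mutation table of cis-regulatory mutations.
#' @param windows A `GRanges` from [make_windows()].
#' @param min_count Minimal mutation count per retained window (default 3).
#' @return A list: `windows` (retained `GRanges` with `n_mutations` metadata)
#'   and `mutations` (data.frame mapping `window` index to rows of `cis_mut`).
#' @export
find_hotspots <- function(cis_mut, windows, min_count = 3) {
  fp <- mutation_footprint(cis_mut)
  ov <- GenomicRanges::findOverlaps(windows, fp, ignore.strand = TRUE)
  counts <- tabulate(S4Vectors::queryHits(ov), nbins = length(windows))
  keep <- which(counts >= min_count)
  win <- windows[keep]
  win$n_mutations <- counts[keep]
  sel <- S4Vectors::queryHits(ov) %in% keep
  mut_map <- data.frame(
    window = match(S4Vectors::queryHits(ov)[sel], keep),
    mutation = S4Vectors::subjectHits(ov)[sel]
  )
  mut_map <- cbind(mut_map,
                   cis_mut[mut_map$mutation, , drop = FALSE],
                   row.names = NULL)
  list(windows = win, mutations = mut_map)
}

#' Assign each mutation to its closest TSS
#'
#' Distance is measured from the midpoint of the mutation's reference
#' footprint to the TSS position; the gene minimizing this distance wins,
#' ties broken by lexicographically smaller gene id (with a warning).
#'
#' @param mut A mutation table.
#' @param tss A data.frame with columns `gene_id`, `chrom`, `tss_pos`
#'   (1-based), `strand`.
#' @param promoter_dist Maximal TSS distance for the promoter call
#'   (default 2000).
#' @return `mut` with added columns `gene_id`, `tss_distance`, `is_promoter`.
#' @export
assign_closest_tss <- function(mut, tss, promoter_dist = 2000) {
  if (nrow(tss) == 0L) stop("empty TSS table")
  fp <- mutation_footprint(mut)
  mid <- (GenomicRanges::start(fp) + GenomicRanges::end(fp)) / 2
  chr <- as.character(GenomicRanges::seqnames(fp))
  gene <- character(nrow(mut)); dist <- numeric(nrow(mut))
  tied <- FALSE
  tss_by_chr <- split(tss, tss$chrom)
  for (i in seq_len(nrow(mut))) {
    cand <- tss_by_chr[[chr[i]]]
    if (is.null(cand)) { gene[i] <- NA_character_; dist[i] <- NA; next }
    d <- abs(cand$tss_pos - mid[i])
    best <- which(d == min(d))
    if (length(best) > 1L) {
      tied <- TRUE
      best <- best[order(cand$gene_id[best])][1L]
    }
    gene[i] <- cand$gene_id[best]
    dist[i] <- d[best]
  }
  if (tied) warning("equidistant TSSs; ties broken by lexicographic gene_id")
  mut$gene_id <- gene
  mut$tss_distance <- dist
  mut$is_promoter <- !is.na(dist) & dist <= promoter_dist
  mut
}

#' Hypergeometric enrichment test
#'
#' Upper-tail probability that at least `k` of `n_sample` drawn items are
#' successes when `K` of `N` items are successes, computed in log space
#' (`phyper`). Used for promoter enrichment of hotspot mutations: k =
#' hotspot mutations in promoters, n_sample = hotspot mutations, K = TFBS
#' mutations in promoters, N = TFBS mutations.
#'
#' @param k Successes observed in the sample.
#' @param n_sample Sample size.
#' @param K Successes in the population.
#' @param N Population size.
#' @param strict If `TRUE`, use the strict tail P(X > k) instead of the
#'   default at-least-observed tail P(X >= k).
#' @return A list: `k`, `n_sample`, `K`, `N`, `p_value`, `log10_p`.
#' @export
hypergeom_enrichment <- function(k, n_sample, K, N, strict = FALSE) {
  if (!(k <= n_sample && n_sample <= N && K <= N && k <= K && k >= 0)) {
    stop("invalid counts: need 0 <= k <= min(n_sample, K) and n_sample, K <= N")
  }
  q <- if (strict) k else k - 1
  logp <- stats::phyper(q, K, N - K, n_sample, lower.tail = FALSE,
                        log.p = TRUE)
  list(k = k, n_sample = n_sample, K = K, N = N,
       p_value = exp(logp), log10_p = logp / log(10))
}
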