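# Mutation-feature overlap, mutation rates, flanking regions, shuffled
# nulls, and the indel germline-repeat heuristic.

#' Count mutations overlapping a feature set
#'
#' A mutation overlaps if its reference footprint intersects the union of the
#' features; each mutation is counted at most once per feature set.
#'
#' @param mut A mutation table (see [mutation_table()]).
#' @param features A `GRanges`.
#' @return A list with `count` and `overlapping` (the subset of `mut`).
#' @export
overlap_count <- function(mut, features) {
  if (nrow(mut) == 0L || length(features) == 0L) {
    return(list(count = 0L, overlapping = mut[integer(0), , drop = FALSE]))
  }
  fp <- mutation_footprint(mut)
  hit <- IRanges::overlapsAny(fp, features, ignore.strand = TRUE)
  list(count = sum(hit), overlapping = mut[hit, , drop = FALSE])
}

#' Merged (union) length of a feature set in bp
#' @param features A `GRanges`.
#' @export
feature_bp <- function(features) {
  sum(GenomicRanges::width(GenomicRanges::reduce(features,
                                                 ignore.strand = TRUE)))
}

#' Mutation rate over a feature set
#'
#' Number of mutations whose footprint lies within the features divided by
#' the merged feature length in bp. Duplicated or overlapping features do not
#' inflate the denominator.
#'
#' @param mut A mutation table (typically one sample).
#' @param features A `GRanges`.
#' @param feature_set_name Label carried into the report.
#' @return A one-row data.frame: `sample_id`, `feature_set_name`,
#'   `n_mutations`, `feature_bp`, `rate` (mutations/bp).
#' @export
mutation_rate <- function(mut, features, feature_set_name = "features") {
  bp <- feature_bp(features)
  if (bp == 0) stop("feature set has zero merged bp")
  n <- overlap_count(mut, features)$count
  data.frame(
    sample_id = if (nrow(mut) > 0L) paste(unique(mut$sample_id),
                                          collapse = ",") else NA_character_,
    feature_set_name = feature_set_name,
    n_mutations = n, feature_bp = bp, rate = n / bp,
    stringsAsFactors = FALSE
  )
}

#' 1-kb flanking regions of a feature set
#'
#' For each feature, the `flank_bp` bases immediately upstream and downstream,
#' clipped to the chromosome; the union of the features themselves is then
#' subtracted so flanks never overlap any feature.
#'
#' @param features A `GRanges`.
#' @param flank_bp Flank width on each side (default 1000).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return A `GRanges` of flank intervals (merged, unstranded).
#' @export
flanking_regions <- function(features, flank_bp = 1000,
                             chrom_lengths = NULL) {
  if (is.null(chrom_lengths)) {
    chrom_lengths <- GenomeInfoDb::seqlengths(features)
    if (any(is.na(chrom_lengths))) {
      stop("chrom_lengths required (or set seqlengths on features)")
    }
  }
  st <- GenomicRanges::start(features)
  en <- GenomicRanges::end(features)
  chr <- as.character(GenomicRanges::seqnames(features))
  len <- chrom_lengths[chr]
  left <- GenomicRanges::GRanges(chr, IRanges::IRanges(
    start = pmax(1L, st - flank_bp), end = st - 1L))
  right <- GenomicRanges::GRanges(chr, IRanges::IRanges(
    start = en + 1L, end = pmin(as.integer(len), en + flank_bp)))
  fl <- c(left, right)
  fl <- fl[GenomicRanges::width(fl) > 0L]
  GenomicRanges::setdiff(GenomicRanges::reduce(fl),
                         GenomicRanges::reduce(features,
                                               ignore.strand = TRUE))
}

#' Reposition mutations uniformly at random (one shuffled genome)
#'
#' Every mutation keeps its sample, alleles and length but is moved to a
#' uniformly random position such that its footprint lies fully on a
#' chromosome. Replicates are indexed: the same `seed` and `index` always
#' reproduce the same shuffled genome, so the 1,000-genome null can be
#' streamed without storing it.
#'
#' @param mut A mutation table.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param seed Base random seed for the null ensemble.
#' @param index Replicate number (1-based).
#' @return A mutation table with repositioned `chrom`/`pos`.
#' @export
shuffle_mutations <- function(mut, chrom_lengths, seed, index = 1L) {
  stopifnot(index >= 1L)
  with_seed(substream_seed(seed, 7001L + index), {
    m <- mut
    w <- ifelse(m$kind == "deletion", nchar(m$ref), 1L)  # footprint span from pos
    # sample chromosome proportional to length, then a position where the
    # footprint fits
    lens <- as.numeric(chrom_lengths)
    ci <- sample.int(length(lens), nrow(m), replace = TRUE,
                     prob = lens / sum(lens))
    m$chrom <- names(chrom_lengths)[ci]
    maxpos <- pmax(1, lens[ci] - w + 1)
    m$pos <- as.integer(1 + floor(stats::runif(nrow(m)) * maxpos))
    m
  })
}

#' Compare per-sample TFBS and exon mutation rates
#'
#' Ordinary least squares of TFBS rate on exon rate across samples, plus the
#' fraction of samples whose TFBS rate exceeds their exon rate.
#'
#' @param rates A data.frame with columns `sample_id`, `exon_rate`,
#'   `tfbs_rate` (one row per sample).
#' @return A list: `per_sample` (input plus `tfbs_gt_exon`),
#'   `fraction_tfbs_gt_exon`, `slope`, `intercept`, `r_squared`.
#' @export
compare_rates <- function(rates) {
  stopifnot(nrow(rates) >= 2L)
  if (stats::var(rates$exon_rate) == 0) {
    stop("exon rates are constant; regression slope undefined")
  }
  fit <- stats::lm(tfbs_rate ~ exon_rate, data = rates)
  rates$tfbs_gt_exon <- rates$tfbs_rate > rates$exon_rate
  list(
    per_sample = rates,
    fraction_tfbs_gt_exon = mean(rates$tfbs_gt_exon),
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = summary(fit)$r.squared
  )
}

#' Find a tandem repeat region spanning an indel start
#'
#' Scans for a maximal run of a repeated 1-6 bp unit covering the position.
#' Runs shorter than two full units (or under `min_span` bases for
#' homopolymers) do not count as repeats.
#'
#' @param seq Chromosome sequence (character or `DNAString`).
#' @param pos 1-based position the repeat must span.
#' @param max_unit Maximal repeat unit length (default 6).
#' @param min_span Minimal homopolymer span (default 4).
#' @return A list `(start, end)` (1-based, closed) or `NULL` if no repeat.
#' @export
find_repeat_region <- function(seq, pos, max_unit = 6L, min_span = 4L) {
  s <- toupper(as.character(seq))
  L <- nchar(s)
  best <- NULL
  for (u in seq_len(max_unit)) {
    # candidate phases: unit starting at pos - u + 1 .. pos
    for (off in seq_len(u)) {
      anchor <- pos - off + 1L
      if (anchor < 1L || anchor + u - 1L > L) next
      unit <- substr(s, anchor, anchor + u - 1L)
      if (grepl("[^ACGT]", unit)) next
      # extend left and right by whole units
      st <- anchor
      while (st - u >= 1L && substr(s, st - u, st - 1L) == unit) st <- st - u
      en <- anchor + u - 1L
      while (en + u <= L && substr(s, en + 1L, en + u) == unit) en <- en + u
      n_units <- (en - st + 1L) / u
      span <- en - st + 1L
      ok <- if (u == 1L) span >= min_span else n_units >= 2L
      if (ok && st <= pos && en >= pos) {
        if (is.null(best) || span > (best$end - best$start + 1L)) {
          best <- list(start = st, end = en)
        }
      }
    }
  }
  best
}

#' Label an indel somatic or germline by the repeat-distance heuristic
#'
#' Indels inside repetitive sequence are hard to place, so an indel is
#' labelled germline when the repeat region extends further from the indel
#' start than the nearest indel observed in the matched normal sample:
#' germline iff a spanning repeat exists, a normal-sample indel distance is
#' known, and `repeat_end - indel_start > nearest_normal_indel_distance`.
#' Otherwise somatic.
#'
#' @param indel_start 1-based start position of the indel.
#' @param repeat_region `NULL` or a list `(start, end)` from
#'   [find_repeat_region()].
#' @param nearest_normal_indel_distance Distance in bp to the closest indel
#'   in the matched normal, or `NULL`/`NA` if none.
#' @return `"germline"` or `"somatic"`.
#' @export
label_indel_germline <- function(indel_start, repeat_region,
                                 nearest_normal_indel_distance) {
  if (is.null(repeat_region)) return("somatic")
  d <- nearest_normal_indel_distance
  if (is.null(d) || is.na(d)) return("somatic")
  if ((repeat_region$end - indel_start) > d) "germline" else "somatic"
}
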