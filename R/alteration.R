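# TFBS alteration scoring: re-scan mutation-bearing alternative sequences
# and compare the best hit against the reference, MANTA-style catalog
# included.

#' Reference and alternative scan windows around a mutation
#'
#' Window lengths follow the motif length n: an SNV yields an alternative
#' window of 2n-1 bp centered on the variant; an insertion of i bp yields
#' 2n-2+i bp with the inserted bases centered; a deletion yields 2(n-1) bp
#' centered at the deleted region. These are the shortest windows in which
#' every motif placement overlapping the variant can be scored. The
#' reference window spans the same reference coordinates (so 2n-2 bp for an
#' insertion locus and 2(n-1)+d bp for a d-bp deletion). Windows are clipped
#' at chromosome ends and flagged when clipping occurred.
#'
#' @param mut A one-row mutation table.
#' @param n Motif length (>= 2).
#' @param genome A named `DNAStringSet`.
#' @return A list: `ref_seq`, `alt_seq`, `ref_start` (1-based genomic start
#'   of the reference window), `clipped`.
#' @export
alt_window <- function(mut, n, genome) {
  stopifnot(nrow(mut) == 1L, n >= 2L)
  chrom <- mut$chrom; pos <- mut$pos
  if (!chrom %in% names(genome)) stop("chromosome absent from genome: ", chrom)
  chr_seq <- genome[[chrom]]
  L <- length(chr_seq)
  ref <- mut$ref; alt <- mut$alt
  obs <- as.character(Biostrings::subseq(chr_seq, pos,
                                         min(L, pos + nchar(ref) - 1L)))
  if (!identical(obs, ref)) {
    stop(sprintf("ref allele mismatch at %s:%d (genome %s, VCF %s)",
                 chrom, pos, obs, ref))
  }
  take <- function(from, to) {
    as.character(Biostrings::subseq(chr_seq, max(1L, from), min(L, to)))
  }
  if (mut$kind == "SNV") {
    from <- pos - (n - 1L); to <- pos + (n - 1L)
    refw <- take(from, to)
    centre <- pos - max(1L, from) + 1L
    altw <- refw
    substr(altw, centre, centre) <- alt
  } else if (mut$kind == "insertion") {
    from <- pos - n + 2L; to <- pos + n - 1L
    left <- take(from, pos)
    right <- if (pos + 1L <= L) take(pos + 1L, to) else ""
    refw <- paste0(left, right)
    altw <- paste0(left, substr(alt, 2L, nchar(alt)), right)
  } else {  # deletion
    d <- nchar(ref) - 1L
    from <- pos - n + 2L; to <- pos + d + n - 1L
    left <- take(from, pos)
    right <- if (pos + d + 1L <= L) take(pos + d + 1L, to) else ""
    refw <- paste0(left, take(pos + 1L, pos + d), right)
    altw <- paste0(left, right)
  }
  list(ref_seq = refw, alt_seq = altw, ref_start = max(1L, from),
       clipped = from < 1L || to > L)
}

#' Best-hit score change between reference and alternative windows
#'
#' Both windows are scanned on both strands in best-hit mode; the score
#' difference and the alternative relative score determine whether the
#' mutation is deleterious for the TFBS (alternative relative score strictly
#' below `deleterious_threshold`).
#'
#' @param ref_seq,alt_seq Window sequences from [alt_window()].
#' @param pwm A `pwm`.
#' @param deleterious_threshold Relative-score cutoff (default 0.80).
#' @return A one-row data.frame: `tf_name`, `ref_score`, `ref_relative_score`,
#'   `alt_score`, `alt_relative_score`, `delta_score`, `deleterious`,
#'   `flagged` (alternative window shorter than the motif).
#' @export
best_hit_delta <- function(ref_seq, alt_seq, pwm,
                           deleterious_threshold = 0.80) {
  rb <- scan_sequence(ref_seq, pwm, mode = "best")
  ab <- scan_sequence(alt_seq, pwm, mode = "best")
  flagged <- nrow(ab) == 0L || nrow(rb) == 0L
  data.frame(
    tf_name = pwm$tf_name,
    ref_score = if (nrow(rb)) rb$score else NA_real_,
    ref_relative_score = if (nrow(rb)) rb$relative_score else NA_real_,
    alt_score = if (nrow(ab)) ab$score else NA_real_,
    alt_relative_score = if (nrow(ab)) ab$relative_score else NA_real_,
    delta_score = if (!flagged) rb$score - ab$score else NA_real_,
    deleterious = if (nrow(ab)) {
      classify_deleterious(ab$relative_score, deleterious_threshold)
    } else NA,
    flagged = flagged,
    stringsAsFactors = FALSE
  )
}

#' Deleterious call from an alternative relative score
#'
#' A mutation is deleterious for a TFBS when the best relative PWM score on
#' the alternative sequence falls strictly below the threshold.
#'
#' @param alt_relative_score Numeric vector.
#' @param threshold Cutoff (default 0.80).
#' @return Logical vector.
#' @export
classify_deleterious <- function(alt_relative_score, threshold = 0.80) {
  alt_relative_score < threshold
}

#' Score every mutation against every TFBS it overlaps
#'
#' One alteration record is emitted per (mutation, TF) pair where the
#' mutation's reference footprint overlaps a predicted TFBS of that TF.
#'
#' @param mut A mutation table.
#' @param hits TFBS `GRanges` from [scan_peaks()].
#' @param genome A named `DNAStringSet`.
#' @param pwms Named list of `pwm` objects (names = TF names).
#' @param deleterious_threshold Cutoff passed to [best_hit_delta()].
#' @return A data.frame: mutation columns plus the [best_hit_delta()] fields.
#' @export
score_alterations <- function(mut, hits, genome, pwms,
                              deleterious_threshold = 0.80) {
  fp <- mutation_footprint(mut)
  ov <- GenomicRanges::findOverlaps(fp, hits, ignore.strand = TRUE)
  if (length(ov) == 0L) {
    return(cbind(mut[integer(0), , drop = FALSE],
                 best_hit_delta("ACGT", "ACGT",
                                pwms[[1L]])[integer(0), , drop = FALSE]))
  }
  pairs <- unique(data.frame(
    m = S4Vectors::queryHits(ov),
    tf = hits$tf_name[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE
  ))
  rows <- lapply(seq_len(nrow(pairs)), function(j) {
    i <- pairs$m[j]
    pw <- pwms[[pairs$tf[j]]]
    w <- alt_window(mut[i, , drop = FALSE], pw$n, genome)
    cbind(mut[i, , drop = FALSE],
          best_hit_delta(w$ref_seq, w$alt_seq, pw, deleterious_threshold),
          row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a catalog of all potential SNV alterations of predicted TFBSs
#'
#' For every position of every TFBS hit and each of the three non-reference
#' bases, the reference/alternative best-hit comparison is precomputed, so
#' any observed SNV can be looked up by (chrom, pos, alt). Storage is an
#' indexed `data.table`; [write_catalog()]/[read_catalog()] round-trip it as
#' TSV.
#'
#' @param hits TFBS `GRanges` from [scan_peaks()].
#' @param genome A named `DNAStringSet`.
#' @param pwms Named list of `pwm` objects.
#' @param deleterious_threshold Cutoff passed to [best_hit_delta()].
#' @return A keyed `data.table` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `tf_name`, scores and the `deleterious` flag.
#' @export
build_catalog <- function(hits, genome, pwms, deleterious_threshold = 0.80) {
  recs <- list(); k <- 0L
  for (i in seq_along(hits)) {
    chrom <- as.character(GenomicRanges::seqnames(hits))[i]
    tf <- hits$tf_name[i]
    pw <- pwms[[tf]]
    for (p in GenomicRanges::start(hits)[i]:GenomicRanges::end(hits)[i]) {
      refb <- as.character(Biostrings::subseq(genome[[chrom]], p, p))
      for (altb in setdiff(BASES, refb)) {
        m <- mutation_table("catalog", chrom, p, refb, altb)
        w <- alt_window(m, pw$n, genome)
        k <- k + 1L
        recs[[k]] <- cbind(
          data.frame(chrom = chrom, pos = p, ref = refb, alt = altb,
                     stringsAsFactors = FALSE),
          best_hit_delta(w$ref_seq, w$alt_seq, pw, deleterious_threshold))
      }
    }
  }
  cat_dt <- data.table::as.data.table(do.call(rbind, recs))
  data.table::setkeyv(cat_dt, c("chrom", "pos", "alt", "tf_name"))
  cat_dt
}

#' Query the alteration catalog
#'
#' @param catalog A catalog from [build_catalog()] or [read_catalog()].
#' @param chrom,pos,alt SNV to look up.
#' @return The matching rows (zero rows if the position is in no TFBS).
#' @export
catalog_query <- function(catalog, chrom, pos, alt) {
  .q_chrom <- as.character(chrom)
  .q_pos <- as.integer(pos)
  .q_alt <- as.character(alt)
  catalog[list(.q_chrom, .q_pos, .q_alt), nomatch = NULL]
}

#' @rdname build_catalog
#' @param catalog A catalog `data.table`.
#' @param path TSV file.
#' @export
write_catalog <- function(catalog, path) {
  data.table::fwrite(catalog, path, sep = "\t")
  invisible(path)
}

#' @rdname build_catalog
#' @export
read_catalog <- function(path) {
  cat_dt <- data.table::fread(path, sep = "\t")
  data.table::setkeyv(cat_dt, c("chrom", "pos", "alt", "tf_name"))
  cat_dt
}
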