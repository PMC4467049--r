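# Position frequency matrices, their log-odds transforms, and TFBS scanning.

BASES <- c("A", "C", "G", "T")

#' Construct a position frequency matrix
#'
#' A PFM records, for each column of a transcription factor binding motif,
#' the number of times each base was observed at that position in a set of
#' aligned binding sites.
#'
#' @param counts Numeric 4 x n matrix of non-negative base counts, rows in
#'   A, C, G, T order (row names are set accordingly).
#' @param tf_name Identifier of the transcription factor.
#' @return An object of class `pfm` with elements `tf_name`, `counts`, `n`.
#' @export
pfm <- function(counts, tf_name = "TF") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("PFM must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 1L) stop("PFM must have at least one column")
  if (any(counts < 0)) stop("PFM counts must be non-negative")
  if (any(colSums(counts) <= 0)) stop("invalid PFM: zero column sum")
  rownames(counts) <- BASES
  structure(list(tf_name = tf_name, counts = counts, n = ncol(counts)),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("PFM %s (%d bp), consensus %s\n", x$tf_name, x$n, consensus(x)))
  print(x$counts)
  invisible(x)
}

#' Consensus sequence of a motif
#'
#' Base with the maximal count (PFM) or weight (PWM) at each column; ties are
#' broken in A, C, G, T order.
#'
#' @param x A `pfm` or `pwm` object.
#' @return A character scalar of length `n`.
#' @export
consensus <- function(x) {
  m <- if (inherits(x, "pfm")) x$counts else x$weights
  paste(BASES[apply(m, 2L, which.max)], collapse = "")
}

#' Convert a PFM to a log-odds position weight matrix
#'
#' Column-wise log2 odds of the pseudocount-smoothed base frequencies against
#' a background distribution:
#' `w[b,i] = log2(((counts[b,i] + pseudocount*background[b]) / (colsum_i + pseudocount)) / background[b])`.
#' The minimal and maximal attainable scores over any length-n sequence
#' (`s_min`, `s_max`) are stored for relative scoring.
#'
#' @param x A `pfm`.
#' @param background Base probabilities (A, C, G, T); must be positive and sum
#'   to 1. Default uniform.
#' @param pseudocount Non-negative smoothing constant distributed in
#'   proportion to the background. Default 0.8.
#' @return An object of class `pwm`.
#' @export
pfm_to_pwm <- function(x, background = rep(0.25, 4), pseudocount = 0.8) {
  stopifnot(inherits(x, "pfm"))
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8) {
    stop("background must be 4 positive probabilities summing to 1")
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  cs <- colSums(x$counts)
  if (any(cs == 0)) stop("invalid PFM: zero column sum")
  p <- sweep(x$counts + pseudocount * background,
             2L, cs + pseudocount, "/")
  w <- log2(p / background)
  rownames(w) <- BASES
  structure(list(
    tf_name = x$tf_name, weights = w, n = ncol(w),
    s_min = sum(apply(w, 2L, min)), s_max = sum(apply(w, 2L, max)),
    col_min = apply(w, 2L, min),
    background = background, pseudocount = pseudocount
  ), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (%d bp), score range [%.3f, %.3f]\n",
              x$tf_name, x$n, x$s_min, x$s_max))
  print(round(x$weights, 3))
  invisible(x)
}

#' Relative PWM score
#'
#' Normalizes a raw log-odds score to `[0, 1]` across motifs:
#' `(score - s_min) / (s_max - s_min)`.
#'
#' @param pwm A `pwm`.
#' @param score Numeric vector of raw scores.
#' @return Numeric vector of relative scores.
#' @export
relative_score <- function(pwm, score) {
  if (pwm$s_max <= pwm$s_min) stop("degenerate PWM: s_max == s_min")
  (score - pwm$s_min) / (pwm$s_max - pwm$s_min)
}

# Encode a DNA string as integer indices into BASES; anything outside
# A/C/G/T (for example N) becomes NA.
encode_dna <- function(seq) {
  match(strsplit(toupper(as.character(seq)), "")[[1L]], BASES)
}

# Raw scores of every length-n window of an encoded sequence. N-containing
# columns contribute the column minimum ("penalize") or poison the window
# with NA ("skip").
window_scores <- function(enc, pwm, n_policy = "penalize") {
  n <- pwm$n
  nw <- length(enc) - n + 1L
  if (nw < 1L) return(numeric(0))
  s <- numeric(nw)
  bad <- logical(nw)
  for (i in seq_len(n)) {
    v <- pwm$weights[, i][enc[i:(i + nw - 1L)]]
    na <- is.na(v)
    if (any(na)) {
      bad <- bad | na
      v[na] <- pwm$col_min[i]
    }
    s <- s + v
  }
  if (n_policy == "skip") s[bad] <- NA_real_
  s
}

#' Scan a sequence with a PWM on both strands
#'
#' Scores every window of motif length on the forward sequence and its
#' reverse complement. In `"hits"` mode every window whose relative score
#' meets `threshold` is returned; in `"best"` mode the single maximal-score
#' hit is returned regardless of threshold, ties broken by lowest start
#' coordinate then forward strand.
#'
#' @param seq A character scalar or `Biostrings::DNAString` over A, C, G, T, N.
#' @param pwm A `pwm`.
#' @param threshold Minimal relative score for a hit (default 0.85).
#' @param mode `"hits"` (all hits above threshold) or `"best"`.
#' @param n_policy How windows containing N score: `"penalize"` (column
#'   minimum contribution, default) or `"skip"` (window dropped).
#' @return A data.frame with columns `start`, `end` (1-based, closed),
#'   `strand`, `tf_name`, `score`, `relative_score`. Sequences shorter than
#'   the motif yield zero rows.
#' @export
scan_sequence <- function(seq, pwm, threshold = 0.85,
                          mode = c("hits", "best"),
                          n_policy = c("penalize", "skip")) {
  mode <- match.arg(mode)
  n_policy <- match.arg(n_policy)
  enc <- encode_dna(seq)
  n <- pwm$n
  L <- length(enc)
  fwd <- window_scores(enc, pwm, n_policy)
  # reverse complement: A<->T, C<->G is 5 - code; NA stays NA
  rc <- rev(5L - enc)
  rev_ <- window_scores(rc, pwm, n_policy)
  nw <- L - n + 1L
  res <- data.frame(
    start = c(seq_len(max(nw, 0L)), L - seq_len(max(nw, 0L)) - n + 2L),
    strand = rep(c("+", "-"), each = max(nw, 0L)),
    score = c(fwd, rev_),
    stringsAsFactors = FALSE
  )
  res <- res[!is.na(res$score), , drop = FALSE]
  if (nrow(res) == 0L) return(empty_hits())
  res$end <- res$start + n - 1L
  res$relative_score <- relative_score(pwm, res$score)
  res$tf_name <- pwm$tf_name
  res <- res[, c("start", "end", "strand", "tf_name", "score",
                 "relative_score")]
  if (mode == "best") {
    ord <- order(-res$score, res$start, res$strand)
    res <- res[ord[1L], , drop = FALSE]
  } else {
    res <- res[res$relative_score >= threshold, , drop = FALSE]
    res <- res[order(res$start, res$strand), , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

empty_hits <- function() {
  data.frame(start = integer(0), end = integer(0), strand = character(0),
             tf_name = character(0), score = numeric(0),
             relative_score = numeric(0), stringsAsFactors = FALSE)
}

#' Predict TFBSs in ChIP-seq peaks
#'
#' Applies every PWM to the full length of every peak on both strands and
#' keeps hits with relative score at or above `threshold`. Coverage is the
#' number of base pairs in the union of all hit intervals (overlaps merged,
#' strand ignored).
#'
#' @param peaks A `GenomicRanges::GRanges` of peak intervals.
#' @param genome A named `Biostrings::DNAStringSet` (one entry per chromosome).
#' @param pwms A list of `pwm` objects (a single `pwm` is accepted).
#' @param threshold Minimal relative score (default 0.85).
#' @param n_policy Passed to [scan_sequence()].
#' @return A list with `hits` (a `GRanges` with metadata columns `tf_name`,
#'   `score`, `relative_score`) and `coverage_bp`.
#' @export
scan_peaks <- function(peaks, genome, pwms, threshold = 0.85,
                       n_policy = "penalize") {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  chroms <- as.character(GenomicRanges::seqnames(peaks))
  missing_chr <- setdiff(unique(chroms), names(genome))
  if (length(missing_chr) > 0L) {
    stop("peak chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "))
  }
  out <- vector("list", length(peaks) * length(pwms))
  k <- 0L
  starts <- GenomicRanges::start(peaks)
  ends <- GenomicRanges::end(peaks)
  for (i in seq_along(peaks)) {
    pseq <- as.character(Biostrings::subseq(genome[[chroms[i]]],
                                            starts[i], ends[i]))
    for (pw in pwms) {
      h <- scan_sequence(pseq, pw, threshold = threshold, mode = "hits",
                         n_policy = n_policy)
      if (nrow(h) > 0L) {
        h$chrom <- chroms[i]
        h$start <- h$start + starts[i] - 1L
        h$end <- h$end + starts[i] - 1L
        k <- k + 1L
        out[[k]] <- h
      }
    }
  }
  if (k == 0L) {
    hits <- GenomicRanges::GRanges()
    return(list(hits = hits, coverage_bp = 0))
  }
  h <- do.call(rbind, out[seq_len(k)])
  hits <- GenomicRanges::GRanges(
    seqnames = h$chrom,
    ranges = IRanges::IRanges(start = h$start, end = h$end),
    strand = h$strand,
    tf_name = h$tf_name, score = h$score, relative_score = h$relative_score
  )
  cov <- sum(GenomicRanges::width(GenomicRanges::reduce(
    hits, ignore.strand = TRUE)))
  list(hits = hits, coverage_bp = cov)
}

#' Write TFBS hits as BED6+1
#'
#' BED score column holds `round(relative_score * 1000)`; the exact relative
#' score is appended as a seventh column.
#'
#' @param hits A `GRanges` as produced by [scan_peaks()].
#' @param path Output file.
#' @export
write_hits_bed <- function(hits, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(hits)),
    start = GenomicRanges::start(hits) - 1L,
    end = GenomicRanges::end(hits),
    name = hits$tf_name,
    score = round(hits$relative_score * 1000),
    strand = as.character(GenomicRanges::strand(hits)),
    relative_score = hits$relative_score
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read TFBS hits written by [write_hits_bed()]
#'
#' @param path BED6+1 file.
#' @return A `GRanges` with `tf_name`, `score` (BED integer) and
#'   `relative_score` metadata columns.
#' @export
read_hits_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  GenomicRanges::GRanges(
    seqnames = df[[1L]],
    ranges = IRanges::IRanges(start = df[[2L]] + 1L, end = df[[3L]]),
    strand = df[[6L]],
    tf_name = df[[4L]], score = df[[5L]], relative_score = df[[7L]]
  )
}
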