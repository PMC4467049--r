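# Independent brute-force oracles. These deliberately share no code with
# the implementation: scoring is done by character arithmetic, overlaps by
# all-pairs loops, and factor-graph marginals by exhaustive enumeration.

BASES4 <- c("A", "C", "G", "T")

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(s)), "")[[1L]]),
        collapse = "")
}

# score one k-mer against a PWM weights matrix by explicit summation;
# characters outside ACGT contribute the column minimum
bf_score_kmer <- function(kmer, weights) {
  ch <- strsplit(toupper(kmer), "")[[1L]]
  s <- 0
  for (i in seq_along(ch)) {
    b <- match(ch[i], BASES4)
    s <- s + if (is.na(b)) min(weights[, i]) else weights[b, i]
  }
  unname(s)
}

# enumerate every window on both strands; returns data.frame of all windows
bf_scan_all <- function(seq, pwm) {
  n <- ncol(pwm$weights)
  L <- nchar(seq)
  if (L < n) {
    return(data.frame(start = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  out <- list()
  for (st in seq_len(L - n + 1L)) {
    win <- substr(seq, st, st + n - 1L)
    out[[length(out) + 1L]] <- data.frame(
      start = st, strand = "+", score = bf_score_kmer(win, pwm$weights))
    out[[length(out) + 1L]] <- data.frame(
      start = st, strand = "-",
      score = bf_score_kmer(revcomp_chr(win), pwm$weights))
  }
  do.call(rbind, out)
}

# all-pairs overlap between point/interval mutations and features (1-based
# closed coordinates)
bf_overlap_count <- function(fp_start, fp_end, f_start, f_end) {
  hit <- logical(length(fp_start))
  for (i in seq_along(fp_start)) {
    for (j in seq_along(f_start)) {
      if (fp_start[i] <= f_end[j] && fp_end[i] >= f_start[j]) {
        hit[i] <- TRUE
        break
      }
    }
  }
  sum(hit)
}

# exhaustive-enumeration marginals for a discrete factor graph in the
# cards/factors representation used by the package
enum_marginals <- function(cards, factors) {
  grid <- as.matrix(do.call(expand.grid, lapply(cards, seq_len)))
  wts <- apply(grid, 1L, function(a) {
    p <- 1
    for (f in factors) {
      tb <- f$table
      p <- p * if (length(f$vars) == 1L) {
        as.numeric(tb)[a[f$vars]]
      } else {
        tb[matrix(a[f$vars], nrow = 1L)]
      }
    }
    p
  })
  z <- sum(wts)
  lapply(seq_along(cards), function(v) {
    vapply(seq_len(cards[v]), function(s) {
      sum(wts[grid[, v] == s]) / z
    }, numeric(1L))
  })
}

# random PFM with a given length (for property tests)
random_pfm <- function(n, name = "TFX") {
  counts <- vapply(seq_len(n), function(i) {
    as.numeric(stats::rmultinom(1L, 20L, prob = stats::runif(4, 0.05, 1)))
  }, numeric(4L))
  counts[counts == 0 & ((seq_len(4) %% 2) == 0)] <- 0  # keep zeros allowed
  if (any(colSums(counts) == 0)) counts[1L, colSums(counts) == 0] <- 1
  pfm(counts, tf_name = name)
}

random_dna <- function(len) {
  paste(sample(BASES4, len, replace = TRUE), collapse = "")
}

# tiny deterministic cohort used by several suites
small_sim <- function(seed = 3) {
  simulate_cohort(sim_config(
    seed = seed, chrom_length = 2e5, n_genes = 12, n_peaks = 20,
    n_samples = 10, n_driver_genes = 2, driver_hit_samples = 3))
}
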