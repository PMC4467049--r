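# Somatic mutation tables, VCF I/O, and reference footprints.
#
# A mutation table is a data.frame with columns sample_id, chrom, pos
# (1-based VCF position), ref, alt, kind ("SNV", "insertion", "deletion").
# Indels are VCF-anchored: the first ref base is the anchor shared by ref
# and alt.

#' Build a validated mutation table
#'
#' @param sample_id,chrom,pos,ref,alt Parallel vectors; `pos` is the 1-based
#'   VCF position, indels carry an anchor base.
#' @return A data.frame with a derived `kind` column.
#' @export
mutation_table <- function(sample_id, chrom, pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  kind <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
          ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
  bad <- nchar(ref) > 1L & nchar(alt) > 1L
  if (any(bad)) stop("complex alleles not supported (ref and alt both > 1 bp)")
  if (any(ref == alt)) stop("ref == alt is not a mutation")
  data.frame(sample_id = as.character(sample_id), chrom = as.character(chrom),
             pos = as.integer(pos), ref = ref, alt = alt, kind = kind,
             stringsAsFactors = FALSE)
}

#' Reference footprint of mutations
#'
#' The genomic interval a mutation alters on the reference: the mutated base
#' for an SNV, the deleted bases for a deletion, and the single anchor base
#' for an insertion (a zero-length event between bases needs a convention;
#' the VCF anchor base is used).
#'
#' @param mut A mutation table.
#' @return A `GRanges`, one range per mutation, metadata columns carried over.
#' @export
mutation_footprint <- function(mut) {
  start <- ifelse(mut$kind == "deletion", mut$pos + 1L, mut$pos)
  end <- ifelse(mut$kind == "deletion", mut$pos + nchar(mut$ref) - 1L,
                ifelse(mut$kind == "insertion", mut$pos, mut$pos))
  gr <- GenomicRanges::GRanges(mut$chrom,
                               IRanges::IRanges(start = start, end = end))
  S4Vectors::mcols(gr) <- mut
  gr
}

#' Read somatic mutations from a VCF file
#'
#' Thin wrapper around `vcfR::read.vcfR` keeping CHROM/POS/REF/ALT;
#' multi-allelic records are split into one row per ALT allele.
#'
#' @param path VCF file (plain text or gzipped).
#' @param sample_id Sample identifier to attach; defaults to the file name
#'   without extension.
#' @return A mutation table.
#' @export
read_somatic_vcf <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  alt_split <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  idx <- rep(seq_len(nrow(fix)), lengths(alt_split))
  mutation_table(sample_id, fix[idx, "CHROM"], as.integer(fix[idx, "POS"]),
                 fix[idx, "REF"], unlist(alt_split))
}

#' Read a directory of per-sample somatic VCFs
#'
#' @param dir Directory containing `*.vcf` files (one per sample).
#' @return A single mutation table; sample ids are the file basenames.
#' @export
read_somatic_vcf_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.vcf$", full.names = TRUE))
  if (length(files) == 0L) stop("no .vcf files in ", dir)
  do.call(rbind, lapply(files, read_somatic_vcf))
}

#' Write a mutation table as a VCF v4.2 file
#'
#' One file per sample is conventional; the table passed in is written as-is
#' (filter by `sample_id` first for per-sample files). Records carry the
#' `SOMATIC` INFO flag.
#'
#' @param mut A mutation table.
#' @param path Output file.
#' @param chrom_lengths Named vector of chromosome lengths for contig headers.
#' @export
write_somatic_vcf <- function(mut, path, chrom_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=SOMATIC,Number=0,Type=Flag,Description=\"Somatic mutation\">"),
             con)
  if (!is.null(chrom_lengths)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
                       as.integer(chrom_lengths)), con)
  }
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(mut) > 0L) {
    ord <- order(mut$chrom, mut$pos)
    m <- mut[ord, , drop = FALSE]
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tSOMATIC",
                       m$chrom, m$pos, m$ref, m$alt), con)
  }
  invisible(path)
}
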