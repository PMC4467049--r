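# JASPAR text-format PFM reader/writer. Two row dialects are accepted:
#   >MA0001.1 NAME            >MA0001.1 NAME
#   A  [ 1 2 3 ]              1 2 3
# (rows always in A, C, G, T order when unlabelled).

#' Read PFMs from a JASPAR text file
#'
#' Accepts both the bracketed dialect (`A [ 1 2 3 ]`) and bare count rows,
#' with four rows per record in A, C, G, T order.
#'
#' @param path JASPAR-format text file.
#' @return A named list of `pfm` objects (named by TF name).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no JASPAR records ('>' headers) in ", path)
  out <- list()
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(block) != 4L) {
      stop("JASPAR record ", lines[hdr[i]], " has ", length(block),
           " matrix rows; expected 4")
    }
    counts <- t(vapply(block, parse_jaspar_row, numeric(count_row_len(block)),
                       USE.NAMES = FALSE))
    fields <- strsplit(sub("^>", "", lines[hdr[i]]), "[ \t]+")[[1L]]
    name <- fields[length(fields)]
    out[[name]] <- pfm(counts, tf_name = name)
  }
  out
}

count_row_len <- function(block) length(parse_jaspar_row(block[[1L]]))

parse_jaspar_row <- function(row) {
  row <- gsub("^[ACGTacgt][ \t]*\\[|\\]$", "", trimws(row))
  as.numeric(strsplit(trimws(row), "[ \t]+")[[1L]])
}

#' Write PFMs in JASPAR bracketed text format
#'
#' @param pfms A list of `pfm` objects (or a single `pfm`).
#' @param path Output file.
#' @export
write_jaspar <- function(pfms, path) {
  if (inherits(pfms, "pfm")) pfms <- list(pfms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pfms) {
    writeLines(paste0(">", p$tf_name), con)
    for (b in seq_len(4L)) {
      writeLines(sprintf("%s  [ %s ]", BASES[b],
                         paste(format(p$counts[b, ], trim = TRUE),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}
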