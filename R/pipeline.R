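# End-to-end orchestration over a run directory, plus the TSV readers
# shared by the analysis stages. All intermediates are plain-text files
# with documented schemas; a JSON manifest records config, seed and
# per-stage output checksums so reruns are verifiable.

#' Read a gene-by-sample expression TSV
#'
#' First column `gene_id`, remaining columns one per sample, log-scale
#' values.
#'
#' @param path TSV file.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("expression matrix contains missing values")
  m
}

#' Drop genes with null expression across all samples
#'
#' @param expr Numeric genes x samples matrix.
#' @return The filtered matrix.
#' @export
filter_null_expression <- function(expr) {
  expr[rowSums(abs(expr)) > 0, , drop = FALSE]
}

#' Read a TSS annotation TSV (`gene_id`, `chrom`, `tss_pos`, `strand`)
#' @param path TSV file.
#' @export
read_tss <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Read a gene-interaction edge list (`gene_a`, `gene_b`[, `weight`])
#' @param path TSV file.
#' @export
read_network <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Default pipeline configuration
#'
#' All stage thresholds in one place: PWM scan relative score 0.85,
#' deleterious cutoff 0.80, 1-kb windows at 500-bp steps with a 3-mutation
#' minimum, 2-kb promoter distance, 1-kb flanks, shuffled-null replicates,
#' and the posterior selection thresholds.
#'
#' @param seed Master seed.
#' @param scan_threshold,deleterious_threshold,window_size,window_step,min_count,promoter_dist,flank_bp,n_shuffles,pr_d_threshold,pr_f_threshold,min_samples
#'   Stage parameters; see the stage functions for semantics.
#' @param stages Character vector of stages to run, in order.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            scan_threshold = 0.85,
                            deleterious_threshold = 0.80,
                            window_size = 1000L, window_step = 500L,
                            min_count = 3L, promoter_dist = 2000L,
                            flank_bp = 1000L, n_shuffles = 1000L,
                            pr_d_threshold = 0.5, pr_f_threshold = 0.5,
                            min_samples = 2L,
                            stages = c("scan", "rates", "hotspots",
                                       "alter", "xseq")) {
  stopifnot(scan_threshold > 0, scan_threshold <= 1,
            deleterious_threshold > 0, deleterious_threshold <= 1,
            window_size > 0, window_step > 0, min_count >= 1)
  structure(list(seed = as.integer(seed), scan_threshold = scan_threshold,
                 deleterious_threshold = deleterious_threshold,
                 window_size = as.integer(window_size),
                 window_step = as.integer(window_step),
                 min_count = as.integer(min_count),
                 promoter_dist = as.integer(promoter_dist),
                 flank_bp = as.integer(flank_bp),
                 n_shuffles = as.integer(n_shuffles),
                 pr_d_threshold = pr_d_threshold,
                 pr_f_threshold = pr_f_threshold,
                 min_samples = as.integer(min_samples),
                 stages = stages),
            class = "pipeline_config")
}

#' Run the analysis pipeline on a simulated cohort
#'
#' Executes scan -> rates -> hotspots -> alter -> xseq on in-memory inputs
#' (a [simulate_cohort()] result or equivalently shaped data loaded from
#' files), honouring the stage toggle list. Stage outputs are returned and,
#' when `out_dir` is given, written as TSV/BED/JSON with a manifest of
#' checksums.
#'
#' @param sim A [simulate_cohort()]-shaped input list.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A list of per-stage results: `scan`, `rates`, `hotspots`,
#'   `alterations`, `xseq`, and `manifest`.
#' @export
run_pipeline <- function(sim, config = pipeline_config(),
                         out_dir = NULL) {
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  pwms <- lapply(sim$pfms, pfm_to_pwm)
  if ("scan" %in% config$stages) {
    res$scan <- stage("scan", scan_peaks(sim$peaks, sim$genome, pwms,
                                         threshold = config$scan_threshold))
  }
  hits <- res$scan$hits
  if ("rates" %in% config$stages) {
    res$rates <- stage("rates", {
      samples <- unique(sim$mutations$sample_id)
      per_sample <- do.call(rbind, lapply(samples, function(s) {
        m <- sim$mutations[sim$mutations$sample_id == s &
                             sim$mutations$kind == "SNV", ]
        data.frame(
          sample_id = s,
          tfbs_rate = mutation_rate(m, hits, "tfbs")$rate,
          exon_rate = mutation_rate(m, sim$exons, "exons")$rate)
      }))
      list(per_sample = per_sample,
           comparison = compare_rates(per_sample))
    })
  }
  cis <- stage("cis", {
    ov <- overlap_count(sim$mutations, hits)
    ov$overlapping
  })
  if ("hotspots" %in% config$stages) {
    res$hotspots <- stage("hotspots", {
      windows <- make_windows(sim$chrom_lengths, config$window_size,
                              config$window_step)
      hs <- find_hotspots(cis, windows, config$min_count)
      hs$mutations <- assign_closest_tss(hs$mutations, sim$tss,
                                         config$promoter_dist)
      hs
    })
  }
  if ("alter" %in% config$stages) {
    res$alterations <- stage("alter",
      score_alterations(cis, hits, sim$genome, pwms,
                        config$deleterious_threshold))
  }
  if ("xseq" %in% config$stages) {
    res$xseq <- stage("xseq", {
      expr <- filter_null_expression(sim$expression)
      alt <- res$alterations
      if (is.null(alt)) {
        alt <- score_alterations(cis, hits, sim$genome, pwms,
                                 config$deleterious_threshold)
      }
      cis_genes <- assign_closest_tss(alt, sim$tss, config$promoter_dist)
      mm <- build_mutation_matrix(cis_genes, sim$coding, expr)
      post <- infer_posteriors(mm, expr, sim$network)
      sel <- select_predictions(post, mm,
                                pr_d_threshold = config$pr_d_threshold,
                                pr_f_threshold = config$pr_f_threshold,
                                min_samples = config$min_samples)
      list(mutation_matrix = mm, posterior = post, predictions = sel)
    })
  }
  if (!is.null(out_dir)) {
    res$manifest <- write_pipeline_outputs(res, config, out_dir)
  }
  res
}

write_pipeline_outputs <- function(res, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(obj, name, writer) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    files[[name]] <<- unname(tools::md5sum(path))
    path
  }
  tsv <- function(obj, path) {
    utils::write.table(obj, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(res$scan)) put(res$scan$hits, "tfbs_hits.bed", write_hits_bed)
  if (!is.null(res$rates)) put(res$rates$per_sample, "rates.tsv", tsv)
  if (!is.null(res$hotspots)) {
    put(res$hotspots$mutations, "hotspot_mutations.tsv", tsv)
  }
  if (!is.null(res$alterations)) put(res$alterations, "alterations.tsv", tsv)
  if (!is.null(res$xseq)) {
    put(data.frame(gene = names(res$xseq$posterior$pr_d),
                   pr_d = unname(res$xseq$posterior$pr_d)),
        "pr_d.tsv", tsv)
    put(res$xseq$predictions$cells, "predictions.tsv", tsv)
  }
  manifest <- list(package_version = as.character(
                     utils::packageVersion("regmut")),
                   config = unclass(config), files = as.list(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
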