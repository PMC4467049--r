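# Mutation-expression integration: dysregulation flags, the patient-gene
# mutation matrix, per-gene expression mixtures, and the hierarchical-Bayes
# model (D_g -> F_g^p -> expression states of the gene and its network
# neighbors) solved by sum-product belief propagation.

#' Flag a gene's expression state in one sample
#'
#' A gene is called up-regulated in a sample when its (log-scale) expression
#' exceeds mu + 1 sigma, and down-regulated below mu - 1 sigma, where mu and
#' sigma are the mean and standard deviation (n-1 denominator) of the gene's
#' expression over all tumor samples (the test sample included by default).
#'
#' @param expr Numeric genes x samples matrix with dimnames.
#' @param gene,sample Row and column to flag.
#' @param leave_one_out If `TRUE`, mu and sigma exclude the test sample.
#' @return `"down"`, `"none"` or `"up"`.
#' @export
flag_dysregulated <- function(expr, gene, sample, leave_one_out = FALSE) {
  x <- expr[gene, ]
  v <- expr[gene, sample]
  if (leave_one_out) x <- x[setdiff(names(x), sample)]
  mu <- mean(x); sig <- stats::sd(x)
  if (!is.finite(sig) || sig == 0) return("none")
  if (v > mu + sig) "up" else if (v < mu - sig) "down" else "none"
}

#' Dysregulation state of every gene in every sample
#'
#' Vectorized form of [flag_dysregulated()].
#'
#' @param expr Numeric genes x samples matrix.
#' @return Character matrix of `"down"`/`"none"`/`"up"`, same shape.
#' @export
dysregulation_matrix <- function(expr) {
  mu <- rowMeans(expr)
  sig <- apply(expr, 1L, stats::sd)
  up <- expr > mu + sig
  down <- expr < mu - sig
  out <- matrix("none", nrow(expr), ncol(expr), dimnames = dimnames(expr))
  out[up] <- "up"
  out[down & sig > 0] <- "down"
  out[up & !(sig > 0)] <- "none"
  out
}

#' Build the binary patient-gene mutation matrix
#'
#' Coding mutations with a qualifying impact class always set the entry; a
#' cis-regulatory mutation (one overlapping a TFBS) sets the entry only when
#' its closest gene is up- or down-regulated in the mutated sample. Each
#' TFBS mutation is associated with a single (closest) gene; a gene may be
#' supported by several TFBSs. Genes absent from the expression matrix are
#' dropped with a warning.
#'
#' @param cis A data.frame of TFBS-overlapping mutations with columns
#'   `sample_id`, `gene_id` (closest gene) and optionally `deleterious`
#'   (from [score_alterations()]).
#' @param coding A data.frame with columns `sample_id`, `gene_id`, `impact`
#'   (or `NULL` for none).
#' @param expr Numeric genes x samples matrix.
#' @param qualifying_impacts Coding impact classes that qualify.
#' @return A list: `matrix` (binary samples x genes), `provenance`
#'   (character matrix: `""`, `"coding"`, `"cis"`, `"both"`), `deleterious`
#'   (logical matrix: any supporting cis mutation predicted deleterious),
#'   `cis_support` (the retained cis rows).
#' @export
build_mutation_matrix <- function(cis, coding, expr,
                                  qualifying_impacts = c(
                                    "nonsense", "missense", "frameshift",
                                    "splice_site", "start_lost",
                                    "stop_lost")) {
  samples <- colnames(expr)
  dys <- dysregulation_matrix(expr)
  keep_gene <- function(df, what) {
    bad <- !df$gene_id %in% rownames(expr)
    if (any(bad)) {
      warning(sum(bad), " ", what,
              " mutation(s) target genes absent from expression; dropped")
    }
    df[!bad & df$sample_id %in% samples, , drop = FALSE]
  }
  cis_q <- if (!is.null(cis) && nrow(cis) > 0L) {
    cis <- keep_gene(cis, "cis")
    sel <- vapply(seq_len(nrow(cis)), function(i) {
      dys[cis$gene_id[i], cis$sample_id[i]] != "none"
    }, logical(1L))
    cis[sel, , drop = FALSE]
  } else cis
  coding_q <- if (!is.null(coding) && nrow(coding) > 0L) {
    coding <- keep_gene(coding, "coding")
    coding[coding$impact %in% qualifying_impacts, , drop = FALSE]
  } else coding
  genes <- sort(unique(c(cis_q$gene_id, coding_q$gene_id)))
  M <- matrix(0L, length(samples), length(genes),
              dimnames = list(samples, genes))
  prov <- matrix("", length(samples), length(genes),
                 dimnames = list(samples, genes))
  del <- matrix(FALSE, length(samples), length(genes),
                dimnames = list(samples, genes))
  if (!is.null(coding_q) && nrow(coding_q) > 0L) {
    idx <- cbind(coding_q$sample_id, coding_q$gene_id)
    M[idx] <- 1L
    prov[idx] <- "coding"
  }
  if (!is.null(cis_q) && nrow(cis_q) > 0L) {
    for (i in seq_len(nrow(cis_q))) {
      s <- cis_q$sample_id[i]; g <- cis_q$gene_id[i]
      M[s, g] <- 1L
      prov[s, g] <- if (prov[s, g] %in% c("coding", "both")) "both" else "cis"
      if (!is.null(cis_q$deleterious) && isTRUE(cis_q$deleterious[i])) {
        del[s, g] <- TRUE
      }
    }
  }
  list(matrix = M, provenance = prov, deleterious = del, cis_support = cis_q)
}

#' Fit a 3-component expression mixture per gene
#'
#' Gaussian location mixture with ordered means (down < neutral < up) per
#' gene, giving the belief-propagation model its emission densities for the
#' three expression states. A plain maximum-likelihood fit is poorly
#' identified here (a tail component happily splits the unimodal bulk, or a
#' 20% shifted subpopulation merges into a widened neutral), so the EM is
#' regularized: two starts (moment-based at mu +/- 2 sigma and
#' quantile-anchored), component scales bounded around a robust core sd
#' (side-specific mad, so a shifted subpopulation does not widen its own
#' gate), tail means kept at least 1.7 core-sd from the median, and a small
#' weight floor so no component dies irrecoverably. The best-likelihood
#' start wins.
#'
#' @param expr Numeric genes x samples matrix.
#' @param max_iter,tol EM stopping rule.
#' @return A named list (per gene) of `means`, `sds`, `weights` (down,
#'   neutral, up) and `converged`.
#' @export
fit_expression_mixture <- function(expr, max_iter = 200L, tol = 1e-6) {
  out <- lapply(rownames(expr), function(g) {
    fit_mixture_1d(expr[g, ], max_iter = max_iter, tol = tol)
  })
  names(out) <- rownames(expr)
  out
}

fit_mixture_1d <- function(x, max_iter = 200L, tol = 1e-6) {
  mu <- mean(x); sig <- stats::sd(x)
  if (!is.finite(sig) || sig < 1e-12) {
    # constant gene: one effective (neutral) component
    s <- max(abs(mu) * 1e-3, 1e-3)
    return(list(means = rep(mu, 3L), sds = rep(s, 3L),
                weights = c(0, 1, 0), converged = TRUE))
  }
  med <- stats::median(x)
  mad_lo <- 1.4826 * stats::median(med - x[x <= med])
  mad_hi <- 1.4826 * stats::median(x[x >= med] - med)
  core <- max(min(mad_lo, mad_hi), 0.2 * sig)
  gate_dn <- 1.7 * max(mad_hi, 0.2 * sig)
  gate_up <- 1.7 * max(mad_lo, 0.2 * sig)
  q <- stats::quantile(x, c(0.075, 0.925), names = FALSE)
  starts <- list(
    list(means = mu + c(-2, 0, 2) * sig, sds = rep(sig, 3L)),
    list(means = c(mean(x[x <= q[1L]]), med, mean(x[x >= q[2L]])),
         sds = rep(core, 3L)))
  fits <- lapply(starts, function(s) {
    em_mixture_1d(x, s$means, s$sds, c(0.1, 0.8, 0.1), med, gate_dn,
                  gate_up, core, floor_sd = 0.1 * sig,
                  max_iter = max_iter, tol = tol)
  })
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1L), "ll"))]]
  if (!best$converged) warning("expression mixture EM did not converge")
  best[c("means", "sds", "weights", "converged")]
}

em_mixture_1d <- function(x, means, sds, w, med, gate_dn, gate_up, core,
                          floor_sd, max_iter, tol, w_floor = 0.02) {
  n <- length(x)
  ll <- ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(1:3, function(k) {
      w[k] * stats::dnorm(x, means[k], sds[k])
    }, numeric(n))
    rowsum_ <- pmax(rowSums(dens), 1e-300)
    ll <- sum(log(rowsum_))
    r <- dens / rowsum_
    nk <- colSums(r)
    w <- pmax(nk / n, w_floor)
    w <- w / sum(w)
    for (k in 1:3) {
      if (nk[k] > 1e-8) {
        means[k] <- sum(r[, k] * x) / nk[k]
        sds[k] <- sqrt(sum(r[, k] * (x - means[k])^2) / nk[k])
      }
    }
    sds <- pmin(pmax(sds, max(0.5 * core, floor_sd)), 1.1 * core)
    ord <- order(means)
    means <- means[ord]; sds <- sds[ord]; w <- w[ord]
    means[1L] <- min(means[1L], med - gate_dn)
    means[3L] <- max(means[3L], med + gate_up)
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  list(means = means, sds = sds, weights = w, converged = converged,
       ll = ll)
}

#' Model parameters for the mutation-expression network model
#'
#' The latent variables carry a direction: D takes states
#' `{null, down, up}` (the gene, when mutated, tends to push expression in
#' one consistent direction — recurrently predicted genes in cancer cohorts
#' are typically dysregulated the same way in every sample), and so does
#' each per-patient F. `Pr(D)` and `Pr(F)` reported downstream are the
#' probabilities of the non-null states, so the Bernoulli semantics of
#' beta and epsilon are unchanged.
#'
#' @param beta P(F active | D active): probability a mutation in an
#'   influential gene acts in a given patient, used when the entry's
#'   provenance is unknown.
#' @param beta_cis,beta_coding Provenance-specific penetrances. A cis entry
#'   reaches the matrix only after the expression-concordance filter and is
#'   supported by a TFBS alteration, so conditional on inclusion it is very
#'   likely to act; coding entries are unfiltered and include passengers.
#' @param epsilon P(F active | D null): leak probability.
#' @param prior_d Prior P(D active), split equally between the two
#'   directions.
#' @param direction_consistency P(F direction == D direction | F active):
#'   how faithfully an acting mutation follows the gene's direction.
#' @param p_dys_self_f1 Probability the mutated gene itself is flagged
#'   dysregulated when the mutation acts (concordant direction;
#'   a small discordant leak `p_self_discordant` is kept separate).
#' @param p_self_discordant Probability of a flag in the direction opposite
#'   to an acting mutation.
#' @param p_dys_nb_f1 Probability a network neighbor is flagged when the
#'   mutation acts (split equally between directions: neighbors respond in
#'   their own directions).
#' @param p_dys_f0 Probability of a non-neutral flag when the mutation does
#'   not act. Calibrated to the null exceedance rate of the mu +/- 1 sigma
#'   rule (2*(1-pnorm(1)) ~ 0.32 for Gaussian expression) so that chance
#'   tails neither masquerade as evidence nor dilute it.
#' @param evidence How expression states enter the factor graph:
#'   `"flag"` (default) attaches the observed mu +/- 1 sigma dysregulation
#'   state of each gene/neighbor as hard evidence; `"mixture"` attaches the
#'   per-gene 3-component mixture densities as soft emissions. The flag mode
#'   is calibrated against the preprocessing rule and is robust to the
#'   mixture's tail components absorbing the very signal being tested.
#' @param max_iter,tol Belief-propagation stopping rule.
#' @return A list of class `xseq_params`.
#' @export
xseq_params <- function(beta = 0.8, beta_cis = 0.9, beta_coding = 0.5,
                        epsilon = 0.05, prior_d = 0.1,
                        direction_consistency = 0.9,
                        p_dys_self_f1 = 0.7, p_self_discordant = 0.02,
                        p_dys_nb_f1 = 0.45,
                        p_dys_f0 = 2 * (1 - stats::pnorm(1)),
                        evidence = c("flag", "mixture"),
                        max_iter = 100L, tol = 1e-8) {
  stopifnot(0 <= epsilon, epsilon < beta, beta <= 1,
            0 < prior_d, prior_d < 1,
            0.5 <= direction_consistency, direction_consistency <= 1,
            p_dys_f0 < p_dys_self_f1 + p_self_discordant,
            p_dys_f0 <= p_dys_nb_f1)
  structure(list(beta = beta, beta_cis = beta_cis,
                 beta_coding = beta_coding, epsilon = epsilon,
                 prior_d = prior_d,
                 direction_consistency = direction_consistency,
                 p_dys_self_f1 = p_dys_self_f1,
                 p_self_discordant = p_self_discordant,
                 p_dys_nb_f1 = p_dys_nb_f1, p_dys_f0 = p_dys_f0,
                 evidence = match.arg(evidence),
                 max_iter = as.integer(max_iter), tol = tol),
            class = "xseq_params")
}

# Factor list for one gene's graph. Variable layout: 1 = D (states null/
# down/up); 2..(np+1) = F_p (same states); then E_{h,p} blocks (expression
# state down/neutral/up) per patient, gene itself first. Exported shape so
# tests can enumerate the same graph exhaustively.
xseq_gene_factors <- function(gene, patients, expr, mixtures, neighbors,
                              params, dys = NULL, provenance = NULL) {
  nb <- intersect(neighbors, rownames(expr))
  hh <- unique(c(gene, nb))
  np <- length(patients)
  nh <- length(hh)
  cards <- c(3L, rep(3L, np), rep(3L, np * nh))
  evar <- function(p, h) 1L + np + (p - 1L) * nh + h
  factors <- list()
  factors[[1]] <- list(vars = 1L,
                       table = c(1 - params$prior_d, params$prior_d / 2,
                                 params$prior_d / 2))
  e <- params$epsilon; cc <- params$direction_consistency
  df_tab_for <- function(prov) {
    b <- switch(prov %||% "unknown",
                cis = params$beta_cis, both = params$beta_cis,
                coding = params$beta_coding, params$beta)
    rbind(c(1 - e, e / 2, e / 2),
          c(1 - b, b * cc, b * (1 - cc)),
          c(1 - b, b * (1 - cc), b * cc))
  }
  q0 <- params$p_dys_f0
  a <- params$p_dys_self_f1; d <- params$p_self_discordant
  fe_self <- rbind(c(q0 / 2, 1 - q0, q0 / 2),
                   c(a, 1 - a - d, d),
                   c(d, 1 - a - d, a))
  pn <- params$p_dys_nb_f1
  fe_nb <- rbind(c(q0 / 2, 1 - q0, q0 / 2),
                 c(pn / 2, 1 - pn, pn / 2),
                 c(pn / 2, 1 - pn, pn / 2))
  k <- 1L
  for (p in seq_len(np)) {
    k <- k + 1L
    factors[[k]] <- list(vars = c(1L, 1L + p),
                         table = df_tab_for(provenance[patients[p]]))
    for (h in seq_len(nh)) {
      k <- k + 1L
      factors[[k]] <- list(vars = c(1L + p, evar(p, h)),
                           table = if (h == 1L) fe_self else fe_nb)
      if (params$evidence == "flag") {
        state <- dys[hh[h], patients[p]]
        lik <- c(down = 0, none = 0, up = 0)
        lik[c(down = 1L, none = 2L, up = 3L)[state]] <- 1
      } else {
        mx <- mixtures[[hh[h]]]
        lik <- stats::dnorm(expr[hh[h], patients[p]], mx$means, mx$sds)
        if (sum(lik) <= 0 || !all(is.finite(lik))) lik <- rep(1, 3L)
      }
      k <- k + 1L
      factors[[k]] <- list(vars = evar(p, h), table = as.numeric(lik))
    }
  }
  list(cards = cards, factors = factors, evar = evar, np = np)
}

# Build the per-gene factor graph and run sum-product BP.
# Returns list(pr_d, pr_f (named by patient), expr_belief (3 x patients for
# the gene itself), converged). `dys` is the precomputed dysregulation state
# matrix (flag evidence mode).
infer_gene <- function(gene, patients, expr, mixtures, neighbors, params,
                       dys = NULL, provenance = NULL) {
  fg <- xseq_gene_factors(gene, patients, expr, mixtures, neighbors,
                          params, dys, provenance)
  res <- bp_infer(fg$cards, fg$factors, max_iter = params$max_iter,
                  tol = params$tol)
  np <- fg$np
  pr_f <- vapply(seq_len(np), function(p) {
    sum(res$marginals[[1L + p]][2:3])
  }, numeric(1L))
  names(pr_f) <- patients
  eb <- vapply(seq_len(np), function(p) res$marginals[[fg$evar(p, 1L)]],
               numeric(3L))
  dimnames(eb) <- list(c("down", "neutral", "up"), patients)
  list(pr_d = sum(res$marginals[[1L]][2:3]), pr_f = pr_f,
       expr_belief = eb, converged = res$converged)
}

#' Infer which mutated genes influence expression
#'
#' For every gene with at least one mutation-matrix entry, a tree-structured
#' factor graph couples the population-level variable D_g (gene influences
#' expression when mutated) to per-patient variables F_g^p (the mutation
#' acts in patient p), which in turn explain the expression states of the
#' gene and its network neighbors in that patient through the fitted
#' per-gene mixtures. Marginals are computed by sum-product belief
#' propagation (exact on these trees).
#'
#' @param mut A mutation-matrix list from [build_mutation_matrix()], or a
#'   binary samples x genes matrix.
#' @param expr Numeric genes x samples matrix.
#' @param network An `igraph` graph or a data.frame edge list
#'   (`gene_a`, `gene_b`, optional weight; weights are ignored).
#' @param params An [xseq_params()] object.
#' @param mixtures Optional precomputed [fit_expression_mixture()] result.
#' @return An object of class `xseq_posterior`: `pr_d` (named vector),
#'   `pr_f` (samples x genes matrix, `NA` where unmutated), `expr_belief`
#'   (per-gene 3 x samples matrices), `converged`.
#' @export
infer_posteriors <- function(mut, expr, network, params = xseq_params(),
                             mixtures = NULL) {
  is_mm <- is.list(mut) && !is.data.frame(mut)
  M <- if (is_mm) mut$matrix else mut
  prov_mat <- if (is_mm) mut$provenance
  if (is.null(mixtures) && params$evidence == "mixture") {
    mixtures <- fit_expression_mixture(expr)
  }
  dys <- if (params$evidence == "flag") dysregulation_matrix(expr)
  g <- if (inherits(network, "igraph")) network else {
    igraph::graph_from_data_frame(network[, 1:2], directed = FALSE)
  }
  genes <- colnames(M)[colSums(M) > 0L]
  pr_d <- stats::setNames(numeric(length(genes)), genes)
  pr_f <- matrix(NA_real_, nrow(M), ncol(M), dimnames = dimnames(M))
  beliefs <- vector("list", length(genes)); names(beliefs) <- genes
  conv <- TRUE
  vn <- igraph::V(g)$name
  for (gene in genes) {
    patients <- rownames(M)[M[, gene] == 1L]
    nbrs <- if (gene %in% vn) {
      names(igraph::neighbors(g, gene))
    } else character(0)
    if (!gene %in% rownames(expr)) next
    prov <- if (!is.null(prov_mat)) {
      stats::setNames(prov_mat[patients, gene], patients)
    }
    r <- infer_gene(gene, patients, expr, mixtures, nbrs, params, dys,
                    prov)
    pr_d[gene] <- r$pr_d
    pr_f[patients, gene] <- r$pr_f
    beliefs[[gene]] <- r$expr_belief
    conv <- conv && r$converged
  }
  structure(list(pr_d = pr_d, pr_f = pr_f, expr_belief = beliefs,
                 converged = conv),
            class = "xseq_posterior")
}

#' @export
print.xseq_posterior <- function(x, ...) {
  cat(sprintf("xseq posterior: %d genes, %d samples; %d gene(s) with Pr(D) >= 0.5\n",
              length(x$pr_d), nrow(x$pr_f), sum(x$pr_d >= 0.5)))
  invisible(x)
}

#' Select predicted genes from the posterior
#'
#' A gene is reported when its all-samples probability Pr(D) reaches the
#' threshold and its single-sample probability Pr(F) is at least
#' `pr_f_threshold` in at least `min_samples` samples (guarding against
#' single-sample false positives). In `"histogram"` mode the Pr(D) threshold
#' is set at the local minimum of the Pr(D) histogram immediately above the
#' largest low-probability peak, falling back to `pr_d_threshold` when no
#' such minimum exists.
#'
#' @param posterior An `xseq_posterior`.
#' @param mut Optional mutation-matrix list from [build_mutation_matrix()];
#'   if given, each reported (gene, sample) carries its mutation category
#'   (`coding` / `tfbs` / `both`, with `_deleterious` appended when a
#'   supporting cis variant is predicted to disrupt its TFBS).
#' @param mode `"fixed"` or `"histogram"`.
#' @param pr_d_threshold All-samples probability cutoff (default 0.5).
#' @param pr_f_threshold Single-sample probability cutoff (default 0.5).
#' @param min_samples Minimal number of qualifying samples (default 2).
#' @return A list: `genes` (data.frame gene, pr_d, n_samples), `cells`
#'   (data.frame gene, sample, pr_f, category), `pr_d_threshold_used`.
#' @export
select_predictions <- function(posterior, mut = NULL,
                               mode = c("fixed", "histogram"),
                               pr_d_threshold = 0.5, pr_f_threshold = 0.5,
                               min_samples = 2L) {
  mode <- match.arg(mode)
  thr <- pr_d_threshold
  if (mode == "histogram") {
    thr <- histogram_threshold(posterior$pr_d, fallback = pr_d_threshold)
  }
  keep <- character(0); cells <- list()
  for (gene in names(posterior$pr_d)) {
    if (posterior$pr_d[gene] < thr) next
    pf <- posterior$pr_f[, gene]
    ok <- which(!is.na(pf) & pf >= pr_f_threshold)
    if (length(ok) < min_samples) next
    keep <- c(keep, gene)
    cat_ <- rep(NA_character_, length(ok))
    if (!is.null(mut)) {
      prov <- mut$provenance[ok, gene]
      cat_ <- ifelse(prov == "cis", "tfbs", prov)
      isdel <- mut$deleterious[ok, gene]
      cat_[isdel & cat_ == "tfbs"] <- "tfbs_deleterious"
      cat_[isdel & cat_ == "both"] <- "both_deleterious"
    }
    cells[[gene]] <- data.frame(
      gene = gene, sample = rownames(posterior$pr_f)[ok],
      pr_f = pf[ok], category = cat_, stringsAsFactors = FALSE)
  }
  genes_df <- data.frame(
    gene = keep,
    pr_d = unname(posterior$pr_d[keep]),
    n_samples = vapply(cells[keep], nrow, integer(1L)),
    stringsAsFactors = FALSE)
  rownames(genes_df) <- NULL
  list(genes = genes_df,
       cells = if (length(cells)) do.call(rbind, c(cells,
                                                   make.row.names = FALSE))
              else data.frame(gene = character(0), sample = character(0),
                              pr_f = numeric(0), category = character(0)),
       pr_d_threshold_used = thr)
}

# Local minimum of the Pr(D) histogram immediately above the largest
# low-probability peak; NULL-safe fallback.
histogram_threshold <- function(pr_d, fallback = 0.5, breaks = 20L) {
  if (length(pr_d) < 10L) return(fallback)
  h <- graphics::hist(pr_d, breaks = seq(0, 1, length.out = breaks + 1L),
                      plot = FALSE)
  cnt <- h$counts
  lowpeak <- which.max(cnt[seq_len(breaks %/% 2L)])
  for (i in seq(lowpeak + 1L, breaks - 1L)) {
    if (cnt[i] <= cnt[i - 1L] && cnt[i] <= cnt[i + 1L]) {
      return(h$breaks[i + 1L])
    }
  }
  fallback
}
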