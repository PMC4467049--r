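# Dysregulation flags, the mutation matrix, expression mixtures, belief
# propagation against exhaustive enumeration, and prediction selection.

expr_fixture <- function(n_genes = 6, n_samples = 20, seed = 2) {
  set.seed(seed)
  matrix(stats::rnorm(n_genes * n_samples, 5, 1), n_genes, n_samples,
         dimnames = list(sprintf("g%d", seq_len(n_genes)),
                         sprintf("s%d", seq_len(n_samples))))
}

test_that("the mu +/- 1 sigma dysregulation rule matches hand computation", {
  e <- matrix(c(1, 2, 3, 4, 5), 1, 5,
              dimnames = list("g1", paste0("s", 1:5)))
  # mu = 3, sd = 1.5811: thresholds 4.5811 and 1.4189
  expect_equal(flag_dysregulated(e, "g1", "s5"), "up")     # 5 > 4.5811
  expect_equal(flag_dysregulated(e, "g1", "s4"), "none")   # 4 < 4.5811
  expect_equal(flag_dysregulated(e, "g1", "s1"), "down")   # 1 < 1.4189
  # constant gene never flags
  ec <- matrix(3, 1, 5, dimnames = list("g1", paste0("s", 1:5)))
  expect_equal(flag_dysregulated(ec, "g1", "s1"), "none")
  # the matrix form agrees with the scalar form everywhere
  em <- expr_fixture()
  dys <- dysregulation_matrix(em)
  for (g in rownames(em)[1:3]) {
    for (s in colnames(em)[1:5]) {
      expect_equal(dys[g, s], flag_dysregulated(em, g, s))
    }
  }
})

test_that("mutation matrix applies the cis expression filter but not a coding one", {
  em <- expr_fixture()
  dys <- dysregulation_matrix(em)
  s_dys <- colnames(em)[which(dys["g1", ] != "none")[1]]
  s_neu <- colnames(em)[which(dys["g1", ] == "none")[1]]
  cis <- data.frame(sample_id = c(s_dys, s_neu), gene_id = "g1",
                    deleterious = c(TRUE, FALSE))
  coding <- data.frame(sample_id = s_neu, gene_id = "g2",
                       impact = c("missense"))
  mm <- build_mutation_matrix(cis, coding, em)
  expect_equal(mm$matrix[s_dys, "g1"], 1L)   # dysregulated cis: kept
  expect_equal(mm$matrix[s_neu, "g1"], 0L)   # neutral cis: filtered
  expect_equal(mm$matrix[s_neu, "g2"], 1L)   # coding: no expression filter
  expect_equal(mm$provenance[s_dys, "g1"], "cis")
  expect_true(mm$deleterious[s_dys, "g1"])
  # both coding and qualifying cis in one sample
  mm2 <- build_mutation_matrix(
    data.frame(sample_id = s_dys, gene_id = "g1", deleterious = FALSE),
    data.frame(sample_id = s_dys, gene_id = "g1", impact = "nonsense"), em)
  expect_equal(mm2$provenance[s_dys, "g1"], "both")
  # non-qualifying coding impacts are dropped
  mm3 <- build_mutation_matrix(NULL,
    data.frame(sample_id = s_neu, gene_id = "g2", impact = "synonymous"), em)
  expect_equal(ncol(mm3$matrix), 0L)
  # unknown genes are dropped with a warning
  expect_warning(build_mutation_matrix(
    data.frame(sample_id = s_dys, gene_id = "nope"), NULL, em), "dropped")
})

test_that("expression mixtures recover neutral bulk and planted shifted fractions", {
  set.seed(71)
  # symmetric unimodal genes: neutral component dominates, mean is centred
  uni <- matrix(stats::rnorm(10 * 200, 5, 1), 10, 200,
                dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:200)))
  fu <- suppressWarnings(fit_expression_mixture(uni))
  w_neutral <- vapply(fu, function(f) f$weights[2], numeric(1))
  m_neutral <- vapply(fu, function(f) f$means[2], numeric(1))
  expect_gte(mean(w_neutral), 0.8)
  expect_lt(max(abs(m_neutral - rowMeans(uni))), 0.25)
  # planted 2-sd up-shift in 20% of samples: up weight averages near 0.2
  shf <- uni
  for (g in rownames(shf)) shf[g, 1:40] <- stats::rnorm(40, 7, 1)
  fs <- suppressWarnings(fit_expression_mixture(shf))
  w_up <- vapply(fs, function(f) f$weights[3], numeric(1))
  expect_lt(abs(mean(w_up) - 0.2), 0.1)
  # constant gene: single effective component, no crash
  cg <- matrix(3, 1, 8, dimnames = list("gc", paste0("s", 1:8)))
  fc <- fit_expression_mixture(cg)[["gc"]]
  expect_equal(fc$weights, c(0, 1, 0))
})

test_that("belief propagation equals exhaustive enumeration on model graphs", {
  set.seed(73)
  em <- expr_fixture(n_genes = 4, n_samples = 8)
  params <- xseq_params()
  dys <- dysregulation_matrix(em)
  # one or two patients, up to two neighbors: <= 12 variables
  cases <- list(
    list(patients = "s1", neighbors = c("g2", "g3")),
    list(patients = c("s1", "s2"), neighbors = "g2"),
    list(patients = c("s1", "s4", "s7"), neighbors = character(0)))
  for (cs in cases) {
    fg <- regmut:::xseq_gene_factors("g1", cs$patients, em, NULL,
                                     cs$neighbors, params, dys)
    got <- regmut:::bp_infer(fg$cards, fg$factors)
    expect_true(got$converged)
    oracle <- enum_marginals(fg$cards, fg$factors)
    for (v in seq_along(fg$cards)) {
      expect_equal(got$marginals[[v]], oracle[[v]], tolerance = 1e-6)
    }
  }
  # and on random tree-shaped factor graphs
  for (rep in 1:5) {
    nv <- sample(4:8, 1)
    cards <- sample(2:3, nv, replace = TRUE)
    factors <- lapply(2:nv, function(v) {
      parent <- sample(v - 1L, 1)
      list(vars = c(parent, v),
           table = matrix(stats::runif(cards[parent] * cards[v], 0.05, 1),
                          cards[parent], cards[v]))
    })
    factors <- c(factors, list(list(vars = 1L,
                                    table = stats::runif(cards[1], 0.1, 1))))
    got <- regmut:::bp_infer(cards, factors)
    oracle <- enum_marginals(cards, factors)
    for (v in seq_len(nv)) {
      expect_equal(got$marginals[[v]], oracle[[v]], tolerance = 1e-6)
    }
  }
})

test_that("a lone patient with neutral expression gives Pr(F) below one half", {
  genes <- paste0("g", 1:4)
  samp <- paste0("s", 1:10)
  # values at mu +/- 0.5 sd: nothing flags
  em <- matrix(rep(c(4.5, 5.5), 20), 4, 10, dimnames = list(genes, samp))
  net <- data.frame(gene_a = "g1", gene_b = c("g2", "g3", "g4"))
  M <- matrix(0L, 10, 1, dimnames = list(samp, "g1"))
  M["s1", "g1"] <- 1L
  post <- infer_posteriors(M, em, net)
  expect_lt(post$pr_f["s1", "g1"], 0.5)
  expect_lt(post$pr_d["g1"], 0.5)
})

test_that("five concordant up-shifted patients give Pr(D) above 0.9", {
  set.seed(9)
  genes <- paste0("g", 1:6)
  samp <- paste0("s", 1:20)
  em <- matrix(stats::rnorm(120, 5, 1), 6, 20,
               dimnames = list(genes, samp))
  hit <- paste0("s", 1:5)
  em["g1", hit] <- 8
  for (nb in c("g2", "g3", "g4")) em[nb, hit] <- 8  # 60% of 5 neighbors
  net <- data.frame(gene_a = "g1", gene_b = paste0("g", 2:6))
  M <- matrix(0L, 20, 1, dimnames = list(samp, "g1"))
  M[hit, "g1"] <- 1L
  post <- infer_posteriors(M, em, net)
  expect_gt(post$pr_d["g1"], 0.9)
  expect_true(all(post$pr_f[hit, "g1"] > 0.5))
  # adding another concordant dysregulated patient never decreases Pr(D)
  M2 <- M; M2["s6", "g1"] <- 1L
  em2 <- em; em2["g1", "s6"] <- 8
  for (nb in c("g2", "g3", "g4")) em2[nb, "s6"] <- 8
  post2 <- infer_posteriors(M2, em2, net)
  expect_gte(post2$pr_d["g1"], post$pr_d["g1"] - 1e-9)
})

test_that("posteriors are invariant to gene and sample permutations", {
  sim <- small_sim(seed = 31)
  expr <- sim$expression
  net <- sim$network
  samp <- colnames(expr)
  M <- matrix(0L, length(samp), 2,
              dimnames = list(samp, rownames(expr)[1:2]))
  dys <- dysregulation_matrix(expr)
  M[which(dys[1, ] != "none")[1:3], 1] <- 1L
  M[which(dys[2, ] != "none")[1:2], 2] <- 1L
  p1 <- infer_posteriors(M, expr, net)
  perm_s <- sample(nrow(M)); perm_g <- 2:1
  p2 <- infer_posteriors(M[perm_s, perm_g], expr[, perm_s], net)
  expect_equal(p1$pr_d[colnames(M)[perm_g]], p2$pr_d, tolerance = 1e-9)
  expect_equal(p1$pr_f[rownames(M)[perm_s], perm_g], p2$pr_f,
               tolerance = 1e-9)
})

test_that("single-sample probabilities recover the planted acting rate", {
  # every planted driver mutation acts; among matrix-included driver
  # entries the mean Pr(F) should approach that rate
  sim <- simulate_cohort(sim_config(seed = 37, n_samples = 100,
                                    driver_hit_samples = 10))
  res <- suppressWarnings(run_pipeline(sim, pipeline_config(seed = 37)))
  post <- res$xseq$posterior
  dm <- sim$truth$driver_mutations
  prf <- mapply(function(s, g) post$pr_f[s, g], dm$sample_id, dm$gene_id)
  prf <- prf[!is.na(prf)]
  expect_gte(length(prf), 10)
  expect_gte(mean(prf), 0.85)
})

test_that("prediction selection enforces the two-sample and threshold rules", {
  pr_d <- c(gA = 0.9, gB = 0.9, gC = 0.4)
  pr_f <- matrix(NA_real_, 4, 3,
                 dimnames = list(paste0("s", 1:4), names(pr_d)))
  pr_f[, "gA"] <- c(0.9, 0.8, NA, NA)
  pr_f[, "gB"] <- c(0.9, 0.2, NA, NA)   # only one qualifying sample
  pr_f[, "gC"] <- c(0.9, 0.9, NA, NA)   # Pr(D) below threshold
  post <- structure(list(pr_d = pr_d, pr_f = pr_f,
                         expr_belief = list(), converged = TRUE),
                    class = "xseq_posterior")
  sel <- select_predictions(post)
  expect_equal(sel$genes$gene, "gA")
  expect_equal(sel$genes$n_samples, 2L)
  expect_equal(sel$cells$sample, c("s1", "s2"))
  # histogram mode falls back to the fixed threshold on tiny inputs
  sel2 <- select_predictions(post, mode = "histogram", pr_d_threshold = 0.5)
  expect_equal(sel2$pr_d_threshold_used, 0.5)
})

test_that("histogram thresholding sits above the low-probability peak", {
  set.seed(77)
  pr_d <- c(stats::rbeta(300, 1, 12), stats::rbeta(40, 15, 1.5))
  thr <- regmut:::histogram_threshold(pr_d, fallback = 0.5)
  expect_gt(thr, quantile(pr_d[pr_d < 0.5], 0.9))
  expect_lt(thr, 0.9)
})
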