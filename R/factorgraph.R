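# A small sum-product belief propagation engine over discrete factor
# graphs. The per-gene graphs used by the expression model are trees
# (D -> F_p -> expression states), where sum-product is exact; the engine
# itself is generic (flooding schedule, convergence on message change) so
# loopy graphs degrade gracefully with a convergence flag.

# factors: list of list(vars = integer vector (variable ids),
#                       table = array with dim = cards[vars])
# cards:   integer vector of variable cardinalities

bp_infer <- function(cards, factors, max_iter = 100L, tol = 1e-8) {
  nv <- length(cards)
  nf <- length(factors)
  # message store: for each (factor, slot) a pair of vectors
  msg_vf <- vector("list", nf)  # variable -> factor
  msg_fv <- vector("list", nf)  # factor -> variable
  for (f in seq_len(nf)) {
    vs <- factors[[f]]$vars
    msg_vf[[f]] <- lapply(vs, function(v) rep(1 / cards[v], cards[v]))
    msg_fv[[f]] <- lapply(vs, function(v) rep(1 / cards[v], cards[v]))
  }
  # index: which (factor, slot) touch each variable
  touch <- vector("list", nv)
  for (f in seq_len(nf)) {
    vs <- factors[[f]]$vars
    for (s in seq_along(vs)) {
      touch[[vs[s]]] <- rbind(touch[[vs[s]]], c(f, s))
    }
  }
  normalize <- function(x) {
    s <- sum(x)
    if (s <= 0 || !is.finite(s)) rep(1 / length(x), length(x)) else x / s
  }
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    delta <- 0
    # factor -> variable
    for (f in seq_len(nf)) {
      vs <- factors[[f]]$vars
      tab <- factors[[f]]$table
      if (length(vs) == 1L) {
        new <- normalize(as.numeric(tab))
        delta <- max(delta, max(abs(new - msg_fv[[f]][[1L]])))
        msg_fv[[f]][[1L]] <- new
        next
      }
      for (s in seq_along(vs)) {
        M <- tab
        for (j in seq_along(vs)) {
          if (j != s) M <- sweep(M, j, msg_vf[[f]][[j]], "*")
        }
        new <- normalize(apply(M, s, sum))
        delta <- max(delta, max(abs(new - msg_fv[[f]][[s]])))
        msg_fv[[f]][[s]] <- new
      }
    }
    # variable -> factor
    for (v in seq_len(nv)) {
      tv <- touch[[v]]
      if (is.null(tv) || nrow(tv) < 2L) next
      prods <- matrix(NA_real_, nrow(tv), cards[v])
      for (r in seq_len(nrow(tv))) {
        prods[r, ] <- msg_fv[[tv[r, 1L]]][[tv[r, 2L]]]
      }
      for (r in seq_len(nrow(tv))) {
        new <- normalize(apply(prods[-r, , drop = FALSE], 2L, prod))
        msg_vf[[tv[r, 1L]]][[tv[r, 2L]]] <- new
      }
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  marginals <- vector("list", nv)
  for (v in seq_len(nv)) {
    tv <- touch[[v]]
    b <- rep(1, cards[v])
    if (!is.null(tv)) {
      for (r in seq_len(nrow(tv))) {
        b <- b * msg_fv[[tv[r, 1L]]][[tv[r, 2L]]]
      }
    }
    marginals[[v]] <- normalize(b)
  }
  list(marginals = marginals, converged = converged, iterations = iter)
}
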