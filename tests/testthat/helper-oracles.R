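# Independent brute-force oracles used to validate the fast implementations.
# These deliberately share no code with the package internals beyond the
# canonical string writer (the convention under test is count equality).

# adjacency list of a molecular_graph: per atom, matrix (neighbour, order)
.oracle_adj <- function(g) {
  n <- n_atoms(g)
  nb <- rep(list(matrix(0L, 0, 2)), n)
  b <- g$bonds
  for (r in seq_len(nrow(b))) {
    nb[[b$i[r]]] <- rbind(nb[[b$i[r]]], c(b$j[r], b$order[r]))
    nb[[b$j[r]]] <- rbind(nb[[b$j[r]]], c(b$i[r], b$order[r]))
  }
  nb
}

# all-pairs graph distances by repeated BFS (no igraph)
oracle_distances <- function(g) {
  n <- n_atoms(g)
  nb <- .oracle_adj(g)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in nb[[u]][, 1]) {
        if (is.infinite(d[s, v])) {
          d[s, v] <- d[s, u] + 1
          queue <- c(queue, v)
        }
      }
    }
  }
  d
}

# Brute-force fragment counts: enumerate every simple path by DFS, keep the
# paths whose length equals the endpoint distance (i.e. shortest paths),
# count each unordered path once, canonicalize identically to the package.
oracle_fragment_counts <- function(g, min_atoms = 2L, max_atoms = 9L) {
  n <- n_atoms(g)
  if (n < 2L) return(setNames(integer(0), character(0)))
  nb <- .oracle_adj(g)
  d <- oracle_distances(g)
  out <- character(0)
  walk <- function(path) {
    u <- path[length(path)]
    if (length(path) >= min_atoms && length(path) <= max_atoms &&
        path[1] < u && d[path[1], u] == length(path) - 1) {
      orders <- vapply(seq_len(length(path) - 1L), function(k) {
        row <- nb[[path[k]]]
        row[row[, 1] == path[k + 1L], 2][1]
      }, integer(1))
      out[[length(out) + 1L]] <<- canonical_fragment(g$elements[path], orders)
    }
    if (length(path) < max_atoms) {
      for (v in nb[[u]][, 1]) {
        if (!(v %in% path)) walk(c(path, v))
      }
    }
  }
  for (s in seq_len(n)) walk(s)
  if (length(out) == 0L) return(setNames(integer(0), character(0)))
  tab <- table(out)
  res <- setNames(as.integer(tab), names(tab))
  res[sort(names(res), method = "radix")]
}

# valence legality and connectivity checker for generated molecules
oracle_valid_molecule <- function(g) {
  limits <- c(C = 4L, N = 3L, O = 2L, P = 5L, S = 2L)
  deg <- integer(n_atoms(g))
  for (r in seq_len(nrow(g$bonds))) {
    deg[g$bonds$i[r]] <- deg[g$bonds$i[r]] + g$bonds$order[r]
    deg[g$bonds$j[r]] <- deg[g$bonds$j[r]] + g$bonds$order[r]
  }
  if (any(deg > limits[g$elements])) return(FALSE)
  if (n_atoms(g) == 1L) return(TRUE)
  all(is.finite(oracle_distances(g)[1, ]))
}

# a battery of random small molecular graphs for oracle comparisons
random_small_graphs <- function(n_graphs, max_atoms = 8L, seed = 1L) {
  spec <- synthetic_spec(n_molecules = n_graphs, size_range = c(2L, max_atoms),
                         seed = seed)
  generate_molecules(spec)$graphs
}

# explicit leave-one-out reference: refits fit_pls per fold
oracle_loo <- function(X, y, max_lv) {
  n <- nrow(X)
  preds <- matrix(NA_real_, n, max_lv)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    sds <- apply(Xi, 2, sd)
    keep <- sds > 0
    Xk <- Xi[, keep, drop = FALSE]
    r <- qr(scale(Xk))$rank
    for (A in seq_len(max_lv)) {
      f <- fit_pls(Xk, y[-i], n_lv = min(A, r, n - 3L))
      preds[i, A] <- predict(f, X[i, keep, drop = FALSE])
    }
  }
  preds
}
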