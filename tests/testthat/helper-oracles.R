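# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

# Hand step-up BH: q_(i) = min_{j >= i} min(1, p_(j) * m / j), in input order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, p[o] * m / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Hypergeometric tail P(X >= k) by explicit enumeration with choose().
hyper_tail_oracle <- function(k, K, N, n) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Chain DAG id1 -> id2 -> ... -> root (last element is the root).
chain_dag <- function(ids) {
  parents <- setNames(vector("list", length(ids)), ids)
  for (i in seq_len(length(ids) - 1)) parents[[ids[i]]] <- ids[i + 1]
  parents[[ids[length(ids)]]] <- character(0)
  go_dag(setNames(ids, ids), parents)
}

# igraph-based shortest-distance matrix (child -> ancestor), Inf if
# unreachable; independent of the package's BFS.
igraph_distances <- function(dag) {
  ids <- names(dag$terms)
  edges <- do.call(rbind, lapply(ids, function(ch) {
    if (length(dag$parents[[ch]]) == 0) return(NULL)
    cbind(ch, dag$parents[[ch]])
  }))
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = TRUE, vertices = ids
  )
  igraph::distances(g, mode = "out")
}

# Brute-force reference for the seven-step common most-specific
# reduction, written against the algorithm statement rather than the
# package implementation: distances via igraph, naive set scans.
common_most_specific_bruteforce <- function(dag, input_sets,
                                            include_self = TRUE) {
  ids <- names(dag$terms)
  D <- igraph_distances(dag)
  anc_of <- function(t) ids[is.finite(D[t, ]) & ids != t]
  # step 1-2: union, keep most specific (no proper descendant in set)
  u <- unique(unlist(input_sets))
  ms <- u[vapply(u, function(t) {
    !any(vapply(setdiff(u, t), function(s) t %in% anc_of(s), logical(1)))
  }, logical(1))]
  common <- character(0)
  non_common <- character(0)
  for (child in ms) {
    cand <- if (include_self) c(child, anc_of(child)) else anc_of(child)
    dists <- D[child, cand]
    hit <- FALSE
    for (d in sort(unique(dists))) {
      at_d <- cand[dists == d]
      present <- at_d[vapply(at_d, function(t) {
        all(vapply(input_sets, function(s) t %in% s, logical(1)))
      }, logical(1))]
      if (length(present)) {
        common <- union(common, present)
        hit <- TRUE
        break
      }
    }
    if (!hit) non_common <- c(non_common, child)
  }
  # step 6: drop common terms that are proper ancestors of other commons
  common <- common[vapply(common, function(t) {
    !any(vapply(setdiff(common, t), function(s) t %in% anc_of(s),
                logical(1)))
  }, logical(1))]
  list(common = sort(common), non_common = sort(non_common))
}

# Straight horizontal ribbon mask: width w px centred on row r0.
ribbon_mask <- function(nr, nc, r0, w, c_from = 1, c_to = nc) {
  m <- matrix(FALSE, nr, nc)
  half <- (w - 1) / 2
  rows <- (r0 - floor(half)):(r0 + ceiling(half))
  m[rows, c_from:c_to] <- TRUE
  m
}
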