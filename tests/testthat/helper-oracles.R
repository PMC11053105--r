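# Independent oracles used by the unit and acceptance tests. These are
# deliberately written against different primitives than the package code
# they check (law of cosines vs atan2, Prim vs Kruskal, DFS vs union-find,
# Pruefer enumeration vs greedy MST).

# Interior angle via the law of cosines.
oracle_angle_lawcos <- function(a, v, b) {
  la <- sqrt(sum((a - v)^2))
  lb <- sqrt(sum((b - v)^2))
  lc <- sqrt(sum((a - b)^2))
  acos(pmin(1, pmax(-1, (la^2 + lb^2 - lc^2) / (2 * la * lb)))) * 180 / pi
}

# Unsigned angle between two lines via atan2 direction difference mod 180.
oracle_line_angle <- function(p1, q1, p2, q2) {
  t1 <- atan2(q1[2] - p1[2], q1[1] - p1[1]) * 180 / pi
  t2 <- atan2(q2[2] - p2[2], q2[1] - p2[1]) * 180 / pi
  d <- abs(t1 - t2) %% 180
  min(d, 180 - d)
}

# Unsigned point-to-line distance via |cross product| / norm.
oracle_point_line_dist <- function(p, lp, lq) {
  d <- lq - lp
  abs(d[1] * (p[2] - lp[2]) - d[2] * (p[1] - lp[1])) / sqrt(sum(d^2))
}

# Connected components by iterative depth-first search.
# Returns a list of sorted node-name vectors, sorted by first member.
oracle_dfs_components <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges$var1[i]; b <- edges$var2[i]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  seen <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (start in nodes) {
    if (seen[[start]]) next
    stack <- start
    comp <- character(0)
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (seen[[v]]) next
      seen[[v]] <- TRUE
      comp <- c(comp, v)
      stack <- c(stack, adj[[v]][!seen[adj[[v]]]])
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, `[`, character(1), 1))]
}

# Canonical partition of a ceph_clusters object, comparable with the DFS oracle.
partition_of <- function(clusters) {
  comps <- split(names(clusters$membership), clusters$membership)
  comps <- lapply(comps, sort)
  names(comps) <- NULL
  comps[order(vapply(comps, `[`, character(1), 1))]
}

# Total MST distance by Prim's algorithm (no shared code with Kruskal).
oracle_prim_total <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- d[1, ]
  total <- 0
  for (k in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    total <- total + unname(best[j])
    in_tree[j] <- TRUE
    best <- pmin(best, d[j, ])
  }
  total
}

# All labeled spanning trees on n nodes via Pruefer sequences, as a matrix
# of linear indices into an n x n distance matrix: one column per tree,
# n - 1 rows. Enumerated once per n and cached.
.pruefer_cache <- new.env(parent = emptyenv())
all_spanning_tree_index <- function(n) {
  key <- as.character(n)
  if (!is.null(.pruefer_cache[[key]])) return(.pruefer_cache[[key]])
  decode <- function(pr) {
    deg <- tabulate(pr, n) + 1L
    edges <- matrix(0L, nrow = n - 1L, ncol = 2L)
    leaf <- which(deg == 1L)
    for (i in seq_along(pr)) {
      l <- min(leaf)
      v <- pr[i]
      edges[i, ] <- c(l, v)
      leaf <- leaf[leaf != l]
      deg[v] <- deg[v] - 1L
      if (deg[v] == 1L) leaf <- c(leaf, v)
    }
    edges[n - 1L, ] <- sort(leaf)
    edges
  }
  seqs <- if (n == 2L) {
    matrix(integer(0), nrow = 1L, ncol = 0L)
  } else {
    as.matrix(do.call(expand.grid, rep(list(seq_len(n)), n - 2L)))
  }
  idx <- matrix(0L, nrow = n - 1L, ncol = max(1L, nrow(seqs)))
  if (n == 2L) {
    idx[1, 1] <- 1L + (2L - 1L) * n  # edge 1-2
  } else {
    for (t in seq_len(nrow(seqs))) {
      e <- decode(as.integer(seqs[t, ]))
      idx[, t] <- e[, 1] + (e[, 2] - 1L) * n
    }
  }
  .pruefer_cache[[key]] <- idx
  idx
}

oracle_bruteforce_mst_total <- function(d) {
  idx <- all_spanning_tree_index(nrow(d))
  min(colSums(matrix(d[idx], nrow = nrow(idx))))
}

# Random symmetric "distance" matrix on v nodes with zero diagonal.
random_distance_matrix <- function(v, names = paste0("V", seq_len(v))) {
  m <- matrix(stats::runif(v * v), v, v)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(names, names)
  m
}

# Random non-degenerate landmark sets (template + modest perturbation).
random_landmark_sets <- function(n, seed, sd = 1.0) {
  generate_landmark_sets(default_landmark_template(perturbation_sd = sd),
                         n = n, seed = seed)
}

# Small deterministic correlation matrix from a generated table.
toy_corr <- function(n_subjects = 200, seed = 11) {
  cfg <- generator_config(n_subjects = n_subjects, seed = seed)
  pearson_matrix(generate_measurement_table(cfg))
}
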