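# Minimum spanning tree of the correlation network: distance d = 1 - |r|,
# Kruskal's algorithm over edges sorted by (distance, lexicographic pair),
# cycle detection by union-find with path compression. The MST is computed
# on the complete distance matrix — no cutoff — which is exactly what makes
# it a cutoff-free skeletal summary.

#' Convert a correlation matrix to the 1 - |r| distance matrix
#'
#' Sign-blind by design: r = 1 and r = -1 both give distance 0.
#'
#' @param corr a `ceph_corr` or correlation matrix.
#' @return An object of class `ceph_dist`: `variables`, `d` (symmetric,
#'   entries in \[0, 1\], zero diagonal), `abs_r`.
#' @export
correlation_to_distance <- function(corr) {
  corr <- .as_corr(corr)
  a <- abs(corr$r)
  a[a > 1] <- 1
  d <- 1 - a
  diag(d) <- 0
  structure(list(variables = corr$variables, d = d, abs_r = a),
            class = "ceph_dist")
}

#' @export
print.ceph_dist <- function(x, ...) {
  cat("<ceph_dist>", length(x$variables), "variables\n")
  invisible(x)
}

#' Minimum spanning tree by Kruskal's algorithm
#'
#' Edges are considered in ascending (distance, lexicographic pair) order
#' — the lexicographic tie-break makes the output deterministic even with
#' tied distances — and accepted unless they close a cycle (union-find
#' with path compression).
#'
#' @param dist a `ceph_dist` (or any complete symmetric distance matrix).
#' @return An object of class `ceph_tree`: `nodes`, `edges` (data frame
#'   `var1, var2, distance, abs_r`, exactly V - 1 rows), `total_distance`,
#'   `annotations`.
#' @export
kruskal_mst <- function(dist) {
  if (!inherits(dist, "ceph_dist")) {
    m <- as.matrix(dist)
    vars <- colnames(m) %||% paste0("V", seq_len(ncol(m)))
    dist <- structure(list(variables = vars, d = m, abs_r = 1 - m),
                      class = "ceph_dist")
  }
  vars <- dist$variables
  n <- length(vars)
  if (n < 2L) stop("need at least 2 variables for a spanning tree")
  idx <- which(upper.tri(dist$d), arr.ind = TRUE)
  w <- dist$d[idx]
  e1 <- vars[idx[, 1]]
  e2 <- vars[idx[, 2]]
  # canonical pair order for the lexicographic tie-break
  lo <- pmin(e1, e2)
  hi <- pmax(e1, e2)
  ord <- order(w, lo, hi)
  uf <- uf_new(n)
  keep <- integer(0)
  for (k in ord) {
    res <- uf_union(uf, idx[k, 1], idx[k, 2])
    uf <- res$uf
    if (res$merged) {
      keep <- c(keep, k)
      if (length(keep) == n - 1L) break
    }
  }
  if (length(keep) != n - 1L) {
    stop("distance matrix is not complete/connected; MST undefined")
  }
  edges <- data.frame(var1 = e1[keep], var2 = e2[keep],
                      distance = w[keep],
                      abs_r = dist$abs_r[idx[keep, , drop = FALSE]],
                      stringsAsFactors = FALSE)
  structure(list(nodes = vars, edges = edges,
                 total_distance = sum(edges$distance),
                 annotations = stats::setNames(rep(NA_character_, n), vars)),
            class = "ceph_tree")
}

#' @export
print.ceph_tree <- function(x, ...) {
  cat("<ceph_tree>", length(x$nodes), "nodes,", nrow(x$edges),
      "edges, total distance", signif(x$total_distance, 6), "\n")
  invisible(x)
}

#' Annotate the tree with cluster labels and flag inter-cluster edges
#'
#' Nodes take the cluster labels of `clusters` (size >= 2 components;
#' others are `"unclustered"`); edges whose endpoints carry different
#' effective labels — each unclustered node counting as its own — are
#' flagged `inter_cluster`. Those flagged edges are the key links between
#' the highly-correlated groups.
#'
#' @param tree a `ceph_tree`.
#' @param clusters a `ceph_clusters` over the same variable set.
#' @return The tree with `annotations` filled and an `inter_cluster`
#'   column added to `edges`.
#' @export
annotate_tree <- function(tree, clusters) {
  if (!setequal(tree$nodes, names(clusters$membership))) {
    stop("variable sets of tree and clusters differ")
  }
  labels <- cluster_table(clusters)
  ann <- stats::setNames(rep("unclustered", length(tree$nodes)), tree$nodes)
  for (lab in names(labels)) ann[labels[[lab]]] <- lab
  tree$annotations <- ann
  eff <- ifelse(ann == "unclustered", paste0("node:", names(ann)), ann)
  names(eff) <- names(ann)
  tree$edges$inter_cluster <- eff[tree$edges$var1] != eff[tree$edges$var2]
  tree
}

#' Write a tree's edge list as TSV
#'
#' Columns `var1, var2, distance, abs_r` and, when annotated,
#' `inter_cluster`.
#'
#' @param tree a `ceph_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree_tsv <- function(tree, path) {
  utils::write.table(tree$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Convert a `ceph_tree` to an igraph object
#'
#' @param tree a `ceph_tree`.
#' @return An igraph graph (edge weight = distance).
#' @export
tree_to_igraph <- function(tree) {
  vert <- data.frame(name = tree$nodes,
                     cluster = ifelse(is.na(tree$annotations), "none",
                                      tree$annotations),
                     stringsAsFactors = FALSE)
  edges <- tree$edges
  edges$weight <- edges$distance
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vert)
}

#' Write a tree to GraphML
#'
#' @param tree a `ceph_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree_graphml <- function(tree, path) {
  igraph::write_graph(tree_to_igraph(tree), path, format = "graphml")
  invisible(path)
}

#' Newick-like nested text rendering of a tree
#'
#' For quick inspection: the tree is rooted at its highest-degree node
#' (ties broken alphabetically) and printed as nested parentheses with
#' branch lengths = distances. Internal nodes carry variable names, so
#' this is "Newick-like", not strict Newick.
#'
#' @param tree a `ceph_tree`.
#' @return A single character string.
#' @export
tree_newick <- function(tree) {
  adj <- lapply(stats::setNames(tree$nodes, tree$nodes),
                function(v) character(0))
  len <- list()
  for (i in seq_len(nrow(tree$edges))) {
    a <- tree$edges$var1[i]; b <- tree$edges$var2[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
    len[[paste(a, b, sep = "\r")]] <- tree$edges$distance[i]
    len[[paste(b, a, sep = "\r")]] <- tree$edges$distance[i]
  }
  deg <- vapply(adj, length, integer(1))
  root <- sort(names(deg)[deg == max(deg)])[1]
  esc <- function(x) gsub("[(),:;]", "_", x)
  render <- function(node, parent) {
    kids <- sort(setdiff(adj[[node]], parent))
    body <- if (length(kids)) {
      paste0("(", paste(vapply(kids, function(k) {
        paste0(render(k, node), ":",
               format(len[[paste(node, k, sep = "\r")]], digits = 10))
      }, character(1)), collapse = ","), ")")
    } else ""
    paste0(body, esc(node))
  }
  paste0(render(root, NA_character_), ";")
}
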