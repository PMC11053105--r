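# Absolute-Pearson correlation networks: variables are nodes, |r| is the
# edge weight, and thresholding at nested cutoffs exposes the cluster
# structure. Cutoff comparison is inclusive (|r| >= cutoff).

#' Pearson correlation matrix of a measurement table
#'
#' Standard Pearson r for every variable pair; signed r is preserved for
#' reporting, |r| is used downstream as the network weight. Two-sided
#' p-values (t reference distribution) are attached for reporting only —
#' they never filter edges.
#'
#' @param table a [measurement_table()], data frame or numeric matrix with
#'   at least 3 complete rows (a `subject_id` column is ignored).
#' @return An object of class `ceph_corr`: list with `variables`, `r`
#'   (symmetric, unit diagonal), `n_subjects`, `p` (p-value matrix).
#' @export
pearson_matrix <- function(table) {
  x <- if (inherits(table, "measurement_table")) {
    table$values
  } else {
    df <- as.data.frame(table)
    df$subject_id <- NULL
    as.matrix(df)
  }
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    stop("missing values present; enforce the complete-case policy upstream ",
         "(validate_table)")
  }
  if (nrow(x) < 3L) stop("need at least 3 complete rows")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(x)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  n <- nrow(x)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  structure(list(variables = colnames(x), r = r, n_subjects = n, p = p),
            class = "ceph_corr")
}

#' @export
print.ceph_corr <- function(x, ...) {
  cat("<ceph_corr>", length(x$variables), "variables,",
      x$n_subjects, "subjects\n")
  invisible(x)
}

# Accept a ceph_corr or a bare correlation matrix.
.as_corr <- function(corr) {
  if (inherits(corr, "ceph_corr")) return(corr)
  r <- as.matrix(corr)
  if (nrow(r) != ncol(r)) stop("correlation matrix must be square")
  if (max(abs(r - t(r))) > 1e-8) stop("correlation matrix must be symmetric")
  if (max(abs(r)) > 1 + 1e-12) stop("|r| must be <= 1")
  vars <- colnames(r) %||% paste0("V", seq_len(ncol(r)))
  structure(list(variables = vars, r = r, n_subjects = NA_integer_, p = NULL),
            class = "ceph_corr")
}

#' Number of distinct variable pairs
#'
#' `v(v-1)/2` — e.g. 2,080 pairs for 65 variables and 91 for 14.
#'
#' @param v number of variables (>= 2).
#' @return Integer pair count.
#' @export
pair_count <- function(v) {
  v <- as.integer(v)
  if (is.na(v) || v < 2L) stop("need at least 2 variables")
  as.integer(v * (v - 1L) / 2L)
}

#' Edge-weight distribution of a correlation network
#'
#' Histogram and empirical cumulative probability distribution function
#' (CPDF) of the |r| weights over all distinct pairs, plus the fraction of
#' pairs at or above each candidate cutoff — the data-driven basis for
#' cutoff selection.
#'
#' @param corr a `ceph_corr` (or correlation matrix).
#' @param bins histogram bin count on \[0, 1\] (default 20; bins are
#'   right-open except the last). The signed histogram uses `2 * bins`
#'   bins on \[-1, 1\].
#' @param cutoffs candidate cutoffs, default 0.4 / 0.6 / 0.8.
#' @return An object of class `ceph_weights`: `weights` (the `v(v-1)/2`
#'   values |r|), `breaks`, `counts`, signed counterparts, `cpdf` (step
#'   function) and `fraction_at_or_above` (named numeric).
#' @export
weight_distribution <- function(corr, bins = 20,
                                cutoffs = c(0.4, 0.6, 0.8)) {
  corr <- .as_corr(corr)
  ut <- upper.tri(corr$r)
  signed <- corr$r[ut]
  w <- abs(signed)
  breaks <- seq(0, 1, length.out = bins + 1)
  counts <- tabulate(findInterval(w, breaks, rightmost.closed = TRUE),
                     nbins = bins)
  sbreaks <- seq(-1, 1, length.out = 2 * bins + 1)
  scounts <- tabulate(findInterval(signed, sbreaks, rightmost.closed = TRUE),
                      nbins = 2 * bins)
  frac <- vapply(cutoffs, function(c) mean(w >= c), numeric(1))
  structure(list(weights = w, signed = signed,
                 breaks = breaks, counts = counts,
                 signed_breaks = sbreaks, signed_counts = scounts,
                 cpdf = stats::ecdf(w),
                 fraction_at_or_above = stats::setNames(frac,
                                                        format(cutoffs))),
            class = "ceph_weights")
}

#' @export
print.ceph_weights <- function(x, ...) {
  cat("<ceph_weights>", length(x$weights), "pair weights; fraction >= cutoff:\n")
  print(round(x$fraction_at_or_above, 4))
  invisible(x)
}

#' Threshold a correlation matrix into a weighted graph
#'
#' Nodes are all variables (isolated nodes kept); an edge joins every
#' distinct pair with |r| >= cutoff (inclusive), weighted by |r|.
#'
#' @param corr a `ceph_corr` (or correlation matrix).
#' @param cutoff threshold in (0, 1).
#' @return An object of class `ceph_graph`: `nodes`, `edges` (data frame
#'   `var1, var2, r, abs_r`), `cutoff`, `annotations` (named character,
#'   `NA` until [overlay_clusters()]).
#' @export
threshold_graph <- function(corr, cutoff) {
  corr <- .as_corr(corr)
  if (!is.numeric(cutoff) || length(cutoff) != 1L ||
      cutoff <= 0 || cutoff >= 1) {
    stop("cutoff must lie in (0, 1)")
  }
  r <- corr$r
  idx <- which(upper.tri(r) & abs(r) >= cutoff, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  edges <- data.frame(var1 = corr$variables[idx[, 1]],
                      var2 = corr$variables[idx[, 2]],
                      r = r[idx], abs_r = abs(r[idx]),
                      stringsAsFactors = FALSE)
  structure(list(nodes = corr$variables, edges = edges, cutoff = cutoff,
                 annotations = stats::setNames(
                   rep(NA_character_, length(corr$variables)),
                   corr$variables)),
            class = "ceph_graph")
}

#' @export
print.ceph_graph <- function(x, ...) {
  cat("<ceph_graph> cutoff", x$cutoff, ":", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

# Internal union-find with path compression (also used by Kruskal).
uf_new <- function(n) list(parent = seq_len(n), rank = integer(n))
uf_find <- function(uf, i) {
  root <- i
  while (uf$parent[root] != root) root <- uf$parent[root]
  while (uf$parent[i] != root) {    # path compression
    nxt <- uf$parent[i]
    uf$parent[i] <- root
    i <- nxt
  }
  list(uf = uf, root = root)
}
uf_union <- function(uf, i, j) {
  fi <- uf_find(uf, i); uf <- fi$uf
  fj <- uf_find(uf, j); uf <- fj$uf
  ri <- fi$root; rj <- fj$root
  if (ri == rj) return(list(uf = uf, merged = FALSE))
  if (uf$rank[ri] < uf$rank[rj]) { tmp <- ri; ri <- rj; rj <- tmp }
  uf$parent[rj] <- ri
  if (uf$rank[ri] == uf$rank[rj]) uf$rank[ri] <- uf$rank[ri] + 1L
  list(uf = uf, merged = TRUE)
}

#' Connected components of a thresholded graph
#'
#' Components of size >= 2 are the "clusters"; singletons are flagged
#' isolated. Component ids are deterministic: numbered by decreasing size,
#' ties by first node in node order.
#'
#' @param graph a `ceph_graph`.
#' @return An object of class `ceph_clusters`: `membership` (named integer),
#'   `sizes`, `isolated` (named logical), `n_clusters` (components of
#'   size >= 2).
#' @export
connected_components <- function(graph) {
  nodes <- graph$nodes
  n <- length(nodes)
  uf <- uf_new(n)
  i1 <- match(graph$edges$var1, nodes)
  i2 <- match(graph$edges$var2, nodes)
  for (k in seq_along(i1)) {
    res <- uf_union(uf, i1[k], i2[k])
    uf <- res$uf
  }
  roots <- vapply(seq_len(n), function(i) uf_find(uf, i)$root, integer(1))
  comp <- match(roots, unique(roots))
  sizes <- tabulate(comp)
  ord <- order(-sizes, vapply(seq_along(sizes),
                              function(c) min(which(comp == c)), integer(1)))
  relabel <- match(seq_along(sizes), ord)
  membership <- stats::setNames(relabel[comp], nodes)
  sizes <- tabulate(membership)
  structure(list(membership = membership, sizes = sizes,
                 isolated = stats::setNames(sizes[membership] == 1L, nodes),
                 n_clusters = sum(sizes >= 2L)),
            class = "ceph_clusters")
}

#' @export
print.ceph_clusters <- function(x, ...) {
  cat("<ceph_clusters>", x$n_clusters, "clusters (size >= 2),",
      sum(x$sizes == 1L), "isolated nodes\n")
  invisible(x)
}

#' Cluster membership as a label -> members list
#'
#' @param clusters a `ceph_clusters`.
#' @param min_size smallest component reported (default 2).
#' @return Named list mapping `C1`, `C2`, ... to member variable names.
#' @export
cluster_table <- function(clusters, min_size = 2L) {
  keep <- which(clusters$sizes >= min_size)
  out <- lapply(keep, function(c) {
    names(clusters$membership)[clusters$membership == c]
  })
  names(out) <- sprintf("C%d", seq_along(keep))
  out
}

#' Is a node set a clique?
#'
#' @param graph a `ceph_graph`.
#' @param nodes node subset to check.
#' @return List with `is_clique` (logical) and `missing` (data frame of
#'   absent pairs, 0 rows for a clique).
#' @export
is_clique <- function(graph, nodes) {
  unknown <- setdiff(nodes, graph$nodes)
  if (length(unknown)) {
    stop("unknown node(s): ", paste(unknown, collapse = ", "))
  }
  nodes <- sort(unique(nodes))
  if (length(nodes) < 2L) {
    return(list(is_clique = TRUE,
                missing = data.frame(var1 = character(0),
                                     var2 = character(0))))
  }
  have <- paste(pmin(graph$edges$var1, graph$edges$var2),
                pmax(graph$edges$var1, graph$edges$var2), sep = "\r")
  pairs <- utils::combn(nodes, 2)
  want <- paste(pmin(pairs[1, ], pairs[2, ]),
                pmax(pairs[1, ], pairs[2, ]), sep = "\r")
  absent <- which(!want %in% have)
  missing <- data.frame(var1 = pairs[1, absent], var2 = pairs[2, absent],
                        stringsAsFactors = FALSE)
  list(is_clique = nrow(missing) == 0L, missing = missing)
}

#' Overlay fine-cutoff clusters onto a coarser base graph
#'
#' Annotates the base graph's nodes with the cluster labels found at a
#' higher cutoff — the standard way to show which tightly-correlated
#' groups sit inside the looser network. Nodes isolated at the fine cutoff
#' are labelled `"unclustered"`.
#'
#' @param base a `ceph_graph` at the lower cutoff.
#' @param fine a `ceph_clusters` computed at a higher cutoff on the same
#'   variable set.
#' @return The base graph with `annotations` filled in.
#' @export
overlay_clusters <- function(base, fine) {
  if (!setequal(base$nodes, names(fine$membership))) {
    stop("variable sets of base graph and fine clusters differ")
  }
  labels <- cluster_table(fine)
  ann <- stats::setNames(rep("unclustered", length(base$nodes)), base$nodes)
  for (lab in names(labels)) ann[labels[[lab]]] <- lab
  base$annotations <- ann
  base
}

#' Compare a subnetwork's edge set to a reference edge list
#'
#' Recomputes the unweighted edge set of the induced subnetwork at a
#' cutoff and reports agreement with a user-supplied reference — the
#' replication-style check against a previously published network.
#'
#' @param corr a `ceph_corr`.
#' @param subset variable names to induce on.
#' @param cutoff threshold in (0, 1).
#' @param reference_edges two-column data frame / matrix of reference pairs.
#' @return List with data frames `matched`, `extra` (present here, absent
#'   in the reference) and `missing` (vice versa), plus counts.
#' @export
subnetwork_compare <- function(corr, subset, cutoff, reference_edges) {
  corr <- .as_corr(corr)
  unknown <- setdiff(subset, corr$variables)
  if (length(unknown)) {
    stop("unknown variable(s) in subset: ", paste(unknown, collapse = ", "))
  }
  ref <- as.data.frame(reference_edges, stringsAsFactors = FALSE)
  if (ncol(ref) < 2L) stop("reference_edges needs two columns")
  ref_unknown <- setdiff(unique(c(ref[[1]], ref[[2]])), subset)
  if (length(ref_unknown)) {
    stop("reference edge names outside the subset: ",
         paste(ref_unknown, collapse = ", "))
  }
  sub_r <- corr$r[subset, subset, drop = FALSE]
  g <- threshold_graph(sub_r, cutoff)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  here <- if (nrow(g$edges)) key(g$edges$var1, g$edges$var2) else character(0)
  there <- if (nrow(ref)) key(ref[[1]], ref[[2]]) else character(0)
  unkey <- function(k) {
    if (!length(k)) {
      return(data.frame(var1 = character(0), var2 = character(0)))
    }
    parts <- do.call(rbind, strsplit(k, "\r", fixed = TRUE))
    data.frame(var1 = parts[, 1], var2 = parts[, 2], stringsAsFactors = FALSE)
  }
  matched <- intersect(here, there)
  list(matched = unkey(matched),
       extra = unkey(setdiff(here, there)),
       missing = unkey(setdiff(there, here)),
       n_matched = length(matched),
       n_extra = length(setdiff(here, there)),
       n_missing = length(setdiff(there, here)))
}

# --- exports -----------------------------------------------------------------

#' Write a correlation matrix as a square CSV (variables as header and
#' first column)
#'
#' @param corr a `ceph_corr` (or matrix).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corr_csv <- function(corr, path) {
  corr <- .as_corr(corr)
  df <- data.frame(variable = corr$variables, corr$r, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a correlation matrix written by [write_corr_csv()]
#'
#' @param path CSV path.
#' @return A `ceph_corr`.
#' @export
read_corr_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  vars <- df[[1]]
  r <- as.matrix(df[, -1, drop = FALSE])
  rownames(r) <- vars
  .as_corr(r)
}

#' Write a graph's edge list as TSV (`var1, var2, r, abs_r`)
#'
#' @param graph a `ceph_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_tsv <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Convert a `ceph_graph` to an igraph object
#'
#' Node attributes: `cluster` (overlay label); edge attributes: `weight`
#' (= |r|) and signed `r`.
#'
#' @param graph a `ceph_graph`.
#' @return An igraph graph.
#' @export
graph_to_igraph <- function(graph) {
  vert <- data.frame(name = graph$nodes,
                     cluster = ifelse(is.na(graph$annotations), "none",
                                      graph$annotations),
                     stringsAsFactors = FALSE)
  edges <- graph$edges
  if (nrow(edges)) {
    edges$weight <- edges$abs_r
  } else {
    edges$weight <- numeric(0)
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vert)
}

#' Write a graph to GraphML
#'
#' @param graph a `ceph_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph_to_igraph(graph), path, format = "graphml")
  invisible(path)
}
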