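test_that("pearson_matrix matches the textbook formula and handles affine columns", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.0)
  y <- c(2.0, 1.1, 3.3, 4.8, 2.9)
  tab <- cbind(x = x, y = y)
  r <- pearson_matrix(tab)$r
  # direct covariance-formula oracle
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r["x", "y"], oracle, tolerance = 1e-12)
  expect_equal(unname(diag(r)), c(1, 1))

  aff <- cbind(x = x, up = 2 * x + 3, down = -2 * x + 3)
  r2 <- pearson_matrix(aff)$r
  expect_equal(r2["x", "up"], 1, tolerance = 1e-12)
  expect_equal(r2["x", "down"], -1, tolerance = 1e-12)

  expect_error(pearson_matrix(cbind(x = x, k = rep(7, 5))), "constant.*k")
  expect_error(pearson_matrix(cbind(x = c(x[1:4], NA), y = y)), "missing")
  expect_error(pearson_matrix(cbind(x = x[1:2], y = y[1:2])), "3")
})

test_that("pair_count reproduces the combinatorial counts", {
  expect_identical(pair_count(65), 2080L)
  expect_identical(pair_count(14), 91L)
  expect_identical(pair_count(2), 1L)
  expect_error(pair_count(1), "at least 2")
})

test_that("weight_distribution: degenerate matrices and exact fraction bookkeeping", {
  id <- diag(4); dimnames(id) <- list(letters[1:4], letters[1:4])
  wd <- weight_distribution(id)
  expect_equal(length(wd$weights), pair_count(4))
  expect_true(all(wd$weights == 0))
  expect_equal(unname(wd$fraction_at_or_above["0.4"]), 0)

  ones <- matrix(1, 3, 3); dimnames(ones) <- list(letters[1:3], letters[1:3])
  expect_equal(unname(weight_distribution(ones)$fraction_at_or_above["0.8"]), 1)

  corr <- toy_corr()
  wd2 <- weight_distribution(corr)
  expect_equal(sum(wd2$counts), pair_count(65))
  # CPDF is a proper CDF
  knots <- stats::knots(wd2$cpdf)
  expect_true(all(diff(wd2$cpdf(knots)) >= 0))
  expect_equal(wd2$cpdf(1), 1)
  # fraction_at_or_above(c) == edges(threshold_graph(c)) / pair_count exactly
  for (c in c(0.4, 0.6, 0.8)) {
    expect_equal(unname(wd2$fraction_at_or_above[format(c)]),
                 nrow(threshold_graph(corr, c)$edges) / pair_count(65))
  }
  expect_true(all(diff(wd2$fraction_at_or_above) <= 0))
})

test_that("threshold_graph keeps isolated nodes, nests across cutoffs, matches a pair scan", {
  corr <- toy_corr()
  above <- threshold_graph(corr, 0.9999)
  expect_equal(length(above$nodes), 65)
  keys <- function(g) paste(g$edges$var1, g$edges$var2)
  g8 <- threshold_graph(corr, 0.8)
  g6 <- threshold_graph(corr, 0.6)
  g4 <- threshold_graph(corr, 0.4)
  expect_true(all(keys(g8) %in% keys(g6)))
  expect_true(all(keys(g6) %in% keys(g4)))
  # telescoping edge-count conservation
  expect_equal((nrow(g4$edges) - nrow(g6$edges)) +
                 (nrow(g6$edges) - nrow(g8$edges)) + nrow(g8$edges),
               nrow(g4$edges))

  sub <- corr$r[1:6, 1:6]
  g <- threshold_graph(sub, 0.5)
  brute <- sum(abs(sub[upper.tri(sub)]) >= 0.5)
  expect_equal(nrow(g$edges), brute)
  expect_true(all(g$edges$abs_r >= 0.5))
  expect_error(threshold_graph(corr, 0), "cutoff")
  expect_error(threshold_graph(corr, 1), "cutoff")
})

test_that("connected_components agrees with a DFS oracle on random graphs", {
  edgeless <- threshold_graph(diag(5) |> (\(m) {
    dimnames(m) <- list(letters[1:5], letters[1:5]); m
  })(), 0.5)
  cc0 <- connected_components(edgeless)
  expect_equal(cc0$n_clusters, 0)
  expect_true(all(cc0$isolated))

  set.seed(90)
  for (i in 1:25) {
    v <- sample(4:12, 1)
    nodes <- paste0("n", seq_len(v))
    m <- matrix(0, v, v, dimnames = list(nodes, nodes))
    pairs <- which(upper.tri(m))
    on <- sample(pairs, size = stats::rbinom(1, length(pairs), 0.2))
    m[on] <- stats::runif(length(on), 0.7, 1)
    m <- pmax(m, t(m)); diag(m) <- 1
    g <- threshold_graph(m, 0.5)
    expect_identical(partition_of(connected_components(g)),
                     oracle_dfs_components(g$nodes, g$edges))
  }
})

test_that("two disjoint triangles give two clusters with deterministic labels", {
  nodes <- letters[1:6]
  m <- diag(6); dimnames(m) <- list(nodes, nodes)
  m[cbind(c(1, 1, 2, 4, 4, 5), c(2, 3, 3, 5, 6, 6))] <- 0.9
  m <- pmax(m, t(m))
  cc <- connected_components(threshold_graph(m, 0.5))
  expect_equal(cc$n_clusters, 2)
  expect_identical(cluster_table(cc),
                   list(C1 = c("a", "b", "c"), C2 = c("d", "e", "f")))
})

test_that("is_clique matches an exhaustive pair check on all 4-subsets", {
  set.seed(91)
  nodes <- paste0("n", 1:10)
  m <- matrix(0, 10, 10, dimnames = list(nodes, nodes))
  on <- sample(which(upper.tri(m)), 25)
  m[on] <- 0.9; m <- pmax(m, t(m)); diag(m) <- 1
  g <- threshold_graph(m, 0.5)
  expect_true(is_clique(g, "n1")$is_clique)
  subsets <- utils::combn(nodes, 4)
  for (j in seq_len(ncol(subsets))) {
    s <- subsets[, j]
    want <- all(abs(m[s, s][upper.tri(m[s, s])]) >= 0.5)
    got <- is_clique(g, s)
    expect_identical(got$is_clique, want)
    expect_equal(nrow(got$missing),
                 sum(abs(m[s, s][upper.tri(m[s, s])]) < 0.5))
  }
  # triangle minus an edge
  tri <- diag(3); dimnames(tri) <- list(c("x", "y", "z"), c("x", "y", "z"))
  tri["x", "y"] <- tri["y", "x"] <- 0.9
  tri["y", "z"] <- tri["z", "y"] <- 0.9
  chk <- is_clique(threshold_graph(tri, 0.5), c("x", "y", "z"))
  expect_false(chk$is_clique)
  expect_equal(nrow(chk$missing), 1)
  expect_setequal(unlist(chk$missing), c("x", "z"))
  expect_error(is_clique(threshold_graph(tri, 0.5), "nope"), "unknown")
})

test_that("overlay_clusters labels fine clusters on the base graph", {
  corr <- toy_corr()
  base <- threshold_graph(corr, 0.6)
  fine <- connected_components(threshold_graph(corr, 0.8))
  over <- overlay_clusters(base, fine)
  labs <- over$annotations
  expect_setequal(names(labs), base$nodes)
  ct <- cluster_table(fine)
  for (lab in names(ct)) {
    expect_true(all(labs[ct[[lab]]] == lab))
    # each annotated cluster is internally connected in the base 0.6 graph
    sub_edges <- over$edges[over$edges$var1 %in% ct[[lab]] &
                              over$edges$var2 %in% ct[[lab]], ]
    part <- oracle_dfs_components(ct[[lab]], sub_edges)
    expect_equal(length(part), 1)
  }
  expect_true(all(labs[fine$isolated] == "unclustered"))
  # all-singleton fine assignment -> everything unclustered
  iso <- connected_components(threshold_graph(corr, 0.9999))
  expect_true(all(overlay_clusters(base, iso)$annotations == "unclustered"))
})

test_that("subnetwork_compare matches a brute-force recomputation", {
  corr <- toy_corr()
  subset <- registry_names()[1:14]
  g <- threshold_graph(corr$r[subset, subset], 0.6)
  ref <- g$edges[, c("var1", "var2")]
  res <- subnetwork_compare(corr, subset, 0.6, ref)
  expect_equal(res$n_extra, 0)
  expect_equal(res$n_missing, 0)
  expect_equal(res$n_matched, nrow(ref))
  # toggle one pair: drop a real edge, add a fake one
  fake <- data.frame(var1 = subset[1], var2 = subset[2])
  stopifnot(!any(ref$var1 == fake$var1 & ref$var2 == fake$var2))
  res2 <- subnetwork_compare(corr, subset, 0.6, rbind(ref[-1, ], fake))
  expect_equal(res2$n_missing, 1)
  expect_equal(res2$n_extra, 1)
  expect_error(subnetwork_compare(corr, c(subset, "ghost"), 0.6, ref),
               "unknown")
})

test_that("graphs are invariant to affine rescaling and equivariant to permutation", {
  cfg <- generator_config(n_subjects = 300, seed = 17)
  tab <- generate_measurement_table(cfg)
  corr <- pearson_matrix(tab)
  g <- threshold_graph(corr, 0.6)
  x2 <- tab$values
  x2[, 5] <- 3.2 * x2[, 5] - 40
  x2[, 20] <- -0.5 * x2[, 20] + 7
  g2 <- threshold_graph(pearson_matrix(measurement_table(x2, tab$units)), 0.6)
  expect_identical(g$edges[, c("var1", "var2")], g2$edges[, c("var1", "var2")])
  expect_equal(g$edges$abs_r, g2$edges$abs_r, tolerance = 1e-12)

  perm <- sample(ncol(tab$values))
  g3 <- threshold_graph(pearson_matrix(tab$values[, perm]), 0.6)
  key <- function(g) sort(paste(pmin(g$edges$var1, g$edges$var2),
                                pmax(g$edges$var1, g$edges$var2)))
  expect_identical(key(g), key(g3))
})

test_that("graph exports parse back (GraphML via igraph, edge TSV, corr CSV)", {
  corr <- toy_corr(n_subjects = 100, seed = 3)
  g <- overlay_clusters(threshold_graph(corr, 0.6),
                        connected_components(threshold_graph(corr, 0.8)))
  gml <- tempfile(fileext = ".graphml")
  write_graphml(g, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), 65)
  expect_equal(igraph::ecount(back), nrow(g$edges))
  expect_setequal(igraph::vertex_attr(back, "cluster"),
                  unique(unname(g$annotations)))

  tsv <- tempfile(fileext = ".tsv")
  write_edge_tsv(g, tsv)
  back2 <- utils::read.delim(tsv)
  expect_equal(nrow(back2), nrow(g$edges))

  csv <- tempfile(fileext = ".csv")
  write_corr_csv(corr, csv)
  corr2 <- read_corr_csv(csv)
  expect_equal(corr2$r, corr$r, tolerance = 1e-12)
})
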