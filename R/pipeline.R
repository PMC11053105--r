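# End-to-end pipeline: table in (or synthetic), correlation matrix, edge
# weight distribution, thresholded networks with cluster overlay, MST, and
# a machine-readable run report. Every figure has a CSV/JSON twin so
# nothing downstream ever needs to read pixels.

#' Pipeline configuration
#'
#' @param input a measurement-table CSV path, a [measurement_table()], or
#'   `NULL` to simulate from `generator`.
#' @param cutoffs strictly increasing thresholds in (0, 1), default the
#'   data-driven 0.4 / 0.6 / 0.8 triple.
#' @param overlay length-2 numeric `c(base, fine)`: clusters found at the
#'   fine cutoff are overlaid on the base-cutoff network (default 0.6/0.8).
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed for the synthetic route.
#' @param generator a [generator_config()] used when `input` is `NULL`.
#' @param registry_path optional JSON registry (for the landmark route of
#'   the CLI).
#' @param drop_outliers if `TRUE`, rows containing any cell with |z| > `z_flag`
#'   are removed; by default outliers are only counted and reported.
#' @param z_flag z-score magnitude above which a cell is flagged (default 4).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL,
                            cutoffs = c(0.4, 0.6, 0.8),
                            overlay = c(0.6, 0.8),
                            out_dir = tempfile("cephnet_run_"),
                            seed = 1L,
                            generator = NULL,
                            registry_path = NULL,
                            drop_outliers = FALSE,
                            z_flag = 4) {
  stopifnot(length(cutoffs) >= 1, all(cutoffs > 0), all(cutoffs < 1),
            all(diff(cutoffs) > 0))
  stopifnot(length(overlay) == 2, overlay[2] > overlay[1])
  structure(list(input = input, cutoffs = cutoffs, overlay = overlay,
                 out_dir = out_dir, seed = as.integer(seed),
                 generator = generator, registry_path = registry_path,
                 drop_outliers = isTRUE(drop_outliers), z_flag = z_flag),
            class = "pipeline_config")
}

#' Validate (and load) a measurement table
#'
#' Enforces the complete-case policy: rows with any missing cell are
#' dropped and logged; duplicate variable names are an error; constant
#' columns are reported in the attribute `constant_columns`.
#'
#' @param x a CSV path (leading `subject_id` column optional), data frame,
#'   or [measurement_table()].
#' @return A [measurement_table()] with at least 3 complete rows.
#' @export
validate_table <- function(x) {
  if (inherits(x, "measurement_table")) {
    df <- as.data.frame(x)
    units <- x$units
  } else {
    df <- if (is.character(x)) {
      if (!file.exists(x)) stop("input file not found: ", x)
      utils::read.csv(x, check.names = FALSE, stringsAsFactors = FALSE)
    } else {
      as.data.frame(x, check.names = FALSE)
    }
    units <- NULL
  }
  if (anyDuplicated(names(df))) {
    stop("duplicate variable names: ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  }
  ids <- if ("subject_id" %in% names(df)) {
    as.character(df$subject_id)
  } else {
    sprintf("subj_%04d", seq_len(nrow(df)))
  }
  df$subject_id <- NULL
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  complete <- stats::complete.cases(m)
  dropped <- ids[!complete]
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 3L) stop("fewer than 3 complete rows after validation")
  if (is.null(units)) {
    units <- stats::setNames(rep("complex", ncol(m)), colnames(m))
    known <- registry_units()
    hit <- intersect(colnames(m), names(known))
    units[hit] <- known[hit]
  }
  tab <- measurement_table(m, units,
                           rejected = if (length(dropped)) {
                             data.frame(subject_id = dropped,
                                        reason = "missing cell(s)",
                                        stringsAsFactors = FALSE)
                           } else NULL)
  sds <- apply(m, 2, stats::sd)
  attr(tab, "constant_columns") <- colnames(m)[sds == 0]
  tab
}

# Count (and optionally drop) |z| > z_flag cells; the flag rule is
# deliberately conservative and removal is opt-in.
.outlier_screen <- function(tab, z_flag, drop) {
  m <- tab$values
  z <- scale(m)
  flagged <- abs(z) > z_flag
  n_cells <- sum(flagged, na.rm = TRUE)
  rows <- rowSums(flagged, na.rm = TRUE) > 0
  if (drop && any(rows)) {
    tab <- measurement_table(m[!rows, , drop = FALSE], tab$units, tab$numbers,
                             rejected = rbind(tab$rejected,
                                              data.frame(subject_id = rownames(m)[rows],
                                                         reason = "outlier |z| flag",
                                                         stringsAsFactors = FALSE)))
  }
  list(table = tab, flagged_cells = n_cells,
       flagged_rows = sum(rows), dropped = drop && any(rows))
}

#' Run the full correlation-network pipeline
#'
#' Stages: load/simulate table, Pearson matrix, weight distribution,
#' thresholded network per cutoff (with the fine-cutoff clusters overlaid
#' on the base network), Kruskal MST with cluster annotations. Writes
#' `corr.csv`, `weights.csv`, `fraction_at_or_above.json`, one GraphML +
#' edge TSV per cutoff, `clusters.json`, `mst.graphml`/`mst.tsv`/
#' `mst.newick`, PNG figures of the weight distribution and MST, and
#' `report.json` / `report.txt`. Deterministic under a fixed seed.
#'
#' @param config a [pipeline_config()].
#' @return The run report (list), invisibly; artifact paths in
#'   `$artifacts`.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stop("pipeline stage '", name, "': ",
                                      conditionMessage(e), call. = FALSE))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  artifacts <- character(0)

  tab <- stage("input", {
    if (is.null(config$input)) {
      gen <- config$generator %||% generator_config(seed = config$seed)
      gen$seed <- config$seed
      generate_measurement_table(gen)
    } else {
      validate_table(config$input)
    }
  })
  tab <- validate_table(tab)
  screen <- stage("outlier-screen",
                  .outlier_screen(tab, config$z_flag, config$drop_outliers))
  tab <- screen$table

  corr <- stage("correlation", pearson_matrix(tab))
  stage("write-corr", write_corr_csv(corr, out("corr.csv")))
  artifacts <- c(artifacts, out("corr.csv"))

  wd <- stage("weights", weight_distribution(corr, cutoffs = config$cutoffs))
  utils::write.csv(data.frame(bin_lo = utils::head(wd$breaks, -1),
                              bin_hi = wd$breaks[-1],
                              count = wd$counts),
                   out("weights.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(wd$fraction_at_or_above),
                       out("fraction_at_or_above.json"),
                       auto_unbox = TRUE, digits = NA)
  artifacts <- c(artifacts, out("weights.csv"), out("fraction_at_or_above.json"))

  graphs <- stage("networks", {
    gs <- lapply(config$cutoffs, function(c) threshold_graph(corr, c))
    names(gs) <- format(config$cutoffs)
    gs
  })
  fine_g <- stage("fine-clusters", threshold_graph(corr, config$overlay[2]))
  clusters <- connected_components(fine_g)
  graphs <- lapply(graphs, overlay_clusters, fine = clusters)
  for (nm in names(graphs)) {
    write_graphml(graphs[[nm]], out(paste0("network_", nm, ".graphml")))
    write_edge_tsv(graphs[[nm]], out(paste0("network_", nm, ".tsv")))
    artifacts <- c(artifacts, out(paste0("network_", nm, ".graphml")),
                   out(paste0("network_", nm, ".tsv")))
  }
  ctab <- cluster_table(clusters)
  jsonlite::write_json(ctab, out("clusters.json"), auto_unbox = FALSE)
  artifacts <- c(artifacts, out("clusters.json"))

  tree <- stage("mst", {
    annotate_tree(kruskal_mst(correlation_to_distance(corr)), clusters)
  })
  write_tree_graphml(tree, out("mst.graphml"))
  write_tree_tsv(tree, out("mst.tsv"))
  writeLines(tree_newick(tree), out("mst.newick"))
  artifacts <- c(artifacts, out("mst.graphml"), out("mst.tsv"),
                 out("mst.newick"))

  fig_ok <- stage("figures", try({
    plot_weight_distribution(wd, out("fig_weights.png"))
    plot_mst(tree, out("fig_mst.png"))
    TRUE
  }, silent = TRUE))
  if (isTRUE(fig_ok)) {
    artifacts <- c(artifacts, out("fig_weights.png"), out("fig_mst.png"))
  }

  # clique check of each fine cluster within the fine-cutoff graph
  cliques <- lapply(ctab, function(members) {
    chk <- is_clique(fine_g, members)
    list(size = length(members), is_clique = chk$is_clique,
         n_missing = nrow(chk$missing))
  })

  cfg_path <- out("config.json")
  jsonlite::write_json(list(cutoffs = config$cutoffs,
                            overlay = config$overlay, seed = config$seed,
                            drop_outliers = config$drop_outliers,
                            z_flag = config$z_flag),
                       cfg_path, auto_unbox = TRUE, digits = NA)
  report <- list(
    tool = "cephnet",
    version = as.character(utils::packageVersion("cephnet")),
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    n_subjects = nrow(tab$values),
    n_variables = ncol(tab$values),
    n_rejected_rows = nrow(tab$rejected),
    outlier_flagged_cells = screen$flagged_cells,
    outlier_flagged_rows = screen$flagged_rows,
    pair_count = pair_count(ncol(tab$values)),
    fraction_at_or_above = as.list(wd$fraction_at_or_above),
    edges_per_cutoff = stats::setNames(
      lapply(graphs, function(g) nrow(g$edges)), names(graphs)),
    clusters = ctab,
    n_clusters = clusters$n_clusters,
    clique_checks = cliques,
    mst = list(total_distance = tree$total_distance,
               n_edges = nrow(tree$edges),
               n_inter_cluster_edges = sum(tree$edges$inter_cluster))
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA)
  writeLines(format_report(report), out("report.txt"))
  report$artifacts <- c(artifacts, cfg_path, out("report.json"),
                        out("report.txt"))
  invisible(report)
}

format_report <- function(report) {
  c(sprintf("cephnet %s run report (seed %d, config %s)", report$version,
            report$seed, report$config_hash),
    sprintf("subjects: %d  variables: %d  pairs: %d  (rejected rows: %d)",
            report$n_subjects, report$n_variables, report$pair_count,
            report$n_rejected_rows),
    sprintf("outlier-flagged cells: %d (rows: %d; removal is opt-in)",
            report$outlier_flagged_cells, report$outlier_flagged_rows),
    "fraction of pairs at or above cutoff:",
    vapply(names(report$fraction_at_or_above), function(c) {
      sprintf("  >= %s : %.4f", c, report$fraction_at_or_above[[c]])
    }, character(1)),
    sprintf("clusters at the fine cutoff (size >= 2): %d", report$n_clusters),
    vapply(names(report$clusters), function(lab) {
      chk <- report$clique_checks[[lab]]
      sprintf("  %s (%d members, %s): %s", lab, chk$size,
              if (chk$is_clique) "clique" else
                sprintf("%d missing pairs", chk$n_missing),
              paste(report$clusters[[lab]], collapse = ", "))
    }, character(1)),
    sprintf("MST: %d edges, total distance %.4f, inter-cluster edges %d",
            report$mst$n_edges, report$mst$total_distance,
            report$mst$n_inter_cluster_edges))
}

#' Plot the edge-weight histogram and CPDF
#'
#' Three panels: signed-r histogram, CPDF of |r|, |r| histogram with the
#' candidate cutoffs marked.
#'
#' @param wd a `ceph_weights`.
#' @param path PNG output path (a device must be available).
#' @return `path`, invisibly.
#' @export
plot_weight_distribution <- function(wd, path) {
  grDevices::png(path, width = 1500, height = 500, res = 110)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  graphics::barplot(wd$signed_counts, names.arg = NULL, space = 0,
                    col = "grey70", border = NA, main = "signed r",
                    xlab = "r", ylab = "pairs")
  graphics::plot(wd$cpdf, main = "CPDF of |r|", xlab = "|r|",
                 ylab = "cumulative probability", verticals = TRUE,
                 do.points = FALSE)
  graphics::barplot(wd$counts, space = 0, col = "grey70", border = NA,
                    main = "|r|", xlab = "|r|", ylab = "pairs")
  invisible(path)
}

#' Plot the annotated MST
#'
#' Force-directed layout; node colours follow cluster annotations (layout
#' is presentation only).
#'
#' @param tree a `ceph_tree`.
#' @param path PNG output path.
#' @param seed layout seed.
#' @return `path`, invisibly.
#' @export
plot_mst <- function(tree, path, seed = 42L) {
  g <- tree_to_igraph(tree)
  labs <- igraph::V(g)$cluster
  pal <- grDevices::hcl.colors(max(2L, length(unique(labs))), "Dynamic")
  cols <- pal[as.integer(factor(labs))]
  cols[labs %in% c("unclustered", "none")] <- "black"
  set.seed(seed)
  lay <- igraph::layout_with_fr(g)
  grDevices::png(path, width = 1000, height = 1000, res = 110)
  on.exit(grDevices::dev.off())
  igraph::plot.igraph(g, layout = lay, vertex.color = cols,
                      vertex.size = 6, vertex.label.cex = 0.6,
                      vertex.label.color = "grey20")
  invisible(path)
}
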