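test_that("build_target_correlation handles the degenerate and identity cases", {
  # one block of all three variables with perfect correlation -> all ones
  cfg <- generator_config(n_subjects = 10,
                          blocks = list(block_spec("A", 1:3, 1, 0)),
                          unassigned_r = 0,
                          variable_names = c("x", "y", "z"),
                          means = rep(0, 3), sds = rep(1, 3))
  expect_equal(unname(build_target_correlation(cfg))[1:3, 1:3],
               matrix(1, 3, 3), ignore_attr = TRUE)
  # zero blocks, zero background -> identity
  cfg2 <- generator_config(n_subjects = 10, blocks = list(), unassigned_r = 0,
                           variable_names = c("x", "y", "z"),
                           means = rep(0, 3), sds = rep(1, 3))
  expect_equal(unname(build_target_correlation(cfg2)), diag(3),
               ignore_attr = TRUE)
})

test_that("two-block targets are PSD (eigen-decomposition oracle)", {
  cfg <- generator_config(n_subjects = 10,
                          blocks = list(block_spec("A", 1:3, 0.9, 0.3),
                                        block_spec("B", 4:6, 0.9, 0.3)),
                          unassigned_r = 0,
                          variable_names = paste0("v", 1:6),
                          means = rep(0, 6), sds = rep(1, 6))
  r <- build_target_correlation(cfg)
  expect_true(isSymmetric(unclass(r), check.attributes = FALSE))
  expect_equal(unname(diag(r)), rep(1, 6))
  expect_true(all(eigen(r, symmetric = TRUE, only.values = TRUE)$values >= -1e-12))
  expect_equal(r[1, 2], 0.9)
  expect_equal(r[1, 4], 0.3)
})

test_that("PSD repair clips mild violations and rejects infeasible specs", {
  mk <- function(u) {
    generator_config(n_subjects = 10,
                     blocks = list(block_spec("A", 1:2, 0.1, 0)),
                     unassigned_r = u, variable_names = c("x", "y", "z"),
                     means = rep(0, 3), sds = rep(1, 3))
  }
  r <- build_target_correlation(mk(0.75))   # slightly non-PSD
  expect_true(attr(r, "psd_projected"))
  expect_lt(attr(r, "max_projection_shift"), 0.05)
  expect_true(all(eigen(r, symmetric = TRUE, only.values = TRUE)$values >= -1e-10))
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_error(build_target_correlation(mk(0.9)), "infeasible.*0.05|infeasible")
})

test_that("block and config invariants are enforced", {
  expect_error(block_spec("A", 1:3, within_r = 0.4, between_r = 0.5),
               "separable")
  expect_error(generator_config(blocks = list(block_spec("A", 1:3, 0.9),
                                              block_spec("B", 3:5, 0.9))),
               "disjoint")
  expect_error(generator_config(n_subjects = 2), "n_subjects")
  expect_error(generator_config(blocks = list(block_spec("A", c(1, 99), 0.9)),
                                variable_names = paste0("v", 1:10),
                                means = rep(0, 10), sds = rep(1, 10)),
               "1..10")
})

test_that("generation is bit-identical under a fixed seed, including serialization", {
  cfg <- generator_config(n_subjects = 50, seed = 123)
  t1 <- generate_measurement_table(cfg)
  t2 <- generate_measurement_table(cfg)
  expect_identical(t1$values, t2$values)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_measurement_table(t1, f1)
  write_measurement_table(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
  t3 <- generate_measurement_table(generator_config(n_subjects = 50, seed = 124))
  expect_false(identical(t1$values, t3$values))
})

test_that("empirical correlations recover the two-block target within the Fisher-z bound", {
  cfg <- generator_config(
    n_subjects = 10000, seed = 9,
    blocks = list(block_spec("A", 1:3, 0.9, 0.3), block_spec("B", 4:6, 0.85, 0.3)),
    unassigned_r = 0, variable_names = paste0("v", 1:6),
    means = c(80, 4, 25, 60, 120, 0.7), sds = c(4, 2, 5, 3, 6, 0.05))
  target <- build_target_correlation(cfg)
  emp <- pearson_matrix(generate_measurement_table(cfg))$r
  expect_lt(max(abs(emp - target)), 0.03)
})

test_that("generated landmark sets honour the template and the seed", {
  tpl <- default_landmark_template(perturbation_sd = 0)
  sets <- generate_landmark_sets(tpl, n = 3, seed = 5)
  for (s in sets) expect_equal(s$points, tpl$mean)
  a <- generate_landmark_sets(n = 4, seed = 42)
  b <- generate_landmark_sets(n = 4, seed = 42)
  expect_identical(lapply(a, `[[`, "points"), lapply(b, `[[`, "points"))
  broken <- default_landmark_template()
  broken$mean <- broken$mean[setdiff(rownames(broken$mean), c("Pt", "Go")), ]
  expect_error(generate_landmark_sets(broken, n = 1), "Pt")
  expect_error(generate_landmark_sets(broken, n = 1), "Go")
})

test_that("landmark files round-trip through CSV and JSON", {
  sets <- random_landmark_sets(3, seed = 8)
  for (ext in c(".csv", ".json")) {
    f <- tempfile(fileext = ext)
    write_landmarks(sets, f)
    back <- read_landmarks(f)
    expect_equal(length(back), 3)
    for (i in 1:3) {
      expect_equal(unname(back[[i]]$points), unname(sets[[i]]$points),
                   tolerance = 1e-12)
      expect_identical(rownames(back[[i]]$points), rownames(sets[[i]]$points))
    }
  }
})

test_that("generator config JSON round-trips and the shipped preset loads", {
  cfg <- generator_config(n_subjects = 100, seed = 77)
  f <- tempfile(fileext = ".json")
  write_generator_config(cfg, f)
  cfg2 <- read_generator_config(f)
  expect_identical(build_target_correlation(cfg),
                   build_target_correlation(cfg2))
  expect_identical(generate_measurement_table(cfg)$values,
                   generate_measurement_table(cfg2)$values)
  shipped <- system.file("extdata", "preset10_blocks.json", package = "cephnet")
  cfg3 <- read_generator_config(shipped)
  expect_equal(length(cfg3$blocks), 10)
  expect_identical(vapply(cfg3$blocks, function(b) b$label, character(1)),
                   c("A-1", "A-2", "B", "C", "D", "E", "F", "G", "H", "I"))
})

test_that("block separability: 0.8 threshold recovers the partition at n = 735", {
  hits <- vapply(1:20, function(s) {
    cfg <- generator_config(seed = s)
    tab <- generate_measurement_table(cfg)
    cc <- connected_components(threshold_graph(pearson_matrix(tab), 0.8))
    part <- partition_of(cc)
    blocks <- lapply(cfg$blocks, function(b) sort(registry_names()[b$members]))
    clusters <- Filter(function(p) length(p) >= 2, part)
    length(clusters) == length(blocks) &&
      all(vapply(blocks, function(b) any(vapply(clusters, identical, logical(1), b)),
                 logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
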