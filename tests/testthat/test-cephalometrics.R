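expected_units <- c(
  mm = 1, mm = 2, deg = 3, mm = 4, deg = 5, mm = 6, mm = 7, mm = 8, deg = 9,
  mm = 10, deg = 11, deg = 12, deg = 13, deg = 14, deg = 15, deg = 16,
  deg = 17, deg = 18, deg = 19, deg = 20, deg = 21, deg = 22, deg = 23,
  mm = 24, deg = 25, mm = 26, deg = 27, mm = 28, mm = 29, deg = 30, mm = 31,
  deg = 32, deg = 33, deg = 34, deg = 35, deg = 36, deg = 37, mm = 38,
  mm = 39, deg = 40, deg = 41, mm = 42, ratio = 43, mm = 44, ratio = 45,
  mm = 46, mm = 47, mm = 48, mm = 49, ratio = 50, deg = 51, deg = 52,
  mm = 53, mm = 54, mm = 55, mm = 56, mm = 57, mm = 58, mm = 59, deg = 60,
  deg = 61, deg = 62, deg = 63, complex = 64, deg = 65)

test_that("the default registry is valid, complete and carries the conventional units", {
  reg <- default_registry()
  expect_length(reg, 65)
  expect_true(validate_registry(reg))
  expect_identical(vapply(reg, function(d) d$no, integer(1)), 1:65)
  expect_identical(unname(registry_units(reg)), names(expected_units))
  expect_false(anyDuplicated(registry_names(reg)) > 0)
})

test_that("composite-index identities hold on random non-degenerate landmark sets", {
  sets <- random_landmark_sets(100, seed = 21)
  reg <- default_registry()
  for (lms in sets) {
    m <- function(no) as.numeric(compute_measurement(lms, no, reg))
    expect_equal(m(23), m(21) - m(22), tolerance = 1e-9)           # ANB = SNA - SNB
    expect_equal(m(13) + m(32) + m(33), 180, tolerance = 1e-9)     # Tweed triangle
    expect_equal(m(62), m(11) + m(17) + m(14), tolerance = 1e-9)   # APDI decomposition
    expect_equal(m(60), m(61) + m(14), tolerance = 1e-9)           # ODI decomposition
    expect_equal(m(37), m(34) + m(35) + m(36), tolerance = 1e-9)   # Bjork sum
    expect_equal(m(29), m(26) - m(28), tolerance = 1e-9)           # Holdaway difference
  }
})

test_that("compute_measurement reports units and looks up by number or name", {
  lms <- landmark_set(default_landmark_template()$mean, "t")
  v <- compute_measurement(lms, 21)
  expect_identical(attr(v, "unit"), "deg")
  expect_equal(as.numeric(compute_measurement(lms, "SNA")), as.numeric(v))
  expect_error(compute_measurement(lms, "no such variable"), "no such")
})

test_that("missing landmarks and degenerate geometry give named errors", {
  tpl <- default_landmark_template()
  pts <- tpl$mean[setdiff(rownames(tpl$mean), "Go"), ]
  lms <- landmark_set(pts, "broken")
  expect_error(compute_measurement(lms, 36), "missing landmark: Go")
  pts2 <- tpl$mean
  pts2["Or", ] <- pts2["Po", ]   # FH collapses
  expect_error(compute_measurement(landmark_set(pts2, "d"), 13), "degenerate|parallel")
})

test_that("rigid motions leave angles and ratios unchanged; scaling scales mm", {
  sets <- random_landmark_sets(40, seed = 33)
  reg <- default_registry()
  units <- registry_units(reg)
  set.seed(34)
  for (lms in sets) {
    ang <- stats::runif(1, -40, 40)
    tr <- stats::runif(2, -90, 90)
    sc <- stats::runif(1, 0.5, 2)
    moved <- transform_landmark_set(lms, angle_deg = ang, translation = tr)
    scaled <- transform_landmark_set(lms, scale = sc)
    base <- vapply(1:65, function(no) as.numeric(compute_measurement(lms, no, reg)),
                   numeric(1))
    m1 <- vapply(1:65, function(no) as.numeric(compute_measurement(moved, no, reg)),
                 numeric(1))
    m2 <- vapply(1:65, function(no) as.numeric(compute_measurement(scaled, no, reg)),
                 numeric(1))
    is_deg <- units %in% c("deg")
    is_mm <- units == "mm"
    is_ratio <- units == "ratio"
    expect_equal(m1[is_deg], base[is_deg], tolerance = 1e-9)
    expect_equal(m1[is_mm], base[is_mm], tolerance = 1e-9)
    expect_equal(m2[is_deg], base[is_deg], tolerance = 1e-9)
    expect_equal(m2[is_ratio], base[is_ratio], tolerance = 1e-9)
    expect_equal(m2[is_mm], sc * base[is_mm], tolerance = 1e-9)
  }
})

test_that("compute_table orders columns, applies the complete-case policy and sweeps cleanly", {
  reg <- default_registry()
  empty <- compute_table(list(), reg)
  expect_equal(nrow(empty$values), 0)
  expect_identical(colnames(empty$values), registry_names(reg))

  sets <- random_landmark_sets(500, seed = 55)
  tab <- compute_table(sets, reg)
  expect_equal(nrow(tab$values), 500)
  expect_equal(nrow(tab$rejected), 0)
  expect_true(all(is.finite(tab$values)))
  # per-primitive range contracts (composites like Sum legitimately exceed 360)
  interior <- c(3, 15, 21, 22, 34, 35, 36, 40, 41, 52, 65)
  expect_true(all(tab$values[, interior] >= 0 & tab$values[, interior] <= 180))
  unsigned_line <- c(5, 9, 11, 12, 18, 20, 25, 27, 30, 51, 61)
  expect_true(all(tab$values[, unsigned_line] >= 0 &
                    tab$values[, unsigned_line] <= 90))
  signed_line <- c(14, 17, 19)
  expect_true(all(tab$values[, signed_line] > -90 &
                    tab$values[, signed_line] <= 90))
  # a subject with broken geometry is rejected and logged, others survive
  tpl <- default_landmark_template()
  bad <- landmark_set(tpl$mean[-1, ], "no_S")
  tab2 <- compute_table(c(sets[1:3], list(bad)), reg)
  expect_equal(nrow(tab2$values), 3)
  expect_equal(tab2$rejected$subject_id, "no_S")
  expect_match(tab2$rejected$reason, "missing landmark: S")
})

test_that("check_redundancy flags affine duplicates and the Bjork identity, not noise", {
  set.seed(66)
  x <- matrix(stats::rnorm(300), 100, 3)
  colnames(x) <- c("a", "b", "c")
  dup <- cbind(x, a_plus_10 = x[, "a"] + 10)
  flags <- check_redundancy(dup)
  expect_equal(nrow(flags), 1)
  expect_setequal(unlist(flags[1, 1:2]), c("a", "a_plus_10"))
  expect_equal(nrow(check_redundancy(x)), 0)

  # Sum vs the SN-to-mandibular-plane angle, computed from the same landmarks
  sets <- random_landmark_sets(150, seed = 67)
  tab <- compute_table(sets)
  sn_mp <- vapply(sets, function(lms) {
    p <- lms$points
    line_line_angle(p["S", ], p["N", ], p["Go", ], p["Me", ])
  }, numeric(1))
  m <- cbind(Sum = tab$values[, "Sum"], `SN-GoMe` = sn_mp)
  flags2 <- check_redundancy(m)
  expect_equal(nrow(flags2), 1)
  expect_gt(flags2$r[1], 0.999)
})

test_that("registry JSON round-trips to identical measurements", {
  reg <- default_registry()
  path <- tempfile(fileext = ".json")
  write_registry(reg, path)
  reg2 <- read_registry(path)
  lms <- random_landmark_sets(5, seed = 77)
  expect_identical(compute_table(lms, reg)$values, compute_table(lms, reg2)$values)
  # the shipped copy is the same registry
  shipped <- system.file("extdata", "registry.json", package = "cephnet")
  expect_identical(compute_table(lms, read_registry(shipped))$values,
                   compute_table(lms, reg)$values)
})

test_that("cyclic or ill-unit registries are rejected", {
  reg <- list(
    measurement_definition(1, "a", "deg",
      list(type = "lincomb", terms = list(list(var = 2, coef = 1)), const = 0)),
    measurement_definition(2, "b", "deg",
      list(type = "lincomb", terms = list(list(var = 1, coef = 1)), const = 0)))
  expect_error(validate_registry(structure(reg, class = "ceph_registry")),
               "cycle")
  reg2 <- list(
    measurement_definition(1, "a", "deg", list(type = "angle3", a = "N", v = "S", b = "Ar")),
    measurement_definition(2, "b", "mm",
      list(type = "lincomb", terms = list(list(var = 1, coef = 2)), const = 0)))
  expect_error(validate_registry(structure(reg2, class = "ceph_registry")),
               "implies 'deg'")
})
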