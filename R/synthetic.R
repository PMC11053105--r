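# Block-structured multivariate Gaussian generator. Stands in for the
# restricted normal-occlusion survey data: it reproduces the qualitative
# correlation structure (tight within-group |r|, weak between-group |r|)
# that drives every downstream network stage, not the marginal
# distributions of any real population.

#' Specify one correlated variable block
#'
#' @param label group label (e.g. `"A-1"`, `"B"`, ... `"I"`).
#' @param members variable numbers belonging to the block.
#' @param within_r target absolute correlation inside the block, in (0, 1\]
#'   (1 is allowed for degenerate perfectly-correlated blocks).
#' @param between_r target absolute correlation to other blocks, in \[0, 1).
#' @return An object of class `block_spec`.
#' @export
block_spec <- function(label, members, within_r, between_r = 0.2) {
  members <- as.integer(members)
  stopifnot(length(members) >= 1, !anyDuplicated(members),
            within_r > 0, within_r <= 1, between_r >= 0, between_r < 1)
  if (within_r <= between_r) {
    stop("block ", label, ": within_r must exceed between_r ",
         "(blocks must be separable)")
  }
  structure(list(label = as.character(label), members = members,
                 within_r = within_r, between_r = between_r),
            class = "block_spec")
}

#' The default 10-block correlation preset
#'
#' Ten blocks mirroring the anatomical variable groups recovered by the
#' correlation-network analysis of a 65-variable cephalometric set (the
#' large incisor-position group split into its two subgroups A-1/A-2):
#' incisor anteroposterior position (A-1), lower-incisor inclination (A-2),
#' upper-incisor inclination (B), maxillo-mandibular anteroposterior
#' relation / facial convexity (C), the overbite-depth composite family (D),
#' facial divergence (E), posterior (F) and anterior (G) vertical facial
#' height, apical-base position relative to the cranial base (H), and
#' mandibular protrusion/growth direction (I). 52 of the 65 variables are
#' assigned; the remaining 13 carry only the background correlation.
#' Within-block targets are fixed in \[0.86, 0.94\].
#'
#' @return List of [block_spec()] objects.
#' @export
default_block_preset <- function() {
  list(
    block_spec("A-1", c(1, 7, 8, 10, 24, 26, 53, 54, 56, 59), 0.92),
    block_spec("A-2", c(3, 9, 20, 27, 32, 33), 0.90),
    block_spec("B",   c(25, 52, 65), 0.88),
    block_spec("C",   c(4, 16, 17, 23), 0.90),
    block_spec("D",   c(60, 61, 63, 64), 0.94),
    block_spec("E",   c(5, 12, 13, 18, 19, 30, 36, 37, 41, 51), 0.86),
    block_spec("F",   c(39, 42, 48), 0.90),
    block_spec("G",   c(47, 49, 55), 0.92),
    block_spec("H",   c(21, 22, 57, 58), 0.88),
    block_spec("I",   c(11, 28, 29, 44, 45), 0.90)
  )
}

#' Generator configuration
#'
#' @param n_subjects number of subjects to simulate (>= 3; the survey scale
#'   is 735).
#' @param blocks list of [block_spec()] objects with disjoint members.
#' @param unassigned_r background correlation for variable pairs involving
#'   a variable in no block.
#' @param means,sds per-variable location and scale in native units; when
#'   `NULL`, taken from the default registry evaluated on the unperturbed
#'   landmark template (means) and unit-typical scatter (sds: 5 deg,
#'   2.5 mm, 0.05 for ratios, 6 for composite indices).
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @param variable_names column names; default the 65 registry names.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 735,
                             blocks = default_block_preset(),
                             unassigned_r = 0.1,
                             means = NULL, sds = NULL,
                             seed = 1L,
                             variable_names = NULL) {
  stopifnot(n_subjects >= 3, unassigned_r >= 0, unassigned_r < 1)
  if (is.null(variable_names)) variable_names <- registry_names()
  p <- length(variable_names)
  members <- unlist(lapply(blocks, function(b) b$members))
  if (anyDuplicated(members)) {
    stop("block member lists must be disjoint")
  }
  if (length(members) && (max(members) > p || min(members) < 1)) {
    stop("block members must be within 1..", p)
  }
  if (is.null(means)) means <- default_variable_means()[seq_len(p)]
  if (is.null(sds)) sds <- default_variable_sds()[seq_len(p)]
  stopifnot(length(means) == p, length(sds) == p, all(sds > 0))
  structure(list(n_subjects = as.integer(n_subjects), blocks = blocks,
                 unassigned_r = unassigned_r, means = as.numeric(means),
                 sds = as.numeric(sds), seed = as.integer(seed),
                 variable_names = variable_names),
            class = "generator_config")
}

#' Default per-variable means: the registry evaluated on the template
#'
#' Evaluating the default registry on the unperturbed landmark template
#' yields a clinically plausible value for every variable; these serve as
#' generator means. They carry no acceptance weight (Pearson correlation is
#' affine-invariant).
#'
#' @return Named numeric vector, one mean per registry variable.
#' @export
default_variable_means <- function() {
  tpl <- default_landmark_template()
  lms <- landmark_set(tpl$mean, subject_id = "template")
  reg <- default_registry()
  tab <- compute_table(list(lms), reg)
  stats::setNames(as.numeric(tab$values[1, ]), colnames(tab$values))
}

#' Default per-variable SDs by unit
#'
#' 5 deg for angles, 2.5 mm for distances, 0.05 for ratios, 6 for the
#' mixed-unit composite — loosely modelled on normal-occlusion norm tables.
#'
#' @return Named numeric vector, one SD per registry variable.
#' @export
default_variable_sds <- function() {
  units <- registry_units()
  sds <- c(deg = 5, mm = 2.5, ratio = 0.05, complex = 6)[units]
  stats::setNames(as.numeric(sds), names(units))
}

#' Build the target correlation matrix implied by a generator config
#'
#' Entries: `within_r` inside each block; the mean of the two blocks'
#' `between_r` across different blocks; `unassigned_r` for any pair
#' involving an unassigned variable; unit diagonal. If the implied matrix
#' is not positive semi-definite it is projected to the nearest PSD
#' correlation matrix by eigenvalue clipping at 0 followed by diagonal
#' re-normalization (recorded in the output attributes); the spec is
#' rejected if the projection moves any entry by more than 0.05.
#'
#' @param config a [generator_config()].
#' @return Correlation matrix with attributes `psd_projected` (logical) and
#'   `max_projection_shift`.
#' @export
build_target_correlation <- function(config) {
  p <- length(config$variable_names)
  r <- matrix(config$unassigned_r, p, p)
  block_of <- rep(NA_character_, p)
  between <- stats::setNames(
    vapply(config$blocks, function(b) b$between_r, numeric(1)),
    vapply(config$blocks, function(b) b$label, character(1)))
  for (b in config$blocks) block_of[b$members] <- b$label
  for (b in config$blocks) {
    r[b$members, b$members] <- b$within_r
    others <- which(!is.na(block_of) & block_of != b$label)
    if (length(others)) {
      r[b$members, others] <- (b$between_r + between[block_of[others]]) / 2
      r[others, b$members] <- t(r[b$members, others])
    }
  }
  diag(r) <- 1
  dimnames(r) <- list(config$variable_names, config$variable_names)

  eig <- eigen(r, symmetric = TRUE)
  projected <- FALSE
  shift <- 0
  if (min(eig$values) < -1e-10) {
    lam <- pmax(eig$values, 0)
    m <- eig$vectors %*% (lam * t(eig$vectors))
    d <- sqrt(diag(m))
    m <- m / tcrossprod(d)
    diag(m) <- 1
    shift <- max(abs(m - r))
    if (shift > 0.05) {
      worst <- which(abs(m - r) == shift, arr.ind = TRUE)[1, ]
      stop("infeasible block spec: PSD projection moves entry (",
           config$variable_names[worst[1]], ", ",
           config$variable_names[worst[2]], ") by ", signif(shift, 3),
           " > 0.05; offending blocks: ",
           paste(unique(stats::na.omit(block_of[worst])), collapse = ", "))
    }
    r <- m
    dimnames(r) <- list(config$variable_names, config$variable_names)
    projected <- TRUE
  }
  attr(r, "psd_projected") <- projected
  attr(r, "max_projection_shift") <- shift
  attr(r, "psd_method") <- "eigenvalue clipping at 0 + diagonal re-normalization"
  r
}

#' Simulate a measurement table with the target correlation structure
#'
#' Samples `n_subjects` rows from a multivariate normal with the target
#' correlation (via the symmetric eigen square root, so PSD-singular
#' targets are allowed), then scales and shifts each column to its native
#' unit. Bit-identical under a fixed seed.
#'
#' @param config a [generator_config()].
#' @return A [measurement_table()] with attribute `target_correlation`.
#' @export
generate_measurement_table <- function(config) {
  if (config$n_subjects < 3L) stop("n_subjects must be >= 3")
  r <- build_target_correlation(config)
  p <- ncol(r)
  eig <- eigen(r, symmetric = TRUE)
  root <- eig$vectors %*% (sqrt(pmax(eig$values, 0)) * t(eig$vectors))
  set.seed(config$seed)
  z <- matrix(stats::rnorm(config$n_subjects * p), config$n_subjects, p)
  x <- z %*% root
  x <- sweep(x, 2, config$sds, `*`)
  x <- sweep(x, 2, config$means, `+`)
  colnames(x) <- config$variable_names
  rownames(x) <- sprintf("subj_%04d", seq_len(config$n_subjects))
  units <- registry_units()
  units <- if (all(config$variable_names %in% names(units))) {
    units[config$variable_names]
  } else {
    stats::setNames(rep("complex", p), config$variable_names)
  }
  tab <- measurement_table(x, units)
  attr(tab, "target_correlation") <- r
  tab
}

#' Read a generator config from JSON
#'
#' Schema: `{"n_subjects":, "seed":, "unassigned_r":,
#' "blocks":[{"label":, "members":[], "within_r":, "between_r":}, ...]}`;
#' optional `means`, `sds`, `variable_names`.
#'
#' @param path JSON file path.
#' @return A [generator_config()].
#' @export
read_generator_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  blocks <- lapply(obj$blocks, function(b) {
    block_spec(b$label, unlist(b$members), b$within_r, b$between_r %||% 0.2)
  })
  generator_config(n_subjects = obj$n_subjects %||% 735,
                   blocks = blocks,
                   unassigned_r = obj$unassigned_r %||% 0.1,
                   means = obj$means, sds = obj$sds,
                   seed = obj$seed %||% 1L,
                   variable_names = obj$variable_names)
}

#' Write a generator config to JSON
#'
#' @param config a [generator_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_generator_config <- function(config, path) {
  obj <- list(n_subjects = config$n_subjects, seed = config$seed,
              unassigned_r = config$unassigned_r,
              blocks = lapply(config$blocks, unclass),
              means = config$means, sds = config$sds,
              variable_names = config$variable_names)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
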