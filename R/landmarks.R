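# Landmark sets: named 2D points for one subject, the geometric source of
# every measurement. Coordinates follow the package convention (x anterior+,
# y superior+, mm, origin at sella in the default template).

#' Landmark names required by the default measurement registry
#'
#' Hard-tissue points (S, N, A, B, Pog, Gn, Me, Go, Ar, Po, Or, ANS, PNS,
#' Pt, Ba), incisor axes (U1T/U1A = upper incisor tip/apex, L1T/L1A lower),
#' molar occlusal points (U6, L6) and the soft-tissue points needed for the
#' esthetic plane (Prn = pronasale, Ls/Li = upper/lower lip, PogS =
#' soft-tissue pogonion).
#'
#' @return Character vector of landmark names.
#' @export
required_landmarks <- function() {
  c("S", "N", "A", "B", "Pog", "Gn", "Me", "Go", "Ar", "Po", "Or",
    "ANS", "PNS", "Pt", "Ba", "U1T", "U1A", "L1T", "L1A",
    "U6", "L6", "Prn", "Ls", "Li", "PogS")
}

#' Construct a landmark set
#'
#' @param points numeric matrix with two columns (x, y) in mm and one named
#'   row per landmark, or a named list of (x, y) pairs.
#' @param subject_id identifier carried through to measurement tables.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, subject_id = "subject") {
  if (is.list(points) && !is.data.frame(points)) {
    nm <- names(points)
    points <- do.call(rbind, lapply(points, as.numeric))
    rownames(points) <- nm
  }
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("landmark coordinates must have 2 columns (x, y)")
  if (is.null(rownames(points)) || anyDuplicated(rownames(points))) {
    stop("landmarks must have unique names")
  }
  if (any(!is.finite(points))) stop("landmark coordinates must be finite")
  colnames(points) <- c("x", "y")
  structure(list(points = points, subject_id = as.character(subject_id)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> subject", x$subject_id, "with",
      nrow(x$points), "landmarks\n")
  invisible(x)
}

# Fetch one landmark as an (x, y) pair, with a named error when absent.
get_landmark <- function(lms, name) {
  pts <- lms$points
  if (!name %in% rownames(pts)) {
    stop("missing landmark: ", name, call. = FALSE)
  }
  as.numeric(pts[name, ])
}

#' Default landmark template
#'
#' Mean (x, y) positions, in mm with sella at the origin, of an idealised
#' adult lateral-cephalometric tracing in the package's coordinate frame
#' (x anterior+, y superior+), plus a per-landmark Gaussian perturbation SD
#' used by [generate_landmark_sets()]. Coordinates are implementation-chosen
#' to produce clinically plausible measurement values; only identities that
#' hold for any non-degenerate configuration are asserted against them.
#'
#' @param perturbation_sd default per-landmark SD in mm (recycled; default
#'   1 mm, a typical inter-observer tracing error).
#' @return A list with elements `mean` (matrix) and `perturbation_sd`
#'   (named numeric vector).
#' @export
default_landmark_template <- function(perturbation_sd = 1.0) {
  xy <- rbind(
    S    = c(0,    0),
    N    = c(70,   5),
    Po   = c(-15, -18),
    Or   = c(60,  -22),
    Ba   = c(-25, -45),
    Ar   = c(-18, -36),
    Pt   = c(8,   -25),
    ANS  = c(68,  -48),
    PNS  = c(18,  -45),
    A    = c(66,  -56),
    B    = c(62,  -95),
    Pog  = c(63, -108),
    Gn   = c(60, -113),
    Me   = c(55, -115),
    Go   = c(-5,  -85),
    U1T  = c(66,  -72.5),
    U1A  = c(57,  -60),
    L1T  = c(63,  -70),
    L1A  = c(55,  -86),
    U6   = c(32,  -63.5),
    L6   = c(32,  -64.5),
    Prn  = c(98,  -30),
    Ls   = c(85,  -62),
    Li   = c(83,  -79),
    PogS = c(72, -108)
  )
  colnames(xy) <- c("x", "y")
  sd <- rep_len(perturbation_sd, nrow(xy))
  names(sd) <- rownames(xy)
  list(mean = xy, perturbation_sd = sd)
}

.validate_template <- function(template) {
  if (!all(c("mean", "perturbation_sd") %in% names(template))) {
    stop("template must have elements 'mean' and 'perturbation_sd'")
  }
  missing <- setdiff(required_landmarks(), rownames(template$mean))
  if (length(missing)) {
    stop("template is missing required landmarks: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sd <- rep_len(template$perturbation_sd, nrow(template$mean))
  if (any(sd < 0)) stop("perturbation_sd must be >= 0")
  invisible(TRUE)
}

#' Generate perturbed landmark sets from a template
#'
#' Each set is the template mean plus independent Gaussian noise per
#' coordinate (SD per landmark from the template). Bit-identical under a
#' fixed seed.
#'
#' @param template a template as from [default_landmark_template()].
#' @param n number of subjects.
#' @param seed integer RNG seed.
#' @return A list of `landmark_set` objects with ids `subj_0001`, ...
#' @export
generate_landmark_sets <- function(template = default_landmark_template(),
                                   n, seed = 1L) {
  .validate_template(template)
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  xy <- template$mean
  sd <- rep_len(template$perturbation_sd, nrow(xy))
  ids <- sprintf("subj_%04d", seq_len(n))
  lapply(seq_len(n), function(i) {
    noise <- matrix(stats::rnorm(length(xy), 0, rep(sd, 2)),
                    nrow = nrow(xy), ncol = 2)
    landmark_set(xy + noise, subject_id = ids[i])
  })
}

#' Read landmark sets from a long-format CSV or JSON file
#'
#' CSV columns: `subject_id, landmark, x, y`. JSON: an object mapping
#' subject id to an object of `landmark: [x, y]`.
#'
#' @param path file path; format inferred from the extension.
#' @return List of `landmark_set` objects.
#' @export
read_landmarks <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    return(lapply(names(raw), function(id) {
      landmark_set(lapply(raw[[id]], function(p) as.numeric(unlist(p))),
                   subject_id = id)
    }))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "landmark", "x", "y")
  if (!all(need %in% names(df))) {
    stop("landmark CSV must have columns: ", paste(need, collapse = ", "))
  }
  lapply(split(df, factor(df$subject_id, levels = unique(df$subject_id))),
         function(d) {
           m <- as.matrix(d[, c("x", "y")])
           rownames(m) <- d$landmark
           landmark_set(m, subject_id = d$subject_id[1])
         })
}

#' Write landmark sets to CSV (long format) or JSON
#'
#' @param sets list of `landmark_set` objects.
#' @param path output path; `.json` selects JSON, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(sets, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- lapply(sets, function(s) {
      stats::setNames(lapply(seq_len(nrow(s$points)),
                             function(i) as.numeric(s$points[i, ])),
                      rownames(s$points))
    })
    names(obj) <- vapply(sets, function(s) s$subject_id, character(1))
    jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = I(17))
  } else {
    df <- do.call(rbind, lapply(sets, function(s) {
      data.frame(subject_id = s$subject_id, landmark = rownames(s$points),
                 x = s$points[, 1], y = s$points[, 2],
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Apply a rigid motion (plus optional scale) to a landmark set
#'
#' @param lms a `landmark_set`.
#' @inheritParams transform_points
#' @return A transformed `landmark_set`.
#' @export
transform_landmark_set <- function(lms, angle_deg = 0, translation = c(0, 0),
                                   scale = 1) {
  landmark_set(transform_points(lms$points, angle_deg, translation, scale),
               subject_id = lms$subject_id)
}
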