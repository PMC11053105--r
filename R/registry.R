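# Declarative measurement registry: each cephalometric variable is a small
# recipe (expression tree) over the geometric primitives in geometry.R, or a
# linear combination / ratio of other variables. The registry is data, not
# code, so composite-index decompositions (APDI, ODI, Sum, ...) remain
# mechanically checkable and the registry can be serialized to JSON.
#
# Recipe types
#   angle3          interior angle a-v-b                         -> deg [0,180]
#   signed_angle3   signed angle at v from ray v->b to ray v->a  -> deg (-180,180]
#   ray_angle       angle between directed rays                  -> deg [0,180]
#   line_angle      angle between two lines (unsigned|signed)    -> deg
#   triangle_angle  interior angle of the triangle of 3 lines    -> deg
#   convexity       180 - angle3, signed by side of line a-b     -> deg
#   dist            point-to-point distance                      -> mm
#   pldist          signed point-to-line distance                -> mm
#   proj            scalar projection of (p - q) on a line       -> mm
#   perp_offset     component of (p - q) normal to a line        -> mm
#   lincomb         const + sum(coef * other variables)
#   ratio           variable / variable                          -> ratio
#
# Point specs are landmark names or list(mid = c(name, name)); line specs are
# list(p = <point>, q = <point>) or list(perp_at = <point>, to = <line>).

MEASUREMENT_UNITS <- c("deg", "mm", "ratio", "complex")

#' Construct a measurement definition
#'
#' @param no variable number (the conventional 1..65 ordering).
#' @param name variable name, used as the column header.
#' @param unit one of `"deg"`, `"mm"`, `"ratio"`, `"complex"`.
#' @param recipe a recipe list (see package vignette for the grammar).
#' @param note optional free-text note, e.g. the sign convention.
#' @return An object of class `ceph_definition`.
#' @export
measurement_definition <- function(no, name, unit, recipe, note = NULL) {
  stopifnot(is.numeric(no), length(no) == 1L, no >= 1)
  if (!unit %in% MEASUREMENT_UNITS) {
    stop("unit must be one of: ", paste(MEASUREMENT_UNITS, collapse = ", "))
  }
  if (is.null(recipe$type)) stop("recipe must have a 'type'")
  structure(list(no = as.integer(no), name = name, unit = unit,
                 recipe = recipe, note = note),
            class = "ceph_definition")
}

# --- recipe evaluation -------------------------------------------------------

eval_point_spec <- function(spec, lms) {
  if (is.character(spec) && length(spec) == 1L) {
    return(get_landmark(lms, spec))
  }
  if (is.list(spec) && !is.null(spec$mid)) {
    mid <- unlist(spec$mid)
    return((eval_point_spec(mid[[1]], lms) + eval_point_spec(mid[[2]], lms)) / 2)
  }
  stop("invalid point spec")
}

eval_line_spec <- function(spec, lms) {
  if (!is.null(spec[["p"]])) {
    return(list(eval_point_spec(spec[["p"]], lms),
                eval_point_spec(spec[["q"]], lms)))
  }
  if (!is.null(spec[["perp_at"]])) {
    base <- eval_line_spec(spec[["to"]], lms)
    d <- base[[2]] - base[[1]]
    at <- eval_point_spec(spec[["perp_at"]], lms)
    return(list(at, at + c(-d[2], d[1])))
  }
  stop("invalid line spec")
}

# Variable numbers a recipe depends on (for topological ordering).
recipe_deps <- function(recipe) {
  switch(recipe$type,
    lincomb = vapply(recipe$terms, function(t) as.integer(t$var), integer(1)),
    ratio = as.integer(c(recipe$num, recipe$den)),
    integer(0)
  )
}

eval_recipe <- function(recipe, lms, values) {
  P <- function(s) eval_point_spec(s, lms)
  L <- function(s) eval_line_spec(s, lms)
  switch(recipe$type,
    angle3 = three_point_angle(P(recipe$a), P(recipe$v), P(recipe$b)),
    signed_angle3 = signed_three_point_angle(P(recipe$a), P(recipe$v),
                                             P(recipe$b)),
    ray_angle = {
      ray_angle(P(recipe$r1$from), P(recipe$r1$to),
                P(recipe$r2$from), P(recipe$r2$to))
    },
    line_angle = {
      l1 <- L(recipe$l1); l2 <- L(recipe$l2)
      line_line_angle(l1[[1]], l1[[2]], l2[[1]], l2[[2]],
                      convention = recipe$convention %||% "unsigned")
    },
    triangle_angle = triangle_interior_angle(L(recipe$l1), L(recipe$l2),
                                             L(recipe$l3)),
    convexity = {
      base <- 180 - three_point_angle(P(recipe$a), P(recipe$v), P(recipe$b))
      side <- signed_point_line_distance(P(recipe$v), P(recipe$a), P(recipe$b),
                                         positive = "anterior")
      if (side < 0) -base else base
    },
    dist = point_distance(P(recipe$p), P(recipe$q)),
    pldist = {
      l <- L(recipe$line)
      signed_point_line_distance(P(recipe$p), l[[1]], l[[2]],
                                 positive = recipe$positive)
    },
    proj = {
      l <- L(recipe$line)
      projection_length(P(recipe$p), P(recipe$q), l[[1]], l[[2]])
    },
    perp_offset = {
      l <- L(recipe$line)
      perpendicular_offset(P(recipe$p), P(recipe$q), l[[1]], l[[2]],
                           positive = recipe$positive %||% "superior")
    },
    lincomb = {
      out <- recipe$const %||% 0
      for (t in recipe$terms) {
        v <- values[[as.character(t$var)]]
        if (is.null(v)) stop("unresolved dependency on variable ", t$var)
        out <- out + t$coef * v
      }
      out
    },
    ratio = {
      den <- values[[as.character(recipe$den)]]
      if (is.null(den)) stop("unresolved dependency on variable ", recipe$den)
      if (abs(den) < 1e-9) stop("degenerate geometry: ratio denominator ~ 0")
      values[[as.character(recipe$num)]] / den
    },
    stop("unknown recipe type: ", recipe$type)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- the default 65-variable registry ---------------------------------------

#' Default cephalometric measurement registry
#'
#' The 65-variable measurement set assembled from nine classical lateral
#' cephalometric analyses (Downs, Tweed, Steiner, Coben, Jarabak, Wits,
#' Ricketts, McNamara, Kim). Angles are in degrees, distances in mm.
#' Sign conventions: anterior is positive for point-to-line distances;
#' for signed line angles the convention is noted per variable. Composite
#' indices (Sum, ODI, APDI, Combination factor, the Holdaway difference)
#' are registered as linear combinations of their components, so their
#' decompositions are exact identities. The Extraction index is an
#' implementation-chosen stand-in composite (its exact classical weighting
#' is not uniquely documented) and is excluded from the identity suite.
#'
#' @return A list of [measurement_definition()] objects, one per variable,
#'   in variable-number order, with attribute `version`.
#' @export
default_registry <- function() {
  LN <- function(p, q) list(p = p, q = q)
  PERP <- function(at, to) list(perp_at = at, to = to)
  MID <- function(a, b) list(mid = c(a, b))

  SN   <- LN("S", "N")          # anterior cranial base
  FH   <- LN("Po", "Or")        # Frankfort horizontal
  MP   <- LN("Go", "Me")        # mandibular plane
  GOGN <- LN("Go", "Gn")
  FP   <- LN("N", "Pog")        # facial plane
  PP   <- LN("PNS", "ANS")      # palatal plane
  OP   <- LN(MID("U1T", "L1T"), MID("U6", "L6"))  # functional occlusal plane
  EP   <- LN("Prn", "PogS")     # esthetic (E-) plane
  U1AX <- LN("U1A", "U1T")      # upper incisor long axis
  L1AX <- LN("L1A", "L1T")      # lower incisor long axis
  AB   <- LN("A", "B")
  NA_  <- LN("N", "A")
  NB   <- LN("N", "B")
  APOG <- LN("A", "Pog")
  YAX  <- LN("S", "Gn")
  BAN  <- LN("Ba", "N")
  PTGN <- LN("Pt", "Gn")
  PTV  <- PERP("Pt", FH)        # pterygoid vertical
  NPRP <- PERP("N", FH)         # nasion perpendicular
  AVRT <- PERP("A", FH)         # vertical through point A

  d <- measurement_definition
  defs <- list(
    d(1, "Incisor overjet", "mm",
      list(type = "proj", p = "U1T", q = "L1T", line = OP),
      "offset of U1 edge anterior to L1 edge, along the occlusal plane"),
    d(2, "Incisor overbite", "mm",
      list(type = "perp_offset", p = "L1T", q = "U1T", line = OP,
           positive = "superior"),
      "vertical overlap normal to the occlusal plane; positive = U1 below L1"),
    d(3, "Interincisal angle", "deg",
      list(type = "ray_angle", r1 = list(from = "U1T", to = "U1A"),
           r2 = list(from = "L1T", to = "L1A"))),
    d(4, "Convexity of point A", "mm",
      list(type = "pldist", p = "A", line = FP, positive = "anterior"),
      "point A to the facial plane N-Pog, anterior positive"),
    d(5, "Lower facial height", "deg",
      list(type = "line_angle", l1 = PP, l2 = MP),
      "palatal plane to mandibular plane angle"),
    d(6, "Upper molar to PTV", "mm",
      list(type = "pldist", p = "U6", line = PTV, positive = "anterior")),
    d(7, "L1 to A-Pog", "mm",
      list(type = "pldist", p = "L1T", line = APOG, positive = "anterior")),
    d(8, "U1 to A-Pog", "mm",
      list(type = "pldist", p = "U1T", line = APOG, positive = "anterior")),
    d(9, "L1 inclination", "deg",
      list(type = "line_angle", l1 = L1AX, l2 = APOG),
      "lower incisor axis to the A-Pog line"),
    d(10, "Lower lip to E-plane", "mm",
      list(type = "pldist", p = "Li", line = EP, positive = "anterior")),
    d(11, "Facial angle", "deg",
      list(type = "line_angle", l1 = FP, l2 = FH)),
    d(12, "Facial axis", "deg",
      list(type = "line_angle", l1 = BAN, l2 = PTGN)),
    d(13, "FMA", "deg",
      list(type = "triangle_angle", l1 = FH, l2 = MP, l3 = L1AX),
      "Tweed triangle interior angle at FH x mandibular plane"),
    d(14, "Palatal plane angle", "deg",
      list(type = "line_angle", l1 = FH, l2 = PP, convention = "signed"),
      "positive when the palatal plane tilts down anteriorly (ANS below PNS)"),
    d(15, "Mandibular Arc", "deg",
      list(type = "angle3", a = "Ar", v = "Go", b = "Gn"),
      "ramus-to-corpus flexure measured at gonion toward gnathion"),
    d(16, "Facial convexity", "deg",
      list(type = "convexity", a = "N", v = "A", b = "Pog"),
      "180 minus angle N-A-Pog, positive when A is anterior to N-Pog"),
    d(17, "A-B plane angle", "deg",
      list(type = "line_angle", l1 = AB, l2 = FP, convention = "signed"),
      "negative when B lies posterior to A relative to the facial plane"),
    d(18, "Y axis", "deg",
      list(type = "line_angle", l1 = FH, l2 = YAX)),
    d(19, "Occlusal plane angle", "deg",
      list(type = "line_angle", l1 = FH, l2 = OP, convention = "signed"),
      "positive when the occlusal plane tilts down anteriorly"),
    d(20, "L1 to Occlusal plane angle", "deg",
      list(type = "line_angle", l1 = L1AX, l2 = OP)),
    d(21, "SNA", "deg", list(type = "angle3", a = "S", v = "N", b = "A")),
    d(22, "SNB", "deg", list(type = "angle3", a = "S", v = "N", b = "B")),
    d(23, "ANB", "deg",
      list(type = "signed_angle3", a = "A", v = "N", b = "B"),
      "positive when A is anterior to B as seen from N; equals SNA - SNB"),
    d(24, "U1 to NA", "mm",
      list(type = "pldist", p = "U1T", line = NA_, positive = "anterior")),
    d(25, "U1 to NA Angle", "deg",
      list(type = "line_angle", l1 = U1AX, l2 = NA_)),
    d(26, "L1 to NB", "mm",
      list(type = "pldist", p = "L1T", line = NB, positive = "anterior")),
    d(27, "L1 to NB Angle", "deg",
      list(type = "line_angle", l1 = L1AX, l2 = NB)),
    d(28, "Pog to NB", "mm",
      list(type = "pldist", p = "Pog", line = NB, positive = "anterior")),
    d(29, "Pog & L1 to NB (diff.)", "mm",
      list(type = "lincomb", terms = list(list(var = 26, coef = 1),
                                          list(var = 28, coef = -1)),
           const = 0),
      "Holdaway difference: (L1 to NB) minus (Pog to NB)"),
    d(30, "Occlusal Plane to SN", "deg",
      list(type = "line_angle", l1 = OP, l2 = SN)),
    d(31, "Wits Appraisal", "mm",
      list(type = "proj", p = "A", q = "B", line = OP),
      "AO-BO: offset of A anterior to B along the occlusal plane"),
    d(32, "IMPA", "deg",
      list(type = "triangle_angle", l1 = MP, l2 = L1AX, l3 = FH),
      "Tweed triangle interior angle at mandibular plane x L1 axis"),
    d(33, "FMIA", "deg",
      list(type = "triangle_angle", l1 = L1AX, l2 = FH, l3 = MP),
      "Tweed triangle interior angle at L1 axis x FH"),
    d(34, "Saddle angle", "deg",
      list(type = "angle3", a = "N", v = "S", b = "Ar")),
    d(35, "Articular angle", "deg",
      list(type = "angle3", a = "S", v = "Ar", b = "Go")),
    d(36, "Gonion angle", "deg",
      list(type = "angle3", a = "Ar", v = "Go", b = "Me")),
    d(37, "Sum", "deg",
      list(type = "lincomb", terms = list(list(var = 34, coef = 1),
                                          list(var = 35, coef = 1),
                                          list(var = 36, coef = 1)),
           const = 0),
      "Bjork sum = saddle + articular + gonial = 360 + SN-to-MP angle"),
    d(38, "Anterior cranial base", "mm",
      list(type = "dist", p = "S", q = "N")),
    d(39, "Posterior cranial base", "mm",
      list(type = "dist", p = "S", q = "Ar")),
    d(40, "Upper gonial angle", "deg",
      list(type = "angle3", a = "Ar", v = "Go", b = "N")),
    d(41, "Lower gonial angle", "deg",
      list(type = "angle3", a = "N", v = "Go", b = "Me")),
    d(42, "Ramus height", "mm",
      list(type = "dist", p = "Ar", q = "Go")),
    d(43, "Posterior cranial base to ramus ratio", "ratio",
      list(type = "ratio", num = 39, den = 42)),
    d(44, "Mandibular body length", "mm",
      list(type = "dist", p = "Go", q = "Me")),
    d(45, "Body to anterior cranial base ratio", "ratio",
      list(type = "ratio", num = 44, den = 38)),
    d(46, "Facial depth", "mm",
      list(type = "dist", p = "N", q = "Go"),
      "linear depth N-Go (the mm-valued depth, distinct from the facial angle)"),
    d(47, "Facial length on Y-axis", "mm",
      list(type = "dist", p = "S", q = "Gn")),
    d(48, "Posterior facial height", "mm",
      list(type = "dist", p = "S", q = "Go")),
    d(49, "Anterior facial height", "mm",
      list(type = "dist", p = "N", q = "Me")),
    d(50, "Posterior to anterior facial height ratio", "ratio",
      list(type = "ratio", num = 48, den = 49)),
    d(51, "Occlusal plane to GoGn", "deg",
      list(type = "line_angle", l1 = OP, l2 = GOGN)),
    d(52, "U1 to SN angle", "deg",
      list(type = "ray_angle", r1 = list(from = "S", to = "N"),
           r2 = list(from = "U1T", to = "U1A")),
      "directed convention so that proclination reads above 90 degrees"),
    d(53, "U1 to facial plane", "mm",
      list(type = "pldist", p = "U1T", line = FP, positive = "anterior")),
    d(54, "L1 to facial plane", "mm",
      list(type = "pldist", p = "L1T", line = FP, positive = "anterior")),
    d(55, "Lower anterior facial height", "mm",
      list(type = "dist", p = "ANS", q = "Me")),
    d(56, "Upper Lip to E-Plane", "mm",
      list(type = "pldist", p = "Ls", line = EP, positive = "anterior")),
    d(57, "Nasion perpendicular to point A", "mm",
      list(type = "pldist", p = "A", line = NPRP, positive = "anterior")),
    d(58, "Pog-N perpendicular", "mm",
      list(type = "pldist", p = "Pog", line = NPRP, positive = "anterior")),
    d(59, "U1 to A vertical", "mm",
      list(type = "pldist", p = "U1T", line = AVRT, positive = "anterior")),
    d(60, "ODI", "deg",
      list(type = "lincomb", terms = list(list(var = 61, coef = 1),
                                          list(var = 14, coef = 1)),
           const = 0),
      "overbite depth indicator = (A-B to mandibular plane) + palatal plane angle"),
    d(61, "A-B to mandibular plane", "deg",
      list(type = "line_angle", l1 = AB, l2 = MP)),
    d(62, "APDI", "deg",
      list(type = "lincomb", terms = list(list(var = 11, coef = 1),
                                          list(var = 17, coef = 1),
                                          list(var = 14, coef = 1)),
           const = 0),
      "anteroposterior dysplasia indicator = facial + A-B plane + palatal plane angles"),
    d(63, "Combination factor", "deg",
      list(type = "lincomb", terms = list(list(var = 60, coef = 1),
                                          list(var = 62, coef = 1)),
           const = 0),
      "ODI + APDI"),
    d(64, "Extraction Index", "complex",
      list(type = "lincomb", terms = list(list(var = 63, coef = 1),
                                          list(var = 3, coef = 0.2),
                                          list(var = 10, coef = 1)),
           const = -26),
      paste("synthetic stand-in composite (combination factor, interincisal",
            "angle and lip protrusion); excluded from the identity suite")),
    d(65, "U1 to FH plane", "deg",
      list(type = "ray_angle", r1 = list(from = "Po", to = "Or"),
           r2 = list(from = "U1T", to = "U1A")),
      "directed convention, typically above 90 degrees")
  )
  structure(defs, class = "ceph_registry", version = "1.0")
}

#' Variable names of a registry, in registration order
#' @param registry a registry as from [default_registry()].
#' @return Character vector of variable names.
#' @export
registry_names <- function(registry = default_registry()) {
  vapply(registry, function(d) d$name, character(1))
}

#' Variable units of a registry
#' @inheritParams registry_names
#' @return Named character vector (names = variable names).
#' @export
registry_units <- function(registry = default_registry()) {
  stats::setNames(vapply(registry, function(d) d$unit, character(1)),
                  registry_names(registry))
}

# Topological evaluation order over lincomb/ratio dependencies.
registry_order <- function(registry) {
  nos <- vapply(registry, function(d) d$no, integer(1))
  if (anyDuplicated(nos)) stop("duplicate variable numbers in registry")
  deps <- lapply(registry, function(d) recipe_deps(d$recipe))
  unknown <- setdiff(unlist(deps), nos)
  if (length(unknown)) {
    stop("registry references undefined variable numbers: ",
         paste(unknown, collapse = ", "))
  }
  order <- integer(0)
  done <- stats::setNames(rep(FALSE, length(nos)), nos)
  remaining <- seq_along(registry)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i) {
      all(done[as.character(deps[[i]])])
    }, logical(1))]
    if (!length(ready)) {
      stop("registry has a dependency cycle among variables: ",
           paste(nos[remaining], collapse = ", "))
    }
    order <- c(order, ready)
    done[as.character(nos[ready])] <- TRUE
    remaining <- setdiff(remaining, ready)
  }
  order
}

#' Validate a measurement registry
#'
#' Checks unique variable numbers and names, known units, resolvable
#' (acyclic) dependencies, and unit consistency of composite recipes
#' (homogeneous linear combinations must carry their components' unit;
#' mixed-unit combinations must be declared `complex`).
#'
#' @inheritParams registry_names
#' @return `TRUE` invisibly; errors describe the first violation found.
#' @export
validate_registry <- function(registry = default_registry()) {
  nms <- registry_names(registry)
  if (anyDuplicated(nms)) stop("duplicate variable names in registry")
  registry_order(registry)  # errors on cycles/unknown deps
  units <- registry_units(registry)
  by_no <- stats::setNames(units, vapply(registry, function(d) d$no, integer(1)))
  for (d in registry) {
    if (d$recipe$type == "lincomb") {
      dep_units <- unique(by_no[as.character(recipe_deps(d$recipe))])
      expected <- if (length(dep_units) == 1L) dep_units else "complex"
      if (d$unit != expected) {
        stop("variable [", d$no, "] ", d$name, ": declared unit '", d$unit,
             "' but linear combination implies '", expected, "'")
      }
    }
    if (d$recipe$type == "ratio" && d$unit != "ratio") {
      stop("variable [", d$no, "] ", d$name, ": ratio recipe must have unit 'ratio'")
    }
  }
  invisible(TRUE)
}

#' Compute one measurement for one subject
#'
#' Dependencies on other registry variables (for composite indices) are
#' resolved recursively against `registry`.
#'
#' @param landmarks a [landmark_set()].
#' @param defn a [measurement_definition()], or a variable number/name
#'   looked up in `registry`.
#' @param registry registry used to resolve composite dependencies.
#' @return The measurement value (numeric scalar) with attribute `unit`.
#' @export
compute_measurement <- function(landmarks, defn,
                                registry = default_registry()) {
  if (is.numeric(defn) || is.character(defn)) {
    key <- defn
    hit <- if (is.numeric(key)) {
      which(vapply(registry, function(d) d$no, integer(1)) == key)
    } else {
      which(registry_names(registry) == key)
    }
    if (length(hit) != 1L) stop("no such registry variable: ", key)
    defn <- registry[[hit]]
  }
  values <- list()
  compute_one <- function(d) {
    key <- as.character(d$no)
    if (!is.null(values[[key]])) return(values[[key]])
    for (dep in recipe_deps(d$recipe)) {
      hit <- which(vapply(registry, function(x) x$no, integer(1)) == dep)
      if (!length(hit)) stop("unresolved dependency on variable ", dep)
      compute_one(registry[[hit]])
    }
    v <- eval_recipe(d$recipe, landmarks, values)
    values[[key]] <<- v
    v
  }
  v <- compute_one(defn)
  if (!is.finite(v)) {
    stop("non-finite value for variable [", defn$no, "] ", defn$name)
  }
  structure(v, unit = defn$unit)
}

# --- measurement tables ------------------------------------------------------

#' Construct a measurement table
#'
#' The central exchange format: subjects x variables numeric matrix with
#' per-column unit and variable-number metadata.
#'
#' @param values numeric matrix, one row per subject (rownames = subject
#'   ids), one named column per variable.
#' @param units named character vector of per-variable units.
#' @param numbers optional named integer vector of variable numbers.
#' @param rejected optional data frame logging rejected subjects.
#' @return An object of class `measurement_table`.
#' @export
measurement_table <- function(values, units, numbers = NULL, rejected = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("values must have column names")
  units <- units[colnames(values)]
  if (any(is.na(units))) stop("every column needs a unit")
  if (is.null(numbers)) {
    numbers <- stats::setNames(seq_len(ncol(values)), colnames(values))
  }
  structure(list(values = values, units = units,
                 numbers = numbers,
                 rejected = rejected %||%
                   data.frame(subject_id = character(0), reason = character(0))),
            class = "measurement_table")
}

#' @export
print.measurement_table <- function(x, ...) {
  cat("<measurement_table>", nrow(x$values), "subjects x",
      ncol(x$values), "variables\n")
  if (nrow(x$rejected)) cat("  rejected rows:", nrow(x$rejected), "\n")
  invisible(x)
}

#' @export
as.data.frame.measurement_table <- function(x, ...) {
  data.frame(subject_id = rownames(x$values), as.data.frame(x$values),
             check.names = FALSE, row.names = NULL)
}

#' Compute the full measurement table for a list of landmark sets
#'
#' Variables are evaluated in dependency (topological) order; column order
#' in the output follows the registry's variable numbering. A subject whose
#' geometry fails any measurement (missing landmark, degenerate line) is
#' rejected whole and logged — the complete-case policy.
#'
#' @param landmark_sets list of [landmark_set()] objects.
#' @param registry a validated registry.
#' @return A [measurement_table()].
#' @export
compute_table <- function(landmark_sets, registry = default_registry()) {
  validate_registry(registry)
  ord <- registry_order(registry)
  nms <- registry_names(registry)
  units <- registry_units(registry)
  nos <- stats::setNames(vapply(registry, function(d) d$no, integer(1)), nms)

  rows <- list()
  rejected <- list()
  for (lms in landmark_sets) {
    res <- tryCatch({
      values <- list()
      for (i in ord) {
        d <- registry[[i]]
        values[[as.character(d$no)]] <- eval_recipe(d$recipe, lms, values)
      }
      out <- vapply(registry, function(d) values[[as.character(d$no)]],
                    numeric(1))
      if (any(!is.finite(out))) stop("non-finite measurement")
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(subject_id = lms$subject_id, reason = conditionMessage(res),
                   stringsAsFactors = FALSE)
    } else {
      rows[[lms$subject_id]] <- res
    }
  }
  values <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    matrix(numeric(0), nrow = 0, ncol = length(nms))
  }
  colnames(values) <- nms
  measurement_table(values, units, nos,
                    rejected = if (length(rejected)) {
                      do.call(rbind, rejected)
                    } else NULL)
}

#' Flag geometrically redundant variable pairs
#'
#' Variable pairs whose absolute Pearson correlation exceeds `threshold`
#' are near-exact geometric duplicates (e.g. the Bjork Sum and the
#' SN-to-mandibular-plane angle, which differ by the constant 360). This is
#' the executable form of the curation rule that removes variables with a
#' geometric correlation of +1 from a measurement set.
#'
#' @param table a [measurement_table()] (or numeric matrix) with >= 3 rows.
#' @param threshold absolute-correlation threshold, default 0.999.
#' @return Data frame with columns `var1`, `var2`, `r` (possibly 0 rows).
#' @export
check_redundancy <- function(table, threshold = 0.999) {
  x <- if (inherits(table, "measurement_table")) table$values else as.matrix(table)
  if (nrow(x) < 3L) stop("need at least 3 subjects")
  r <- suppressWarnings(stats::cor(x))
  r[!is.finite(r)] <- 0
  idx <- which(upper.tri(r) & abs(r) > threshold, arr.ind = TRUE)
  data.frame(var1 = colnames(x)[idx[, 1]], var2 = colnames(x)[idx[, 2]],
             r = r[idx], stringsAsFactors = FALSE)
}

# --- serialization -----------------------------------------------------------

#' Write a registry to JSON
#'
#' @param registry a registry.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  obj <- list(version = attr(registry, "version") %||% "1.0",
              variables = lapply(registry, unclass))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read a registry from JSON
#'
#' @param path path to a JSON file written by [write_registry()] (or a
#'   user-supplied custom registry in the same schema).
#' @return A validated registry.
#' @export
read_registry <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  defs <- lapply(obj$variables, function(v) {
    measurement_definition(v$no, v$name, v$unit, v$recipe, v$note)
  })
  reg <- structure(defs, class = "ceph_registry",
                   version = obj$version %||% "1.0")
  validate_registry(reg)
  reg
}

#' Write a measurement table to CSV
#'
#' Leading `subject_id` column, then one column per variable with the
#' variable name as header.
#'
#' @param table a [measurement_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
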