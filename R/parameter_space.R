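# Input parameter space and idealized coronary geometry for the two
# multi-vessel-disease patient types (2L: LAD+RCA lesions; 3L: LAD+LCx+RCA).

#' Conversion factor: 1 mmHg in Pa
#' @keywords internal
MMHG_PA <- 133.322

#' Load the input parameter table for a patient type
#'
#' Returns the packaged table of model input parameters with their uniform
#' sampling ranges, as used by the virtual cohort generator. The table holds
#' 29 scalar parameters (the two myocardial resistance fractions are separate
#' entries sharing one printed range) plus, per stenotic lesion, a severity
#' percentage and a length, and one stenosis position parameter shared by all
#' lesions. This yields 34 parameters for patient type \code{"2L"}
#' (lesions in LAD and RCA) and 36 for \code{"3L"} (LAD, LCx and RCA).
#'
#' @param patient_type `"2L"` or `"3L"`.
#' @return An object of class `parameter_space`: a list with elements
#'   `patient_type`, `entries` (data frame with columns `name`, `lower`,
#'   `upper`, `unit`, `role`, `description`), `dimension`, and `lesions`
#'   (character vector of lesion vessels).
#' @export
load_parameter_table <- function(patient_type) {
  patient_type <- match_patient_type(patient_type)
  path <- system.file("extdata", "parameter_table.csv", package = "corovpc",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  lesions <- lesion_vessels(patient_type)
  drop <- setdiff(c("LCx", "LAD", "RCA"), lesions)
  if (length(drop) > 0) {
    tab <- tab[!(tab$name %in% c(paste0("sev_", drop), paste0("len_", drop))), ,
               drop = FALSE]
  }
  rownames(tab) <- NULL
  space <- structure(
    list(patient_type = patient_type, entries = tab,
         dimension = nrow(tab), lesions = lesions),
    class = "parameter_space")
  validate_parameter_space(space)
  space
}

#' @keywords internal
match_patient_type <- function(patient_type) {
  if (!is.character(patient_type) || length(patient_type) != 1L ||
      !(patient_type %in% c("2L", "3L"))) {
    stop("unknown patient type: must be \"2L\" or \"3L\"", call. = FALSE)
  }
  patient_type
}

#' @keywords internal
lesion_vessels <- function(patient_type) {
  switch(patient_type, "2L" = c("LAD", "RCA"), "3L" = c("LCx", "LAD", "RCA"))
}

#' Validate a parameter space object
#'
#' Checks the structural invariants: strictly increasing bounds, unique names,
#' and the exact dimension (34 for 2L, 36 for 3L).
#' @param space a `parameter_space`.
#' @return the space, invisibly; errors on violation.
#' @export
validate_parameter_space <- function(space) {
  stopifnot(inherits(space, "parameter_space"))
  tab <- space$entries
  if (anyDuplicated(tab$name)) stop("parameter names must be unique")
  if (!all(tab$lower < tab$upper)) {
    bad <- tab$name[tab$lower >= tab$upper]
    stop("parameter bounds must satisfy lower < upper: ", paste(bad, collapse = ", "))
  }
  expected <- if (space$patient_type == "2L") 34L else 36L
  if (nrow(tab) != expected || space$dimension != expected) {
    stop("parameter space for ", space$patient_type, " must have dimension ",
         expected, ", got ", nrow(tab))
  }
  invisible(space)
}

#' @export
print.parameter_space <- function(x, ...) {
  cat("<parameter_space> patient-", x$patient_type, ", d = ", x$dimension,
      " (lesions: ", paste(x$lesions, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Construct a parameter vector in a space
#'
#' @param space a `parameter_space`.
#' @param values numeric vector of length `space$dimension`, in the entries'
#'   printed units; may be named (checked against the space ordering).
#' @return named numeric vector of class `parameter_vector` with the space
#'   attached as attribute `space`.
#' @export
parameter_vector <- function(space, values) {
  validate_parameter_space(space)
  if (length(values) != space$dimension) {
    stop("values must have length ", space$dimension, ", got ", length(values))
  }
  if (!is.null(names(values))) {
    if (!identical(names(values), space$entries$name)) {
      stop("names of values do not match the parameter space ordering")
    }
  } else {
    names(values) <- space$entries$name
  }
  out <- as.numeric(values)
  names(out) <- space$entries$name
  bad <- out < space$entries$lower | out > space$entries$upper
  if (any(bad)) {
    stop("values out of bounds for: ", paste(names(out)[bad], collapse = ", "))
  }
  structure(out, space = space, class = c("parameter_vector", "numeric"))
}

#' Midpoint parameter vector of a space
#' @param space a `parameter_space`.
#' @return a `parameter_vector` at the centre of every range.
#' @export
midpoint_vector <- function(space) {
  parameter_vector(space, (space$entries$lower + space$entries$upper) / 2)
}

#' Murray's law daughter radius
#'
#' At a bifurcation obeying Murray's law the cubes of the radii balance:
#' `mother^3 = daughter^3 + side^3`. Given the mother and side-branch radii
#' this returns the radius of the continuing daughter vessel.
#'
#' @param mother_radius mother vessel radius (cm), positive.
#' @param side_radius side branch radius (cm), in (0, mother_radius).
#' @return daughter radius (cm).
#' @export
murray_daughter_radius <- function(mother_radius, side_radius) {
  stopifnot(is.numeric(mother_radius), is.numeric(side_radius))
  if (any(mother_radius <= 0)) stop("mother_radius must be positive")
  if (any(side_radius < 0)) stop("side_radius must be non-negative")
  if (any(side_radius >= mother_radius)) {
    stop("degenerate bifurcation: side_radius must be smaller than mother_radius")
  }
  (mother_radius^3 - side_radius^3)^(1 / 3)
}

#' Build the idealized coronary geometry
#'
#' Constructs the three-vessel epicardial tree: a 2 cm left main (LM)
#' bifurcating into a 10 cm LAD and an 8 cm LCx, and a 10 cm RCA arising
#' directly from the aortic root. All side branches have a 0.1 cm radius,
#' successive main-line radii follow Murray's law, and the wall thickness of
#' every coronary segment is 10% of its radius. Lesion slots are C1 (RCA),
#' the proximal segment C7 (LAD) and C11 (LCx, patient-3L only); the C7 host
#' segment is twice as long as C1 and C11 so that the longer LAD lesions fit.
#'
#' The LM proximal radius and the left-tree flow split are not printed in the
#' source material; they default to 0.2 cm and LAD:LCx:RCA = 50:30:20 and are
#' configurable.
#'
#' @param patient_type `"2L"` or `"3L"`.
#' @param lm_radius proximal LM radius in cm (default 0.2).
#' @param side_radius side-branch radius in cm (default 0.1).
#' @param flow_split resting flow split over `c(LAD, LCx, RCA)`, summing to 1.
#' @return object of class `coronary_geometry`: list with `segments`
#'   (data frame: `id`, `vessel`, `parent`, `length_cm`, `radius_cm`,
#'   `wall_cm`, `flow_frac` = fraction of the vessel inlet flow carried,
#'   `side` = logical), `lesion_slots` (data frame: `vessel`, `segment`,
#'   `pos_lower`, `pos_upper`), `flow_split`, `lm_radius`.
#' @export
build_geometry <- function(patient_type, lm_radius = 0.2, side_radius = 0.1,
                           flow_split = c(LAD = 0.5, LCx = 0.3, RCA = 0.2)) {
  patient_type <- match_patient_type(patient_type)
  stopifnot(lm_radius > side_radius, abs(sum(flow_split) - 1) < 1e-12)
  left <- flow_split[["LAD"]] + flow_split[["LCx"]]
  # LM splits into LAD and LCx with radii cubes proportional to flow shares
  r_lad0 <- lm_radius * (flow_split[["LAD"]] / left)^(1 / 3)
  r_lcx0 <- murray_daughter_radius(lm_radius, r_lad0)

  taper <- function(r0, n) {
    # successive radii after each side bifurcation (Murray's law)
    r <- numeric(n)
    r[1] <- r0
    for (i in seq_len(n - 1)) r[i + 1] <- murray_daughter_radius(r[i], side_radius)
    r
  }
  frac <- function(r) {
    # cumulative fraction of vessel inlet flow carried by each segment
    # (side branch takes its Murray share r_side^3 / r_mother^3 at each split)
    cumprod(c(1, (r[-1]^3 / r[-length(r)]^3)))
  }

  seg <- function(id, vessel, parent, len, r, phi, side = FALSE) {
    data.frame(id = id, vessel = vessel, parent = parent, length_cm = len,
               radius_cm = r, wall_cm = 0.1 * r, flow_frac = phi,
               side = side, stringsAsFactors = FALSE)
  }

  r_lad <- taper(r_lad0, 4); phi_lad <- frac(r_lad)
  r_rca <- taper(r_lad0, 4); phi_rca <- frac(r_rca)  # RCA mirrors the LAD
  r_lcx <- taper(r_lcx0, 3); phi_lcx <- frac(r_lcx)

  segments <- rbind(
    seg("C5", "LM", "aorta", 2.0, lm_radius, 1.0),
    # LAD: 1 + 4 + 2.5 + 2.5 = 10 cm, three side branches
    seg("C6",  "LAD", "C5",  1.0, r_lad[1], phi_lad[1]),
    seg("C7",  "LAD", "C6",  4.0, r_lad[2], phi_lad[2]),
    seg("C8a", "LAD", "C7",  2.5, r_lad[3], phi_lad[3]),
    seg("C8b", "LAD", "C8a", 2.5, r_lad[4], phi_lad[4]),
    seg("S1",  "LAD", "C6",  3.0, side_radius, NA, side = TRUE),
    seg("C9",  "LAD", "C7",  3.0, side_radius, NA, side = TRUE),
    seg("C10", "LAD", "C8a", 3.0, side_radius, NA, side = TRUE),
    # RCA: 2 + 3 + 3 + 2 = 10 cm, three side branches
    seg("C1", "RCA", "aorta", 2.0, r_rca[1], phi_rca[1]),
    seg("C2", "RCA", "C1",    3.0, r_rca[2], phi_rca[2]),
    seg("C3", "RCA", "C2",    3.0, r_rca[3], phi_rca[3]),
    seg("C4", "RCA", "C3",    2.0, r_rca[4], phi_rca[4]),
    seg("R1", "RCA", "C1",    3.0, side_radius, NA, side = TRUE),
    seg("R2", "RCA", "C2",    3.0, side_radius, NA, side = TRUE),
    seg("R3", "RCA", "C3",    3.0, side_radius, NA, side = TRUE),
    # LCx: 2 + 3 + 3 = 8 cm, two side branches
    seg("C11", "LCx", "C5",  2.0, r_lcx[1], phi_lcx[1]),
    seg("C12", "LCx", "C11", 3.0, r_lcx[2], phi_lcx[2]),
    seg("C13", "LCx", "C12", 3.0, r_lcx[3], phi_lcx[3]),
    seg("M1",  "LCx", "C11", 3.0, side_radius, NA, side = TRUE),
    seg("P1",  "LCx", "C12", 3.0, side_radius, NA, side = TRUE)
  )

  slots <- data.frame(
    vessel = c("RCA", "LAD", "LCx"),
    segment = c("C1", "C7", "C11"),
    pos_lower = 0.1, pos_upper = 0.9,
    stringsAsFactors = FALSE)
  slots <- slots[slots$vessel %in% lesion_vessels(patient_type), , drop = FALSE]
  rownames(slots) <- NULL

  structure(
    list(patient_type = patient_type, segments = segments,
         lesion_slots = slots,
         flow_split = flow_split, lm_radius = lm_radius,
         side_radius = side_radius),
    class = "coronary_geometry")
}

#' @export
print.coronary_geometry <- function(x, ...) {
  cat("<coronary_geometry> patient-", x$patient_type, ": ",
      nrow(x$segments), " segments, lesion slots: ",
      paste(x$lesion_slots$segment, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Total main-line length of a vessel in a geometry
#' @keywords internal
vessel_length <- function(geometry, vessel) {
  s <- geometry$segments
  sum(s$length_cm[s$vessel == vessel & !s$side])
}
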