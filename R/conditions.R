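#' Generation configuration for the two-line stimulus set
#'
#' Collects the geometric constants of the stimulus set: overall extent
#' (the visual angle a stimulus subtends), nominal gap between the two
#' segment centers, the per-condition parameter step `delta` separating
#' the base from the nonaccidental boundary, jitter bounds and display
#' eccentricity.  The replication configuration differs only in its
#' larger center gap (2.25 deg) and blocked trial ordering.
#'
#' @param extent stimulus bounding extent in deg (default 3).
#' @param gap nominal distance between segment centers in deg
#'   (default 1.5; the replication used 2.25).
#' @param deltas named numeric vector overriding per-condition parameter
#'   steps.  Defaults: 10 deg for angular parameters, 0.35 deg for
#'   offsets/slides (0.5 for the crossing condition), 0.3 deg sagitta for
#'   curvature.
#' @param pos_jitter,ori_jitter display jitter half-ranges (deg).
#' @param eccentricity distance of each stimulus from fixation (deg).
#' @param substitute_degenerate replace mirror-degenerate exemplars with
#'   rotated poses (default TRUE); if FALSE such exemplars raise an error.
#' @return list of class `nap_config`.
#' @export
nap_config <- function(extent = 3, gap = 1.5, deltas = NULL,
                       pos_jitter = 0.25, ori_jitter = 5,
                       eccentricity = 5, substitute_degenerate = TRUE) {
  stopifnot(extent > 0, gap > 0, gap < extent * 1.5)
  d <- .nap_default_deltas()
  if (!is.null(deltas)) {
    bad <- setdiff(names(deltas), names(d))
    if (length(bad)) stop("unknown condition in deltas: ",
                          paste(bad, collapse = ", "))
    d[names(deltas)] <- deltas
  }
  structure(list(extent = extent, gap = gap, deltas = d,
                 pos_jitter = pos_jitter, ori_jitter = ori_jitter,
                 eccentricity = eccentricity,
                 substitute_degenerate = isTRUE(substitute_degenerate)),
            class = "nap_config")
}

#' @rdname nap_config
#' @export
replication_config <- function(...) nap_config(gap = 2.25, ...)

.nap_default_deltas <- function() {
  c(alignment = 0.35, collinearity_between = 10, generic_to_L = 0.35,
    generic_to_T = 0.35, generic_to_X = 0.5, T_to_L = 0.35,
    X_to_T = 0.35, cotermination = 0.35, expansion_constant = 10,
    collinearity_within = 10, curvature_edges = 0.3,
    curvature_axis = 0.3, curvature_control = 0.3)
}

# Internal registry.  Each entry: category, param_name, boundary,
# admissible parameter range (function of config) and a geometry builder
# mapping (param, cfg) -> list of nap_segment in the canonical pose.
# Conventions: origin at stimulus center (stimuli are re-centered after
# building), y increases upward, all units deg of visual angle.
.nap_condition_registry <- function() {
  HALF <- function(cfg) cfg$extent / 2
  list(
    alignment = list(
      category = "between_objects",
      param_name = "lateral_offset_deg", boundary = 0,
      range = function(cfg) c(0, 0.9 * cfg$gap),
      build = function(p, cfg) {
        L <- cfg$extent - cfg$deltas[["alignment"]]
        x0 <- sqrt(cfg$gap^2 - p^2) / 2   # keeps center gap exact
        list(nap_segment(c(-x0,  p / 2), 90, L),
             nap_segment(c( x0, -p / 2), 90, L))
      }),
    collinearity_between = list(
      category = "between_objects",
      param_name = "angular_deviation_deg", boundary = 0,
      range = function(cfg) c(-80, 80),
      build = function(p, cfg) {
        L <- min(cfg$gap - 0.05, cfg$extent - cfg$gap)
        list(nap_segment(c(-cfg$gap / 2, 0), 0, L),
             nap_segment(c( cfg$gap / 2, 0), p, L))
      }),
    generic_to_L = list(
      category = "between_objects",
      param_name = "apex_separation_deg", boundary = 0,
      range = function(cfg) c(0, 1.5),
      build = function(p, cfg) {
        s <- sin(pi / 4); cc <- cos(pi / 4)   # right-angle chevron
        La <- HALF(cfg) / s
        Lb <- La - cfg$deltas[["generic_to_L"]]
        ua <- c(-s, cc); ub <- c(s, cc)
        list(nap_segment(La / 2 * ua, 135, La),
             nap_segment((p + Lb / 2) * ub, 45, Lb))
      }),
    generic_to_T = list(
      category = "between_objects",
      param_name = "endpoint_height_deg", boundary = 0,
      range = function(cfg) c(0, 1.5),
      build = function(p, cfg) {
        xb <- 0.3
        Lb <- 2 * (sqrt(cfg$gap^2 - xb^2) - cfg$deltas[["generic_to_T"]])
        list(nap_segment(c(0, 0), 0, cfg$extent),
             nap_segment(c(xb, p + Lb / 2), 90, Lb))
      }),
    generic_to_X = list(
      category = "between_objects",
      param_name = "endpoint_height_deg", boundary = -0.35,
      range = function(cfg) c(-1, 1),
      build = function(p, cfg) {
        xb <- 0.3
        pb <- -0.35 + cfg$deltas[["generic_to_X"]]   # base height
        Lb <- 2 * (sqrt(cfg$gap^2 - xb^2) - pb)
        list(nap_segment(c(0, 0), 0, cfg$extent),
             nap_segment(c(xb, p + Lb / 2), 90, Lb))
      }),
    T_to_L = list(
      category = "between_objects",
      param_name = "contact_from_end_deg", boundary = 0,
      range = function(cfg) c(0, cfg$extent / 2),
      build = function(p, cfg) {
        dd <- cfg$deltas[["T_to_L"]]
        Lb <- min(2 * sqrt(max(cfg$gap^2 - (HALF(cfg) - dd)^2, 0.25)),
                  0.9 * cfg$extent)
        list(nap_segment(c(0, 0), 0, cfg$extent),
             nap_segment(c(HALF(cfg) - p, Lb / 2), 90, Lb))
      }),
    X_to_T = list(
      category = "between_objects",
      param_name = "overhang_deg", boundary = 0,
      range = function(cfg) c(0, 1.2),
      build = function(p, cfg) {
        Lb <- 2.6 * cfg$extent / 3
        xb <- min(sqrt(max(cfg$gap^2 - (Lb / 2 - cfg$deltas[["X_to_T"]])^2,
                           0.04)),
                  HALF(cfg) - 0.15)
        list(nap_segment(c(0, 0), 0, cfg$extent),
             nap_segment(c(xb, Lb / 2 - p), 90, Lb))
      }),
    cotermination = list(
      category = "within_object",
      param_name = "vertex_gap_deg", boundary = 0,
      range = function(cfg) c(0, 1.5),
      build = function(p, cfg) {
        s <- sin(pi / 3); cc <- cos(pi / 3)   # 120 deg opening
        La <- HALF(cfg) / s
        Lb <- La - cfg$deltas[["cotermination"]]
        ua <- c(-s, cc); ub <- c(s, cc)
        list(nap_segment(La / 2 * ua, 150, La),
             nap_segment((p + Lb / 2) * ub, 30, Lb))
      }),
    expansion_constant = list(
      category = "within_object",
      param_name = "divergence_angle_deg", boundary = 0,
      range = function(cfg) c(0, 55),
      build = function(p, cfg) {
        list(nap_segment(c(0,  cfg$gap / 2),  p / 2, cfg$extent),
             nap_segment(c(0, -cfg$gap / 2), -p / 2, cfg$extent))
      }),
    collinearity_within = list(
      category = "within_object",
      param_name = "bend_angle_deg", boundary = 0,
      range = function(cfg) c(-85, 85),
      build = function(p, cfg) {
        dd <- cfg$deltas[["collinearity_within"]]
        L <- min(cfg$gap, HALF(cfg)) / cos(dd * pi / 360)
        h <- p * pi / 360                     # half bend, radians
        ctr <- c(L / 2 * cos(h), L / 2 * sin(h))
        list(nap_segment(ctr * c(-1, 1), 180 - p / 2, L),
             nap_segment(ctr,            p / 2,       L))
      }),
    curvature_edges = list(
      category = "within_object",
      param_name = "edge_sagitta_deg", boundary = 0,
      range = function(cfg) c(-1.4, 1.4),
      build = function(p, cfg) {
        list(nap_segment(c(0,  cfg$gap / 2), 0, cfg$extent,  p),
             nap_segment(c(0, -cfg$gap / 2), 0, cfg$extent, -p))
      }),
    curvature_axis = list(
      category = "within_object",
      param_name = "axis_sagitta_deg", boundary = 0,
      range = function(cfg) c(-1.4, 1.4),
      build = function(p, cfg) {
        list(nap_segment(c(0,  cfg$gap / 2), 0, cfg$extent, p),
             nap_segment(c(0, -cfg$gap / 2), 0, cfg$extent, p))
      }),
    curvature_control = list(
      category = "control",
      param_name = "sagitta_deg", boundary = 0,
      range = function(cfg) c(-1.4, 1.4),
      build = function(p, cfg) {
        list(nap_segment(c(0, 0), 0, cfg$extent, p))
      })
  )
}

#' Condition taxonomy of the two-line stimulus set
#'
#' Thirteen conditions: seven between-object relations (alignment,
#' collinearity between objects, and five junction-type conditions),
#' five within-object relations (cotermination, expansion vs. constant
#' separation, collinearity within an object, curvature of the edges,
#' curvature of the configural axis), plus a single-line curvature
#' control.  Each condition is reduced to one scalar parameter whose
#' boundary value is the nonaccidental configuration; the base sits at
#' `boundary + delta` and the metric variant at `boundary + 2 delta`, so
#' base-to-variant distances are exactly equal in parameter units.
#'
#' @param config a [nap_config()].
#' @return data.frame with columns `name`, `category`, `param_name`,
#'   `boundary_value`, `delta`, `gap`.
#' @export
condition_specs <- function(config = nap_config()) {
  reg <- .nap_condition_registry()
  data.frame(
    name = names(reg),
    category = vapply(reg, `[[`, "", "category"),
    param_name = vapply(reg, `[[`, "", "param_name"),
    boundary_value = vapply(reg, `[[`, 0, "boundary"),
    delta = as.numeric(config$deltas[names(reg)]),
    gap = config$gap,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Names of the 13 stimulus conditions
#' @return character vector of length 13.
#' @export
condition_names <- function() names(.nap_condition_registry())
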