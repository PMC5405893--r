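#' Stimulus objects
#'
#' A stimulus is one or two [nap_segment()]s plus labels: the condition it
#' belongs to, which member of a triplet it is (`base`, `metric`,
#' `nonaccidental`), the exemplar index, the scalar parameter value that
#' generated it, and the mirroring that was applied.
#'
#' @param segments list of `nap_segment`.
#' @param condition condition name (see [condition_specs()]).
#' @param variant one of `"base"`, `"metric"`, `"nonaccidental"`.
#' @param exemplar integer exemplar index (0-based).
#' @param param_value scalar parameter value of the generating axis.
#' @param mirror one of `"none"`, `"left_right"`, `"up_down"`, `"both"`.
#' @param stimulus_id identifier; constructed from the labels if `NULL`.
#' @return An object of class `nap_stimulus`.
#' @export
nap_stimulus <- function(segments, condition, variant, exemplar = 0L,
                         param_value = NA_real_, mirror = "none",
                         stimulus_id = NULL) {
  stopifnot(is.list(segments), length(segments) %in% 1:2,
            all(vapply(segments, inherits, logical(1), "nap_segment")))
  variant <- match.arg(variant, c("base", "metric", "nonaccidental"))
  mirror <- match.arg(mirror, c("none", "left_right", "up_down", "both"))
  if (is.null(stimulus_id))
    stimulus_id <- sprintf("%s_e%d_%s", condition, exemplar, variant)
  structure(
    list(stimulus_id = stimulus_id, condition = condition,
         variant = variant, exemplar = as.integer(exemplar),
         segments = segments, param_value = param_value, mirror = mirror),
    class = "nap_stimulus")
}

#' @export
print.nap_stimulus <- function(x, ...) {
  cat(sprintf("<nap_stimulus> %s: condition %s, %s variant, exemplar %d, param %.4g, mirror %s, %d segment(s)\n",
              x$stimulus_id, x$condition, x$variant, x$exemplar,
              x$param_value, x$mirror, length(x$segments)))
  invisible(x)
}

stimulus_point_cloud <- function(s, n = 129) {
  do.call(rbind, lapply(s$segments, segment_points, n = n))
}

#' Bounding box and extent of a stimulus
#'
#' The extent is the larger side of the axis-aligned bounding box of the
#' stimulus geometry (arcs sampled densely), i.e. the visual angle the
#' stimulus subtends.
#'
#' @param s a `nap_stimulus`.
#' @return `stimulus_bbox`: list with `xlim`, `ylim`, `center`;
#'   `stimulus_extent`: scalar degrees.
#' @export
stimulus_bbox <- function(s) {
  pts <- stimulus_point_cloud(s)
  xlim <- range(pts[, 1]); ylim <- range(pts[, 2])
  list(xlim = xlim, ylim = ylim,
       center = c(mean(xlim), mean(ylim)))
}

#' @rdname stimulus_bbox
#' @export
stimulus_extent <- function(s) {
  b <- stimulus_bbox(s)
  max(diff(b$xlim), diff(b$ylim))
}

recenter_stimulus <- function(s) {
  ctr <- stimulus_bbox(s)$center
  s$segments <- lapply(s$segments, seg_translate, dxy = -ctr)
  s
}

translate_stimulus <- function(s, dxy) {
  s$segments <- lapply(s$segments, seg_translate, dxy = dxy)
  s
}

rotate_stimulus <- function(s, angle_deg, about = NULL) {
  if (is.null(about)) about <- stimulus_bbox(s)$center
  s$segments <- lapply(s$segments, seg_rotate, angle_deg = angle_deg,
                       about = about)
  s
}

#' Mirror a stimulus about its bounding-box midline
#'
#' Reflects the geometry about the vertical (`left_right`) or horizontal
#' (`up_down`) midline of the stimulus bounding box.  Condition, variant
#' and exemplar labels are preserved; the `mirror` field is composed with
#' the applied axis (two identical mirrorings cancel).
#'
#' @param s a `nap_stimulus`.
#' @param axis `"left_right"` or `"up_down"`.
#' @return The mirrored `nap_stimulus`.
#' @export
mirror_stimulus <- function(s, axis = c("left_right", "up_down")) {
  axis <- match.arg(axis)
  b <- stimulus_bbox(s)
  m <- if (axis == "left_right") b$center[1] else b$center[2]
  s$segments <- lapply(s$segments, seg_mirror, axis = axis, m = m)
  s$mirror <- compose_mirror(s$mirror, axis)
  s
}

compose_mirror <- function(current, axis) {
  states <- c(none = 0L, left_right = 1L, up_down = 2L, both = 3L)
  inv <- names(states)
  new <- bitwXor(states[[current]], states[[axis]])
  inv[new + 1L]
}

#' Distance between the two segment centers
#'
#' @param s a two-segment `nap_stimulus`.
#' @return Euclidean distance in degrees of visual angle.
#' @export
center_gap <- function(s) {
  if (length(s$segments) != 2L)
    stop("center_gap() requires a two-segment stimulus; '",
         s$stimulus_id, "' has ", length(s$segments))
  sqrt(sum((s$segments[[1]]$center - s$segments[[2]]$center)^2))
}

#' Apply positional and orientation jitter to a stimulus
#'
#' Draws a whole-stimulus translation with each coordinate uniform in
#' `[-pos_bound, pos_bound]` degrees and a whole-stimulus rotation
#' uniform in `[-ori_bound, ori_bound]` degrees about the stimulus
#' bounding-box center, emulating the per-stimulus display jitter of the
#' search task.  Uses R's current RNG stream, so results are
#' deterministic under `set.seed()`.
#'
#' @param s a `nap_stimulus`.
#' @param pos_bound positional jitter half-range in deg (default 0.25).
#' @param ori_bound orientation jitter half-range in deg (default 5).
#' @return The jittered `nap_stimulus`.
#' @export
apply_jitter <- function(s, pos_bound = 0.25, ori_bound = 5) {
  dxy <- stats::runif(2, -pos_bound, pos_bound)
  rot <- stats::runif(1, -ori_bound, ori_bound)
  s <- rotate_stimulus(s, rot)
  translate_stimulus(s, dxy)
}
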