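#' Line-segment primitives in degrees of visual angle
#'
#' A stimulus is built from one or two segments.  Each segment is a
#' shallow circular arc described by its chord: `center` (chord midpoint),
#' `orientation` (chord direction, degrees counterclockwise from
#' horizontal), `length` (chord length) and `sagitta` (signed
#' perpendicular offset of the arc midpoint from the chord midpoint;
#' 0 is a straight line, positive bulges toward the left normal of the
#' chord direction).  All quantities are degrees of visual angle; the
#' representation never touches pixels.
#'
#' Orientation is canonicalized to `[0, 180)`; flipping the chord
#' direction flips the sign of the sagitta, so the canonical form is
#' unique for a given point set.
#'
#' @param center numeric length-2, chord midpoint (deg).
#' @param orientation chord direction in degrees CCW from horizontal.
#' @param length chord length in deg, must be positive.
#' @param sagitta signed arc height in deg; `|sagitta| < length/2`
#'   (shallow-arc regime).
#' @return An object of class `nap_segment`.
#' @export
nap_segment <- function(center, orientation, length, sagitta = 0) {
  stopifnot(is.numeric(center), length(center) == 2L, is.finite(center))
  if (!is.finite(length) || length <= 0)
    stop("segment length must be positive, got ", length)
  if (!is.finite(sagitta) || abs(sagitta) >= length / 2)
    stop("|sagitta| must be < length/2 (shallow arc): sagitta = ",
         sagitta, ", length = ", length)
  ori <- orientation %% 360
  if (ori >= 180) {
    ori <- ori - 180
    sagitta <- -sagitta
  }
  structure(
    list(center = as.numeric(center), orientation = as.numeric(ori),
         length = as.numeric(length), sagitta = as.numeric(sagitta)),
    class = "nap_segment")
}

#' @export
print.nap_segment <- function(x, ...) {
  cat(sprintf(
    "<nap_segment> center (%.3f, %.3f) deg, orientation %.2f deg, length %.3f deg, sagitta %.3f deg\n",
    x$center[1], x$center[2], x$orientation, x$length, x$sagitta))
  invisible(x)
}

#' Chord endpoints of a segment
#'
#' @param seg a `nap_segment`.
#' @return 2x2 matrix, one endpoint per row.
#' @export
segment_endpoints <- function(seg) {
  u <- c(cos(seg$orientation * pi / 180), sin(seg$orientation * pi / 180))
  rbind(seg$center - seg$length / 2 * u,
        seg$center + seg$length / 2 * u)
}

#' Sample points along a segment (arc-aware)
#'
#' Straight segments are sampled linearly; curved segments along the
#' circular arc defined by chord plus sagitta.
#'
#' @param seg a `nap_segment`.
#' @param n number of sample points.
#' @return n x 2 matrix of (x, y) points in deg.
#' @export
segment_points <- function(seg, n = 65) {
  ep <- segment_endpoints(seg)
  if (abs(seg$sagitta) < 1e-12) {
    t <- seq(0, 1, length.out = n)
    return(cbind(ep[1, 1] + t * (ep[2, 1] - ep[1, 1]),
                 ep[1, 2] + t * (ep[2, 2] - ep[1, 2])))
  }
  th <- seg$orientation * pi / 180
  nrm <- c(-sin(th), cos(th))          # left normal of chord direction
  h <- seg$length / 2
  s <- seg$sagitta
  R <- (h^2 + s^2) / (2 * abs(s))
  # circle center lies opposite the bulge
  O <- seg$center + (s - sign(s) * R) * nrm
  a1 <- atan2(ep[1, 2] - O[2], ep[1, 1] - O[1])
  a2 <- atan2(ep[2, 2] - O[2], ep[2, 1] - O[1])
  am <- atan2(seg$center[2] + s * nrm[2] - O[2],
              seg$center[1] + s * nrm[1] - O[1])
  # choose the arc from a1 to a2 passing through the arc midpoint am
  d <- (a2 - a1) %% (2 * pi)
  dm <- (am - a1) %% (2 * pi)
  if (dm > d) d <- d - 2 * pi          # go the other way round
  ang <- a1 + seq(0, 1, length.out = n) * d
  cbind(O[1] + R * cos(ang), O[2] + R * sin(ang))
}

seg_translate <- function(seg, dxy) {
  nap_segment(seg$center + dxy, seg$orientation, seg$length, seg$sagitta)
}

seg_rotate <- function(seg, angle_deg, about = c(0, 0)) {
  a <- angle_deg * pi / 180
  Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  ctr <- as.numeric(Rm %*% (seg$center - about)) + about
  nap_segment(ctr, seg$orientation + angle_deg, seg$length, seg$sagitta)
}

# Reflect about the vertical line x = m (left_right) or horizontal
# line y = m (up_down).  Reflections reverse handedness, so the sagitta
# sign flips along with the orientation mapping.
seg_mirror <- function(seg, axis = c("left_right", "up_down"), m = 0) {
  axis <- match.arg(axis)
  if (axis == "left_right") {
    ctr <- c(2 * m - seg$center[1], seg$center[2])
    nap_segment(ctr, 180 - seg$orientation, seg$length, -seg$sagitta)
  } else {
    ctr <- c(seg$center[1], 2 * m - seg$center[2])
    nap_segment(ctr, -seg$orientation, seg$length, -seg$sagitta)
  }
}
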