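#' Rasterization configuration
#'
#' Display convention of the search task: white strokes on a mid-gray
#' background.  Defaults give 128 x 128 px images (4 deg canvas at 32
#' px/deg) with 2 px anti-aliased strokes, keeping the smallest
#' geometric manipulations at or above 2 px.
#'
#' @param pixels_per_degree raster resolution (px/deg).
#' @param canvas_extent square canvas side in deg.
#' @param line_width stroke width in px.
#' @param foreground,background gray levels in `[0, 1]`; must differ.
#' @param anti_aliasing logical; linear coverage ramp at stroke borders.
#' @return list of class `render_config`.
#' @export
render_config <- function(pixels_per_degree = 32, canvas_extent = 4,
                          line_width = 2, foreground = 1, background = 0.5,
                          anti_aliasing = TRUE) {
  stopifnot(pixels_per_degree > 0, canvas_extent > 0, line_width > 0)
  if (foreground == background)
    stop("foreground and background gray levels must differ")
  structure(list(pixels_per_degree = pixels_per_degree,
                 canvas_extent = canvas_extent, line_width = line_width,
                 foreground = foreground, background = background,
                 anti_aliasing = isTRUE(anti_aliasing)),
            class = "render_config")
}

#' Rasterize a stimulus to a grayscale matrix
#'
#' Renders each segment as a stroke of constant pixel width along the
#' straight chord or circular arc (arcs approximated by dense polylines,
#' error well below filter scale).  The matrix uses image convention:
#' rows are y (top row = largest y), columns are x; pixel centers lie on
#' a grid symmetric about the canvas center, so mirroring a stimulus
#' corresponds exactly to mirroring the matrix.
#'
#' @param s a [nap_stimulus()] (geometry centered near the origin).
#' @param cfg a [render_config()].
#' @return numeric matrix with values in `[background, foreground]`
#'   (exactly two levels when `anti_aliasing = FALSE`).
#' @export
rasterize <- function(s, cfg = render_config()) {
  n <- round(cfg$canvas_extent * cfg$pixels_per_degree)
  img <- matrix(cfg$background, n, n)
  if (length(s$segments) == 0L) return(img)
  ppd <- cfg$pixels_per_degree
  half <- cfg$canvas_extent / 2
  r_px <- cfg$line_width / 2
  pad <- r_px / ppd
  # distance field per pixel, computed locally around dense samples
  distf <- matrix(Inf, n, n)
  for (k in seq_along(s$segments)) {
    seg <- s$segments[[k]]
    b <- apply(segment_points(seg, 9), 2, range)
    if (any(abs(b) > half - pad))
      stop("segment ", k, " of stimulus '", s$stimulus_id,
           "' exceeds the canvas extent (", cfg$canvas_extent, " deg)")
    npts <- max(2L, ceiling(seg$length * ppd * 4))
    pts <- segment_points(seg, npts)
    # to pixel coordinates: col = (x + half) * ppd + 0.5, pixel centers
    # at integer col/row in 1..n
    px <- (pts[, 1] + half) * ppd + 0.5
    py <- (half - pts[, 2]) * ppd + 0.5
    rad <- ceiling(r_px + 1.5)
    for (i in seq_len(nrow(pts))) {
      c0 <- max(1L, floor(px[i] - rad)); c1 <- min(n, ceiling(px[i] + rad))
      r0 <- max(1L, floor(py[i] - rad)); r1 <- min(n, ceiling(py[i] + rad))
      cols <- c0:c1; rows <- r0:r1
      d <- sqrt(outer((rows - py[i])^2, (cols - px[i])^2, "+"))
      blk <- distf[rows, cols, drop = FALSE]
      distf[rows, cols] <- pmin(blk, d)
    }
  }
  if (cfg$anti_aliasing) {
    cov <- pmin(1, pmax(0, r_px + 0.5 - distf))
  } else {
    cov <- (distf <= r_px) * 1
  }
  img + cov * (cfg$foreground - cfg$background)
}

#' Write / read a grayscale stimulus image as 8-bit PNG
#'
#' @param img numeric matrix in `[0, 1]` (image convention, as returned
#'   by [rasterize()]).
#' @param path file path.
#' @export
write_stimulus_png <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname write_stimulus_png
#' @export
read_stimulus_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' Rasterize every stimulus of a set
#'
#' @param set a `nap_stimulus_set`.
#' @param cfg a [render_config()].
#' @param dir optional directory; when given, each image is also written
#'   as `<stimulus_id>.png`.
#' @return named list of image matrices keyed by `stimulus_id`.
#' @export
rasterize_set <- function(set, cfg = render_config(), dir = NULL) {
  out <- list()
  for (tr in set)
    for (v in c("base", "metric", "nonaccidental")) {
      s <- tr[[v]]
      img <- rasterize(s, cfg)
      out[[s$stimulus_id]] <- img
      if (!is.null(dir))
        write_stimulus_png(img, file.path(dir, paste0(s$stimulus_id, ".png")))
    }
  out
}
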