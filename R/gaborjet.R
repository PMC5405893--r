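#' Gabor-jet model configuration
#'
#' A V1-like image representation: complex Gabor filters at several
#' log-spaced spatial frequencies and orientations, whose response
#' magnitudes are sampled at a square grid of image locations ("jets").
#' Defaults follow the configuration commonly used with this model
#' family: 12 x 12 grid, 5 scales, 8 orientations (2,880 magnitudes per
#' image), frequencies log-spaced from 2 to 16 cycles/image.
#'
#' @param grid_size jets per side.
#' @param n_scales number of spatial-frequency scales.
#' @param n_orientations number of orientations in `[0, pi)`.
#' @param freq_range range in cycles per image, `c(low, high)`.
#' @param sigma_factor Gaussian envelope s.d. as a fraction of the
#'   wavelength (controls bandwidth; default 0.35 keeps the largest
#'   kernel inside a 128 px image).
#' @return list of class `jet_config`.  Frequencies are stored strictly
#'   decreasing across scales (coarse scale index = lowest frequency
#'   last).
#' @export
jet_config <- function(grid_size = 12, n_scales = 5, n_orientations = 8,
                       freq_range = c(2, 16), sigma_factor = 0.35) {
  stopifnot(grid_size >= 1, n_scales >= 1, n_orientations >= 1,
            length(freq_range) == 2, all(freq_range > 0))
  freqs <- exp(seq(log(max(freq_range)), log(min(freq_range)),
                   length.out = n_scales))
  structure(list(grid_size = as.integer(grid_size),
                 n_scales = as.integer(n_scales),
                 n_orientations = as.integer(n_orientations),
                 frequencies = freqs, sigma_factor = sigma_factor),
            class = "jet_config")
}

#' Orientations (radians) of a jet configuration
#' @param cfg a [jet_config()].
#' @export
jet_orientations <- function(cfg) {
  seq(0, pi, length.out = cfg$n_orientations + 1)[seq_len(cfg$n_orientations)]
}

#' Build the complex Gabor filter bank
#'
#' Each kernel is a quadrature pair: a Gaussian envelope times a complex
#' exponential carrier, with the residual DC response removed by
#' subtracting a scaled copy of the envelope, so a uniform image yields
#' (numerically) zero response.
#'
#' @param image_side image side in px.
#' @param cfg a [jet_config()].
#' @return list of class `gabor_bank`: `kernels` is an
#'   `n_scales x n_orientations` list matrix of complex matrices.
#' @export
make_filter_bank <- function(image_side, cfg = jet_config()) {
  oris <- jet_orientations(cfg)
  kernels <- vector("list", cfg$n_scales * cfg$n_orientations)
  dim(kernels) <- c(cfg$n_scales, cfg$n_orientations)
  for (si in seq_len(cfg$n_scales)) {
    f <- cfg$frequencies[si]            # cycles per image
    lambda <- image_side / f            # wavelength in px
    sigma <- cfg$sigma_factor * lambda
    hw <- ceiling(2.5 * sigma)
    if (2 * hw + 1 > image_side)
      stop(sprintf("kernel support %d px exceeds image side %d px (scale %d, frequency %.3g c/img)",
                   2 * hw + 1, image_side, si, f))
    x <- -hw:hw
    X <- matrix(x, 2 * hw + 1, 2 * hw + 1, byrow = TRUE)   # col -> x
    Y <- matrix(rev(x), 2 * hw + 1, 2 * hw + 1)            # row -> y (up)
    env <- exp(-(X^2 + Y^2) / (2 * sigma^2))
    k <- 2 * pi * f / image_side        # rad per px
    for (oi in seq_along(oris)) {
      th <- oris[oi]
      carrier <- exp(1i * k * (X * cos(th) + Y * sin(th)))
      ker <- env * carrier
      ker <- ker - env * (sum(ker) / sum(env))   # exact zero DC
      kernels[[si, oi]] <- ker
    }
  }
  structure(list(kernels = kernels, image_side = as.integer(image_side),
                 config = cfg), class = "gabor_bank")
}

# Dense circular convolution of a real image with a complex kernel via
# FFT; returns the complex response map at every pixel.
.conv_fft <- function(img_fft, ker, n) {
  hw <- (nrow(ker) - 1L) %/% 2L
  big <- matrix(0 + 0i, n, n)
  idx <- ((-hw:hw) %% n) + 1L
  # kernel centered at (1,1) with wrap-around so the convolution is a
  # correlation sampled at pixel positions
  big[idx, idx] <- ker[(2 * hw + 1):1, (2 * hw + 1):1][ , , drop = FALSE]
  stats::fft(img_fft * Conj(stats::fft(big)), inverse = TRUE) / (n * n)
}

#' Extract jet features from an image
#'
#' Computes the magnitude of every complex filter response at
#' `grid_size^2` uniformly spaced image locations.  The image median
#' (the background gray level for these sparse stimuli) is subtracted
#' before filtering so responses reflect stroke structure only;
#' convolution uses circular boundaries.
#'
#' Vector ordering: location-major, row by row of the grid (top row of
#' the image first), then scale (highest frequency first), then
#' orientation; i.e. index = ((gy-1)*G + (gx-1)) * S*O + (s-1)*O + o.
#'
#' @param image square numeric matrix.
#' @param cfg a [jet_config()].
#' @param bank optional precomputed [make_filter_bank()] for this image
#'   side (built on the fly if `NULL`).
#' @return list of class `jet_features`: `magnitudes` (numeric vector of
#'   length `grid_size^2 * n_scales * n_orientations`), `grid` (the grid
#'   pixel coordinates) and `config`.
#' @export
extract_jets <- function(image, cfg = jet_config(), bank = NULL) {
  if (!is.matrix(image) || nrow(image) != ncol(image))
    stop("extract_jets() requires a square image matrix")
  n <- nrow(image)
  if (is.null(bank)) bank <- make_filter_bank(n, cfg)
  stopifnot(bank$image_side == n)
  g <- cfg$grid_size
  if (n < g) stop("image side smaller than jet grid")
  # uniformly spaced grid with half-spacing margin, forced symmetric
  # about the image center so mirroring the image permutes grid columns
  pos0 <- seq(0.5 + n / (2 * g), n + 0.5 - n / (2 * g), length.out = g)
  pos <- integer(g)
  for (i in seq_len(ceiling(g / 2))) {
    pos[i] <- as.integer(floor(pos0[i] + 0.5))
    pos[g + 1L - i] <- n + 1L - pos[i]
  }
  if (g %% 2L == 1L) pos[(g + 1L) %/% 2L] <- as.integer(round((n + 1) / 2))
  img0 <- image - stats::median(image)
  img_fft <- stats::fft(img0)
  S <- cfg$n_scales; O <- cfg$n_orientations
  mags <- array(0, c(O, S, g, g))       # filled then permuted
  for (si in seq_len(S)) for (oi in seq_len(O)) {
    resp <- .conv_fft(img_fft, bank$kernels[[si, oi]], n)
    mags[oi, si, , ] <- abs(resp[pos, pos])   # [row=y, col=x]
  }
  # reorder to location-major (grid row, grid col), scale, orientation
  v <- as.vector(aperm(mags, c(1, 2, 4, 3)))  # o, s, gx, gy -> fastest o
  structure(list(magnitudes = v, grid = pos, config = cfg),
            class = "jet_features")
}

#' Cosine similarity between two jet feature vectors
#'
#' `dot(a, b) / (|a| |b|)`; lies in `[0, 1]` because magnitudes are
#' nonnegative.  The corresponding dissimilarity is one minus this
#' value.
#'
#' @param a,b `jet_features` objects or bare numeric vectors of equal
#'   length.
#' @return scalar in `[0, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  va <- if (inherits(a, "jet_features")) a$magnitudes else as.numeric(a)
  vb <- if (inherits(b, "jet_features")) b$magnitudes else as.numeric(b)
  if (length(va) != length(vb))
    stop("feature vectors have different lengths")
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0)
    stop("cosine similarity undefined for a zero feature vector")
  sum(va * vb) / (na * nb)
}

#' Low-level similarity audit of all stimulus triplets
#'
#' Rasterizes each triplet in canonical pose (no jitter), extracts jet
#' features, and compares each variant to the base by cosine similarity.
#' A triplet is "matched" when the nonaccidental variant is at least as
#' similar to the base as the metric variant, i.e. any residual
#' low-level difference favors the metric variant and cannot explain a
#' nonaccidental detection advantage.
#'
#' @param set a `nap_stimulus_set` (or list of `nap_triplet`).
#' @param render_cfg a [render_config()].
#' @param jet_cfg a [jet_config()].
#' @return data.frame of class `nap_audit` with columns `triplet_id`,
#'   `condition`, `sim_nap_base`, `sim_mp_base`, `matched`.
#' @export
audit_triplets <- function(set, render_cfg = render_config(),
                           jet_cfg = jet_config()) {
  n <- round(render_cfg$canvas_extent * render_cfg$pixels_per_degree)
  bank <- make_filter_bank(n, jet_cfg)
  rows <- lapply(set, function(tr) {
    jets <- lapply(c("base", "metric", "nonaccidental"), function(v)
      extract_jets(rasterize(tr[[v]], render_cfg), jet_cfg, bank))
    s_nap <- cosine_similarity(jets[[1]], jets[[3]])
    s_mp <- cosine_similarity(jets[[1]], jets[[2]])
    data.frame(triplet_id = tr$triplet_id, condition = tr$condition,
               sim_nap_base = s_nap, sim_mp_base = s_mp,
               matched = s_nap >= s_mp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("nap_audit", "data.frame")
  out
}

#' Summarize a triplet audit
#'
#' Fraction of matched triplets and per-condition means of the two
#' similarities with standard errors across triplets of the same
#' condition.
#'
#' @param audit result of [audit_triplets()].
#' @return list with `fraction_matched` and data.frame `by_condition`.
#' @export
audit_summary <- function(audit) {
  se <- function(x) stats::sd(x) / sqrt(length(x))
  by <- do.call(rbind, lapply(split(audit, audit$condition), function(d)
    data.frame(condition = d$condition[1], n = nrow(d),
               mean_sim_nap = mean(d$sim_nap_base), se_sim_nap = se(d$sim_nap_base),
               mean_sim_mp = mean(d$sim_mp_base), se_sim_mp = se(d$sim_mp_base),
               fraction_matched = mean(d$matched), stringsAsFactors = FALSE)))
  rownames(by) <- NULL
  list(fraction_matched = mean(audit$matched), by_condition = by)
}
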