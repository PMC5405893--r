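#' Realize a stimulus from a condition and parameter value
#'
#' Builds the deterministic geometry of a stimulus for a given condition
#' at a given point on the condition's scalar parameter axis, applies the
#' pose/mirroring transform of the requested exemplar and re-centers the
#' bounding box at the origin.
#'
#' @param condition condition name (see [condition_names()]).
#' @param param_value scalar parameter value; must lie in the condition's
#'   admissible range.
#' @param exemplar exemplar index 0..5 selecting the pose/mirror
#'   combination (0 = canonical pose).
#' @param config a [nap_config()].
#' @param variant variant label stored on the stimulus.
#' @return a [nap_stimulus()].
#' @export
realize <- function(condition, param_value, exemplar = 0L,
                    config = nap_config(), variant = "base") {
  reg <- .nap_condition_registry()
  if (!condition %in% names(reg))
    stop("unknown condition name: '", condition, "'")
  entry <- reg[[condition]]
  rng <- entry$range(config)
  if (!is.finite(param_value) || param_value < rng[1] || param_value > rng[2])
    stop(sprintf("param_value %.4g for condition '%s' outside valid range [%.4g, %.4g]",
                 param_value, condition, rng[1], rng[2]))
  segs <- entry$build(param_value, config)
  s <- nap_stimulus(segs, condition, variant, exemplar = exemplar,
                    param_value = param_value)
  s <- recenter_stimulus(s)
  tr <- exemplar_transforms(condition, config)[[exemplar + 1L]]
  apply_exemplar_transform(s, tr)
}

apply_exemplar_transform <- function(s, tr) {
  if (tr$rot != 0) {
    s <- rotate_stimulus(s, tr$rot, about = c(0, 0))
    s <- recenter_stimulus(s)
  }
  if (tr$mirror != "none") s <- mirror_stimulus(s, tr$mirror)
  s
}

# Geometry signature used for duplicate/degeneracy detection: dense
# point cloud, rounded and lexicographically sorted so that direction of
# traversal and segment order do not matter.
stimulus_signature <- function(s, digits = 6) {
  pts <- round(stimulus_point_cloud(s, n = 33), digits)
  pts[pts == 0] <- 0                      # normalize signed zero
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  paste(sprintf("%.6f,%.6f", pts[, 1], pts[, 2]), collapse = ";")
}

#' Pose/mirror transforms defining the six exemplars of a condition
#'
#' Exemplars are generated as two canonical poses (identity and a 90 deg
#' rotation), each combined with no mirroring, a left-right mirror and an
#' up-down mirror.  Combinations whose geometry duplicates an already
#' accepted exemplar (mirror-symmetric stimuli) are replaced by rotated
#' poses (30, 60, 120, 150, ... deg) when
#' `config$substitute_degenerate` is TRUE, otherwise they raise an error
#' naming the degenerate exemplar slot.
#'
#' @param condition condition name.
#' @param config a [nap_config()].
#' @return list of 6 transforms, each `list(rot = deg, mirror = axis)`.
#' @export
exemplar_transforms <- function(condition, config = nap_config()) {
  reg <- .nap_condition_registry()
  entry <- reg[[condition]]
  if (is.null(entry)) stop("unknown condition name: '", condition, "'")
  p_base <- entry$boundary + config$deltas[[condition]]
  base <- recenter_stimulus(
    nap_stimulus(entry$build(p_base, config), condition, "base"))

  slots <- list(
    list(rot = 0,  mirror = "none"), list(rot = 0,  mirror = "left_right"),
    list(rot = 0,  mirror = "up_down"), list(rot = 90, mirror = "none"),
    list(rot = 90, mirror = "left_right"), list(rot = 90, mirror = "up_down"))
  subs <- lapply(c(30, 60, 120, 150, 210, 240, 300, 330),
                 function(a) list(rot = a, mirror = "none"))

  accepted <- list(); seen <- character(0); sub_i <- 1L
  for (k in seq_along(slots)) {
    cand <- slots[[k]]
    sig <- stimulus_signature(apply_exemplar_transform(base, cand))
    while (sig %in% seen) {
      if (!config$substitute_degenerate)
        stop("exemplar slot ", k - 1L, " of condition '", condition,
             "' (rot ", cand$rot, ", mirror ", cand$mirror,
             ") mirrors onto an existing exemplar")
      if (sub_i > length(subs))
        stop("no non-degenerate pose available for condition '",
             condition, "'")
      cand <- subs[[sub_i]]; sub_i <- sub_i + 1L
      sig <- stimulus_signature(apply_exemplar_transform(base, cand))
    }
    seen <- c(seen, sig)
    accepted[[k]] <- cand
  }
  accepted
}

#' Build one base/metric/nonaccidental triplet
#'
#' The nonaccidental variant sits exactly at the condition's boundary
#' value, the base at `boundary + delta` and the metric variant at
#' `boundary + 2 delta`, so the two variants are equidistant from the
#' base on the parameter axis but only one of them crosses the
#' nonaccidental boundary.
#'
#' @param condition condition name.
#' @param exemplar exemplar index 0..5.
#' @param config a [nap_config()].
#' @return list of class `nap_triplet` with elements `triplet_id`,
#'   `condition`, `exemplar`, `base`, `metric`, `nonaccidental`.
#' @export
make_triplet <- function(condition, exemplar = 0L, config = nap_config()) {
  reg <- .nap_condition_registry()
  if (!condition %in% names(reg))
    stop("unknown condition name: '", condition, "'")
  b <- reg[[condition]]$boundary
  d <- config$deltas[[condition]]
  structure(list(
    triplet_id = sprintf("%s_e%d", condition, exemplar),
    condition = condition, exemplar = as.integer(exemplar),
    base = realize(condition, b + d, exemplar, config, "base"),
    metric = realize(condition, b + 2 * d, exemplar, config, "metric"),
    nonaccidental = realize(condition, b, exemplar, config, "nonaccidental")),
    class = "nap_triplet")
}

#' @export
print.nap_triplet <- function(x, ...) {
  cat(sprintf("<nap_triplet> %s: params base %.4g / metric %.4g / nonaccidental %.4g\n",
              x$triplet_id, x$base$param_value, x$metric$param_value,
              x$nonaccidental$param_value))
  invisible(x)
}

#' Generate the full stimulus set
#'
#' Produces 6 exemplars for each of the 13 conditions: 78 triplets, 234
#' stimuli.
#'
#' @param config a [nap_config()].
#' @return list of `nap_triplet` with class `nap_stimulus_set`; the
#'   generating config is attached as attribute `config`.
#' @export
generate_stimulus_set <- function(config = nap_config()) {
  triplets <- list()
  for (cond in condition_names())
    for (ex in 0:5)
      triplets[[sprintf("%s_e%d", cond, ex)]] <-
        make_triplet(cond, ex, config)
  structure(triplets, class = "nap_stimulus_set", config = config)
}

#' @export
print.nap_stimulus_set <- function(x, ...) {
  conds <- vapply(x, `[[`, "", "condition")
  cat(sprintf("<nap_stimulus_set> %d triplets across %d conditions (gap %.3g deg, extent %.3g deg)\n",
              length(x), length(unique(conds)),
              attr(x, "config")$gap, attr(x, "config")$extent))
  invisible(x)
}

#' Flat manifest of a stimulus set
#'
#' One row per stimulus with identifiers, labels, parameter value and
#' flattened segment geometry (`segK_cx, segK_cy, segK_ori, segK_len,
#' segK_sag`; second-segment columns are `NA` for the single-line
#' control).
#'
#' @param set a `nap_stimulus_set`.
#' @return data.frame with 3 rows per triplet.
#' @export
stimulus_manifest <- function(set) {
  rows <- lapply(set, function(tr) {
    do.call(rbind, lapply(c("base", "metric", "nonaccidental"), function(v) {
      s <- tr[[v]]
      g <- unlist(lapply(1:2, function(i) {
        if (i <= length(s$segments)) {
          sg <- s$segments[[i]]
          c(sg$center, sg$orientation, sg$length, sg$sagitta)
        } else rep(NA_real_, 5)
      }))
      names(g) <- as.vector(outer(c("cx", "cy", "ori", "len", "sag"),
                                  1:2, function(a, b) paste0("seg", b, "_", a)))
      data.frame(stimulus_id = s$stimulus_id, triplet_id = tr$triplet_id,
                 condition = s$condition, variant = v,
                 exemplar = s$exemplar, mirror = s$mirror,
                 param_value = s$param_value, t(g),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
as.data.frame.nap_stimulus_set <- function(x, ...) stimulus_manifest(x)

#' Write / read a stimulus manifest CSV
#' @param set a `nap_stimulus_set`.
#' @param path file path.
#' @export
write_stimulus_manifest <- function(set, path) {
  utils::write.csv(stimulus_manifest(set), path, row.names = FALSE)
  invisible(path)
}

#' Write / read a generation config as YAML or JSON
#'
#' Format chosen from the file extension (`.yaml`/`.yml` or `.json`).
#' @param config a [nap_config()].
#' @param path file path.
#' @export
write_nap_config <- function(config, path) {
  x <- unclass(config)
  x$deltas <- as.list(x$deltas)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nap_config
#' @export
read_nap_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  nap_config(extent = x$extent, gap = x$gap, deltas = unlist(x$deltas),
             pos_jitter = x$pos_jitter, ori_jitter = x$ori_jitter,
             eccentricity = x$eccentricity,
             substitute_degenerate = x$substitute_degenerate)
}
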