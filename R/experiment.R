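#' Build the factorial odd-one-out trial table
#'
#' Fully crosses triplet (78) x changed variant (metric, nonaccidental)
#' x role (the variant is the odd target among three bases, or the base
#' is the odd target among three variants) x target quadrant (4), each
#' combination tested once: 1,248 trials.  Interleaved mode randomizes
#' the order across all conditions; blocked mode (the replication's
#' design) presents each condition in its own block, with block order
#' and within-block order randomized.
#'
#' @param set a `nap_stimulus_set` (78 triplets) or list of triplets.
#' @param mode `"interleaved"` or `"blocked"`.
#' @param reduced allow stimulus sets other than 78 triplets (for
#'   reduced designs and simulation studies).
#' @return data.frame of `TrialRecord`s: `trial_id`, `triplet_id`,
#'   `condition`, `variant_changed`, `role`, `target_quadrant`, `block`,
#'   `order_index`.  Rows are ordered by `order_index`.
#' @export
build_trial_table <- function(set, mode = c("interleaved", "blocked"),
                              reduced = FALSE) {
  mode <- match.arg(mode)
  if (length(set) != 78L && !reduced)
    stop("stimulus set has ", length(set),
         " triplets, expected 78 (use reduced = TRUE for reduced designs)")
  ids <- vapply(set, `[[`, "", "triplet_id")
  conds <- vapply(set, `[[`, "", "condition")
  tab <- expand.grid(target_quadrant = 1:4,
                     role = c("variant_is_target", "base_is_target"),
                     variant_changed = c("metric", "nonaccidental"),
                     triplet_id = ids,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$condition <- conds[match(tab$triplet_id, ids)]
  n <- nrow(tab)
  if (mode == "interleaved") {
    ord <- sample.int(n)
    tab$block <- "interleaved"
  } else {
    block_order <- sample(unique(tab$condition))
    pos <- vector("integer", n)
    k <- 0L
    for (b in block_order) {
      i <- which(tab$condition == b)
      pos[i[sample.int(length(i))]] <- k + seq_along(i)
      k <- k + length(i)
    }
    ord <- order(pos)
    tab$block <- tab$condition
  }
  tab <- tab[ord, ]
  tab$order_index <- seq_len(n)
  tab$trial_id <- sprintf("trial_%04d", seq_len(n))
  rownames(tab) <- NULL
  tab[, c("trial_id", "triplet_id", "condition", "variant_changed",
          "role", "target_quadrant", "block", "order_index")]
}

#' Lay out the four-stimulus display of one trial
#'
#' Places four stimuli at 5 deg eccentricity in the four display
#' quadrants (polar angles 45, 135, 225, 315 deg for quadrants 1..4).
#' The target quadrant holds the odd stimulus; the other three hold
#' identical distractors.  When the role is `variant_is_target` the odd
#' stimulus is the changed variant among three bases; when
#' `base_is_target` it is the base among three copies of the changed
#' variant.  Every placement is jittered independently in position
#' (within the configured bound, default +-0.25 deg per coordinate) and
#' orientation (default +-5 deg).
#'
#' @param trial one row of [build_trial_table()].
#' @param set the `nap_stimulus_set` the table was built from.
#' @param config a [nap_config()] (eccentricity and jitter bounds).
#' @return list of class `display_spec`: `trial_id` and `placements`, a
#'   list of four entries with `quadrant`, `stimulus_id`, `is_target`,
#'   `center` (deg from fixation), `jitter_offset`, `jitter_rotation`,
#'   and the placed `stimulus` geometry.
#' @export
layout_trial <- function(trial, set, config = nap_config()) {
  tr <- set[[trial$triplet_id]]
  if (is.null(tr)) stop("trial references unknown triplet ", trial$triplet_id)
  variant <- tr[[trial$variant_changed]]
  odd <- if (trial$role == "variant_is_target") variant else tr$base
  dis <- if (trial$role == "variant_is_target") tr$base else variant
  angles <- c(45, 135, 225, 315) * pi / 180
  placements <- lapply(1:4, function(q) {
    s0 <- if (q == trial$target_quadrant) odd else dis
    dxy <- stats::runif(2, -config$pos_jitter, config$pos_jitter)
    rot <- stats::runif(1, -config$ori_jitter, config$ori_jitter)
    ctr <- config$eccentricity * c(cos(angles[q]), sin(angles[q])) + dxy
    s <- rotate_stimulus(s0, rot)
    s <- translate_stimulus(s, ctr - stimulus_bbox(s)$center)
    list(quadrant = q, stimulus_id = s0$stimulus_id,
         is_target = q == trial$target_quadrant, center = ctr,
         jitter_offset = dxy, jitter_rotation = rot, stimulus = s)
  })
  structure(list(trial_id = trial$trial_id, placements = placements),
            class = "display_spec")
}

#' Write a trial table CSV
#' @param trials result of [build_trial_table()].
#' @param path file path.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}
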