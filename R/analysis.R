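#' Per-participant median reaction times
#'
#' Computes the median RT for every participant x condition x changed
#' variant cell.  Because RT distributions are right-skewed, the
#' per-participant median (midpoint convention for even counts, R's
#' default) is used as the participant-level summary that downstream
#' tests compare.  By default only correct trials enter the medians.
#'
#' @param responses a response table from [simulate_responses()] (or any
#'   data.frame with `participant`, `condition`, `variant_changed`,
#'   `rt`, `correct`).
#' @param correct_only drop error trials before computing medians
#'   (default TRUE).
#' @return data.frame of class `median_table`: `participant`,
#'   `condition`, `variant_changed`, `median_rt`, `n_trials_used`.
#' @export
compute_medians <- function(responses, correct_only = TRUE) {
  d <- if (correct_only) responses[responses$correct, ] else responses
  cells <- expand.grid(participant = unique(responses$participant),
                       condition = unique(responses$condition),
                       variant_changed = unique(responses$variant_changed),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(x) paste(x$participant, x$condition, x$variant_changed,
                           sep = "\r")
  idx <- split(seq_len(nrow(d)), key(d))
  got <- idx[key(cells)]
  empty <- vapply(got, function(i) is.null(i) || length(i) == 0L, TRUE)
  if (any(empty)) {
    e <- cells[which(empty)[1], ]
    stop(sprintf("no usable trials in cell participant %s, condition %s, variant %s",
                 e$participant, e$condition, e$variant_changed))
  }
  cells$median_rt <- vapply(got, function(i) stats::median(d$rt[i]), 0)
  cells$n_trials_used <- vapply(got, length, 0L)
  rownames(cells) <- NULL
  class(cells) <- c("median_table", "data.frame")
  cells
}

.new_test_result <- function(statistic, df, p, tail, alpha = 0.05,
                             n_comparisons = 1L, method = "") {
  structure(list(statistic = statistic, df = df, p = p, tail = tail,
                 alpha = alpha, n_comparisons = as.integer(n_comparisons),
                 significant_bonferroni = p < alpha / n_comparisons,
                 method = method),
            class = "nap_test")
}

#' @export
print.nap_test <- function(x, ...) {
  dfs <- paste(x$df, collapse = ", ")
  cat(sprintf("%s: statistic = %.4f, df = %s, %s-tailed p = %.4g%s\n",
              x$method, x$statistic, dfs, x$tail, x$p,
              if (x$n_comparisons > 1)
                sprintf(" (Bonferroni over %d: %s)", x$n_comparisons,
                        if (x$significant_bonferroni) "significant"
                        else "not significant")
              else ""))
  invisible(x)
}

#' One-tailed related-samples t test for one condition
#'
#' Tests whether metric-change medians exceed nonaccidental-change
#' medians across participants: for each participant the difference
#' `d_p = median_MP - median_NAP` is formed and a paired t test of
#' `mean(d) > 0` on `n - 1` degrees of freedom is run (the direction
#' expresses the hypothesis that nonaccidental changes are detected
#' faster).
#'
#' @param med a `median_table` from [compute_medians()].
#' @param condition condition to test.
#' @param alpha significance level before correction.
#' @param n_comparisons Bonferroni divisor (default 13 conditions).
#' @return a `nap_test` with fields `statistic` (t), `df`, `p`, `tail`,
#'   `alpha`, `n_comparisons`, `significant_bonferroni`.
#' @export
paired_t_one_tailed <- function(med, condition, alpha = 0.05,
                                n_comparisons = 13L) {
  d <- med[med$condition == condition, ]
  if (nrow(d) == 0) stop("condition '", condition, "' not present")
  w <- stats::reshape(d[, c("participant", "variant_changed", "median_rt")],
                      idvar = "participant", timevar = "variant_changed",
                      direction = "wide")
  mp <- w$median_rt.metric; nap <- w$median_rt.nonaccidental
  if (anyNA(mp) || anyNA(nap) || length(mp) < 2)
    stop("need both variant cells for at least 2 participants")
  diffs <- mp - nap
  n <- length(diffs)
  if (stats::sd(diffs) == 0) {
    if (mean(diffs) == 0)
      return(.new_test_result(0, n - 1L, 0.5, "one", alpha, n_comparisons,
                              "paired t (one-tailed)"))
    t <- sign(mean(diffs)) * Inf
    return(.new_test_result(t, n - 1L, if (t > 0) 0 else 1, "one",
                            alpha, n_comparisons, "paired t (one-tailed)"))
  }
  tt <- stats::t.test(mp, nap, paired = TRUE, alternative = "greater")
  .new_test_result(unname(tt$statistic), unname(tt$parameter),
                   tt$p.value, "one", alpha, n_comparisons,
                   "paired t (one-tailed)")
}

#' Per-condition one-tailed t tests with Bonferroni flags
#'
#' Runs [paired_t_one_tailed()] for every condition in the median table
#' and flags results significant under Bonferroni correction.
#'
#' @param med a `median_table`.
#' @inheritParams paired_t_one_tailed
#' @return data.frame with one row per condition: `condition`, `t`,
#'   `df`, `p`, `significant_uncorrected`, `significant_bonferroni`.
#' @export
condition_t_tests <- function(med, alpha = 0.05, n_comparisons = 13L) {
  conds <- unique(med$condition)
  rows <- lapply(conds, function(cn) {
    r <- paired_t_one_tailed(med, cn, alpha, n_comparisons)
    data.frame(condition = cn, t = r$statistic, df = r$df, p = r$p,
               significant_uncorrected = r$p < alpha,
               significant_bonferroni = r$significant_bonferroni,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply Bonferroni significance flags to a set of test results
#'
#' The flag is `p < alpha / n_comparisons` with a strict inequality, so
#' a p value exactly at the corrected threshold does not pass (e.g.
#' p = 0.005 is not significant at alpha 0.05 over 13 comparisons,
#' threshold 0.003846).
#'
#' @param results data.frame with a `p` column, or a list of `nap_test`.
#' @param alpha family-wise significance level.
#' @param n_comparisons number of tests in the family; must be at least
#'   the number of results.
#' @return the input with `significant_bonferroni` (re)computed.
#' @export
bonferroni_flags <- function(results, alpha = 0.05, n_comparisons = 13L) {
  nres <- if (is.data.frame(results)) nrow(results) else length(results)
  if (n_comparisons < nres)
    stop("n_comparisons (", n_comparisons, ") smaller than number of results (",
         nres, ")")
  thr <- alpha / n_comparisons
  if (is.data.frame(results)) {
    results$significant_bonferroni <- results$p < thr
    results
  } else {
    lapply(results, function(r) {
      r$alpha <- alpha; r$n_comparisons <- as.integer(n_comparisons)
      r$significant_bonferroni <- r$p < thr
      r
    })
  }
}

#' 2x2 within-subject interaction test
#'
#' Repeated-measures ANOVA for the condition x distance-type (metric
#' vs. nonaccidental) interaction between two conditions, fully within
#' subject, used to ask whether the nonaccidental advantage differs
#' between a configural condition and the single-line curvature control.
#' With one observation per cell the interaction F on (1, n-1) degrees
#' of freedom equals the square of the paired t on per-participant
#' difference-of-differences.
#'
#' @param med a `median_table`.
#' @param condition_a,condition_b the two conditions.
#' @return a `nap_test` with the F statistic, df pair and two-tailed p.
#' @export
rm_interaction_2x2 <- function(med, condition_a, condition_b) {
  d <- med[med$condition %in% c(condition_a, condition_b), ]
  parts <- unique(med$participant)
  cell <- function(p, cn, v) {
    x <- d$median_rt[d$participant == p & d$condition == cn &
                       d$variant_changed == v]
    if (length(x) != 1) stop(sprintf("missing cell: %s / %s / %s", p, cn, v))
    x
  }
  dd <- vapply(parts, function(p)
    (cell(p, condition_a, "metric") - cell(p, condition_a, "nonaccidental")) -
    (cell(p, condition_b, "metric") - cell(p, condition_b, "nonaccidental")),
    0)
  n <- length(dd)
  if (all(dd == 0) || stats::sd(dd) == 0) {
    f <- if (mean(dd) == 0) 0 else Inf
    return(.new_test_result(f, c(1L, n - 1L), if (f == 0) 1 else 0, "two",
                            method = "RM-ANOVA interaction"))
  }
  if (condition_a == condition_b)
    return(.new_test_result(0, c(1L, n - 1L), 1, "two",
                            method = "RM-ANOVA interaction"))
  dat <- d
  dat$cond <- factor(dat$condition, levels = c(condition_a, condition_b))
  dat$dist <- factor(dat$variant_changed)
  dat$pp <- factor(dat$participant)
  fit <- stats::aov(median_rt ~ cond * dist + Error(pp / (cond * dist)),
                    data = dat)
  tab <- summary(fit)[["Error: pp:cond:dist"]][[1]]
  f <- tab["cond:dist", "F value"]
  p <- tab["cond:dist", "Pr(>F)"]
  .new_test_result(unname(f), c(1L, n - 1L), unname(p), "two",
                   method = "RM-ANOVA interaction")
}

#' Accuracy summary by condition and changed variant
#'
#' Mean accuracy with binomial standard errors for every condition x
#' changed-variant cell plus marginal rows per changed variant
#' (condition `"all"`).  Purely descriptive: near-ceiling accuracies
#' are reported but not tested.
#'
#' @param responses a response table.
#' @return data.frame with `condition`, `variant_changed`, `n_trials`,
#'   `accuracy`, `se`.
#' @export
accuracy_summary <- function(responses) {
  agg <- function(d, cond_label) {
    do.call(rbind, lapply(split(d, d$variant_changed), function(x)
      data.frame(condition = cond_label, variant_changed = x$variant_changed[1],
                 n_trials = nrow(x), accuracy = mean(x$correct),
                 se = sqrt(mean(x$correct) * (1 - mean(x$correct)) / nrow(x)),
                 stringsAsFactors = FALSE)))
  }
  per <- do.call(rbind, lapply(split(responses, responses$condition),
                               function(d) agg(d, d$condition[1])))
  out <- rbind(per, agg(responses, "all"))
  rownames(out) <- NULL
  out
}

#' Mean reaction-time difference per triplet
#'
#' Per-triplet mean RT on nonaccidental-change trials minus metric-change
#' trials (correct trials only by default), the behavioural side of the
#' model-behaviour correlation.
#'
#' @param responses a response table containing `triplet_id`.
#' @param correct_only drop error trials (default TRUE).
#' @return data.frame `triplet_id`, `rt_nap`, `rt_mp`, `rt_diff`.
#' @export
rt_by_triplet <- function(responses, correct_only = TRUE) {
  d <- if (correct_only) responses[responses$correct, ] else responses
  rows <- lapply(split(d, d$triplet_id), function(x) {
    data.frame(triplet_id = x$triplet_id[1],
               rt_nap = mean(x$rt[x$variant_changed == "nonaccidental"]),
               rt_mp = mean(x$rt[x$variant_changed == "metric"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rt_diff <- out$rt_nap - out$rt_mp
  rownames(out) <- NULL
  out
}

#' Correlation between low-level similarity and behaviour
#'
#' Pearson correlation across stimulus triplets between the behavioural
#' reaction-time difference (nonaccidental minus metric) and the
#' Gabor-jet similarity difference (`sim_nap_base - sim_mp_base` by
#' default; set `sign = "dissimilarity"` to correlate against the
#' dissimilarity difference, which only flips the sign of r).
#'
#' @param rt_diffs result of [rt_by_triplet()] (or data.frame with
#'   `triplet_id`, `rt_diff`).
#' @param audits result of [audit_triplets()].
#' @param sign `"similarity"` (default) or `"dissimilarity"`.
#' @return list with `r`, `df`, `p` (two-tailed), `n`.
#' @export
model_behavior_correlation <- function(rt_diffs, audits,
                                       sign = c("similarity", "dissimilarity")) {
  sign <- match.arg(sign)
  m <- merge(rt_diffs[, c("triplet_id", "rt_diff")],
             audits[, c("triplet_id", "sim_nap_base", "sim_mp_base")],
             by = "triplet_id")
  x <- m$sim_nap_base - m$sim_mp_base
  if (sign == "dissimilarity") x <- -x
  y <- m$rt_diff
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: one of the inputs is constant")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), df = unname(ct$parameter),
       p = ct$p.value, n = nrow(m))
}

#' Across-participant summary of condition medians
#'
#' Mean of per-participant median RTs with standard errors of the mean,
#' per condition and changed variant — the summary a bar plot of
#' condition means would show.
#'
#' @param med a `median_table`.
#' @return data.frame `condition`, `variant_changed`, `mean_median_rt`,
#'   `sem`, `n_participants`.
#' @export
condition_summary <- function(med) {
  rows <- lapply(split(med, list(med$condition, med$variant_changed)),
                 function(d) data.frame(
                   condition = d$condition[1],
                   variant_changed = d$variant_changed[1],
                   mean_median_rt = mean(d$median_rt),
                   sem = stats::sd(d$median_rt) / sqrt(nrow(d)),
                   n_participants = nrow(d), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$condition, out$variant_changed), ]
  rownames(out) <- NULL
  out
}
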