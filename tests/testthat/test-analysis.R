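test_that("cell medians use the midpoint convention and flag empty cells", {
  resp <- data.frame(
    participant = "p01", condition = "c1",
    variant_changed = rep(c("metric", "nonaccidental"), c(3, 2)),
    rt = c(400, 500, 600, 400, 600), correct = TRUE,
    stringsAsFactors = FALSE)
  med <- compute_medians(resp)
  expect_equal(med$median_rt[med$variant_changed == "metric"], 500)
  expect_equal(med$median_rt[med$variant_changed == "nonaccidental"], 500)
  expect_equal(sort(med$n_trials_used), c(2L, 3L))

  resp_bad <- resp
  resp_bad$correct[resp_bad$variant_changed == "nonaccidental"] <- FALSE
  expect_error(compute_medians(resp_bad), "no usable trials")
  expect_silent(compute_medians(resp_bad, correct_only = FALSE))
})

test_that("paired t matches the hand formula, including degenerate cases", {
  # frozen hand computation: differences (10, 20, 30), n = 3
  med <- data.frame(
    participant = rep(c("a", "b", "c"), each = 2),
    condition = "c1",
    variant_changed = rep(c("metric", "nonaccidental"), 3),
    median_rt = c(510, 500, 620, 600, 730, 700),
    stringsAsFactors = FALSE)
  r <- paired_t_one_tailed(med, "c1")
  expect_equal(r$statistic, 20 / (10 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$statistic, 3.4641016, tolerance = 1e-6)
  expect_equal(r$df, 2)
  expect_equal(r$p, stats::pt(r$statistic, 2, lower.tail = FALSE))

  # oracle equivalence on 100 random datasets
  set.seed(101)
  for (i in 1:100) {
    m <- random_median_table(n_participants = sample(3:12, 1))
    r <- paired_t_one_tailed(m, "c1")
    w <- reshape(m[, c("participant", "variant_changed", "median_rt")],
                 idvar = "participant", timevar = "variant_changed",
                 direction = "wide")
    o <- oracle_paired_t(w$median_rt.metric, w$median_rt.nonaccidental)
    expect_equal(r$statistic, o$t, tolerance = 1e-10)
    expect_equal(r$p, o$p, tolerance = 1e-10)
  }

  # degenerate: identical cells -> t = 0, p = 0.5
  m0 <- random_median_table()
  m0$median_rt <- rep(m0$median_rt[m0$variant_changed == "metric"], 2)
  r0 <- paired_t_one_tailed(m0, "c1")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 0.5)
  # zero variance, nonzero mean -> limiting p
  m1 <- m0
  m1$median_rt[m1$variant_changed == "metric"] <-
    m1$median_rt[m1$variant_changed == "nonaccidental"] + 50
  r1 <- paired_t_one_tailed(m1, "c1")
  expect_identical(r1$statistic, Inf)
  expect_equal(r1$p, 0)
})

test_that("Bonferroni flags use a strict threshold over 13 comparisons", {
  res <- data.frame(condition = c("a", "b", "c"),
                    p = c(0.005, 0.001, 0.05 / 13))
  out <- bonferroni_flags(res, alpha = 0.05, n_comparisons = 13)
  # p = .005 does not survive 0.05/13 = 0.003846
  expect_false(out$significant_bonferroni[1])
  expect_true(out$significant_bonferroni[2])
  expect_false(out$significant_bonferroni[3])   # boundary is strict
  expect_error(bonferroni_flags(res, n_comparisons = 2), "smaller")
  # corrected flags can never exceed uncorrected flags
  set.seed(7)
  ps <- runif(13)
  d <- data.frame(p = ps)
  expect_lte(sum(bonferroni_flags(d)$significant_bonferroni),
             sum(ps < 0.05))
})

test_that("the 2x2 interaction F equals the squared paired t on difference-of-differences", {
  set.seed(202)
  for (i in 1:25) {
    m <- random_median_table(n_participants = 10,
                             conditions = c("a", "b"))
    r <- rm_interaction_2x2(m, "a", "b")
    w <- reshape(m, idvar = c("participant", "condition"),
                 timevar = "variant_changed", direction = "wide")
    wa <- w[w$condition == "a", ]; wb <- w[w$condition == "b", ]
    wa <- wa[order(wa$participant), ]; wb <- wb[order(wb$participant), ]
    dd <- (wa$median_rt.metric - wa$median_rt.nonaccidental) -
      (wb$median_rt.metric - wb$median_rt.nonaccidental)
    t_o <- mean(dd) / (sd(dd) / sqrt(length(dd)))
    expect_equal(r$statistic, t_o^2, tolerance = 1e-9)
    expect_equal(r$df, c(1L, 9L))
    expect_equal(r$p, 2 * stats::pt(abs(t_o), 9, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
  # all-zero difference-of-differences and self-comparison give F = 0
  m <- random_median_table(conditions = c("a", "b"))
  ma <- m[m$condition == "a", ]
  mb <- ma; mb$condition <- "b"
  r0 <- rm_interaction_2x2(rbind(ma, mb), "a", "b")
  expect_equal(r0$statistic, 0)
  r_self <- rm_interaction_2x2(m, "a", "a")
  expect_equal(r_self$statistic, 0)
})

test_that("the model-behaviour correlation matches the covariance-formula oracle", {
  set.seed(303)
  for (i in 1:50) {
    n <- sample(10:78, 1)
    rt <- data.frame(triplet_id = sprintf("t%02d", 1:n),
                     rt_diff = rnorm(n))
    aud <- data.frame(triplet_id = sprintf("t%02d", 1:n),
                      sim_nap_base = runif(n), sim_mp_base = runif(n))
    r <- model_behavior_correlation(rt, aud)
    x <- aud$sim_nap_base - aud$sim_mp_base
    y <- rt$rt_diff
    r_o <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(r$r, r_o, tolerance = 1e-12)
    expect_equal(r$df, n - 2)
    t_o <- r_o * sqrt((n - 2) / (1 - r_o^2))
    expect_equal(r$p, 2 * stats::pt(abs(t_o), n - 2, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  # perfect and undefined cases
  rt <- data.frame(triplet_id = c("a", "b", "c"), rt_diff = c(1, 2, 3))
  aud <- data.frame(triplet_id = c("a", "b", "c"),
                    sim_nap_base = c(0.1, 0.2, 0.3), sim_mp_base = 0)
  expect_equal(model_behavior_correlation(rt, aud)$r, 1)
  aud$sim_nap_base <- 0.5
  expect_error(model_behavior_correlation(rt, aud), "constant")
  # sign convention flips r under the dissimilarity reading
  aud$sim_nap_base <- c(0.1, 0.2, 0.35)
  r_sim <- model_behavior_correlation(rt, aud)$r
  r_dis <- model_behavior_correlation(rt, aud, sign = "dissimilarity")$r
  expect_equal(r_sim, -r_dis)
})

test_that("parameter recovery: median-RT differences track the generating advantage", {
  set <- fx_default_set()
  set.seed(404)
  trials <- build_trial_table(set)
  params <- observer_params(nap_advantage = 80, participant_mean_sd = 0,
                            n_participants = 12)
  r <- simulate_responses(trials, params)
  med <- compute_medians(r)
  cs <- condition_summary(med)
  d <- with(cs, mean_median_rt[variant_changed == "metric"] -
              mean_median_rt[variant_changed == "nonaccidental"])
  # grand mean over 13 conditions x 12 participants: generous MC band
  expect_lt(abs(mean(d) - 80), 15)
})
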