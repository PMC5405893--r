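test_that("segment invariants and closed-form endpoints hold", {
  expect_error(nap_segment(c(0, 0), 0, -1), "positive")
  expect_error(nap_segment(c(0, 0), 0, 1, 0.6), "sagitta")

  s <- nap_segment(c(1, 2), 30, 2, 0.4)
  ep <- segment_endpoints(s)
  u <- c(cos(pi / 6), sin(pi / 6))
  expect_equal(ep[1, ], c(1, 2) - u, tolerance = 1e-12)
  expect_equal(ep[2, ], c(1, 2) + u, tolerance = 1e-12)

  # arc sampling starts/ends at the chord endpoints and bulges by the
  # sagitta at the midpoint
  pts <- segment_points(s, 101)
  expect_equal(pts[1, ], ep[1, ], tolerance = 1e-9)
  expect_equal(pts[101, ], ep[2, ], tolerance = 1e-9)
  mid <- pts[51, ]
  nrm <- c(-sin(pi / 6), cos(pi / 6))
  expect_equal(as.numeric(mid), as.numeric(c(1, 2) + 0.4 * nrm),
               tolerance = 1e-9)
})

test_that("realize builds the advertised boundary configurations", {
  # straight control line at the zero-curvature boundary
  s <- realize("curvature_control", 0)
  expect_length(s$segments, 1)
  expect_identical(s$segments[[1]]$sagitta, 0)

  # parallel edges at the zero-divergence boundary
  s <- realize("expansion_constant", 0)
  oris <- vapply(s$segments, `[[`, 0, "orientation")
  expect_equal(oris[1], oris[2], tolerance = 1e-12)

  # joined edges differing in orientation by the bend parameter, with
  # the joint endpoints coincident; checked against the chord formula
  s <- realize("collinearity_within", 10)
  oris <- vapply(s$segments, `[[`, 0, "orientation")
  expect_equal(abs(180 - abs(oris[1] - oris[2])) %% 180, 10,
               tolerance = 1e-9)
  ep1 <- segment_endpoints(s$segments[[1]])
  ep2 <- segment_endpoints(s$segments[[2]])
  d <- as.matrix(dist(rbind(ep1, ep2)))
  expect_lt(min(d[1:2, 3:4]), 1e-9)   # the joint

  expect_error(realize("no_such_condition", 0), "unknown condition")
  expect_error(realize("curvature_control", 99), "range")
})

test_that("triplets are equidistant with the nonaccidental variant at the boundary", {
  set <- fx_default_set()
  specs <- condition_specs()
  for (tr in set) {
    pb <- tr$base$param_value
    expect_equal(abs(tr$metric$param_value - pb),
                 abs(tr$nonaccidental$param_value - pb))
    expect_true(pb > min(tr$metric$param_value, tr$nonaccidental$param_value) &&
                pb < max(tr$metric$param_value, tr$nonaccidental$param_value))
    expect_equal(tr$nonaccidental$param_value,
                 specs$boundary_value[specs$name == tr$condition])
  }
  # curvature control: straight nonaccidental line, metric sagitta twice base
  tr <- set[["curvature_control_e0"]]
  expect_identical(tr$nonaccidental$segments[[1]]$sagitta, 0)
  expect_equal(tr$metric$segments[[1]]$sagitta,
               2 * tr$base$segments[[1]]$sagitta)
})

test_that("the default stimulus set has the full design structure", {
  set <- fx_default_set()
  expect_length(set, 78)
  m <- stimulus_manifest(set)
  expect_equal(nrow(m), 234)
  expect_equal(length(unique(m$condition)), 13)
  expect_true(all(table(m$condition) == 18))  # 6 triplets x 3 variants
  expect_false(any(duplicated(m$stimulus_id)))
  specs <- condition_specs()
  expect_equal(sum(specs$category != "control"), 12)
  # exemplars of a condition are geometrically distinct
  for (cond in c("curvature_control", "alignment", "cotermination")) {
    sigs <- vapply(0:5, function(e)
      naplines:::stimulus_signature(set[[paste0(cond, "_e", e)]]$base), "")
    expect_false(any(duplicated(sigs)))
  }
})

test_that("mirroring is an involution that reflects geometry and keeps labels", {
  s <- realize("cotermination", 0.35)
  for (ax in c("left_right", "up_down")) {
    m2 <- mirror_stimulus(mirror_stimulus(s, ax), ax)
    expect_identical(naplines:::stimulus_signature(m2),
                     naplines:::stimulus_signature(s))
    expect_identical(m2$mirror, "none")
  }
  m <- mirror_stimulus(s, "left_right")
  expect_identical(m$condition, s$condition)
  expect_identical(m$variant, s$variant)

  # fixed point: straight horizontal segment is left-right symmetric
  h <- nap_stimulus(list(nap_segment(c(0, 0), 0, 2)), "curvature_control",
                    "base")
  expect_identical(naplines:::stimulus_signature(mirror_stimulus(h, "left_right")),
                   naplines:::stimulus_signature(h))

  # reflection-matrix oracle: up-down mirror negates orientation and y
  s30 <- nap_stimulus(list(nap_segment(c(0.2, 0.4), 30, 1.5)),
                      "curvature_control", "base")
  md <- mirror_stimulus(s30, "up_down")
  ep <- segment_endpoints(s30$segments[[1]])
  ep_m <- segment_endpoints(md$segments[[1]])
  ctr_y <- mean(range(ep[, 2]))
  oracle <- cbind(ep[, 1], 2 * ctr_y - ep[, 2])
  expect_equal(ep_m[order(ep_m[, 1]), ], oracle[order(oracle[, 1]), ],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(md$segments[[1]]$orientation, 150)  # -30 canonicalized
})

test_that("center gap matches the configured value for stacked layouts", {
  expect_equal(center_gap(realize("curvature_edges", 0.3)), 1.5)
  expect_equal(center_gap(realize("expansion_constant", 10)), 1.5)
  expect_equal(center_gap(realize("alignment", 0.35)), 1.5)
  rep_cfg <- replication_config()
  expect_equal(center_gap(realize("curvature_edges", 0.3, config = rep_cfg)),
               2.25)
  # 3-4-5 triangle
  s <- nap_stimulus(list(nap_segment(c(0, 0), 0, 1),
                         nap_segment(c(3, 4), 0, 1)),
                    "alignment", "base")
  expect_equal(center_gap(s), 5)
  expect_error(center_gap(realize("curvature_control", 0.3)), "two-segment")
})

test_that("jitter respects bounds, is seed-deterministic and vanishes at zero bounds", {
  s <- realize("curvature_edges", 0.3)
  b0 <- stimulus_bbox(s)$center
  set.seed(11)
  for (i in 1:200) {
    j <- apply_jitter(s)
    off <- stimulus_bbox(j)$center - b0
    expect_true(all(abs(off) <= 0.25 + 1e-9))
  }
  set.seed(4); j1 <- apply_jitter(s)
  set.seed(4); j2 <- apply_jitter(s)
  expect_identical(j1, j2)
  set.seed(4); j0 <- apply_jitter(s, pos_bound = 0, ori_bound = 0)
  expect_equal(j0$segments, s$segments, tolerance = 1e-12)
})

test_that("degenerate mirror exemplars error when substitution is disabled", {
  cfg <- nap_config(substitute_degenerate = FALSE)
  expect_error(exemplar_transforms("curvature_control", cfg),
               "exemplar slot")
  expect_silent(exemplar_transforms("cotermination", cfg))
})

test_that("manifest and config round-trip through disk formats", {
  cfg <- nap_config(gap = 2.25, deltas = c(curvature_edges = 0.4))
  p_yaml <- tempfile(fileext = ".yaml")
  p_json <- tempfile(fileext = ".json")
  write_nap_config(cfg, p_yaml)
  write_nap_config(cfg, p_json)
  for (p in c(p_yaml, p_json)) {
    cfg2 <- read_nap_config(p)
    expect_equal(cfg2$gap, 2.25)
    expect_equal(cfg2$deltas[["curvature_edges"]], 0.4)
    expect_equal(cfg2$deltas[["alignment"]], cfg$deltas[["alignment"]])
  }
  path <- tempfile(fileext = ".csv")
  write_stimulus_manifest(fx_default_set(), path)
  m <- read.csv(path)
  expect_equal(nrow(m), 234)
  expect_true(all(is.na(m$seg2_len[m$condition == "curvature_control"])))
})
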