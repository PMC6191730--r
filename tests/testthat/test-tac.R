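test_that("roi_set validates geometry", {
  zl <- zone_layout(64)
  expect_error(roi_set(list(a = zl$pharynx, b = zl$pharynx)), "disjoint")
  expect_error(roi_set(list(a = matrix(numeric(0), 0, 2))), "empty")
  expect_error(roi_set(list(a = cbind(70, 3)), matrix_size = 64), "outside")
  rois <- default_roi_set(64)
  expect_setequal(names(rois$pixels),
                  c("pharynx", "upper_oesophagus", "mid_oesophagus",
                    "lower_oesophagus", "stomach", "background"))
})

test_that("a uniform image gives an all-zero background-corrected curve", {
  study <- make_study(uniform_frames(8, 5))
  tac <- extract_tac(study, default_roi_set(64), "pharynx")
  expect_equal(tac$values, rep(0, 8))
  expect_equal(tac$times, (0:7) * 15 + 7.5)
})

test_that("a constant organ excess divides through by the frame duration", {
  zl <- zone_layout(64)
  study <- excess_study(zl$pharynx, excess = 10, bg_level = 4,
                        n_frames = 8, frame_seconds = 15)
  tac <- extract_tac(study, default_roi_set(64), "pharynx")
  # 10 counts/px over 15 s = 0.667 counts/px/s; decay correction over the
  # 2-minute segment stays below 0.4%
  expect_equal(tac$values[1], 10 / 15, tolerance = 5e-4)
  expect_lt(max(abs(tac$values - 10 / 15)), 0.004)
})

test_that("a simulated no-reflux patient has a near-zero pharyngeal curve", {
  p <- kinetics_params(reflux_event_rate_upright = 0,
                       reflux_event_rate_supine = 0,
                       transit_residue_fraction = 0)
  imgs <- render_frames(simulate_kinetics(p, seed = 3), seed = 3)
  tac <- extract_tac(imgs$supine, default_roi_set(64), "pharynx")
  # Poisson SE of the mean background-corrected value across 60 frames
  bg_rate <- render_params()$background_rate
  n_org <- nrow(default_roi_set(64)$pixels$pharynx)
  n_bg <- nrow(default_roi_set(64)$pixels$background)
  se_frame <- sqrt(bg_rate * 30 * (1 / n_org + 1 / n_bg)) / 30
  expect_lt(abs(mean(tac$values)), 3 * se_frame / sqrt(60))
})

test_that("curve grading follows the slope z statistic", {
  t_s <- seq(0, 1770, by = 30)
  declining <- make_tac(t_s, 10 - 0.01 * t_s / 60 * 60 + rnorm(60, 0, 1e-6))
  expect_equal(grade_curve(declining)$grade, 1L)
  expect_equal(grade_curve(declining)$label, "declining")
  flat <- make_tac(t_s, rep(5, 60))
  expect_equal(grade_curve(flat)$grade, 2L)
  set.seed(2)
  rising <- make_tac(t_s, 1 + 0.05 * t_s / 60 + rnorm(60, 0, 0.1))
  expect_equal(grade_curve(rising)$grade, 3L)
  expect_error(grade_curve(make_tac(c(0, 15, 30), c(1, 2, 3))), "4 points")
  expect_error(grade_curve(make_tac(rep(10, 5), 1:5)), "variance")
})

test_that("least-squares slope and SE match the closed form", {
  set.seed(8)
  for (n in c(4, 6, 10)) {
    t_s <- sort(runif(n, 0, 1800))
    v <- rnorm(n)
    g <- grade_curve(make_tac(t_s, v), z_crit = 2)
    o <- slope_oracle(t_s / 60, v)
    expect_equal(g$slope, unname(o["slope"]), tolerance = 1e-10)
    expect_equal(g$slope_se, unname(o["se"]), tolerance = 1e-10)
  }
})

test_that("grade is invariant to value offsets and time scaling preserves slope sign", {
  set.seed(3)
  t_s <- seq(0, 1770, by = 30)
  v <- 5 - 0.002 * t_s + rnorm(60, 0, 0.5)
  g0 <- grade_curve(make_tac(t_s, v))
  g_shift <- grade_curve(make_tac(t_s, v + 100))
  expect_equal(g0$grade, g_shift$grade)
  expect_equal(g0$slope, g_shift$slope, tolerance = 1e-12)
  g_scale <- grade_curve(make_tac(t_s * 3, v))
  expect_equal(sign(g0$slope), sign(g_scale$slope))
  expect_equal(g0$z, g_scale$z, tolerance = 1e-10)
})

test_that("slope estimates cover the generating line at the nominal rate", {
  set.seed(4)
  t_s <- seq(0, 1770, by = 30)
  true_slope <- -0.02  # counts/px/s per minute
  covered <- vapply(1:1000, function(i) {
    v <- 3 + true_slope * t_s / 60 + rnorm(60, 0, 0.3)
    g <- grade_curve(make_tac(t_s, v))
    abs(g$slope - true_slope) <= 2 * g$slope_se
  }, logical(1))
  expect_gt(mean(covered), 0.93)  # nominal ~95.4% coverage at 2 SE
})

test_that("gastric half-clearance recovers exact exponentials and flags non-decay", {
  t_s <- seq(0, 1800, by = 30)
  v <- 8 * 2^(-t_s / 60 / 10)
  expect_equal(gastric_half_clearance(make_tac(t_s, v, roi = "stomach")), 10,
               tolerance = 1e-9)
  rising <- make_tac(t_s, 8 * 2^(t_s / 60 / 20), roi = "stomach")
  expect_identical(gastric_half_clearance(rising), Inf)
  expect_error(gastric_half_clearance(make_tac(t_s, c(-1, v[-1]))), "initial")
  expect_error(gastric_half_clearance(make_tac(t_s[1:10], v[1:10])), "10 minutes")
})

test_that("pharynx/background ratio has unit baseline and detects excess", {
  study <- make_study(uniform_frames(8, 6))
  rois <- default_roi_set(64)
  r <- pharynx_background_ratio(study, rois)
  expect_equal(r$per_frame, rep(1, 8))
  expect_equal(r$summary, 1)
  zl <- zone_layout(64)
  study2 <- excess_study(zl$pharynx, excess = 6, bg_level = 6)
  expect_equal(pharynx_background_ratio(study2, rois)$summary, 2)
  study0 <- make_study(uniform_frames(4, 0))
  expect_error(pharynx_background_ratio(study0, rois), "background")
})

test_that("no-reflux patients keep the summary ratio below 1.5 in >=95% of seeds", {
  ratios <- vapply(1:40, function(s) {
    kc <- c(0.5, 0.05, 0.25, 0.12)[s %% 4 + 1]
    p <- kinetics_params(reflux_event_rate_upright = 0,
                         reflux_event_rate_supine = 0, clearance_rate = kc)
    imgs <- render_frames(simulate_kinetics(p, seed = s), seed = s)
    rois <- default_roi_set(64)
    max(pharynx_background_ratio(imgs$upright, rois)$summary,
        pharynx_background_ratio(imgs$supine, rois)$summary)
  }, numeric(1))
  expect_gte(mean(ratios < 1.5), 0.95)
})

test_that("curve grades emerge from the reflux kinetics", {
  # heavy reflux with poor clearance -> rising supine pharyngeal curve
  g_high <- vapply(1:30, function(s) {
    p <- kinetics_params(reflux_event_rate_upright = 1,
                         reflux_event_rate_supine = 0.6,
                         clearance_rate = 0.03, max_reflux_height = "pharynx")
    imgs <- render_frames(simulate_kinetics(p, seed = 100 + s), seed = 100 + s)
    grade_curve(extract_tac(imgs$supine, default_roi_set(64), "pharynx"))$grade
  }, integer(1))
  expect_gte(mean(g_high == 3L), 0.9)

  # no reflux -> declining supine pharyngeal curve (the swallow residue washout)
  g_none <- vapply(1:60, function(s) {
    kc <- c(0.5, 0.05, 0.25, 0.12)[s %% 4 + 1]
    p <- kinetics_params(reflux_event_rate_upright = 0,
                         reflux_event_rate_supine = 0, clearance_rate = kc)
    imgs <- render_frames(simulate_kinetics(p, seed = 500 + s), seed = 500 + s)
    grade_curve(extract_tac(imgs$supine, default_roi_set(64), "pharynx"))$grade
  }, integer(1))
  expect_gte(mean(g_none == 1L), 0.99)
})

test_that("grade-3 supine pharyngeal curves track high-reflux / low-clearance ground truth", {
  cfg <- cohort_config(n_total = 200, n_gord = 58, n_lpr = 142)
  pl <- run_pipeline(cfg, seed = 7)
  kin <- pl$cohort$kinetics
  truth <- vapply(kin, function(k) {
    k$max_reflux_height == "pharynx" && k$reflux_event_rate_supine >= 0.3 &&
      k$clearance_rate <= 0.12
  }, logical(1))
  g3 <- pl$results$grade_pharynx_supine == 3L
  balanced <- (mean(g3[truth]) + mean(!g3[!truth])) / 2
  expect_gte(balanced, 0.85)
})
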