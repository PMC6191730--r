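test_that("configuration errors name the offending field", {
  expect_error(cohort_config(n_total = 100, n_gord = 30, n_lpr = 80), "n_gord")
  expect_error(cohort_config(ph_category_probs = c(0.5, 0.4, 0.2)),
               "ph_category_probs")
  expect_error(cohort_config(aspiration_prob_lpr = 1.3), "aspiration_prob_lpr")
})

test_that("default cohort reproduces the configured class split exactly", {
  co <- generate_cohort(cohort_config(), seed = 1)
  expect_equal(nrow(co$patients), 250L)
  expect_equal(sum(co$patients$symptom_class == "GORD"), 72L)
  expect_equal(sum(co$patients$symptom_class == "LPR"), 178L)
  expect_true(all(co$patients$age >= 20 & co$patients$age <= 85))
  expect_true(all(co$patients$los_pressure > 0))
})

test_that("zero aspiration probability yields no aspirators", {
  cfg <- cohort_config(aspiration_prob_gord = 0, aspiration_prob_lpr = 0)
  co <- generate_cohort(cfg, seed = 2)
  expect_false(any(co$patients$true_aspiration))
  expect_true(all(vapply(co$kinetics, function(k) k$aspiration_fraction,
                         numeric(1)) == 0))
})

test_that("identical seed gives a bit-identical cohort; different seeds differ", {
  cfg <- cohort_config(n_total = 40, n_gord = 12, n_lpr = 28)
  expect_identical(generate_cohort(cfg, seed = 9), generate_cohort(cfg, seed = 9))
  a <- generate_cohort(cfg, seed = 9)$patients
  b <- generate_cohort(cfg, seed = 10)$patients
  expect_false(identical(a, b))
})

test_that("extending the cohort does not reshuffle earlier patients", {
  small <- generate_cohort(cohort_config(n_total = 30, n_gord = 30, n_lpr = 0),
                           seed = 4)
  big <- generate_cohort(cohort_config(n_total = 60, n_gord = 60, n_lpr = 0),
                         seed = 4)
  expect_identical(small$patients, big$patients[1:30, ])
})

test_that("LOS pressure marginal matches the lognormal mean/median solution", {
  # location ln(2.3) and scale sqrt(2 ln(6.3/2.3)) give median 2.3, mean 6.3
  set.seed(1)
  x <- stats::rlnorm(1e5, log(2.3), sqrt(2 * log(6.3 / 2.3)))
  expect_lt(abs(mean(x) / 6.3 - 1), 0.05)
  expect_lt(abs(stats::median(x) / 2.3 - 1), 0.05)
})

test_that("aspiration rates stay calibrated to the study marginals across seeds", {
  cfg <- cohort_config()
  counts <- vapply(1:200, function(s) {
    p <- generate_cohort(cfg, seed = s)$patients
    c(sum(p$true_aspiration[p$symptom_class == "LPR"]),
      sum(p$true_aspiration[p$symptom_class == "GORD"]))
  }, numeric(2))
  # mean fraction across seeds within the exact (Clopper-Pearson) 99%
  # interval of the observed study proportions
  ci_lpr <- c(stats::qbeta(0.005, 58, 178 - 58 + 1),
              stats::qbeta(0.995, 58 + 1, 178 - 58))
  ci_gord <- c(stats::qbeta(0.005, 10, 72 - 10 + 1),
               stats::qbeta(0.995, 10 + 1, 72 - 10))
  expect_gt(mean(counts[1, ]) / 178, ci_lpr[1])
  expect_lt(mean(counts[1, ]) / 178, ci_lpr[2])
  expect_gt(mean(counts[2, ]) / 72, ci_gord[1])
  expect_lt(mean(counts[2, ]) / 72, ci_gord[2])
})

test_that("copula couplings land near their targets", {
  cfg <- cohort_config()
  stats_by_seed <- vapply(1:40, function(s) {
    p <- generate_cohort(cfg, seed = 400 + s)$patients
    lpr <- p[p$symptom_class == "LPR", ]
    gord <- p[p$symptom_class == "GORD", ]
    c(cor(lpr$iom_grade == "severe", lpr$true_aspiration),
      cor(gord$iom_grade == "severe", gord$true_aspiration),
      cor(p$proximal_acid_pct, p$distal_acid_pct))
  }, numeric(3))
  means <- rowMeans(stats_by_seed)
  expect_lt(abs(means[1] - 0.54), 0.05)
  expect_lt(abs(means[2] - 0.21), 0.05)
  expect_lt(abs(means[3] - 0.32), 0.05)
})

test_that("severe motility impairment maps to low oesophageal clearance", {
  co <- generate_cohort(cohort_config(), seed = 3)
  cl <- vapply(co$kinetics, function(k) k$clearance_rate, numeric(1))
  g <- co$patients$iom_grade
  expect_gt(mean(cl[g == "normal"]), mean(cl[g == "severe"]))
  expect_true(all(co$patients$true_aspiration ==
                    (vapply(co$kinetics, function(k) k$aspiration_fraction,
                            numeric(1)) > 0)))
  heights <- vapply(co$kinetics, function(k) k$max_reflux_height, character(1))
  expect_true(all(heights[co$patients$true_aspiration] == "pharynx"))
})

test_that("reflux episodes are classified by their minimum pH", {
  expect_equal(classify_ph(c(6.5, 3.2, 5.0)), "acid")
  expect_equal(classify_ph(4.0), "weakly_acid")
  expect_equal(classify_ph(c(7.0, 7.4)), "non_acid")
  expect_equal(classify_ph(6.99), "weakly_acid")
  expect_error(classify_ph(numeric(0)), "empty")
  expect_error(classify_ph(c(3, 15)), "0, 14")
})
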