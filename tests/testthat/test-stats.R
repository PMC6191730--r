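test_that("Fisher exact p matches exhaustive enumeration on all small tables", {
  worst <- 0
  for (n in 1:12) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      d <- n - a - b - cc
      if (a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0) next
      m <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
      worst <- max(worst, abs(fisher_exact_two_tailed(m) - fisher_oracle(m)))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("Fisher exact agrees with the reference implementation and the study tables", {
  tables <- list(matrix(c(58, 120, 10, 62), 2, byrow = TRUE),
                 matrix(c(62, 116, 12, 60), 2, byrow = TRUE),
                 matrix(c(48, 130, 35, 37), 2, byrow = TRUE),
                 matrix(c(3, 60, 15, 22), 2, byrow = TRUE))
  for (m in tables) {
    expect_equal(fisher_exact_two_tailed(m),
                 stats::fisher.test(m)$p.value, tolerance = 1e-9)
  }
  expect_equal(fisher_exact_two_tailed(contingency_table(5, 5, 5, 5)), 1.0)
})

test_that("Fisher p is invariant to transposition and row/column swaps", {
  set.seed(9)
  for (i in 1:20) {
    m <- matrix(rpois(4, 20), 2)
    p <- fisher_exact_two_tailed(m)
    expect_equal(fisher_exact_two_tailed(t(m)), p, tolerance = 1e-12)
    expect_equal(fisher_exact_two_tailed(m[2:1, 2:1]), p, tolerance = 1e-12)
  }
  expect_error(contingency_table(-1, 2, 3, 4), "non-negative")
})

test_that("predictive values follow the table convention and flag undefined cells", {
  perfect <- predictive_values(contingency_table(10, 0, 0, 10))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))
  inverted <- predictive_values(contingency_table(0, 10, 10, 0))
  expect_equal(inverted$ppv, 0)
  expect_equal(inverted$npv, 0)
  pv <- predictive_values(contingency_table(49, 1, 3, 60))
  expect_equal(pv$ppv, 0.98)
  expect_equal(pv$npv, 60 / 63)
  undef <- predictive_values(contingency_table(0, 0, 5, 5))
  expect_true(is.na(undef$ppv))
  expect_false(is.na(undef$npv))
})

test_that("pearson_r matches trivial identities and rejects degenerate input", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  expect_equal(pearson_r(x, x)$r, 1.0)
  expect_equal(pearson_r(x, -x)$r, -1.0)
  expect_error(pearson_r(x, rep(1, 5)), "variance")
  expect_error(pearson_r(x, x[1:3]), "equal length")
  set.seed(10)
  a <- rnorm(50); b <- 0.5 * a + rnorm(50)
  ct <- stats::cor.test(a, b)
  pr <- pearson_r(a, b)
  expect_equal(pr$r, unname(ct$estimate))
  expect_equal(pr$p, ct$p.value)
})

test_that("cohort proximal-distal acid correlation hits the copula target", {
  rs <- vapply(1:100, function(s)
    with(generate_cohort(cohort_config(), seed = 4000 + s)$patients,
         cor(proximal_acid_pct, distal_acid_pct)), numeric(1))
  expect_lt(abs(mean(rs) - 0.32), 0.05)
})

test_that("AUC equals brute-force pairwise counting on small inputs", {
  set.seed(11)
  worst <- 0
  for (i in 1:200) {
    n <- sample(4:12, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- sample(1:4, n, replace = TRUE)  # ties likely
    r <- roc_auc(scores, labels)
    worst <- max(worst, abs(r$auc - auc_oracle(scores, labels)))
    # trapezoidal area under the empirical curve equals the rank AUC
    trap <- sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
    expect_lt(abs(trap - r$auc), 1e-12)
  }
  expect_lt(worst, 1e-12)
})

test_that("AUC behaves at the extremes and under score negation", {
  expect_equal(roc_auc(c(3, 4, 5, 1, 2), c(TRUE, TRUE, TRUE, FALSE, FALSE))$auc, 1.0)
  set.seed(12)
  scores <- rnorm(40); labels <- rep(c(TRUE, FALSE), 20)
  expect_equal(roc_auc(scores, labels)$auc + roc_auc(-scores, labels)$auc, 1.0,
               tolerance = 1e-12)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC is centred on 0.5 for uninformative scores", {
  set.seed(13)
  aucs <- vapply(1:200, function(i) {
    roc_auc(rnorm(1000), rep(c(TRUE, FALSE), 500))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.01)
})

test_that("AUC and Hanley-McNeil SE agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(14)
  scores <- c(rnorm(30, 1), rnorm(50))
  labels <- rep(c(TRUE, FALSE), c(30, 50))
  r <- roc_auc(scores, labels)
  ref <- pROC::roc(response = labels, predictor = scores, quiet = TRUE,
                   direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("benchmark_report assembles auditable tables from a cohort results frame", {
  set.seed(15)
  n <- 80
  results <- data.frame(
    patient_id = sprintf("P%03d", 1:n),
    symptom_class = rep(c("LPR", "GORD"), c(56, 24)),
    iom_grade = factor(sample(c("normal", "mild", "moderate", "severe"), n, TRUE),
                       levels = c("normal", "mild", "moderate", "severe"),
                       ordered = TRUE),
    proximal_acid_pct = rgamma(n, 1.2, 0.5),
    distal_acid_pct = rgamma(n, 1.5, 0.3),
    los_pressure = rlnorm(n, log(2.3), 1.4),
    aspiration = rep(c(TRUE, FALSE), c(20, 60)),
    grade_pharynx_upright = sample(1:3, n, TRUE),
    grade_pharynx_supine = c(rep(3, 20), rep(1, 40), sample(1:3, 20, TRUE)),
    grade_upper_upright = sample(1:3, n, TRUE),
    grade_upper_supine = sample(1:3, n, TRUE))
  rep_ <- benchmark_report(results)
  expect_length(rep_$cross_tabs, 4)
  expect_gte(length(rep_$roc), 3)
  # partition check: each cross-tab covers every patient exactly once
  for (tb in rep_$cross_tabs) expect_equal(sum(tb), n)
  # no grade-1 supine pharynx patient aspirates in this construction -> NPV 1
  expect_equal(rep_$predictive_values$pharynx_supine$declining$npv, 1.0)
  # printed counts reproduce the reported predictive values exactly
  pv <- rep_$predictive_values$pharynx_supine$rising
  expect_equal(pv$ppv, pv$table[1, 1] / sum(pv$table[1, ]))
  # Fisher on the aspiration-by-class table matches a direct recomputation
  f <- rep_$fisher$aspiration_by_class
  expect_equal(f$p, fisher_exact_two_tailed(f$table))
  expect_error(benchmark_report(results[, -3]), "iom_grade")
})
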