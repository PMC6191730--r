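#' 2x2 contingency table
#'
#' Cell convention: rows are group or test result (row 1 = exposed / test
#' positive), columns are outcome (column 1 = outcome present), so
#' \code{a, b} form the first row and \code{c, d} the second.
#'
#' @param a,b,c,d non-negative integer counts
#' @return an object of class \code{contingency_table} (a 2x2 integer
#'   matrix)
#' @export
contingency_table <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("contingency_table: counts must be non-negative integers")
  if (sum(counts) == 0) stop("contingency_table: total count must be > 0")
  m <- matrix(as.integer(round(counts)), 2, 2, byrow = TRUE)
  class(m) <- c("contingency_table", class(m))
  m
}

as_table22 <- function(x) {
  if (inherits(x, "contingency_table")) return(unclass(x))
  if (is.matrix(x) && all(dim(x) == 2)) return(x)
  stop("expected a 2x2 contingency table")
}

#' Fisher's exact test, two-tailed
#'
#' Exact two-sided p-value for independence in a 2x2 table with fixed
#' margins, defined as the sum of hypergeometric probabilities of all tables
#' (with the observed margins) no more probable than the observed one — the
#' usual "sum of small p" convention. Probabilities within a relative
#' 1e-7 of the observed one are counted as ties.
#'
#' @param table a \code{\link{contingency_table}} or 2x2 matrix of counts
#' @return p-value in (0, 1]
#' @export
fisher_exact_two_tailed <- function(table) {
  m <- as_table22(table)
  if (any(m < 0)) stop("fisher_exact_two_tailed: negative counts")
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0L, r1 + c1 - n)
  hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Sensitivity, specificity and predictive values
#'
#' Row 1 of the table is the positive test (e.g. rising curve), row 2 the
#' negative test; column 1 the outcome (e.g. aspiration). Cells whose
#' denominator margin is zero are returned as \code{NA} (flagged undefined)
#' rather than silently zero.
#'
#' @param table a \code{\link{contingency_table}} or 2x2 matrix
#' @return object of class \code{diagnostic_summary}: list with
#'   \code{sensitivity}, \code{specificity}, \code{ppv}, \code{npv}
#' @export
predictive_values <- function(table) {
  m <- as_table22(table)
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(sensitivity = safe(a, a + c),
                 specificity = safe(d, b + d),
                 ppv = safe(a, a + b),
                 npv = safe(d, c + d),
                 table = m),
            class = "diagnostic_summary")
}

#' Pearson product-moment correlation with two-sided p
#'
#' @param x,y numeric vectors of equal length (at least 3), each with
#'   non-zero variance
#' @return list with \code{r} and \code{p} (two-sided, from the t
#'   transformation with n - 2 degrees of freedom)
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("pearson_r: x and y must have equal length >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("pearson_r: zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' ROC curve and AUC for a diagnostic marker
#'
#' The AUC is computed by the rank (pairwise concordance) formulation with
#' ties counted one half, which equals the trapezoidal area under the
#' empirical ROC curve. The standard error uses the Hanley-McNeil formula
#' and the p-value is a two-sided normal test of AUC = 0.5.
#'
#' @param scores numeric or ordinal marker values (higher = more suspicious)
#' @param labels logical (or 0/1) outcome, \code{TRUE} = event
#' @return object of class \code{roc_result}: \code{thresholds},
#'   \code{tpr}, \code{fpr}, \code{auc}, \code{auc_se}, \code{p_value},
#'   \code{n_pos}, \code{n_neg}
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("roc_auc: missing values")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("roc_auc: both classes must be present")
  # midranks give the tie-corrected Mann-Whitney statistic
  rk <- rank(scores)
  auc <- (sum(rk[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # empirical ROC curve: sweep thresholds from high to low
  cuts <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(cuts, function(th) mean(scores[labels] >= th), numeric(1))
  fpr <- vapply(cuts, function(th) mean(scores[!labels] >= th), numeric(1))
  tpr <- c(0, tpr, 1); fpr <- c(0, fpr, 1)
  thresholds <- c(Inf, cuts, -Inf)

  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) + (n0 - 1) * (q2 - auc^2)) /
    (n1 * n0)
  se <- sqrt(max(v, 0))
  p <- if (se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / se) else
    as.numeric(auc == 0.5)
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr,
                 auc = auc, auc_se = se, p_value = p,
                 n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (SE %.3f), p = %.4g [%d events / %d non-events]\n",
              x$auc, x$auc_se, x$p_value, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)
  cat(sprintf("sensitivity %s  specificity %s  PPV %s  NPV %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv), fmt(x$npv)))
  invisible(x)
}

#' Benchmark report over per-patient cohort results
#'
#' Assembles the study-level benchmarking from a per-patient results table:
#' grade-by-class-by-aspiration cross-tabulations for the pharyngeal and
#' upper-oesophageal curves in both postures, Fisher's exact tests
#' (aspiration by symptom class, severe IOM by class, normal motility by
#' class), predictive values of declining and rising curves for aspiration,
#' and ROC analyses for each candidate marker. Every table carries the exact
#' counts used so each number is auditable. No multiplicity correction is
#' applied (each test at the 0.05 level).
#'
#' @param results data frame with one row per patient and columns
#'   \code{patient_id}, \code{symptom_class}, \code{iom_grade},
#'   \code{proximal_acid_pct}, \code{distal_acid_pct}, \code{los_pressure},
#'   \code{aspiration} (logical), and curve grades
#'   \code{grade_pharynx_upright}, \code{grade_pharynx_supine},
#'   \code{grade_upper_upright}, \code{grade_upper_supine}
#' @return object of class \code{reflux_report}
#' @export
benchmark_report <- function(results) {
  needed <- c("patient_id", "symptom_class", "iom_grade",
              "proximal_acid_pct", "distal_acid_pct", "los_pressure",
              "aspiration", "grade_pharynx_upright", "grade_pharynx_supine",
              "grade_upper_upright", "grade_upper_supine")
  missing <- setdiff(needed, names(results))
  if (length(missing))
    stop("benchmark_report: missing columns: ", paste(missing, collapse = ", "))

  asp <- as.logical(results$aspiration)
  cls <- results$symptom_class

  cross_tabs <- list()
  for (site in c("pharynx", "upper")) {
    for (posture in c("upright", "supine")) {
      g <- results[[sprintf("grade_%s_%s", site, posture)]]
      cross_tabs[[sprintf("%s_%s", site, posture)]] <-
        table(grade = g, class = cls, aspiration = asp)
    }
  }

  tab_asp <- contingency_table(sum(cls == "LPR" & asp), sum(cls == "LPR" & !asp),
                               sum(cls == "GORD" & asp), sum(cls == "GORD" & !asp))
  severe <- results$iom_grade == "severe"
  normal <- results$iom_grade == "normal"
  tab_sev <- contingency_table(sum(cls == "LPR" & severe), sum(cls == "LPR" & !severe),
                               sum(cls == "GORD" & severe), sum(cls == "GORD" & !severe))
  tab_norm <- contingency_table(sum(cls == "LPR" & normal), sum(cls == "LPR" & !normal),
                                sum(cls == "GORD" & normal), sum(cls == "GORD" & !normal))
  fisher <- list(
    aspiration_by_class = list(table = tab_asp, p = fisher_exact_two_tailed(tab_asp)),
    severe_iom_by_class = list(table = tab_sev, p = fisher_exact_two_tailed(tab_sev)),
    normal_motility_by_class = list(table = tab_norm, p = fisher_exact_two_tailed(tab_norm)))

  # predictive values of curve grades for aspiration: a rising curve is the
  # positive test (PPV), a declining curve the negative test (NPV)
  pv <- list()
  for (key in names(cross_tabs)) {
    g <- results[[paste0("grade_", key)]]
    rising <- contingency_table(sum(g == 3 & asp), sum(g == 3 & !asp),
                                sum(g != 3 & asp), sum(g != 3 & !asp))
    declining <- contingency_table(sum(g != 1 & asp), sum(g != 1 & !asp),
                                   sum(g == 1 & asp), sum(g == 1 & !asp))
    pv[[key]] <- list(rising = predictive_values(rising),
                      declining = predictive_values(declining))
  }

  markers <- list(
    pharynx_grade_upright = results$grade_pharynx_upright,
    pharynx_grade_supine = results$grade_pharynx_supine,
    upper_grade_upright = results$grade_upper_upright,
    upper_grade_supine = results$grade_upper_supine,
    iom_grade = as.integer(factor(results$iom_grade, levels = IOM_LEVELS,
                                  ordered = TRUE)),
    proximal_acid_pct = results$proximal_acid_pct,
    distal_acid_pct = results$distal_acid_pct,
    los_pressure = results$los_pressure)
  roc <- if (length(unique(asp)) < 2) list() else {
    out <- lapply(markers, function(s) {
      if (length(unique(s)) < 2) return(NULL)
      roc_auc(s, asp)
    })
    out[!vapply(out, is.null, logical(1))]
  }

  structure(list(n = nrow(results), cross_tabs = cross_tabs,
                 fisher = fisher, predictive_values = pv, roc = roc,
                 footer = "Each test at the 0.05 level; no multiple-testing correction applied."),
            class = "reflux_report")
}

#' @export
print.reflux_report <- function(x, ...) {
  cat(sprintf("Reflux benchmark report over %d patients\n", x$n))
  for (nm in names(x$fisher)) {
    f <- x$fisher[[nm]]
    cat(sprintf("  Fisher %-26s p = %.4g  [%s]\n", nm, f$p,
                paste(t(unclass(f$table)), collapse = "/")))
  }
  for (key in names(x$predictive_values)) {
    p <- x$predictive_values[[key]]
    cat(sprintf("  %-16s rising PPV %.3f | declining NPV %.3f\n", key,
                p$rising$ppv, p$declining$npv))
  }
  for (nm in names(x$roc)) {
    cat(sprintf("  ROC %-22s AUC %.3f (p = %.3g)\n", nm, x$roc[[nm]]$auc,
                x$roc[[nm]]$p_value))
  }
  cat(" ", x$footer, "\n")
  invisible(x)
}
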