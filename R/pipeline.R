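#' Analyse one patient's simulated study
#'
#' Runs the per-patient half of the pipeline: simulate kinetics, render the
#' images, extract and grade the pharyngeal and upper-oesophageal
#' time-activity curves in both postures, estimate gastric half-clearance
#' from the supine stomach curve, compute the pharynx/background ratio, and
#' call pulmonary aspiration on the delayed image.
#'
#' @param params a \code{\link{kinetics_params}}
#' @param protocol an \code{\link{acquisition_protocol}}
#' @param rparams rendering calibration (\code{\link{render_params}})
#' @param seed integer seed (kinetics and noise substreams are derived from
#'   it)
#' @param z_crit slope z cutoff passed to \code{\link{grade_curve}}
#' @param threshold aspiration line-profile threshold
#' @return list with \code{images}, \code{tacs}, \code{grades} (named list
#'   of \code{curve_grade}), \code{half_clearance_min},
#'   \code{pharynx_bg_ratio}, \code{aspiration} (an
#'   \code{aspiration_call})
#' @export
analyse_patient <- function(params, protocol = acquisition_protocol(),
                            rparams = render_params(), seed = 1L,
                            z_crit = 2.0, threshold = 2.0) {
  series <- simulate_kinetics(params, protocol, seed = seed)
  images <- render_frames(series, protocol, rparams,
                          seed = patient_seed(seed, 1L, stream = 9L))
  rois <- default_roi_set(protocol$dynamic_matrix)

  tacs <- list()
  grades <- list()
  for (posture in c("upright", "supine")) {
    for (roi in c("pharynx", "upper_oesophagus")) {
      tc <- extract_tac(images[[posture]], rois, roi)
      key <- sprintf("%s_%s", if (roi == "pharynx") "pharynx" else "upper", posture)
      tacs[[key]] <- tc
      grades[[key]] <- grade_curve(tc, z_crit = z_crit)
    }
  }
  stomach_tac <- extract_tac(images$supine, rois, "stomach")
  tacs$stomach_supine <- stomach_tac
  half_clear <- gastric_half_clearance(stomach_tac)
  ratio <- max(pharynx_background_ratio(images$upright, rois)$summary,
               pharynx_background_ratio(images$supine, rois)$summary)
  prof <- line_profile(images$delayed)
  call <- detect_aspiration(prof, threshold = threshold)
  list(images = images, tacs = tacs, grades = grades,
       half_clearance_min = half_clear, pharynx_bg_ratio = ratio,
       profile = prof, aspiration = call)
}

#' Run the full cohort pipeline
#'
#' Orchestrates simulate, TAC extraction and grading, aspiration detection
#' and statistical benchmarking for a whole cohort: generates the ground
#' truth, simulates and analyses every patient, assembles the per-patient
#' results table and builds the \code{\link{benchmark_report}}. Deterministic
#' given the seed. If \code{out_dir} is given, writes \code{cohort.csv}
#' (ground truth), \code{results.csv}, \code{report.json} and, when
#' \code{write_images} is set, one study-bundle directory per patient.
#'
#' @param config a \code{\link{cohort_config}}
#' @param protocol an \code{\link{acquisition_protocol}}
#' @param rparams rendering calibration
#' @param seed master seed (default \code{config$seed})
#' @param z_crit curve-grading cutoff
#' @param threshold aspiration threshold
#' @param out_dir optional output directory
#' @param write_images also write per-patient image bundles (slow)
#' @param verbose print progress every 50 patients
#' @return list of class \code{reflux_pipeline}: \code{cohort},
#'   \code{results} (data frame), \code{report}
#' @export
run_pipeline <- function(config = cohort_config(),
                         protocol = acquisition_protocol(),
                         rparams = render_params(),
                         seed = config$seed, z_crit = 2.0, threshold = 2.0,
                         out_dir = NULL, write_images = FALSE,
                         verbose = FALSE) {
  cohort <- generate_cohort(config, seed = seed)
  n <- nrow(cohort$patients)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pa <- tryCatch(
      analyse_patient(cohort$kinetics[[i]], protocol, rparams,
                      seed = patient_seed(seed, i, stream = 1L),
                      z_crit = z_crit, threshold = threshold),
      error = function(e) stop(sprintf("pipeline stage 'analyse' failed for patient %s: %s",
                                       cohort$patients$patient_id[i],
                                       conditionMessage(e))))
    rows[[i]] <- data.frame(
      patient_id = cohort$patients$patient_id[i],
      grade_pharynx_upright = pa$grades$pharynx_upright$grade,
      grade_pharynx_supine = pa$grades$pharynx_supine$grade,
      grade_upper_upright = pa$grades$upper_upright$grade,
      grade_upper_supine = pa$grades$upper_supine$grade,
      half_clearance_min = pa$half_clearance_min,
      pharynx_bg_ratio = pa$pharynx_bg_ratio,
      aspiration = pa$aspiration$positive,
      aspiration_max_ratio = pa$aspiration$max_ratio,
      stringsAsFactors = FALSE)
    if (!is.null(out_dir) && write_images) {
      write_study(list(patient_id = cohort$patients$patient_id[i],
                       upright = pa$images$upright, supine = pa$images$supine,
                       delayed = pa$images$delayed,
                       provenance = list(seed = seed, patient_index = i)),
                  file.path(out_dir, "studies", cohort$patients$patient_id[i]))
    }
    if (verbose && i %% 50 == 0)
      message(sprintf("  analysed %d / %d patients", i, n))
  }
  derived <- do.call(rbind, rows)
  results <- merge(cohort$patients, derived, by = "patient_id", sort = FALSE)
  results <- results[order(results$patient_id), ]
  report <- benchmark_report(results)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cohort$patients, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    utils::write.csv(results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report_to_list(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(cohort = cohort, results = results, report = report,
                 seed = seed),
            class = "reflux_pipeline")
}

# plain-list view of a report, for JSON serialization
report_to_list <- function(report) {
  list(
    n = report$n,
    fisher = lapply(report$fisher, function(f)
      list(counts = as.integer(t(unclass(f$table))), p = f$p)),
    predictive_values = lapply(report$predictive_values, function(p)
      list(rising_ppv = p$rising$ppv, declining_npv = p$declining$npv,
           rising_counts = as.integer(t(unclass(p$rising$table))),
           declining_counts = as.integer(t(unclass(p$declining$table))))),
    roc = lapply(report$roc, function(r)
      list(auc = r$auc, auc_se = r$auc_se, p_value = r$p_value)),
    cross_tabs = lapply(report$cross_tabs, function(tb)
      as.data.frame(tb, stringsAsFactors = FALSE)),
    footer = report$footer)
}

#' @export
print.reflux_pipeline <- function(x, ...) {
  print(x$cohort)
  cat(sprintf("Detected aspiration in %d / %d patients (%.0f%%)\n",
              sum(x$results$aspiration), nrow(x$results),
              100 * mean(x$results$aspiration)))
  print(x$report)
  invisible(x)
}
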