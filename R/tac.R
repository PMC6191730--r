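#' Region-of-interest set for time-activity curve extraction
#'
#' Named pixel regions over the dynamic matrix: pharynx, the three
#' oesophageal thirds, stomach, and a background region over the lateral
#' chest. Regions are given as rectangles (\code{row0/row1/col0/col1},
#' 0-based inclusive, row-major origin top-left) or explicit two-column
#' (row, col) pixel matrices, and must be pairwise disjoint and non-empty.
#'
#' @param regions named list of regions
#' @param matrix_size image matrix the ROIs are defined on
#' @return an object of class \code{roi_set}
#' @export
roi_set <- function(regions, matrix_size = 64L) {
  stopifnot(is.list(regions), length(names(regions)) == length(regions))
  px <- lapply(regions, function(r) {
    if (is.matrix(r)) {
      stopifnot(ncol(r) == 2)
      r
    } else {
      zone_pixels(r)
    }
  })
  for (nm in names(px)) {
    p <- px[[nm]]
    if (nrow(p) == 0) stop(sprintf("roi_set: region '%s' is empty", nm))
    if (any(p < 0) || any(p >= matrix_size))
      stop(sprintf("roi_set: region '%s' extends outside the %dx%d matrix",
                   nm, matrix_size, matrix_size))
  }
  keys <- lapply(px, function(p) p[, 1] * matrix_size + p[, 2])
  all_keys <- unlist(keys)
  if (anyDuplicated(all_keys))
    stop("roi_set: regions must be pairwise disjoint")
  structure(list(pixels = px, matrix_size = as.integer(matrix_size)),
            class = "roi_set")
}

#' Default ROI set matching the simulator's schematic anatomy
#'
#' @param matrix_size dynamic matrix size in pixels
#' @return an \code{roi_set} with regions \code{pharynx},
#'   \code{upper_oesophagus}, \code{mid_oesophagus},
#'   \code{lower_oesophagus}, \code{stomach} and \code{background}
#' @export
default_roi_set <- function(matrix_size = 64L) {
  zl <- zone_layout(matrix_size)
  roi_set(list(pharynx = zl$pharynx,
               upper_oesophagus = zl$upper,
               mid_oesophagus = zl$mid,
               lower_oesophagus = zl$lower,
               stomach = zl$stomach,
               background = zl$background),
          matrix_size = matrix_size)
}

# mean counts per pixel inside one ROI for every frame of a study
roi_mean_counts <- function(study, rois, roi_name) {
  p <- rois$pixels[[roi_name]]
  if (is.null(p)) stop(sprintf("ROI '%s' not present in the ROI set", roi_name))
  n <- nrow(study$frames[[1]])
  if (any(p >= n)) stop(sprintf("ROI '%s' lies outside the %dx%d frame", roi_name, n, n))
  idx <- p[, 2] * n + p[, 1] + 1L  # column-major linear index from (row, col)
  vapply(study$frames, function(f) mean(f[idx]), numeric(1))
}

#' Extract a background-corrected time-activity curve
#'
#' For each frame, the mean counts per pixel in the organ ROI minus the mean
#' counts per pixel in the background ROI, divided by the frame duration and
#' decay-corrected to the start of the acquisition segment. Times are frame
#' midpoints in seconds since segment start. Values may be negative after
#' background correction.
#'
#' @param study a \code{dynamic_study}
#' @param rois an \code{\link{roi_set}}
#' @param roi_name name of the organ region
#' @param background_name name of the background region
#' @return an object of class \code{tac} with fields \code{roi_name},
#'   \code{posture}, \code{times} (s), \code{values}
#'   (counts / pixel / second)
#' @export
extract_tac <- function(study, rois, roi_name, background_name = "background") {
  if (length(study$frames) == 0) stop("extract_tac: study has no frames")
  frame_s <- study$frame_times[2] - study$frame_times[1]
  if (length(study$frames) == 1)
    frame_s <- if (study$posture == "upright") study$protocol$upright_frame_seconds
               else study$protocol$supine_frame_seconds
  organ <- roi_mean_counts(study, rois, roi_name)
  bg <- roi_mean_counts(study, rois, background_name)
  t_mid <- study$frame_times + frame_s / 2
  lam_min <- decay_lambda_per_min(study$protocol)
  values <- (organ - bg) / frame_s * exp(lam_min * t_mid / 60)
  structure(list(roi_name = roi_name, posture = study$posture,
                 times = t_mid, values = values),
            class = "tac")
}

#' Grade a time-activity curve as declining, flat or rising
#'
#' Fits a least-squares line to values vs time and classifies the curve by
#' the slope z statistic: grade 1 (declining) if \code{slope/se < -z_crit},
#' grade 3 (rising) if \code{> +z_crit}, grade 2 (flat) otherwise.
#'
#' @param tac a \code{tac} object (or any list with \code{times} in seconds
#'   and \code{values})
#' @param z_crit critical value of the slope z statistic (default 2.0)
#' @return an object of class \code{curve_grade} with fields \code{grade}
#'   (1/2/3), \code{label}, \code{slope} and \code{slope_se} (counts /
#'   pixel / second per minute)
#' @export
grade_curve <- function(tac, z_crit = 2.0) {
  t_min <- tac$times / 60
  v <- tac$values
  if (length(v) < 4) stop("grade_curve: need at least 4 points")
  if (stats::var(t_min) == 0) stop("grade_curve: zero variance in time")
  fit <- stats::lm(v ~ t_min)
  # summary.lm warns on an exactly flat, noise-free curve (se = 0); that
  # degenerate case is graded flat below
  sm <- suppressWarnings(summary(fit)$coefficients)
  slope <- sm["t_min", "Estimate"]
  se <- sm["t_min", "Std. Error"]
  z <- if (se > 0) slope / se else 0
  grade <- if (z > z_crit) 3L else if (z < -z_crit) 1L else 2L
  structure(list(grade = grade,
                 label = c("declining", "flat", "rising")[grade],
                 slope = slope, slope_se = se, z = z, z_crit = z_crit),
            class = "curve_grade")
}

#' Gastric half-clearance time
#'
#' Fits a single exponential to the (already decay-corrected) stomach
#' time-activity curve by log-linear least squares and returns
#' \code{log(2)} over the fitted emptying rate, in minutes. A non-positive
#' fitted rate (a flat or rising stomach curve) returns \code{Inf},
#' meaning half clearance was not reached.
#'
#' @param tac stomach \code{tac} spanning at least 10 minutes with a
#'   positive initial value
#' @return half-clearance time in minutes, or \code{Inf}
#' @export
gastric_half_clearance <- function(tac) {
  t_min <- tac$times / 60
  v <- tac$values
  if (diff(range(t_min)) < 10)
    stop("gastric_half_clearance: curve must span at least 10 minutes")
  if (v[1] <= 0)
    stop("gastric_half_clearance: non-positive initial stomach activity")
  keep <- v > 0
  if (sum(keep) < 4)
    stop("gastric_half_clearance: too few positive points to fit")
  fit <- stats::lm(log(v[keep]) ~ t_min[keep])
  rate <- -unname(stats::coef(fit)[2])
  if (rate <= 0) return(Inf)
  log(2) / rate
}

#' Pharynx-to-background count ratio
#'
#' Ratio of the uncorrected mean pharyngeal counts per pixel to the mean
#' background counts per pixel, per frame, with the study summary taken as
#' the maximum over frames.
#'
#' @param study a \code{dynamic_study}
#' @param rois an \code{\link{roi_set}}
#' @param pharynx_name,background_name region names
#' @return list with \code{per_frame} (numeric vector) and \code{summary}
#'   (max over frames)
#' @export
pharynx_background_ratio <- function(study, rois, pharynx_name = "pharynx",
                                     background_name = "background") {
  ph <- roi_mean_counts(study, rois, pharynx_name)
  bg <- roi_mean_counts(study, rois, background_name)
  if (any(bg <= 0)) stop("pharynx_background_ratio: background mean must be > 0")
  r <- ph / bg
  list(per_frame = r, summary = max(r))
}

#' @export
print.curve_grade <- function(x, ...) {
  cat(sprintf("Curve grade %d (%s): slope %.4g +/- %.4g counts/px/s per min (z = %.2f)\n",
              x$grade, x$label, x$slope, x$slope_se, x$z))
  invisible(x)
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("Time-activity curve: %s (%s), %d frames, %.3g to %.3g counts/px/s\n",
              x$roi_name, x$posture, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.tac <- function(x, ...) {
  graphics::plot(x$times / 60, x$values, type = "b", pch = 16,
                 xlab = "time (min)", ylab = "counts / pixel / s",
                 main = sprintf("%s (%s)", x$roi_name, x$posture), ...)
  graphics::abline(stats::lm(x$values ~ I(x$times / 60)), col = "red", lty = 2)
  invisible(x)
}
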