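new_dynamic_study <- function(frames, frame_times, posture, protocol) {
  structure(list(posture = posture, frames = frames,
                 frame_times = frame_times, protocol = protocol),
            class = "dynamic_study")
}

#' Render gamma-camera images from a simulated kinetics series
#'
#' Paints each compartment's activity into its fixed schematic zone
#' (\code{\link{zone_layout}}), adds a uniform body background, scales by
#' frame duration and camera sensitivity, and Poisson-samples realized
#' counts. Lung zones receive counts only from the lungs compartment. The
#' delayed static image is rendered at the fine matrix from the activities
#' at the delayed time point.
#'
#' @param series a \code{kinetics_series} from \code{\link{simulate_kinetics}}
#' @param protocol the \code{\link{acquisition_protocol}} used for the series
#' @param params rendering calibration from \code{\link{render_params}}
#' @param seed integer seed for the Poisson noise
#' @return a list with elements \code{upright} and \code{supine}
#'   (\code{dynamic_study} objects: posture, list of integer count matrices,
#'   frame start times in seconds since segment start, protocol) and
#'   \code{delayed} (a \code{delayed_image}: integer count matrix plus
#'   acquisition time in minutes since colloid administration)
#' @export
render_frames <- function(series, protocol = acquisition_protocol(),
                          params = render_params(), seed = 1L) {
  stopifnot(inherits(series, "kinetics_series"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  up <- series[series$phase == "upright", , drop = FALSE]
  sup <- series[series$phase == "supine", , drop = FALSE]
  del <- series[series$phase == "delayed", , drop = FALSE]
  if (nrow(up) != protocol$upright_n_frames || nrow(sup) != protocol$supine_n_frames ||
      nrow(del) != 1L)
    stop("render_frames: series does not cover the protocol frame times")

  render_segment <- function(seg, frame_s, n) {
    lapply(seq_len(nrow(seg)), function(i) {
      expected <- expected_frame(as.list(seg[i, COMPARTMENTS]), frame_s, n, params)
      matrix(stats::rpois(length(expected), expected), nrow = n)
    })
  }
  nd <- protocol$dynamic_matrix
  upright <- new_dynamic_study(
    render_segment(up, protocol$upright_frame_seconds, nd),
    frame_times = (seq_len(nrow(up)) - 1) * protocol$upright_frame_seconds,
    posture = "upright", protocol = protocol)
  supine <- new_dynamic_study(
    render_segment(sup, protocol$supine_frame_seconds, nd),
    frame_times = (seq_len(nrow(sup)) - 1) * protocol$supine_frame_seconds,
    posture = "supine", protocol = protocol)

  nD <- protocol$delayed_matrix
  exp_del <- expected_frame(as.list(del[1, COMPARTMENTS]),
                            protocol$delayed_duration_seconds, nD, params)
  delayed <- structure(
    list(pixels = matrix(stats::rpois(length(exp_del), exp_del), nrow = nD),
         acquisition_time_minutes = protocol$delayed_time_minutes,
         protocol = protocol),
    class = "delayed_image")
  list(upright = upright, supine = supine, delayed = delayed)
}

#' Expected (noise-free) count image for one frame
#'
#' @param activity named list/vector of compartment activities in MBq
#'   (pharynx, upper, mid, lower, stomach, lungs)
#' @param frame_seconds frame duration in seconds
#' @param matrix_size square image size in pixels
#' @param params rendering calibration from \code{\link{render_params}}
#' @return numeric matrix of expected counts per pixel
#' @export
expected_frame <- function(activity, frame_seconds, matrix_size,
                           params = render_params()) {
  zl <- zone_layout(matrix_size)
  # background rate is calibrated per pixel at the 64x64 matrix; scale by
  # pixel area so total body background is matrix-independent
  bg <- params$background_rate * (64 / matrix_size)^2 * frame_seconds
  img <- matrix(bg, matrix_size, matrix_size)
  paint <- function(zone, act_mbq, npix) {
    if (act_mbq <= 0) return()
    rate <- act_mbq * params$sensitivity * frame_seconds / npix
    img[(zone$row0:zone$row1) + 1L, (zone$col0:zone$col1) + 1L] <<-
      img[(zone$row0:zone$row1) + 1L, (zone$col0:zone$col1) + 1L] + rate
  }
  for (comp in c("pharynx", "upper", "mid", "lower", "stomach")) {
    paint(zl[[comp]], as.numeric(activity[[comp]]), zone_npix(zl[[comp]]))
  }
  nl <- zone_npix(zl$lungs_left) + zone_npix(zl$lungs_right)
  paint(zl$lungs_left, as.numeric(activity[["lungs"]]), nl)
  paint(zl$lungs_right, as.numeric(activity[["lungs"]]), nl)
  img
}

#' @export
print.dynamic_study <- function(x, ...) {
  cat(sprintf("Dynamic study (%s): %d frames of %gs, %dx%d, total counts %d\n",
              x$posture, length(x$frames),
              if (x$posture == "upright") x$protocol$upright_frame_seconds
              else x$protocol$supine_frame_seconds,
              nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              sum(vapply(x$frames, sum, numeric(1)))))
  invisible(x)
}

#' @export
print.delayed_image <- function(x, ...) {
  cat(sprintf("Delayed image: %dx%d at %g min, total counts %d\n",
              nrow(x$pixels), ncol(x$pixels), x$acquisition_time_minutes,
              sum(x$pixels)))
  invisible(x)
}
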