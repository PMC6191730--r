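#' Physical half-life of Tc-99m in hours
#'
#' Standard physical constant used for decay correction throughout the
#' package (6.0067 h).
#' @export
TC99M_HALF_LIFE_HOURS <- 6.0067

#' Gamma-camera acquisition protocol
#'
#' Describes the two-phase dynamic acquisition (upright then supine) and the
#' delayed static image used for lung-aspiration assessment. Defaults follow
#' the standard clinical protocol: 8 upright frames of 15 s into a 64x64
#' matrix, 60 supine frames of 30 s, and a 256x256 delayed static image two
#' hours after oral administration of the colloid tracer.
#'
#' @param upright_frame_seconds upright frame duration (s)
#' @param upright_duration_seconds total upright acquisition (s)
#' @param supine_frame_seconds supine frame duration (s)
#' @param supine_duration_seconds total supine acquisition (s)
#' @param dynamic_matrix square dynamic matrix size (pixels)
#' @param delayed_matrix square delayed matrix size (pixels)
#' @param delayed_time_minutes minutes from colloid administration to the
#'   delayed image
#' @param delayed_duration_seconds delayed static acquisition time (s)
#' @param isotope_half_life_hours physical half-life used for decay
#'   correction
#' @return an object of class \code{acquisition_protocol}
#' @export
acquisition_protocol <- function(upright_frame_seconds = 15,
                                 upright_duration_seconds = 120,
                                 supine_frame_seconds = 30,
                                 supine_duration_seconds = 1800,
                                 dynamic_matrix = 64L,
                                 delayed_matrix = 256L,
                                 delayed_time_minutes = 120,
                                 delayed_duration_seconds = 600,
                                 isotope_half_life_hours = TC99M_HALF_LIFE_HOURS) {
  p <- list(
    upright_frame_seconds = upright_frame_seconds,
    upright_duration_seconds = upright_duration_seconds,
    supine_frame_seconds = supine_frame_seconds,
    supine_duration_seconds = supine_duration_seconds,
    dynamic_matrix = as.integer(dynamic_matrix),
    delayed_matrix = as.integer(delayed_matrix),
    delayed_time_minutes = delayed_time_minutes,
    delayed_duration_seconds = delayed_duration_seconds,
    isotope_half_life_hours = isotope_half_life_hours
  )
  p$upright_n_frames <- as.integer(round(upright_duration_seconds / upright_frame_seconds))
  p$supine_n_frames <- as.integer(round(supine_duration_seconds / supine_frame_seconds))
  stopifnot(p$upright_n_frames * upright_frame_seconds == upright_duration_seconds,
            p$supine_n_frames * supine_frame_seconds == supine_duration_seconds)
  class(p) <- "acquisition_protocol"
  p
}

# Compartments, ordered from the stomach upwards along the reflux path.
COMPARTMENTS <- c("pharynx", "upper", "mid", "lower", "stomach", "lungs")
REFLUX_HEIGHTS <- c("lower", "mid", "upper", "pharynx")

#' Schematic anatomical zone layout
#'
#' Fixed rectangular zones into which compartment activity is painted when
#' rendering frames, expressed at the 64x64 dynamic matrix and scaled
#' proportionally for other matrix sizes. Row-major, origin top-left,
#' 0-based indices, ranges inclusive. The layout is a reproducible schematic
#' anatomy (pharynx at the top, oesophageal thirds stacked above the
#' stomach in the lower left, two hilar airway zones flanking the
#' mediastinum), not a patient-realistic one, so region-of-interest
#' placement needs no registration.
#'
#' @param matrix_size square image matrix size in pixels
#' @return named list of zones; each zone is a list with 0-based inclusive
#'   pixel ranges \code{row0, row1, col0, col1}
#' @export
zone_layout <- function(matrix_size = 64L) {
  s <- matrix_size / 64
  z <- function(r0, r1, c0, c1) list(row0 = as.integer(floor(r0 * s)),
                                     row1 = as.integer(floor((r1 + 1) * s) - 1),
                                     col0 = as.integer(floor(c0 * s)),
                                     col1 = as.integer(floor((c1 + 1) * s) - 1))
  list(
    pharynx    = z(3, 8, 28, 35),
    upper      = z(12, 21, 30, 33),
    mid        = z(22, 31, 30, 33),
    lower      = z(32, 41, 30, 33),
    stomach    = z(44, 58, 8, 28),
    # lungs compartment concentrates in the main airways / hilar regions
    lungs_left  = z(16, 21, 20, 25),
    lungs_right = z(16, 21, 38, 43),
    background = z(18, 36, 2, 6)
  )
}

#' Default rendering parameters
#'
#' Counting calibration for the schematic gamma camera. \code{sensitivity}
#' is whole-zone counts per MBq per second (a typical planar low-energy
#' high-resolution collimator figure); \code{background_rate} is the uniform
#' body-background count rate per pixel per second at the 64x64 matrix and is
#' scaled by pixel area for other matrix sizes (the same soft-tissue activity
#' is spread over more pixels at finer sampling).
#'
#' @param sensitivity counts per MBq per second delivered to a zone
#' @param background_rate counts per pixel per second at 64x64
#' @return named list
#' @export
render_params <- function(sensitivity = 100, background_rate = 0.3) {
  list(sensitivity = sensitivity, background_rate = background_rate)
}

# pixel-index helper: matrix of (row, col) 0-based coordinates of a zone
zone_pixels <- function(zone) {
  rows <- zone$row0:zone$row1
  cols <- zone$col0:zone$col1
  cbind(row = rep(rows, times = length(cols)),
        col = rep(cols, each = length(rows)))
}

zone_npix <- function(zone) {
  (zone$row1 - zone$row0 + 1L) * (zone$col1 - zone$col0 + 1L)
}

# logical mask of a zone inside an n x n image (R matrix, 1-based)
zone_mask <- function(zone, n) {
  m <- matrix(FALSE, n, n)
  m[(zone$row0:zone$row1) + 1L, (zone$col0:zone$col1) + 1L] <- TRUE
  m
}

decay_lambda_per_min <- function(protocol) {
  log(2) / (protocol$isotope_half_life_hours * 60)
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat("Acquisition protocol\n")
  cat(sprintf("  upright: %d frames x %gs (%dx%d)\n", x$upright_n_frames,
              x$upright_frame_seconds, x$dynamic_matrix, x$dynamic_matrix))
  cat(sprintf("  supine:  %d frames x %gs (%dx%d)\n", x$supine_n_frames,
              x$supine_frame_seconds, x$dynamic_matrix, x$dynamic_matrix))
  cat(sprintf("  delayed: %dx%d at %g min, %gs static\n", x$delayed_matrix,
              x$delayed_matrix, x$delayed_time_minutes, x$delayed_duration_seconds))
  invisible(x)
}
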