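#' Line profile through the hilar regions of a delayed image
#'
#' Samples counts along a full transverse image row (optionally averaged
#' over a 3-row band) together with the mean counts per pixel of a
#' background reference region outside the lungs and mediastinum. If
#' \code{row} is \code{NULL}, the row maximizing the summed lung-zone counts
#' within the hilar band of the schematic layout is chosen, so the profile
#' passes through the densest airway activity.
#'
#' @param image a \code{delayed_image}
#' @param row 0-based row index, or \code{NULL} to auto-select
#' @param background_region rectangle or (row, col) pixel matrix for the
#'   background reference; defaults to the lateral-chest zone of the
#'   schematic layout scaled to the image matrix
#' @param band_rows number of rows averaged (1 or 3)
#' @return object of class \code{line_profile} with fields \code{row},
#'   \code{values} (counts per pixel along the row), \code{background_level}
#'   and the lung-zone column ranges used by
#'   \code{\link{detect_aspiration}}
#' @export
line_profile <- function(image, row = NULL, background_region = NULL,
                         band_rows = 3L) {
  px <- image$pixels
  n <- nrow(px)
  zl <- zone_layout(n)
  if (is.null(background_region)) background_region <- zl$background
  bg_px <- if (is.matrix(background_region)) background_region else zone_pixels(background_region)
  if (nrow(bg_px) == 0) stop("line_profile: empty background region")
  bg_level <- mean(px[bg_px[, 2] * n + bg_px[, 1] + 1L])

  lung_rows <- zl$lungs_left$row0:zl$lungs_left$row1
  if (is.null(row)) {
    lung_cols <- c((zl$lungs_left$col0:zl$lungs_left$col1) + 1L,
                   (zl$lungs_right$col0:zl$lungs_right$col1) + 1L)
    sums <- rowSums(px[lung_rows + 1L, lung_cols, drop = FALSE])
    row <- lung_rows[which.max(sums)]
  }
  if (row < 0 || row >= n) stop("line_profile: row outside the image")
  rows <- if (band_rows > 1) {
    half <- (band_rows - 1L) %/% 2L
    pmin(pmax((row - half):(row + half), 0L), n - 1L)
  } else row
  values <- colMeans(px[rows + 1L, , drop = FALSE])
  structure(list(row = as.integer(row), values = values,
                 background_level = bg_level,
                 lung_zones = list(left = c(zl$lungs_left$col0, zl$lungs_left$col1),
                                   right = c(zl$lungs_right$col0, zl$lungs_right$col1))),
            class = "line_profile")
}

#' Detect pulmonary aspiration from a hilar line profile
#'
#' A study is called positive for aspiration when the peak count density in
#' either lung zone of the profile exceeds \code{threshold} times the
#' background level (strict inequality).
#'
#' @param profile a \code{\link{line_profile}}
#' @param threshold multiple of background required for a positive call
#'   (default 2.0)
#' @return object of class \code{aspiration_call} with fields
#'   \code{positive}, \code{max_ratio} and \code{side} (\code{"left"},
#'   \code{"right"}, \code{"both"} or \code{"none"})
#' @export
detect_aspiration <- function(profile, threshold = 2.0) {
  if (!is.finite(profile$background_level) || profile$background_level <= 0)
    stop("detect_aspiration: background level must be > 0")
  zone_ratio <- function(z) {
    cols <- (z[1]:z[2]) + 1L
    max(profile$values[cols]) / profile$background_level
  }
  rl <- zone_ratio(profile$lung_zones$left)
  rr <- zone_ratio(profile$lung_zones$right)
  max_ratio <- max(rl, rr)
  pos_l <- rl > threshold
  pos_r <- rr > threshold
  side <- if (pos_l && pos_r) "both" else if (pos_l) "left" else if (pos_r) "right" else "none"
  structure(list(positive = pos_l || pos_r, max_ratio = max_ratio,
                 side = side, threshold = threshold, row = profile$row),
            class = "aspiration_call")
}

#' @export
print.aspiration_call <- function(x, ...) {
  cat(sprintf("Aspiration: %s (peak/background %.2f, threshold %g, side %s, row %d)\n",
              if (x$positive) "POSITIVE" else "negative", x$max_ratio,
              x$threshold, x$side, x$row))
  invisible(x)
}

#' @export
plot.line_profile <- function(x, ...) {
  graphics::plot(seq_along(x$values) - 1L, x$values, type = "l",
                 xlab = "column (pixels)", ylab = "counts / pixel",
                 main = sprintf("Line profile, row %d", x$row), ...)
  graphics::abline(h = x$background_level, lty = 2)
  graphics::abline(h = 2 * x$background_level, lty = 3, col = "red")
  invisible(x)
}
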