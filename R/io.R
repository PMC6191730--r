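# Study bundle fixture format: a directory holding study.json (metadata)
# plus one plain-text counts file per segment. Each frame is one line of
# space-separated non-negative integers in row-major order (origin
# top-left). Integer counts round-trip bit-exactly through text.

flatten_rowmajor <- function(m) as.integer(t(m))
unflatten_rowmajor <- function(v, n) matrix(as.integer(v), nrow = n, byrow = TRUE)

write_frames_txt <- function(frames, path) {
  lines <- vapply(frames, function(f) paste(flatten_rowmajor(f), collapse = " "),
                  character(1))
  writeLines(lines, path)
}

read_frames_txt <- function(path, n, n_frames) {
  lines <- readLines(path)
  if (length(lines) != n_frames)
    stop(sprintf("parse error in %s: expected %d frames, found %d",
                 path, n_frames, length(lines)))
  lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.integer(strsplit(lines[[i]], " ", fixed = TRUE)[[1]]))
    if (length(v) != n * n || anyNA(v))
      stop(sprintf("parse error in %s: frame %d malformed (expected %d integer pixels)",
                   path, i, n * n))
    unflatten_rowmajor(v, n)
  })
}

#' Write a study bundle to disk
#'
#' Writes one patient's upright and supine dynamic studies and the delayed
#' image to a directory in the plain-text fixture format (JSON metadata +
#' one counts file per segment). The round trip through
#' \code{\link{read_study}} is bit-exact.
#'
#' @param bundle list with \code{patient_id}, \code{upright}, \code{supine}
#'   (\code{dynamic_study}), \code{delayed} (\code{delayed_image}) and an
#'   optional \code{provenance} list (seed, configuration, timestamps)
#' @param path directory to create/write into
#' @return \code{path}, invisibly
#' @export
write_study <- function(bundle, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  pr <- bundle$upright$protocol
  meta <- list(
    patient_id = bundle$patient_id,
    protocol = unclass(pr),
    frame_times = list(upright = bundle$upright$frame_times,
                       supine = bundle$supine$frame_times),
    delayed_acquisition_time_minutes = bundle$delayed$acquisition_time_minutes,
    provenance = bundle$provenance)
  jsonlite::write_json(meta, file.path(path, "study.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_frames_txt(bundle$upright$frames, file.path(path, "upright.txt"))
  write_frames_txt(bundle$supine$frames, file.path(path, "supine.txt"))
  write_frames_txt(list(bundle$delayed$pixels), file.path(path, "delayed.txt"))
  invisible(path)
}

#' Read a study bundle from disk
#'
#' @param path directory written by \code{\link{write_study}}
#' @return a study bundle list (see \code{\link{write_study}})
#' @export
read_study <- function(path) {
  meta_path <- file.path(path, "study.json")
  if (!file.exists(meta_path)) stop("read_study: no study.json under ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pr <- do.call(acquisition_protocol,
                meta$protocol[setdiff(names(meta$protocol),
                                      c("upright_n_frames", "supine_n_frames"))])
  nd <- pr$dynamic_matrix
  upright <- new_dynamic_study(
    read_frames_txt(file.path(path, "upright.txt"), nd, pr$upright_n_frames),
    frame_times = meta$frame_times$upright, posture = "upright", protocol = pr)
  supine <- new_dynamic_study(
    read_frames_txt(file.path(path, "supine.txt"), nd, pr$supine_n_frames),
    frame_times = meta$frame_times$supine, posture = "supine", protocol = pr)
  delayed <- structure(
    list(pixels = read_frames_txt(file.path(path, "delayed.txt"),
                                  pr$delayed_matrix, 1L)[[1]],
         acquisition_time_minutes = meta$delayed_acquisition_time_minutes,
         protocol = pr),
    class = "delayed_image")
  list(patient_id = meta$patient_id, upright = upright, supine = supine,
       delayed = delayed, provenance = meta$provenance)
}

#' Write an ROI set to JSON
#' @param rois an \code{\link{roi_set}}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
write_rois <- function(rois, path) {
  out <- list(matrix_size = rois$matrix_size,
              regions = lapply(rois$pixels, function(p)
                list(row = p[, 1], col = p[, 2])))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ROI set from JSON
#' @param path file written by \code{\link{write_rois}}
#' @return an \code{\link{roi_set}}
#' @export
read_rois <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  regions <- lapply(x$regions, function(r) cbind(row = r$row, col = r$col))
  roi_set(regions, matrix_size = x$matrix_size)
}

#' Write per-patient TACs as CSV
#'
#' Long format with columns \code{patient_id, roi, posture, t_seconds,
#' value}.
#'
#' @param tacs named list (per patient) of lists of \code{tac} objects
#' @param path output CSV
#' @return \code{path}, invisibly
#' @export
write_tacs_csv <- function(tacs, path) {
  rows <- list()
  for (pid in names(tacs)) {
    for (tc in tacs[[pid]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, roi = tc$roi_name, posture = tc$posture,
        t_seconds = tc$times, value = tc$values, stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
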