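# Trajectory file I/O ---------------------------------------------------------
#
# Plain tab-separated text with unit-suffixed headers: time_s, angle_deg
# and optionally x_cm, y_cm. Metadata travels in a JSON side-car file
# `<path>.meta.json`.

#' Write an angular trajectory to delimited text
#'
#' @param traj an [angular_trajectory()].
#' @param path output file path; metadata (if any) is written to
#'   `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "angular_trajectory"))
  d <- data.frame(time_s = traj$time_s, angle_deg = traj$angle_deg)
  if (!is.null(traj$x_cm)) {
    d$x_cm <- traj$x_cm
    d$y_cm <- traj$y_cm
  }
  utils::write.table(format(d, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (length(traj$meta) > 0) {
    jsonlite::write_json(traj$meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read an angular trajectory from delimited text
#'
#' Expects a header with at least `time_s` and `angle_deg` (plus optional
#' `x_cm`/`y_cm`). Non-monotone time stamps or missing angles are
#' rejected with the offending data row number.
#'
#' @param path file written by [write_trajectory()] or an equivalent
#'   export.
#' @return An [angular_trajectory()]; metadata is restored from the
#'   side-car file when present.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  need <- c("time_s", "angle_deg")
  if (!all(need %in% names(d))) {
    stop("malformed trajectory file: header must contain ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  bad_angle <- which(!is.finite(d$angle_deg))
  if (length(bad_angle) > 0) {
    stop("non-finite angle_deg at data row ", bad_angle[1], call. = FALSE)
  }
  bad_time <- which(diff(d$time_s) <= 0)
  if (length(bad_time) > 0) {
    stop("non-increasing time_s at data row ", bad_time[1] + 1,
         call. = FALSE)
  }
  meta <- list()
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  }
  has_xy <- all(c("x_cm", "y_cm") %in% names(d))
  angular_trajectory(d$time_s, d$angle_deg,
                     x_cm = if (has_xy) d$x_cm else NULL,
                     y_cm = if (has_xy) d$y_cm else NULL,
                     meta = meta)
}
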