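# Angular trajectories and per-episode rotometry features --------------------

#' Construct an angular trajectory
#'
#' Sampled cumulative angular position, signed contralateral-positive
#' (anti-clockwise for a right-hemisphere lesion), with optional 2-D
#' position in cm.
#'
#' @param time_s strictly increasing sample times, s.
#' @param angle_deg cumulative angular position, deg.
#' @param x_cm,y_cm optional position, cm (both or neither).
#' @param meta named list of free-form metadata (animal id, seed, ...).
#' @return An object of class `angular_trajectory`.
#' @export
angular_trajectory <- function(time_s, angle_deg, x_cm = NULL, y_cm = NULL,
                               meta = list()) {
  stopifnot(is.numeric(time_s), is.numeric(angle_deg),
            length(time_s) == length(angle_deg), length(time_s) >= 2)
  if (anyNA(time_s) || anyNA(angle_deg)) {
    stop("time/angle must not contain missing values", call. = FALSE)
  }
  if (is.unsorted(time_s, strictly = TRUE)) {
    stop("time_s must be strictly increasing", call. = FALSE)
  }
  if (xor(is.null(x_cm), is.null(y_cm))) {
    stop("provide both x_cm and y_cm, or neither", call. = FALSE)
  }
  if (!is.null(x_cm)) {
    stopifnot(length(x_cm) == length(time_s), length(y_cm) == length(time_s))
  }
  structure(list(time_s = as.numeric(time_s),
                 angle_deg = as.numeric(angle_deg),
                 x_cm = if (is.null(x_cm)) NULL else as.numeric(x_cm),
                 y_cm = if (is.null(y_cm)) NULL else as.numeric(y_cm),
                 meta = meta),
            class = "angular_trajectory")
}

#' @export
print.angular_trajectory <- function(x, ...) {
  cat(sprintf(
    "<angular_trajectory> %d samples over %.1f s, net %.2f rotations%s\n",
    length(x$time_s), diff(range(x$time_s)),
    (x$angle_deg[length(x$angle_deg)] - x$angle_deg[1]) / 360,
    if (is.null(x$x_cm)) "" else " (+position)"))
  invisible(x)
}

.trapz <- function(t, v) sum(diff(t) * (utils::head(v, -1) + v[-1]) / 2)

#' Rotometry features of one DBS-on window
#'
#' The angle is re-zeroed at the first sample inside the half-open window
#' `[start_s, end_s)`; rotation counts are the re-zeroed angle / 360.
#' Features: `max_rotation` (window maximum), `net_rotation` (value at
#' the last sample), `auc_rot_s` (trapezoidal integral of the rotation
#' count over the window, rotation * s) and `distance_cm` (path length of
#' the position track; `NA` when the trajectory has no position data).
#'
#' @param traj an [angular_trajectory()].
#' @param start_s,end_s window bounds, s.
#' @param label condition label carried into the output row.
#' @return One-row data frame.
#' @export
episode_features <- function(traj, start_s, end_s, label = NA_character_) {
  stopifnot(inherits(traj, "angular_trajectory"), end_s > start_s)
  idx <- which(traj$time_s >= start_s - 1e-9 & traj$time_s < end_s - 1e-9)
  if (length(idx) < 2) {
    stop("window [", start_s, ", ", end_s, ") contains fewer than 2 samples",
         call. = FALSE)
  }
  rot <- (traj$angle_deg[idx] - traj$angle_deg[idx[1]]) / 360
  tt <- traj$time_s[idx]
  dist <- NA_real_
  if (!is.null(traj$x_cm)) {
    dist <- sum(sqrt(diff(traj$x_cm[idx])^2 + diff(traj$y_cm[idx])^2))
  }
  data.frame(label = label,
             max_rotation = max(rot),
             net_rotation = rot[length(rot)],
             auc_rot_s = .trapz(tt, rot),
             distance_cm = dist)
}

#' Feature table of a whole session
#'
#' Applies [episode_features()] to every DBS-on window of the protocol,
#' in episode order, and joins each episode's injected charge rate.
#'
#' @param traj an [angular_trajectory()] covering the protocol.
#' @param protocol a `session_protocol`.
#' @return Data frame with one row per ON episode: `label`,
#'   `max_rotation`, `net_rotation`, `auc_rot_s`, `distance_cm`,
#'   `charge_rate_ucs`.
#' @export
session_features <- function(traj, protocol) {
  stopifnot(inherits(traj, "angular_trajectory"),
            inherits(protocol, "session_protocol"))
  wins <- episode_windows(protocol)
  t_max <- max(traj$time_s)
  missing <- wins$label[wins$start_s + 1e-6 >= t_max]
  if (length(missing) > 0) {
    stop("trajectory (", round(t_max, 3), " s) does not cover episodes: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(wins)), function(i) {
    f <- episode_features(traj, wins$start_s[i], wins$end_s[i],
                          wins$label[i])
    f$charge_rate_ucs <- charge_rate(window_train(wins[i, ]))
    f
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply the apomorphine lesion criterion
#'
#' An animal counts as well-lesioned when it averages at least
#' `threshold_rpm` net contralateral (anti-clockwise, positive-signed)
#' rotations per minute over the first `duration_min` minutes of the
#' post-injection trace.
#'
#' @param traj an [angular_trajectory()] of at least `duration_min`
#'   minutes.
#' @param duration_min assessment window, minutes.
#' @param threshold_rpm criterion, rotations per minute.
#' @return TRUE / FALSE.
#' @export
assess_lesion <- function(traj, duration_min = 30, threshold_rpm = 3) {
  stopifnot(inherits(traj, "angular_trajectory"))
  t_end <- traj$time_s[1] + duration_min * 60
  if (max(traj$time_s) < t_end - 1e-9) {
    stop("trajectory shorter than the ", duration_min,
         "-minute assessment window", call. = FALSE)
  }
  idx <- which(traj$time_s <= t_end + 1e-9)
  net_rot <- (traj$angle_deg[idx[length(idx)]] - traj$angle_deg[idx[1]]) / 360
  net_rot / duration_min >= threshold_rpm
}
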