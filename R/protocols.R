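# Session protocols ----------------------------------------------------------
#
# A session is an ordered, non-overlapping timeline of DBS-on episodes and
# off-periods. Episodes are stored as one data frame row each; OFF rows
# carry NA train parameters. Time origin t = 0 is the onset of the first
# ON episode and sessions end at the offset of the last ON episode.

.EPISODE_COLS <- c("label", "start_s", "duration_s", "on", "shape",
                   "amplitude_ua", "pulse_width_us", "interphase_us",
                   "frequency_hz")

.new_session_protocol <- function(episodes, paradigm, I0_ua = NA_real_,
                                  Q0_uc = NA_real_) {
  stopifnot(is.data.frame(episodes), all(.EPISODE_COLS %in% names(episodes)))
  episodes <- episodes[.EPISODE_COLS]
  rownames(episodes) <- NULL
  if (any(episodes$duration_s <= 0)) stop("episode durations must be > 0")
  ends <- episodes$start_s + episodes$duration_s
  if (is.unsorted(episodes$start_s, strictly = TRUE) ||
      any(utils::head(ends, -1) > episodes$start_s[-1] + 1e-9)) {
    stop("episodes must be ordered and non-overlapping")
  }
  structure(list(episodes = episodes, paradigm = paradigm,
                 I0_ua = I0_ua, Q0_uc = Q0_uc),
            class = "session_protocol")
}

#' @export
print.session_protocol <- function(x, ...) {
  on <- sum(x$episodes$on)
  cat(sprintf(
    "<session_protocol> paradigm '%s': %d ON episodes, %.0f s total (I0 = %s uA, Q0 = %s uC)\n",
    x$paradigm, on,
    max(x$episodes$start_s + x$episodes$duration_s),
    format(x$I0_ua), format(x$Q0_uc)))
  invisible(x)
}

# Interleave ON specs with OFF gaps on a running clock.
.assemble_timeline <- function(on_rows, off_s, extra_gap_after = numeric(0)) {
  t <- 0
  out <- vector("list", 2L * nrow(on_rows))
  for (i in seq_len(nrow(on_rows))) {
    row <- on_rows[i, , drop = FALSE]
    row$start_s <- t
    row$on <- TRUE
    out[[2L * i - 1L]] <- row
    t <- t + row$duration_s
    if (i < nrow(on_rows)) {
      gap <- if (as.character(i) %in% names(extra_gap_after)) {
        extra_gap_after[[as.character(i)]]
      } else off_s
      out[[2L * i]] <- data.frame(
        label = sprintf("off_%d", i), start_s = t, duration_s = gap,
        on = FALSE, shape = NA_character_, amplitude_ua = NA_real_,
        pulse_width_us = NA_real_, interphase_us = NA_real_,
        frequency_hz = NA_real_)
      t <- t + gap
    }
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

.on_row <- function(label, duration_s, shape, amplitude_ua, pulse_width_us,
                    interphase_us, frequency_hz) {
  data.frame(label = label, start_s = NA_real_, duration_s = duration_s,
             on = TRUE, shape = shape, amplitude_ua = amplitude_ua,
             pulse_width_us = pulse_width_us, interphase_us = interphase_us,
             frequency_hz = frequency_hz)
}

#' Build the amplitude-sweep session protocol
#'
#' Five 30-s DBS-on episodes at amplitude multipliers 1, 1.25, 1.5, 1.75
#' and 2 times the individual threshold `I0`, separated by 45-s off
#' periods. The carrier is a rectangular biphasic train at 130 Hz, 65 us
#' pulse width, 100 us interphase interval.
#'
#' @param I0_ua individual threshold amplitude, uA (> 0).
#' @param on_s,off_s episode and pause durations, s.
#' @param frequency_hz,pulse_width_us,interphase_us carrier parameters.
#' @param randomize_order shuffle the condition order (off by default: the
#'   reference experiments ran a fixed ascending order).
#' @return A `session_protocol`.
#' @export
build_amplitude_protocol <- function(I0_ua, on_s = 30, off_s = 45,
                                     frequency_hz = 130, pulse_width_us = 65,
                                     interphase_us = 100,
                                     randomize_order = FALSE) {
  stopifnot(I0_ua > 0, on_s > 0, off_s > 0)
  mult <- c(1, 1.25, 1.5, 1.75, 2)
  if (randomize_order) mult <- sample(mult)
  on_rows <- do.call(rbind, lapply(mult, function(m) {
    .on_row(sprintf("%gxI0", m), on_s, "RECT", m * I0_ua,
            pulse_width_us, interphase_us, frequency_hz)
  }))
  .new_session_protocol(.assemble_timeline(on_rows, off_s),
                        paradigm = "amplitude", I0_ua = I0_ua,
                        Q0_uc = charge_per_phase("RECT", I0_ua, pulse_width_us))
}

#' Build the frequency-sweep session protocol
#'
#' Seven 30-s DBS-on episodes at 15, 50, 100, 130, 180, 250 and 350 Hz
#' with 45-s pauses. The amplitude is fixed at the threshold titrated at
#' the 15-Hz baseline and left unchanged, so the injected charge scales
#' with the frequency (truncated multipliers 1, 3.3, 6.6, 8.6, 12, 16.6,
#' 23.3 relative to 15 Hz).
#'
#' @param I0_at_15Hz_ua threshold amplitude titrated at 15 Hz, uA (> 0).
#' @param frequencies_hz episode frequencies, Hz.
#' @param on_s,off_s episode and pause durations, s.
#' @param pulse_width_us,interphase_us carrier parameters.
#' @param randomize_order shuffle the condition order (off by default).
#' @return A `session_protocol`.
#' @export
build_frequency_protocol <- function(I0_at_15Hz_ua,
                                     frequencies_hz = c(15, 50, 100, 130,
                                                        180, 250, 350),
                                     on_s = 30, off_s = 45,
                                     pulse_width_us = 65, interphase_us = 100,
                                     randomize_order = FALSE) {
  stopifnot(I0_at_15Hz_ua > 0, length(frequencies_hz) >= 1)
  f <- if (randomize_order) sample(frequencies_hz) else frequencies_hz
  on_rows <- do.call(rbind, lapply(f, function(fi) {
    .on_row(sprintf("%gHz", fi), on_s, "RECT", I0_at_15Hz_ua,
            pulse_width_us, interphase_us, fi)
  }))
  .new_session_protocol(
    .assemble_timeline(on_rows, off_s),
    paradigm = "frequency", I0_ua = I0_at_15Hz_ua,
    Q0_uc = charge_per_phase("RECT", I0_at_15Hz_ua, pulse_width_us))
}

#' Build the waveform/charge session protocol
#'
#' Five charge blocks (1, 1.25, 1.5, 1.75, 2 times `Q0`), each a
#' Rect-Sine-Tri-Lin.Dec sequence of 30-s episodes with 45-s off periods
#' inside the block and a 20-min recovery break between blocks. Within a
#' block every shape's amplitude is charge-matched via
#' [equivalent_amplitude()], so all four episodes inject the same charge
#' per phase. Carrier: 130 Hz, 100 us pulse width, 100 us interphase gap.
#'
#' @param Q0_uc threshold charge per phase for the rectangular reference,
#'   uC (> 0).
#' @param pulse_width_us per-phase pulse width, us.
#' @param on_s,off_s,block_break_s timing parameters, s.
#' @param frequency_hz,interphase_us carrier parameters.
#' @param randomize_order shuffle the shape order inside each block
#'   (off by default).
#' @return A `session_protocol` with 20 ON episodes labelled like
#'   `"1.5xQ0_Rect"`.
#' @export
build_waveform_protocol <- function(Q0_uc, pulse_width_us = 100, on_s = 30,
                                    off_s = 45, block_break_s = 1200,
                                    frequency_hz = 130, interphase_us = 100,
                                    randomize_order = FALSE) {
  stopifnot(Q0_uc > 0, pulse_width_us > 0)
  mult <- c(1, 1.25, 1.5, 1.75, 2)
  shapes <- PULSE_SHAPES
  on_rows <- do.call(rbind, lapply(mult, function(m) {
    sh <- if (randomize_order) sample(shapes) else shapes
    do.call(rbind, lapply(sh, function(s) {
      .on_row(sprintf("%gxQ0_%s", m, shape_display(s)), on_s, s,
              equivalent_amplitude(s, m * Q0_uc, pulse_width_us),
              pulse_width_us, interphase_us, frequency_hz)
    }))
  }))
  # long break after each block of 4 shapes (episodes 4, 8, 12, 16)
  extra <- stats::setNames(rep(block_break_s, 4), c("4", "8", "12", "16"))
  .new_session_protocol(
    .assemble_timeline(on_rows, off_s, extra_gap_after = extra),
    paradigm = "waveform", Q0_uc = Q0_uc)
}

#' DBS-on episode windows of a protocol
#'
#' @param protocol a `session_protocol`.
#' @return Data frame of the ON episodes in order, with half-open time
#'   windows `[start_s, end_s)` and the train parameters.
#' @export
episode_windows <- function(protocol) {
  stopifnot(inherits(protocol, "session_protocol"))
  e <- protocol$episodes[protocol$episodes$on, , drop = FALSE]
  data.frame(label = e$label, start_s = e$start_s,
             end_s = e$start_s + e$duration_s, shape = e$shape,
             amplitude_ua = e$amplitude_ua,
             pulse_width_us = e$pulse_width_us,
             interphase_us = e$interphase_us,
             frequency_hz = e$frequency_hz,
             row.names = NULL)
}

#' Train specification of one ON episode
#' @param window one row of [episode_windows()].
#' @return A [pulse_train()].
#' @export
window_train <- function(window) {
  pulse_train(window$shape, window$amplitude_ua, window$pulse_width_us,
              window$interphase_us, window$frequency_hz)
}

#' Write / read a session protocol as a JSON config
#'
#' The config is plain structured text with unit-suffixed keys; reading a
#' written config reproduces the protocol exactly.
#'
#' @param protocol a `session_protocol`.
#' @param path file path.
#' @return `write_protocol()` returns `path` invisibly; `read_protocol()`
#'   returns the `session_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "session_protocol"))
  jsonlite::write_json(
    list(paradigm = protocol$paradigm, I0_ua = protocol$I0_ua,
         Q0_uc = protocol$Q0_uc, episodes = protocol$episodes),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ep <- as.data.frame(x$episodes)
  ep$shape <- as.character(ep$shape)
  for (col in c("amplitude_ua", "pulse_width_us", "interphase_us",
                "frequency_hz")) {
    ep[[col]] <- as.numeric(ep[[col]])
  }
  .new_session_protocol(ep, x$paradigm,
                        I0_ua = if (is.null(x$I0_ua)) NA_real_ else x$I0_ua,
                        Q0_uc = if (is.null(x$Q0_uc)) NA_real_ else x$Q0_uc)
}
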