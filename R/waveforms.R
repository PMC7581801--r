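#' @keywords internal
"_PACKAGE"

# Pulse-shape calculus -------------------------------------------------------
#
# All amplitudes are peak currents in microamperes, all durations in
# microseconds unless a suffix says otherwise. Charges are surfaced in
# microcoulombs (1 uA * 1 us = 1 pC = 1e-6 uC); conversions live here and
# nowhere else.

.UA_US_TO_UC <- 1e-6 # pC -> uC

#' Supported pulse shapes
#'
#' Envelope conventions for one phase of a biphasic pulse, peak normalized
#' to 1:
#' \describe{
#'   \item{RECT}{constant 1 over the whole phase.}
#'   \item{SINE}{half-sine \eqn{\sin(\pi t / PW)}.}
#'   \item{TRI}{symmetric isosceles triangle peaking at \eqn{PW/2}.}
#'   \item{LIN_DEC}{sawtooth ramp starting at the peak and decaying
#'     linearly to 0 (linearly decaying ramp).}
#' }
#' @format Character vector of the four accepted tags.
#' @export
PULSE_SHAPES <- c("RECT", "SINE", "TRI", "LIN_DEC")

# Fraction of the bounding rectangle A*PW covered by each phase envelope.
.SHAPE_AREA_FACTOR <- c(RECT = 1, SINE = 2 / pi, TRI = 0.5, LIN_DEC = 0.5)

#' Validate and normalize a pulse-shape tag
#'
#' Accepts the canonical tags plus the display spellings used in reports
#' ("Rect", "Sine", "Tri", "Lin.Dec").
#'
#' @param tag character scalar.
#' @return One of `PULSE_SHAPES`.
#' @export
pulse_shape <- function(tag) {
  stopifnot(is.character(tag), length(tag) == 1L, !is.na(tag))
  norm <- toupper(gsub("[. ]", "_", trimws(tag)))
  norm <- sub("^LIN_?DEC_?$", "LIN_DEC", norm)
  if (!norm %in% PULSE_SHAPES) {
    stop("unknown pulse shape '", tag, "'; expected one of ",
         paste(PULSE_SHAPES, collapse = ", "), call. = FALSE)
  }
  norm
}

#' Display name of a pulse shape (as used in condition labels)
#' @param shape a tag accepted by [pulse_shape()].
#' @return character scalar, e.g. `"Lin.Dec"`.
#' @export
shape_display <- function(shape) {
  c(RECT = "Rect", SINE = "Sine", TRI = "Tri", LIN_DEC = "Lin.Dec")[[
    pulse_shape(shape)]]
}

#' Specify one biphasic pulse train
#'
#' One stimulation condition: shape, peak amplitude of the first phase,
#' per-phase pulse width, zero-current interphase interval and repetition
#' frequency. The pulse (two phases plus gap) must fit within one period.
#'
#' @param shape pulse shape tag, see [pulse_shape()].
#' @param amplitude_ua peak current of the first phase, uA (> 0).
#' @param pulse_width_us duration of each phase, us (> 0).
#' @param interphase_us zero-current gap between the two phases, us (>= 0).
#' @param frequency_hz pulse repetition rate, Hz (> 0).
#' @param polarity `"cathodic_first"` (default) or `"anodic_first"`.
#' @return An object of class `pulse_train`.
#' @examples
#' pulse_train("RECT", amplitude_ua = 100, pulse_width_us = 65,
#'             interphase_us = 100, frequency_hz = 130)
#' @export
pulse_train <- function(shape, amplitude_ua, pulse_width_us,
                        interphase_us = 0, frequency_hz = 130,
                        polarity = c("cathodic_first", "anodic_first")) {
  shape <- pulse_shape(shape)
  polarity <- match.arg(polarity)
  stopifnot(is.numeric(amplitude_ua), is.numeric(pulse_width_us),
            is.numeric(interphase_us), is.numeric(frequency_hz))
  if (amplitude_ua <= 0) stop("amplitude_ua must be > 0", call. = FALSE)
  if (pulse_width_us <= 0) stop("pulse_width_us must be > 0", call. = FALSE)
  if (interphase_us < 0) stop("interphase_us must be >= 0", call. = FALSE)
  if (frequency_hz <= 0) stop("frequency_hz must be > 0", call. = FALSE)
  period_us <- 1e6 / frequency_hz
  if (period_us < 2 * pulse_width_us + interphase_us) {
    stop("pulse (2*PW + interphase) does not fit in the period 1/f",
         call. = FALSE)
  }
  structure(
    list(shape = shape, amplitude_ua = amplitude_ua,
         pulse_width_us = pulse_width_us, interphase_us = interphase_us,
         frequency_hz = frequency_hz, polarity = polarity),
    class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf(
    "<pulse_train> %s %g uA, PW %g us, gap %g us, %g Hz (%s)\n",
    shape_display(x$shape), x$amplitude_ua, x$pulse_width_us,
    x$interphase_us, x$frequency_hz, x$polarity))
  invisible(x)
}

#' Electrode specification
#'
#' Only the electrode-tissue impedance matters for the energy estimate.
#' Usable chronic platinum/iridium microwire assemblies sit below ~5 kOhm
#' in saline; values far above that are accepted but worth questioning.
#'
#' @param impedance_ohm electrode-tissue impedance, Ohm (> 0).
#' @return An object of class `electrode_spec`.
#' @export
electrode_spec <- function(impedance_ohm) {
  stopifnot(is.numeric(impedance_ohm), length(impedance_ohm) == 1L)
  if (!is.finite(impedance_ohm) || impedance_ohm <= 0) {
    stop("impedance_ohm must be a positive finite number", call. = FALSE)
  }
  structure(list(impedance_ohm = impedance_ohm), class = "electrode_spec")
}

#' Charge delivered in one phase of a biphasic pulse
#'
#' Integral of |i(t)| over a single phase whose peak equals `amplitude_ua`:
#' the bounding-rectangle charge `A * PW` scaled by the envelope's area
#' fraction (RECT 1, SINE 2/pi, TRI 1/2, LIN_DEC 1/2).
#'
#' @param shape pulse shape tag.
#' @param amplitude_ua peak current, uA (> 0).
#' @param pulse_width_us phase duration, us (> 0).
#' @return Charge per phase in uC.
#' @examples
#' charge_per_phase("RECT", 100, 65) # 0.0065 uC = 6500 pC
#' @export
charge_per_phase <- function(shape, amplitude_ua, pulse_width_us) {
  shape <- pulse_shape(shape)
  if (any(amplitude_ua <= 0)) stop("amplitude_ua must be > 0", call. = FALSE)
  if (any(pulse_width_us <= 0)) stop("pulse_width_us must be > 0", call. = FALSE)
  .SHAPE_AREA_FACTOR[[shape]] * amplitude_ua * pulse_width_us * .UA_US_TO_UC
}

#' Peak amplitude needed for a target charge per phase
#'
#' Exact inverse of [charge_per_phase()] in the amplitude argument; used to
#' charge-match alternative waveforms against a rectangular reference
#' (e.g. a sine phase needs pi/2 times the rectangular amplitude for the
#' same charge at equal pulse width).
#'
#' @param shape pulse shape tag.
#' @param target_charge_uc charge per phase, uC (> 0).
#' @param pulse_width_us phase duration, us (> 0).
#' @return Peak amplitude in uA.
#' @export
equivalent_amplitude <- function(shape, target_charge_uc, pulse_width_us) {
  shape <- pulse_shape(shape)
  if (any(target_charge_uc <= 0)) stop("target_charge_uc must be > 0", call. = FALSE)
  if (any(pulse_width_us <= 0)) stop("pulse_width_us must be > 0", call. = FALSE)
  target_charge_uc / (.SHAPE_AREA_FACTOR[[shape]] * pulse_width_us * .UA_US_TO_UC)
}

#' Absolute charge injected per second by a pulse train
#'
#' Both phases of the charge-balanced biphasic pulse count toward the
#' injected |charge|, hence the factor 2. Exactly linear in amplitude and
#' in frequency.
#'
#' @param spec a [pulse_train()].
#' @return Charge rate in uC/s.
#' @examples
#' charge_rate(pulse_train("RECT", 100, 65, 100, 130)) # 1.69 uC/s
#' @export
charge_rate <- function(spec) {
  stopifnot(inherits(spec, "pulse_train"))
  2 * charge_per_phase(spec$shape, spec$amplitude_ua, spec$pulse_width_us) *
    spec$frequency_hz
}

#' Charge multiplier of one frequency relative to a baseline
#'
#' At identical amplitude and pulse width the injected charge scales as
#' f / f0. Reported multipliers are conventionally truncated (floored) to
#' one decimal, giving the series 3.3, 6.6, 8.6, 12, 16.6, 23.3 for
#' 50/100/130/180/250/350 Hz against a 15 Hz baseline.
#'
#' @param frequency_hz stimulation frequency, Hz (> 0).
#' @param baseline_frequency_hz reference frequency, Hz (> 0).
#' @param truncate_1dp floor the ratio to one decimal place (default TRUE).
#' @return Dimensionless charge ratio.
#' @export
charge_multiplier <- function(frequency_hz, baseline_frequency_hz,
                              truncate_1dp = TRUE) {
  if (any(frequency_hz <= 0) || any(baseline_frequency_hz <= 0)) {
    stop("frequencies must be > 0", call. = FALSE)
  }
  r <- frequency_hz / baseline_frequency_hz
  if (truncate_1dp) r <- floor(r * 10 + 1e-9) / 10
  r
}

#' Total electrical energy delivered (TEED) per second
#'
#' Computes the commonly cited estimate `TEED = I^2 * f * PW / Z`, exactly
#' as printed in the DBS literature. Note the caveat: the formula
#' originates from voltage-controlled stimulators; applied verbatim to a
#' current amplitude `I` the division (rather than multiplication) by the
#' impedance `Z` makes the quantity dimensionally odd (A^2/Ohm rather than
#' watts). It is reproduced as printed, not corrected, so values are
#' comparable with the published ones.
#'
#' @param amplitude_ua current amplitude, uA (> 0).
#' @param frequency_hz stimulation frequency, Hz (> 0).
#' @param pulse_width_us pulse width, us (> 0).
#' @param electrode an [electrode_spec()] (or a bare positive impedance in
#'   Ohm).
#' @return TEED estimate in A^2 * s^-1 * s / Ohm (see caveat above).
#' @examples
#' teed(100, 130, 65, electrode_spec(1000)) # 8.45e-14
#' @export
teed <- function(amplitude_ua, frequency_hz, pulse_width_us, electrode) {
  if (is.numeric(electrode)) electrode <- electrode_spec(electrode)
  stopifnot(inherits(electrode, "electrode_spec"))
  if (any(amplitude_ua <= 0) || any(frequency_hz <= 0) ||
      any(pulse_width_us <= 0)) {
    stop("amplitude, frequency and pulse width must be > 0", call. = FALSE)
  }
  (amplitude_ua * 1e-6)^2 * frequency_hz * (pulse_width_us * 1e-6) /
    electrode$impedance_ohm
}

# Sampling -------------------------------------------------------------------

# Envelope of one phase evaluated at times t in [0, PW] (peak = 1).
.phase_envelope <- function(shape, t, pw) {
  switch(shape,
         RECT = rep(1, length(t)),
         SINE = sin(pi * t / pw),
         TRI = 1 - abs(2 * t / pw - 1),
         LIN_DEC = 1 - t / pw)
}

#' Sample one biphasic pulse at microsecond resolution
#'
#' Emulates the arbitrary-current-waveform output of a research
#' stimulator: a first phase with the requested envelope and polarity, a
#' zero-current interphase gap, and a time-mirrored second phase of
#' opposite sign, so the pulse is charge balanced by construction.
#' Samples are midpoint values of each `dt` bin.
#'
#' @param spec a [pulse_train()].
#' @param dt_us sampling step, us; must satisfy `dt_us <= pulse_width_us/10`.
#' @return An object of class `sampled_waveform` with fields `dt_us` and
#'   `current_ua`.
#' @export
sample_pulse <- function(spec, dt_us = 1) {
  stopifnot(inherits(spec, "pulse_train"))
  if (dt_us <= 0) stop("dt_us must be > 0", call. = FALSE)
  if (dt_us > spec$pulse_width_us / 10) {
    stop("dt_us too coarse: need dt_us <= pulse_width_us / 10", call. = FALSE)
  }
  n_phase <- max(1L, as.integer(round(spec$pulse_width_us / dt_us)))
  n_gap <- as.integer(round(spec$interphase_us / dt_us))
  t_mid <- (seq_len(n_phase) - 0.5) * dt_us
  env <- .phase_envelope(spec$shape, t_mid, spec$pulse_width_us)
  sign1 <- if (spec$polarity == "cathodic_first") -1 else 1
  first <- sign1 * spec$amplitude_ua * env
  samples <- c(first, rep(0, n_gap), -rev(first))
  structure(list(dt_us = dt_us, current_ua = samples),
            class = "sampled_waveform")
}

#' @export
print.sampled_waveform <- function(x, ...) {
  cat(sprintf("<sampled_waveform> %d samples @ %g us (%.4g us total)\n",
              length(x$current_ua), x$dt_us, length(x$current_ua) * x$dt_us))
  invisible(x)
}

#' Net and per-phase charge of a sampled waveform
#'
#' @param wf a `sampled_waveform`.
#' @return Named list with `net_uc` (should be ~0 for a biphasic pulse)
#'   and `per_phase_uc` (half the absolute-charge integral).
#' @export
sampled_charge <- function(wf) {
  stopifnot(inherits(wf, "sampled_waveform"))
  list(net_uc = sum(wf$current_ua) * wf$dt_us * .UA_US_TO_UC,
       per_phase_uc = sum(abs(wf$current_ua)) * wf$dt_us * .UA_US_TO_UC / 2)
}

#' Sample a pulse train of several periods
#'
#' Repeats the single sampled pulse at the train's repetition period,
#' padding the remainder of each period with zero current.
#'
#' @param spec a [pulse_train()].
#' @param n_pulses number of periods to emit (>= 1).
#' @param dt_us sampling step, us.
#' @return A `sampled_waveform` covering `n_pulses / frequency_hz` seconds.
#' @export
sample_train <- function(spec, n_pulses = 1, dt_us = 1) {
  stopifnot(n_pulses >= 1)
  pulse <- sample_pulse(spec, dt_us)
  period_n <- as.integer(round(1e6 / spec$frequency_hz / dt_us))
  pad <- max(0L, period_n - length(pulse$current_ua))
  one <- c(pulse$current_ua, rep(0, pad))
  structure(list(dt_us = dt_us, current_ua = rep(one, n_pulses)),
            class = "sampled_waveform")
}

#' Write a sampled waveform as delimited text
#'
#' Two columns, `time_us` (bin midpoints) and `current_ua`, tab separated.
#'
#' @param wf a `sampled_waveform`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(wf, path) {
  stopifnot(inherits(wf, "sampled_waveform"))
  d <- data.frame(
    time_us = (seq_along(wf$current_ua) - 0.5) * wf$dt_us,
    current_ua = wf$current_ua)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
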