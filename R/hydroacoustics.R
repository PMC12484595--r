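#' Calibrated hydrophone pressure recording
#'
#' Container for a uniformly sampled pressure time series in pascal.
#'
#' @param samples Pressure samples (Pa).
#' @param sample_rate Sample rate (Hz).
#' @param start_time Time of the first sample (s).
#' @return An object of class `pressure_recording`.
#' @export
pressure_recording <- function(samples, sample_rate, start_time = 0) {
  if (sample_rate <= 0) stop_invalid("sample_rate must be > 0")
  if (!all(is.finite(samples))) stop_invalid("samples must be finite")
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate,
                 start_time = start_time),
            class = "pressure_recording")
}

#' @export
print.pressure_recording <- function(x, ...) {
  cat(sprintf("pressure_recording: %d samples @ %g Hz (%.2f s), start %g s\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, x$start_time))
  invisible(x)
}

#' Apply hydrophone calibration to a raw waveform
#'
#' Converts raw recorded amplitude to pressure using the hydrophone
#' sensitivity. The sensitivity is given as a magnitude in dB re 1 uPa
#' per unit raw amplitude (hydrophone data sheets quote, e.g., "205 dB re
#' 1 uPa" for a -205 dB re 1 V/uPa receiver): one raw unit corresponds to
#' `10^(|sensitivity|/20)` uPa, stored in Pa.
#'
#' @param raw Raw waveform (numeric vector).
#' @param sensitivity_db Sensitivity magnitude (dB re 1 uPa per raw unit).
#' @param sample_rate Sample rate (Hz).
#' @param start_time Time of first sample (s).
#' @return A [pressure_recording()].
#' @export
calibrate <- function(raw, sensitivity_db, sample_rate, start_time = 0) {
  p_upa <- raw * 10^(abs(sensitivity_db) / 20)
  pressure_recording(p_upa * 1e-6, sample_rate, start_time)
}

#' Band-limit a recording to the analysis band
#'
#' Zero-phase band-pass filtering (forward-backward Butterworth cascade: a
#' 2nd-order high-pass at `f_lo` and a 4th-order low-pass at `f_hi`).
#' Zero-phase filtering is used so peak-to-peak pressure is not distorted
#' by filter phase lag; DC and sub-band energy (including any offset) are
#' removed.
#'
#' @param rec A [pressure_recording()].
#' @param f_lo Lower band edge (Hz).
#' @param f_hi Upper band edge (Hz); must be below Nyquist.
#' @return A band-limited [pressure_recording()].
#' @export
bandlimit <- function(rec, f_lo = 10, f_hi = 20000) {
  stopifnot(inherits(rec, "pressure_recording"))
  nyq <- rec$sample_rate / 2
  if (f_lo >= f_hi) stop_invalid("f_lo must be < f_hi")
  if (f_hi >= nyq) stop_invalid("f_hi (%g Hz) must be below Nyquist (%g Hz)", f_hi, nyq)
  hp <- signal::butter(2, f_lo / nyq, type = "high")
  lp <- signal::butter(4, f_hi / nyq, type = "low")
  y <- signal::filtfilt(lp, signal::filtfilt(hp, rec$samples))
  pressure_recording(y, rec$sample_rate, rec$start_time)
}

window_indices <- function(rec, window_start, window_length) {
  i0 <- round((window_start - rec$start_time) * rec$sample_rate) + 1
  i1 <- i0 + round(window_length * rec$sample_rate) - 1
  if (i0 < 1 || i1 > length(rec$samples))
    stop_invalid("window [%g, %g] s not fully inside the recording",
                 window_start, window_start + window_length)
  i0:i1
}

#' Windowed sound exposure level
#'
#' SEL over one window: `10 * log10( sum(p_uPa^2) * dt / (1 uPa^2 * 1 s) )`
#' in dB re 1 uPa^2 s, with dt = 1/sample_rate. An all-zero (silent)
#' window returns `-Inf` rather than an error, so recording gaps survive
#' the pipeline.
#'
#' @param rec A [pressure_recording()] (pressure in Pa).
#' @param window_start Window start time (s).
#' @param window_length Window length (s).
#' @return SEL in dB re 1 uPa^2 s.
#' @export
window_sel <- function(rec, window_start = rec$start_time, window_length = 10) {
  stopifnot(inherits(rec, "pressure_recording"))
  idx <- window_indices(rec, window_start, window_length)
  p_upa <- rec$samples[idx] * 1e6
  energy <- sum(p_upa^2) / rec$sample_rate
  if (energy == 0) return(-Inf)
  10 * log10(energy)
}

#' Windowed peak-to-peak pressure
#'
#' Maximum minus minimum instantaneous pressure over the window (Pa).
#'
#' @inheritParams window_sel
#' @return Peak-to-peak pressure (Pa).
#' @export
window_p2p <- function(rec, window_start = rec$start_time, window_length = 10) {
  stopifnot(inherits(rec, "pressure_recording"))
  idx <- window_indices(rec, window_start, window_length)
  max(rec$samples[idx]) - min(rec$samples[idx])
}

#' Windowed sound metrics joined to source distance
#'
#' Partitions the recording into contiguous, non-overlapping windows
#' starting at the recording start, band-limits once, and computes SEL and
#' peak-to-peak pressure per window. Each window is annotated with the
#' source distance interpolated from the approach track at the window
#' midpoint. Windows shorter than `window_length` at the end of the
#' recording are dropped. Because analysis windows can be shorter than the
#' shot interval, some windows contain no shot; they carry the vessel
#' noise floor.
#'
#' @param rec A [pressure_recording()].
#' @param track Data frame with `time_s`, `distance_m` covering the
#'   recording time span.
#' @param window_length Window length (s).
#' @param f_lo,f_hi Analysis band edges (Hz); set `filter = FALSE` to skip
#'   band-limiting.
#' @param filter Band-limit before computing metrics?
#' @return Data frame: `window_start_s`, `distance_m`, `sel_db`, `p2p_pa`.
#' @export
metrics_vs_distance <- function(rec, track, window_length = 10,
                                f_lo = 10, f_hi = 20000, filter = TRUE) {
  stopifnot(inherits(rec, "pressure_recording"))
  dur <- length(rec$samples) / rec$sample_rate
  t0 <- rec$start_time
  if (min(track$time_s) > t0 || max(track$time_s) < t0 + dur - window_length)
    stop_invalid("track [%g, %g] s does not cover recording span [%g, %g] s",
                 min(track$time_s), max(track$time_s), t0, t0 + dur)
  use <- if (filter) bandlimit(rec, f_lo, f_hi) else rec
  starts <- t0 + window_length * (seq_len(floor(dur / window_length)) - 1)
  sel <- vapply(starts, function(s) window_sel(use, s, window_length), numeric(1))
  p2p <- vapply(starts, function(s) window_p2p(use, s, window_length), numeric(1))
  dist <- stats::approx(track$time_s, track$distance_m,
                        xout = starts + window_length / 2, rule = 2)$y
  data.frame(window_start_s = starts, distance_m = dist,
             sel_db = sel, p2p_pa = p2p)
}
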