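#' Simulate the vessel approach track
#'
#' Linear kinematics of a seismic vessel approaching a stationary receiver
#' at constant speed: distance decreases as `start_distance -
#' vessel_speed * t`, reaches the pass point, and increases again as the
#' vessel opens the range on the far side.
#'
#' @param scenario An [approach_scenario()].
#' @param dt Sampling interval of the track (s).
#' @return A data frame with columns `time_s` and `distance_m`.
#' @export
gen_approach_track <- function(scenario, dt = 1) {
  stopifnot(inherits(scenario, "approach_scenario"))
  time <- seq(0, scenario$duration, by = dt)
  distance <- abs(scenario$start_distance - scenario$vessel_speed * time)
  data.frame(time_s = time, distance_m = distance)
}

# Pulse energy of A*exp(-t/tau)*sin(2 pi f t) integrated over all time:
# A^2 * tau / 4 (average of sin^2 is 1/2; integral of exp(-2t/tau) is
# tau/2). Used to set the amplitude from a target per-shot SEL.
pulse_amplitude_for_sel <- function(sel_db, tau) {
  sqrt(4 * 10^(sel_db / 10) / tau)       # amplitude in uPa
}

#' Simulate a calibrated airgun approach recording
#'
#' Generates a pressure time series (Pa) containing Gaussian vessel noise
#' whose expected windowed SEL equals `noise_floor_sel`, plus one
#' exponentially damped sinusoidal pulse per airgun shot. The pulse's
#' per-shot SEL follows `source_sel_at_1m - spreading_exponent *
#' log10(distance)`, i.e. geometric spreading loss from the source level.
#'
#' The returned shot log and window truth table carry the generator's
#' ground truth so that windowed metrics recovered downstream can be
#' compared against what was planted: for each contiguous
#' `window_length`-second window, `expected_sel_db` is the dB sum of the
#' noise-floor energy and the nominal energy of all shots whose onset
#' falls in the window.
#'
#' @param scenario An [approach_scenario()].
#' @param track Optional track from [gen_approach_track()]; generated from
#'   the scenario if omitted.
#' @param n_shots Number of shots; defaults to as many as fit in the
#'   duration. Use 0 for a noise-only recording.
#' @param window_length Window length used for the ground-truth table (s).
#' @return A list of class `airgun_recording` with elements `rec` (a
#'   [pressure_recording()]), `shots` (data frame: `shot`, `time_s`,
#'   `distance_m`, `sel_db`, `amplitude_pa`) and `window_truth` (data
#'   frame: `window_start_s`, `expected_sel_db`, `n_shots`).
#' @export
gen_airgun_recording <- function(scenario, track = NULL, n_shots = NULL,
                                 window_length = 10) {
  stopifnot(inherits(scenario, "approach_scenario"))
  fs <- scenario$sample_rate
  dur <- scenario$duration
  if (dur < window_length)
    stop_invalid("duration (%g s) is shorter than one %g s window", dur, window_length)
  if (is.null(track)) track <- gen_approach_track(scenario)
  n <- round(dur * fs)

  # Vessel noise: white Gaussian scaled so the expected IN-BAND windowed
  # SEL equals the floor. The floor is defined over the analysis band
  # (band[1]..band[2] Hz); white noise spreads its energy uniformly to
  # Nyquist, so the total variance is inflated by (fs/2) / bandwidth.
  band_frac <- (scenario$band[2] - scenario$band[1]) / (fs / 2)
  sigma_upa <- sqrt(10^(scenario$noise_floor_sel / 10) /
                      (window_length * band_frac))
  max_shots <- floor(dur / scenario$shot_interval)
  if (is.null(n_shots)) n_shots <- max_shots
  if (n_shots > max_shots) n_shots <- max_shots

  samples <- with_seed(scenario$seed, rnorm(n, sd = sigma_upa))

  shots <- data.frame(shot = integer(0), time_s = numeric(0),
                      distance_m = numeric(0), sel_db = numeric(0),
                      amplitude_pa = numeric(0))
  if (n_shots > 0) {
    t_shot <- (seq_len(n_shots) - 1) * scenario$shot_interval
    d_shot <- pmax(stats::approx(track$time_s, track$distance_m,
                                 xout = t_shot, rule = 2)$y, 1)
    sel_shot <- scenario$source_sel_at_1m -
      scenario$spreading_exponent * log10(d_shot)
    amp_upa <- pulse_amplitude_for_sel(sel_shot, scenario$pulse_decay)
    # damped sinusoid template truncated at 8 decay constants
    t_pulse <- seq(0, 8 * scenario$pulse_decay, by = 1 / fs)
    template <- exp(-t_pulse / scenario$pulse_decay) *
      sin(2 * pi * scenario$pulse_frequency * t_pulse)
    for (k in seq_len(n_shots)) {
      i0 <- round(t_shot[k] * fs) + 1
      idx <- i0:min(i0 + length(template) - 1, n)
      samples[idx] <- samples[idx] + amp_upa[k] * template[seq_along(idx)]
    }
    shots <- data.frame(shot = seq_len(n_shots), time_s = t_shot,
                        distance_m = d_shot, sel_db = sel_shot,
                        amplitude_pa = amp_upa * 1e-6)
  }

  w_start <- seq(0, dur - window_length, by = window_length)
  noise_energy <- 10^(scenario$noise_floor_sel / 10)
  exp_energy <- rep(noise_energy, length(w_start))
  n_in_win <- integer(length(w_start))
  if (n_shots > 0) {
    win_of_shot <- floor(shots$time_s / window_length) + 1
    keep <- win_of_shot <= length(w_start)
    for (k in which(keep)) {
      w <- win_of_shot[k]
      exp_energy[w] <- exp_energy[w] + 10^(shots$sel_db[k] / 10)
      n_in_win[w] <- n_in_win[w] + 1L
    }
  }
  window_truth <- data.frame(window_start_s = w_start,
                             expected_sel_db = 10 * log10(exp_energy),
                             n_shots = n_in_win)

  structure(list(
    rec = pressure_recording(samples * 1e-6, fs),
    shots = shots, window_truth = window_truth
  ), class = "airgun_recording")
}

#' Read and write mono WAV files
#'
#' Minimal RIFF/WAVE support for the two encodings used here: 16-bit PCM
#' and 32-bit IEEE float, single channel. `write_wav` stores pressure
#' samples scaled by `scale` (so that field-scale pressures fit integer
#' PCM); `read_wav` returns the raw waveform and sample rate, leaving
#' calibration to [calibrate()].
#'
#' @param samples Numeric vector of samples.
#' @param path File path.
#' @param sample_rate Sample rate (Hz).
#' @param format `"float"` (32-bit IEEE) or `"pcm16"`.
#' @param scale Multiplier applied to samples before writing (and undone
#'   by the reader only if you pass it there too).
#' @return `read_wav` returns a list with `samples`, `sample_rate`.
#' @export
write_wav <- function(samples, path, sample_rate, format = c("float", "pcm16"),
                      scale = 1) {
  format <- match.arg(format)
  x <- samples * scale
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x)
  bytes_per <- if (format == "float") 4L else 2L
  data_size <- n * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (format == "float") 3L else 1L, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")
  writeBin(8L * bytes_per, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "float") {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(pmax(pmin(round(x), 32767), -32768)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop_invalid("not a RIFF/WAVE file: %s", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop_invalid("not a RIFF/WAVE file: %s", path)
  fmt_code <- NULL; n_channels <- 1L; sample_rate <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop_invalid("no data chunk in %s", path)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_code <- readBin(con, integer(), size = 2, endian = "little")
      n_channels <- readBin(con, integer(), size = 2, endian = "little")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, raw(), n = size - 16))
    } else if (identical(id, "data")) {
      if (is.null(fmt_code)) stop_invalid("data chunk before fmt chunk in %s", path)
      if (fmt_code == 3 && bits == 32) {
        x <- readBin(con, numeric(), n = size / 4, size = 4, endian = "little")
      } else if (fmt_code == 1 && bits == 16) {
        x <- readBin(con, integer(), n = size / 2, size = 2,
                     signed = TRUE, endian = "little")
      } else {
        stop_invalid("unsupported WAV encoding (format %d, %d bit)", fmt_code, bits)
      }
      if (n_channels > 1) {
        warning("multichannel WAV; using first channel")
        x <- x[seq(1, length(x), by = n_channels)]
      }
      return(list(samples = as.numeric(x), sample_rate = sample_rate))
    } else {
      invisible(readBin(con, raw(), n = size + size %% 2))
    }
  }
}
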