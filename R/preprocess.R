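#' Bandpass filter a raw PPG signal
#'
#' 4th-order Chebyshev type II bandpass (stopband edges 0.5-10 Hz, 20 dB
#' stopband attenuation by default), applied forward-backward so the net
#' group delay is zero. Zero-phase application matters because pulse arrival
#' time is a timing measurement: a one-pass IIR would bias every landmark.
#'
#' @param ppg raw PPG samples.
#' @param fs sampling frequency, Hz (> 20, so the 10 Hz edge is below
#'   Nyquist with headroom).
#' @param config a [pipeline_config()] (band edges, order, stopband dB).
#' @return Filtered samples, same length as the input.
#' @export
filter_ppg <- function(ppg, fs, config = pipeline_config()) {
  if (fs <= 2 * max(config$ppg_band)) {
    stop("fs too low for the ", max(config$ppg_band), " Hz band edge")
  }
  flt <- signal::cheby2(config$ppg_order, Rp = config$ppg_stopband_db,
                        W = config$ppg_band / (fs / 2), type = "pass")
  # demean first: the Chebyshev II stopband floor is -20 dB, not -Inf, and
  # removing the offset also suppresses the slow startup transient
  as.numeric(signal::filtfilt(flt, ppg - mean(ppg)))
}

#' Bandpass filter a raw ECG signal
#'
#' 4th-order Butterworth bandpass (0.5-40 Hz by default), zero-phase.
#'
#' @param ecg raw ECG samples.
#' @inheritParams filter_ppg
#' @return Filtered samples, same length as the input.
#' @export
filter_ecg <- function(ecg, fs, config = pipeline_config()) {
  if (fs <= 2 * max(config$ecg_band)) {
    stop("fs too low for the ", max(config$ecg_band), " Hz band edge")
  }
  flt <- signal::butter(config$ecg_order, W = config$ecg_band / (fs / 2),
                        type = "pass")
  as.numeric(signal::filtfilt(flt, ecg - mean(ecg)))
}

#' Normalize a PPG by its AC/DC decomposition
#'
#' Divides the pulsatile (AC) component -- the bandpass-filtered signal --
#' by the quasi-static (DC) component, estimated as the mean of the raw
#' record. The result is dimensionless and invariant to rescaling the raw
#' signal by any positive constant.
#'
#' @param ppg_filtered bandpass-filtered PPG (the AC part).
#' @param ppg_raw raw PPG of the same length (the DC part is its mean).
#' @param config a [pipeline_config()] (`dc_tol`).
#' @return Normalized, dimensionless PPG samples.
#' @export
normalize_ac_dc <- function(ppg_filtered, ppg_raw,
                            config = pipeline_config()) {
  stopifnot(length(ppg_filtered) == length(ppg_raw))
  dc <- mean(ppg_raw)
  if (abs(dc) < config$dc_tol * max(1, max(abs(ppg_raw)))) {
    stop("degenerate DC: raw PPG mean is (near) zero")
  }
  ppg_filtered / dc
}

#' Forward-difference derivative
#'
#' `out[i] = (x[i+1] - x[i]) * fs`, with the final sample replicated so the
#' length is preserved. Applied once to the normalized PPG this gives the
#' velocity waveform (VPG, 1/s); applied twice, the acceleration waveform
#' (APG, 1/s^2).
#'
#' @param x sample vector (length >= 2).
#' @param fs sampling frequency, Hz.
#' @return Numeric vector of the same length as `x`.
#' @export
#' @examples
#' derive(c(0, 1, 4, 9), fs = 1)  # 1 3 5 5
derive <- function(x, fs) {
  if (length(x) < 2L) stop("derive() needs at least 2 samples")
  d <- diff(x) * fs
  c(d, d[length(d)])
}

#' Preprocess a waveform record
#'
#' Runs the full preprocessing chain: zero-phase bandpass filtering of ECG
#' and PPG, AC/DC normalization of the PPG, and forward-difference VPG and
#' APG. The ABP channel is passed through untouched (it is the labelling
#' reference and is read raw). The first and last `edge_margin` seconds are
#' flagged so beat extraction can avoid filter transients.
#'
#' @param record a `ppgbp_record` (or any list with `ecg`, `ppg`, `abp`,
#'   `fs` fields).
#' @param config a [pipeline_config()].
#' @return A `ppgbp_processed` list: `ecg_f`, `ppg_n`, `vpg`, `apg`, `abp`,
#'   `fs`, `n`, `margin` (s).
#' @export
process_record <- function(record, config = pipeline_config()) {
  fs <- record$fs
  ecg_f <- filter_ecg(record$ecg, fs, config)
  ppg_f <- filter_ppg(record$ppg, fs, config)
  ppg_n <- normalize_ac_dc(ppg_f, record$ppg, config)
  vpg <- derive(ppg_n, fs)
  apg <- derive(vpg, fs)
  structure(list(ecg_f = ecg_f, ppg_n = ppg_n, vpg = vpg, apg = apg,
                 abp = record$abp, fs = fs, n = length(ppg_n),
                 margin = config$edge_margin),
            class = "ppgbp_processed")
}
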