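#' Pipeline configuration
#'
#' Builds the configuration list consumed by every stage of the pipeline.
#' All keys have defaults; unknown keys are rejected so that typos in a
#' config file cannot silently fall back to a default.
#'
#' Every constant that the analysis leaves open (filter stopband attenuation,
#' R-detector window lengths, category thresholds, classifier
#' hyperparameters) lives here, so a run is fully described by its config.
#'
#' @param ... named overrides of the default keys listed below.
#'
#' @return A named list of class `ppgbp_config`:
#' \describe{
#'   \item{fs}{sampling frequency, Hz (default 125)}
#'   \item{ppg_band, ppg_order, ppg_stopband_db}{PPG Chebyshev II bandpass:
#'     stopband edges in Hz, order, stopband attenuation in dB}
#'   \item{ecg_band, ecg_order}{ECG Butterworth bandpass edges (Hz) and order}
#'   \item{edge_margin}{seconds trimmed at each record end before beat
#'     extraction (filter transients)}
#'   \item{rpeak_w_peak, rpeak_w_beat, rpeak_offset, refractory}{R-peak
#'     detector: event/beat moving-average windows (s), threshold offset
#'     (fraction of mean squared signal), refractory period (s)}
#'   \item{a_window}{APG a-wave search extension beyond the VPG w point (s)}
#'   \item{cde_frac}{fraction of the beat period bounding the c/d/e search}
#'   \item{apg_prominence}{minimum swing between successive APG extrema to
#'     count as real c/d/e waves, as a fraction of the beat's APG range}
#'   \item{dc_tol}{relative tolerance below which the PPG DC level is
#'     considered degenerate}
#'   \item{thresh_prehyp, thresh_hyp}{SBP category thresholds, mmHg}
#'   \item{train_frac, cv_folds}{train split fraction and CV fold count}
#'   \item{knn_k, adaboost_rounds, bagged_trees}{classifier hyperparameters}
#' }
#' @export
#' @examples
#' cfg <- pipeline_config(knn_k = 7)
#' cfg$knn_k
pipeline_config <- function(...) {
  defaults <- list(
    fs = 125,
    ppg_band = c(0.5, 10), ppg_order = 4, ppg_stopband_db = 20,
    ecg_band = c(0.5, 40), ecg_order = 4,
    edge_margin = 1,
    rpeak_w_peak = 0.097, rpeak_w_beat = 0.611,
    rpeak_offset = 0.08, refractory = 0.2,
    a_window = 0.04,
    cde_frac = 0.85,
    apg_prominence = 0.03,
    dc_tol = 1e-6,
    thresh_prehyp = 120, thresh_hyp = 140,
    train_frac = 0.7, cv_folds = 10,
    knn_k = 5, adaboost_rounds = 50, bagged_trees = 100
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) {
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    }
    defaults[names(overrides)] <- overrides
  }
  structure(defaults, class = "ppgbp_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys present in the file override the defaults of [pipeline_config()];
#' unknown keys are an error.
#'
#' @param path path to a YAML file of config keys.
#' @return A `ppgbp_config` list.
#' @export
config_from_yaml <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(pipeline_config, vals)
}
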