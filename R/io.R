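# Channel-name aliases used when mapping files to ecg/abp/ppg roles.
default_channel_aliases <- list(
  ecg = c("ECG", "II", "I", "III", "MLII", "V", "ecg"),
  abp = c("ABP", "ART", "BP", "abp"),
  ppg = c("PLETH", "PPG", "pleth", "ppg")
)

map_channels <- function(found, channel_map = default_channel_aliases) {
  out <- list()
  for (role in c("ecg", "abp", "ppg")) {
    hit <- which(found %in% channel_map[[role]])
    if (!length(hit)) {
      stop("channel ", toupper(role), " not found; channels present: ",
           paste(found, collapse = ", "))
    }
    out[[role]] <- hit[1L]
  }
  out
}

#' Write a waveform record as CSV plus a JSON sidecar
#'
#' The CSV has columns `time`, `ECG`, `ABP`, `PLETH`; the sidecar
#' (`<path>.json`) carries the sampling rate, subject id and -- for
#' synthetic records -- the ground truth.
#'
#' @param record a `ppgbp_record`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path) {
  n <- length(record$ecg)
  # serialize at 17 significant digits so doubles round-trip exactly
  df <- data.frame(time = sprintf("%.17g", (0:(n - 1)) / record$fs),
                   ECG = sprintf("%.17g", record$ecg),
                   ABP = sprintf("%.17g", record$abp),
                   PLETH = sprintf("%.17g", record$ppg))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(subject_id = record$subject_id, fs = record$fs,
               duration = record$duration)
  if (!is.null(record$ground_truth)) {
    gt <- record$ground_truth
    meta$ground_truth <- list(
      r_times = gt$r_times, ppg_onset_times = gt$ppg_onset_times,
      pat_true = gt$pat_true, sbp_true = gt$sbp_true,
      category_true = gt$category_true,
      fiducial_rel = as.list(gt$fiducial_rel))
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a waveform record from CSV (with optional JSON sidecar)
#'
#' @param path CSV path written by [write_record_csv()] or any CSV whose
#'   header names the channels (aliases: ECG/II/...; ABP/ART; PLETH/PPG).
#' @param channel_map named list of alias vectors for roles `ecg`, `abp`,
#'   `ppg`.
#' @param fs sampling rate override; if `NULL` it is taken from the sidecar
#'   or inferred from the `time` column.
#' @return A `ppgbp_record`.
#' @export
read_record_csv <- function(path, channel_map = default_channel_aliases,
                            fs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
          else NULL
  if (is.null(fs)) {
    fs <- meta$fs %||%
      (if ("time" %in% names(df)) 1 / stats::median(diff(df$time))
       else stop("sampling rate unknown: no sidecar and no time column"))
  }
  roles <- map_channels(setdiff(names(df), "time"), channel_map)
  chans <- setdiff(names(df), "time")
  gt <- NULL
  if (!is.null(meta$ground_truth)) {
    g <- meta$ground_truth
    gt <- list(r_times = as.numeric(g$r_times),
               ppg_onset_times = as.numeric(g$ppg_onset_times),
               pat_true = g$pat_true, sbp_true = g$sbp_true,
               category_true = g$category_true,
               fiducial_rel = unlist(g$fiducial_rel))
  }
  structure(list(subject_id = meta$subject_id %||% basename(path),
                 fs = round(fs, 6),
                 ecg = df[[chans[roles$ecg]]],
                 abp = df[[chans[roles$abp]]],
                 ppg = df[[chans[roles$ppg]]],
                 duration = nrow(df) / fs,
                 ground_truth = gt),
            class = "ppgbp_record")
}

#' Write a record in WFDB-style format (.hea header + 16-bit .dat)
#'
#' A minimal single-segment writer: a text header naming the channels
#' (`ECG`, `ABP`, `PLETH`) with per-channel gain and baseline, and an
#' interleaved little-endian 16-bit signal file. Amplitudes are quantized
#' to the 16-bit ADC grid.
#'
#' @param record a `ppgbp_record`.
#' @param record_name path prefix; writes `<record_name>.hea` and
#'   `<record_name>.dat`.
#' @return `record_name`, invisibly.
#' @export
write_record_wfdb <- function(record, record_name) {
  sigs <- list(ECG = record$ecg, ABP = record$abp, PLETH = record$ppg)
  units <- c(ECG = "mV", ABP = "mmHg", PLETH = "NU")
  n <- length(record$ecg)
  gains <- numeric(3); baselines <- integer(3)
  adc <- matrix(0L, nrow = 3, ncol = n)
  for (k in 1:3) {
    x <- sigs[[k]]
    rng <- max(x) - min(x)
    if (rng <= 0) rng <- 1
    gain <- 30000 / rng
    # WFDB convention: physical = (adc - baseline) / gain
    base <- as.integer(-round(min(x) * gain) - 15000L)
    adc[k, ] <- as.integer(round(x * gain) + base)
    gains[k] <- gain; baselines[k] <- base
  }
  hea <- c(sprintf("%s 3 %g %d", basename(record_name), record$fs, n),
           sprintf("%s.dat 16 %.6f(%d)/%s 16 0 0 0 0 %s",
                   basename(record_name), gains, baselines,
                   units, names(sigs)))
  writeLines(hea, paste0(record_name, ".hea"))
  con <- file(paste0(record_name, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(adc), con, size = 2, endian = "little")
  invisible(record_name)
}

#' Read a WFDB-style record written by [write_record_wfdb()]
#'
#' @param record_name path prefix of the `.hea`/`.dat` pair (a trailing
#'   `.hea` is stripped if present).
#' @param channel_map alias list as in [read_record_csv()].
#' @return A `ppgbp_record` (no ground truth).
#' @export
read_record_wfdb <- function(record_name,
                             channel_map = default_channel_aliases) {
  record_name <- sub("\\.hea$", "", record_name)
  hea_path <- paste0(record_name, ".hea")
  if (!file.exists(hea_path)) stop("file not found: ", hea_path)
  hea <- readLines(hea_path)
  head_fields <- strsplit(trimws(hea[1L]), "\\s+")[[1L]]
  nsig <- as.integer(head_fields[2L])
  fs <- as.numeric(head_fields[3L])
  n <- as.integer(head_fields[4L])
  gains <- numeric(nsig); baselines <- integer(nsig); chans <- character(nsig)
  for (k in seq_len(nsig)) {
    f <- strsplit(trimws(hea[1L + k]), "\\s+")[[1L]]
    spec <- f[3L]                      # gain(baseline)/units
    gains[k] <- as.numeric(sub("\\(.*$", "", spec))
    baselines[k] <- as.integer(sub("^.*\\((-?[0-9]+)\\).*$", "\\1", spec))
    chans[k] <- f[length(f)]
  }
  con <- file(paste0(record_name, ".dat"), "rb")
  on.exit(close(con))
  raw <- readBin(con, what = "integer", n = nsig * n, size = 2,
                 endian = "little", signed = TRUE)
  adc <- matrix(raw, nrow = nsig)
  phys <- lapply(seq_len(nsig), function(k) {
    (adc[k, ] - baselines[k]) / gains[k]
  })
  roles <- map_channels(chans, channel_map)
  structure(list(subject_id = basename(record_name), fs = fs,
                 ecg = phys[[roles$ecg]], abp = phys[[roles$abp]],
                 ppg = phys[[roles$ppg]], duration = n / fs,
                 ground_truth = NULL),
            class = "ppgbp_record")
}

#' Read a waveform record, dispatching on the file type
#'
#' @param path a `.csv` file or a WFDB-style header/prefix.
#' @param channel_map alias list; see [read_record_csv()].
#' @return A `ppgbp_record`.
#' @export
read_record <- function(path, channel_map = default_channel_aliases) {
  if (grepl("\\.csv$", path)) {
    read_record_csv(path, channel_map)
  } else if (grepl("\\.hea$", path) || file.exists(paste0(path, ".hea"))) {
    read_record_wfdb(path, channel_map)
  } else {
    stop("unknown record format: ", path)
  }
}

#' Write a tidy per-landmark fiducial dump
#'
#' One row per landmark per beat: subject, beat index, landmark, level,
#' time, amplitude, presence flag.
#'
#' @param record a `ppgbp_record`.
#' @param path output CSV path.
#' @param config a [pipeline_config()].
#' @return The dump data.frame, invisibly.
#' @export
write_fiducial_csv <- function(record, path, config = pipeline_config()) {
  proc <- process_record(record, config)
  r_times <- detect_r_peaks(proc$ecg_f, proc$fs, config)
  beats <- segment_beats(proc, r_times, config)
  rows <- list()
  for (k in seq_along(beats)) {
    fids <- locate_fiducials(proc, beats[[k]], config)
    if (is.null(fids)) next
    fids$subject_id <- record$subject_id
    fids$beat <- k
    rows[[length(rows) + 1L]] <- fids
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out[, c("subject_id", "beat", "landmark", "level",
                           "time", "amplitude", "present")],
                   path, row.names = FALSE)
  invisible(out)
}
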