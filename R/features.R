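#' Pulse arrival time of one beat
#'
#' PAT is measured from the ECG R wave to the `b_-2` point -- the
#' projection of the APG b wave onto the PPG, i.e. the middle of the PPG
#' systolic upstroke. The mid-upstroke point tracks blood pressure more
#' reliably than the pulse foot or peak.
#'
#' @param r_time R-peak time (s) opening the beat.
#' @param fiducials fiducial set of that beat from [locate_fiducials()].
#' @return PAT in seconds, or `NA` if the b wave is absent.
#' @export
compute_pat <- function(r_time, fiducials) {
  tb <- fid_time(fiducials, "b_-2")
  if (is.na(tb)) return(NA_real_)
  tb - r_time
}

#' Time span between two landmarks
#'
#' @param fiducials fiducial set from [locate_fiducials()].
#' @param p,q landmark names; the span is `t(q) - t(p)` (negative if `q`
#'   precedes `p`).
#' @return Seconds, or `NA` if either landmark is absent.
#' @export
time_span <- function(fiducials, p, q) {
  fid_time(fiducials, q) - fid_time(fiducials, p)
}

#' Amplitude of a landmark
#'
#' PPG-level amplitudes are measured from the beat baseline (the PPG value
#' at the onset O, so `amplitude(O) == 0`); VPG and APG amplitudes from
#' their zero lines.
#'
#' @inheritParams time_span
#' @param p landmark name.
#' @return Signal units, or `NA` if absent.
#' @export
amplitude <- function(fiducials, p) {
  fid_amp(fiducials, p)
}

# resolve a landmark to its sample index; NA when absent
fid_index <- function(fids, landmark) {
  i <- match(landmark, fids$landmark)
  if (is.na(i) || !fids$present[i]) NA_integer_ else fids$index[i]
}

#' Waveform (AC-component) area between two landmarks
#'
#' Sum of baseline-subtracted normalized-PPG samples over the inclusive
#' sample range from `p` to `q`.
#'
#' @param proc a `ppgbp_processed` record.
#' @param fiducials fiducial set of the beat.
#' @param p,q landmark names with `t(p) <= t(q)`.
#' @return Signal-units x samples, or `NA` if either landmark is absent.
#' @export
waveform_area <- function(proc, fiducials, p, q) {
  ip <- fid_index(fiducials, p); iq <- fid_index(fiducials, q)
  if (is.na(ip) || is.na(iq)) return(NA_real_)
  if (iq < ip) stop("waveform_area: landmarks out of order")
  sum(proc$ppg_n[ip:iq] - attr(fiducials, "baseline"))
}

#' Power area between two landmarks
#'
#' Quadratic sum (sum of squares) of the normalized-PPG samples over the
#' inclusive sample range from `p` to `q`.
#'
#' @inheritParams waveform_area
#' @return Signal-units^2 x samples, or `NA` if either landmark is absent.
#' @export
power_area <- function(proc, fiducials, p, q) {
  ip <- fid_index(fiducials, p); iq <- fid_index(fiducials, q)
  if (is.na(ip) || is.na(iq)) return(NA_real_)
  if (iq < ip) stop("power_area: landmarks out of order")
  sum(proc$ppg_n[ip:iq]^2)
}

#' Slope between two landmarks
#'
#' `(amplitude(q) - amplitude(p)) / (t(q) - t(p))`; symmetric under
#' exchanging `p` and `q`.
#'
#' @inheritParams time_span
#' @return Signal units per second, or `NA` if a landmark is absent or the
#'   two times coincide.
#' @export
slope <- function(fiducials, p, q) {
  dt <- time_span(fiducials, p, q)
  if (is.na(dt) || dt == 0) return(NA_real_)
  (amplitude(fiducials, q) - amplitude(fiducials, p)) / dt
}

#' APG composite ratios
#'
#' Arithmetic on the a--e APG wave amplitudes, e.g. `b/a`, `d/a`,
#' `(b-c-d)/a`.
#'
#' @inheritParams time_span
#' @param formula one of `"b/a"`, `"c/a"`, `"d/a"`, `"e/a"`,
#'   `"(b-c-d-e)/a"`, `"(b-c-d)/a"`.
#' @return Dimensionless ratio, or `NA` if a required wave is absent or
#'   `a == 0`.
#' @export
apg_composite <- function(fiducials, formula = c("b/a", "c/a", "d/a", "e/a",
                                                 "(b-c-d-e)/a", "(b-c-d)/a")) {
  formula <- match.arg(formula)
  a <- amplitude(fiducials, "a")
  if (is.na(a) || a == 0) return(NA_real_)
  g <- function(x) amplitude(fiducials, x)
  switch(formula,
         "b/a" = g("b") / a,
         "c/a" = g("c") / a,
         "d/a" = g("d") / a,
         "e/a" = g("e") / a,
         "(b-c-d-e)/a" = (g("b") - g("c") - g("d") - g("e")) / a,
         "(b-c-d)/a" = (g("b") - g("c") - g("d")) / a)
}

#' The ten selected PPG morphological features of one beat
#'
#' The feature definitions (landmark names follow the `-1`/`-2` projection
#' convention: `q_-k` is landmark `q` read `k` derivative levels below its
#' own signal):
#' \describe{
#'   \item{f1}{power area S to `c_-2` over the full-beat power area O to
#'     `O_next` (dimensionless)}
#'   \item{f2}{slope `b_-2` to `d_-2` on the PPG (1/s)}
#'   \item{f3}{time span S to `c_-2` (s)}
#'   \item{f4}{amplitude ratio `c_-2`/S on the PPG}
#'   \item{f5}{time span S to `d_-2` (s)}
#'   \item{f6}{APG composite (b-c-d)/a}
#'   \item{f7}{APG d-wave amplitude (1/s^2)}
#'   \item{f8}{VPG ratio `c_-1`/w}
#'   \item{f9}{APG composite d/a}
#'   \item{f10}{slope S to `c_-2` on the PPG (1/s)}
#' }
#' Components whose landmarks are missing are `NA` (never imputed).
#'
#' @param proc a `ppgbp_processed` record.
#' @param fiducials fiducial set of the beat.
#' @return Named numeric vector `f1` .. `f10`.
#' @export
compute_table1_features <- function(proc, fiducials) {
  # a noisy beat can misorder landmarks; treat reversed spans as missing
  ordered <- function(p, q) {
    ip <- fid_index(fiducials, p); iq <- fid_index(fiducials, q)
    !is.na(ip) && !is.na(iq) && ip <= iq
  }
  num <- if (ordered("S", "c_-2")) power_area(proc, fiducials, "S", "c_-2")
         else NA_real_
  den <- if (ordered("O", "O_next")) power_area(proc, fiducials, "O", "O_next")
         else NA_real_
  f1 <- if (is.na(num) || is.na(den) || den == 0) NA_real_ else num / den
  ampS <- amplitude(fiducials, "S")
  ampc2 <- amplitude(fiducials, "c_-2")
  f4 <- if (is.na(ampS) || ampS == 0) NA_real_ else ampc2 / ampS
  ampw <- amplitude(fiducials, "w")
  ampc1 <- amplitude(fiducials, "c_-1")
  f8 <- if (is.na(ampw) || ampw == 0) NA_real_ else ampc1 / ampw
  c(f1 = f1,
    f2 = slope(fiducials, "b_-2", "d_-2"),
    f3 = time_span(fiducials, "S", "c_-2"),
    f4 = f4,
    f5 = time_span(fiducials, "S", "d_-2"),
    f6 = apg_composite(fiducials, "(b-c-d)/a"),
    f7 = amplitude(fiducials, "d"),
    f8 = f8,
    f9 = apg_composite(fiducials, "d/a"),
    f10 = slope(fiducials, "S", "c_-2"))
}

#' Aggregate per-beat feature vectors to one subject-level vector
#'
#' Component-wise median over the beats where that component is present;
#' the median is robust to residual detection errors in single beats.
#'
#' @param per_beat matrix or data.frame, one row per beat, columns the
#'   feature components (`NA` allowed).
#' @return Named numeric vector of medians, with attribute `n_beats` giving
#'   the per-component count of contributing beats. Errors if no beat
#'   contributes to any component.
#' @export
aggregate_subject <- function(per_beat) {
  m <- as.matrix(per_beat)
  if (nrow(m) < 1L || all(is.na(m))) {
    stop("no valid beats to aggregate")
  }
  out <- apply(m, 2, stats::median, na.rm = TRUE)
  attr(out, "n_beats") <- apply(m, 2, function(x) sum(!is.na(x)))
  out
}

#' Extract the subject-level feature vector and label from one record
#'
#' Runs preprocessing, R-peak detection, beat segmentation, fiducial
#' location, PAT and the ten-feature computation beat by beat, aggregates
#' by the per-component median, extracts SBP from the raw ABP, and labels
#' the blood-pressure category.
#'
#' @param record a `ppgbp_record` (synthetic or read from disk).
#' @param config a [pipeline_config()].
#' @return One-row data.frame: `subject_id`, `sbp`, `label`, `pat`,
#'   `f1`..`f10`, `n_beats` (beats contributing to PAT), `n_beats_kept`
#'   (valid beats). `NULL` if no beat could be analysed.
#' @export
extract_features_record <- function(record, config = pipeline_config()) {
  proc <- process_record(record, config)
  r_times <- detect_r_peaks(proc$ecg_f, proc$fs, config)
  beats <- segment_beats(proc, r_times, config)
  if (length(beats) < 1L) return(NULL)
  rows <- vector("list", length(beats))
  for (k in seq_along(beats)) {
    fids <- locate_fiducials(proc, beats[[k]], config)
    if (is.null(fids)) next
    rows[[k]] <- c(pat = compute_pat(beats[[k]]$r_time, fids),
                   compute_table1_features(proc, fids))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  per_beat <- do.call(rbind, rows)
  agg <- aggregate_subject(per_beat)
  sbp <- extract_sbp(record$abp, beats)
  data.frame(subject_id = record$subject_id,
             sbp = sbp,
             label = label_bp_category(sbp, config),
             t(agg),
             n_beats = attr(agg, "n_beats")[["pat"]],
             n_beats_kept = nrow(per_beat),
             stringsAsFactors = FALSE)
}

#' Feature table for a cohort of records
#'
#' @param records list of `ppgbp_record`s.
#' @param config a [pipeline_config()].
#' @param verbose print per-record progress counters.
#' @return data.frame with one row per analysable subject (see
#'   [extract_features_record()]); subjects with no valid beats are dropped
#'   with a message.
#' @export
cohort_feature_table <- function(records, config = pipeline_config(),
                                 verbose = FALSE) {
  rows <- lapply(records, function(r) {
    row <- extract_features_record(r, config)
    if (is.null(row)) {
      message("subject ", r$subject_id, ": no valid beats, excluded")
    } else if (verbose) {
      message("subject ", r$subject_id, ": ", row$n_beats_kept,
              " beats kept")
    }
    row
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no analysable subjects in the cohort")
  do.call(rbind, rows)
}
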