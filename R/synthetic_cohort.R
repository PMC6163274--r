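#' Pulse morphology parameters
#'
#' Parameters of the smooth closed-form pulse used by the synthetic
#' generator. The pulse is a sum of Gaussian lobes: a systolic lobe
#' (amplitude 1), a reflection "shoulder" between the systolic peak and the
#' dicrotic wave, a dicrotic lobe, and a subtracted notch Gaussian. Shoulder
#' and notch amplitudes scale with `dicrotic_amplitude`, so setting it to 0
#' yields a single-lobe pulse.
#'
#' @param systolic_width Gaussian width (s) of the systolic lobe; the
#'   systolic peak sits at 2.5 widths after the pulse onset.
#' @param dicrotic_amplitude dicrotic lobe amplitude as a fraction of the
#'   systolic amplitude, in `[0, 1]`.
#' @param dicrotic_delay delay (s) of the dicrotic peak after the systolic
#'   peak.
#' @param notch_depth depth of the dicrotic notch as a fraction of the
#'   dicrotic amplitude, in `[0, 1]`.
#' @param baseline_wander_amp amplitude of sinusoidal baseline wander as a
#'   fraction of the pulse amplitude (applied to the PPG channel only).
#' @param baseline_wander_freq wander frequency, Hz.
#' @return A named list of class `ppgbp_morphology`.
#' @export
morphology_params <- function(systolic_width = 0.065,
                              dicrotic_amplitude = 0.30,
                              dicrotic_delay = 0.34,
                              notch_depth = 0.85,
                              baseline_wander_amp = 0.05,
                              baseline_wander_freq = 0.25) {
  m <- list(systolic_width = systolic_width,
            dicrotic_amplitude = dicrotic_amplitude,
            dicrotic_delay = dicrotic_delay,
            notch_depth = notch_depth,
            baseline_wander_amp = baseline_wander_amp,
            baseline_wander_freq = baseline_wander_freq)
  for (f in c("dicrotic_amplitude", "notch_depth", "baseline_wander_amp")) {
    if (!is.numeric(m[[f]]) || length(m[[f]]) != 1L || m[[f]] < 0 || m[[f]] > 1) {
      stop("invalid morphology field '", f, "': must be a fraction in [0, 1]")
    }
  }
  for (f in c("systolic_width", "dicrotic_delay", "baseline_wander_freq")) {
    if (!is.numeric(m[[f]]) || length(m[[f]]) != 1L || m[[f]] < 0) {
      stop("invalid morphology field '", f, "': must be non-negative")
    }
  }
  structure(m, class = "ppgbp_morphology")
}

#' Subject specification for the synthetic generator
#'
#' @param subject_id identifier string.
#' @param heart_rate beats per minute, in `[40, 180]`.
#' @param sbp,dbp systolic / diastolic pressure, mmHg (`dbp < sbp`).
#' @param pat_true true pulse arrival time (s), in `(0.05, 0.6)`:
#'   the delay from each ECG R wave to the PPG pulse onset.
#' @param morphology a [morphology_params()] list.
#' @param noise_sd additive white-noise level as a fraction of the pulse
#'   amplitude (>= 0).
#' @param seed integer RNG seed; generation is deterministic given the spec.
#' @param duration record length, s.
#' @param fs sampling frequency, Hz.
#' @return A named list of class `ppgbp_subject_spec`.
#' @export
subject_spec <- function(subject_id, heart_rate = 75, sbp = 110, dbp = 70,
                         pat_true = 0.25, morphology = morphology_params(),
                         noise_sd = 0.05, seed = 1L,
                         duration = 120, fs = 125) {
  chk <- function(cond, field, msg) {
    if (!cond) stop("invalid subject spec field '", field, "': ", msg)
  }
  chk(is.numeric(heart_rate) && heart_rate >= 40 && heart_rate <= 180,
      "heart_rate", "must be in [40, 180] beats/min")
  chk(is.numeric(sbp) && is.numeric(dbp) && dbp < sbp, "dbp",
      "must satisfy dbp < sbp")
  chk(is.numeric(pat_true) && pat_true > 0.05 && pat_true < 0.6, "pat_true",
      "must be in (0.05, 0.6) s")
  chk(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(inherits(morphology, "ppgbp_morphology"), "morphology",
      "must be a morphology_params() object")
  chk(is.numeric(duration) && duration > 2, "duration", "must exceed 2 s")
  chk(is.numeric(fs) && fs > 20, "fs", "must exceed 20 Hz")
  structure(list(subject_id = as.character(subject_id),
                 heart_rate = heart_rate, sbp = sbp, dbp = dbp,
                 pat_true = pat_true, morphology = morphology,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 duration = duration, fs = fs),
            class = "ppgbp_subject_spec")
}

# Closed-form pulse: sum of Gaussian lobes evaluated at times t (s) relative
# to the pulse onset. Internal constants (shoulder/notch placement) are part
# of the construction; see the methods vignette.
pulse_gaussians <- function(t, morph) {
  s1 <- morph$systolic_width
  mu1 <- 2.5 * s1
  a2 <- morph$dicrotic_amplitude
  dd <- morph$dicrotic_delay
  sh_a <- 1.3 * a2
  sh_mu <- mu1 + 0.45 * dd
  sh_s <- 1.1 * s1
  mu2 <- mu1 + dd
  s2 <- 1.6 * s1
  nd <- morph$notch_depth * a2
  mn <- mu1 + 0.62 * dd
  # notch width floored at 30 ms so its curvature stays inside the 10 Hz
  # band the PPG filter preserves
  sn <- max(0.12 * dd, 0.035)
  exp(-(t - mu1)^2 / (2 * s1^2)) +
    sh_a * exp(-(t - sh_mu)^2 / (2 * sh_s^2)) +
    a2 * exp(-(t - mu2)^2 / (2 * s2^2)) -
    nd * exp(-(t - mn)^2 / (2 * sn^2))
}

#' Single-beat pulse template
#'
#' Samples one period of the periodic pulse train defined by a morphology,
#' rolled so the first sample is the onset minimum and scaled so the
#' systolic peak is 1.
#'
#' @param morphology a [morphology_params()] list.
#' @param beat_period beat period, s (must exceed the systolic width and the
#'   dicrotic delay).
#' @param fs sampling frequency, Hz.
#' @return Numeric vector of `round(beat_period * fs)` samples in `[0, 1]`.
#' @export
pulse_template <- function(morphology, beat_period, fs) {
  if (!inherits(morphology, "ppgbp_morphology")) {
    morphology <- do.call(morphology_params, morphology)
  }
  if (beat_period <= morphology$systolic_width) {
    stop("beat_period must exceed systolic_width")
  }
  if (morphology$dicrotic_delay >= beat_period) {
    stop("dicrotic_delay must be smaller than beat_period")
  }
  n <- round(beat_period * fs)
  t <- (0:(n - 1)) / fs
  # periodic wrap: neighbours' tails included
  p <- pulse_gaussians(t, morphology) +
    pulse_gaussians(t + beat_period, morphology) +
    pulse_gaussians(t - beat_period, morphology)
  i0 <- which.min(p)
  p <- c(p[i0:n], p[seq_len(i0 - 1L)])
  (p - min(p)) / (max(p) - min(p))
}

#' Closed-form landmark times of the pulse template
#'
#' Evaluates the clean (noise-free) pulse construction on the sampling
#' grid and reads off the landmark times directly, independent of the
#' record-level detection path (R-peak detection, beat segmentation,
#' AC/DC normalization, search windows). Serves as the ground-truth oracle
#' for the fiducial detector: times are relative to the pulse onset (the
#' nominal start of the Gaussian construction).
#'
#' By default the construction is taken through the same zero-phase PPG
#' bandpass the analysis uses (`bandlimited = TRUE`, evaluated on a long
#' periodic train so filter transients cannot reach the measured beat):
#' landmark positions of a sampled pulse are only defined relative to an
#' analysis bandwidth, and a 10 Hz band genuinely shifts the notch region
#' of a sharp-notched pulse. Set `bandlimited = FALSE` for the raw
#' construction.
#'
#' @inheritParams pulse_template
#' @param config a [pipeline_config()] (filter and search-window constants).
#' @param bandlimited apply the analysis PPG bandpass before reading off
#'   landmarks (default `TRUE`).
#' @return Named numeric vector of landmark times (s, relative to onset)
#'   for O, S, N, D, w, x, y, z, a, b, c, d, e; `NA` for landmarks absent
#'   from this morphology.
#' @export
template_landmarks <- function(morphology, beat_period, fs,
                               config = pipeline_config(),
                               bandlimited = TRUE) {
  nb <- if (bandlimited) 13L else 3L
  mid <- nb %/% 2L
  n3 <- round(nb * beat_period * fs)
  tt <- (0:(n3 - 1)) / fs
  p <- numeric(n3)
  for (k in 0:(nb - 1L)) p <- p + pulse_gaussians(tt - k * beat_period,
                                                  morphology)
  if (bandlimited) p <- filter_ppg(p, fs, config)
  d1 <- c(diff(p) * fs, 0)
  d2 <- c(diff(d1) * fs, 0)
  seg <- which(tt >= mid * beat_period & tt < (mid + 1L) * beat_period)
  out <- c(O = NA_real_, S = NA_real_, N = NA_real_, D = NA_real_,
           w = NA_real_, x = NA_real_, y = NA_real_, z = NA_real_,
           a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
           e = NA_real_)
  o0 <- mid * beat_period
  rel <- function(i) refine_time(p, i, fs) - o0
  rel1 <- function(i) refine_time(d1, i, fs) - o0
  rel2 <- function(i) refine_time(d2, i, fs) - o0

  iS <- seg[which.max(p[seg])]
  pre <- seg[seg <= iS]
  iO <- pre[which.min(p[pre])]
  out["S"] <- rel(iS); out["O"] <- rel(iO)
  up <- pre[pre >= iO]
  iw <- up[which.max(d1[up])]
  out["w"] <- rel1(iw)
  awin <- seg[seg >= iO & tt[seg] <= tt[iw] + config$a_window]
  ia <- awin[which.max(d2[awin])]
  out["a"] <- rel2(ia)
  post <- seg[seg > ia]
  ib <- post[which.min(d2[post])]
  out["b"] <- rel2(ib)
  bound <- seg[1L] + round(config$cde_frac * length(seg))
  cde <- (ib + 1L):min(bound, seg[length(seg)])
  if (length(cde) > 3L) {
    mx <- cde[local_maxima(d2[cde])]
    mn <- cde[local_minima(d2[cde])]
    tol <- config$apg_prominence * (max(d2[seg]) - min(d2[seg]))
    kept <- prune_extrema(d2, c(mx, mn), tol)
    kmx <- kept[kept %in% mx]; kmn <- kept[kept %in% mn]
    ic <- if (length(kmx)) kmx[1L] else NA_integer_
    if (!is.na(ic)) {
      out["c"] <- rel2(ic)
      kmn <- kmn[kmn > ic]
      id <- if (length(kmn)) kmn[1L] else NA_integer_
      if (!is.na(id)) {
        out["d"] <- rel2(id)
        kmx <- kmx[kmx > id]
        ie <- if (length(kmx)) kmx[1L] else NA_integer_
        if (!is.na(ie)) out["e"] <- rel2(ie)
      }
    }
  }
  dia <- seg[seg > iS & seg <= bound]
  if (length(dia) > 3L) {
    ix <- dia[which.min(d1[dia])]
    out["x"] <- rel1(ix)
    ymx <- dia[local_maxima(d1[dia])]
    ymx <- ymx[ymx > ix]
    if (length(ymx)) {
      iy <- ymx[1L]
      out["y"] <- rel1(iy)
      zmn <- dia[local_minima(d1[dia])]
      zmn <- zmn[zmn > iy]
      if (length(zmn)) out["z"] <- rel1(zmn[1L])
    }
  }
  # N: PPG local minimum nearest the e-wave time after S; D: next local max
  pmins <- seg[local_minima(p[seg])]
  pmins <- pmins[pmins > iS]
  te <- out["e"]
  if (length(pmins) && is.finite(te)) {
    iN <- pmins[which.min(abs((tt[pmins] - o0) - te))]
    out["N"] <- rel(iN)
    pmaxs <- seg[local_maxima(p[seg])]
    pmaxs <- pmaxs[pmaxs > iN]
    if (length(pmaxs)) out["D"] <- rel(pmaxs[1L])
  } else if (is.finite(te)) {
    out["N"] <- te
  }
  out
}

#' Generate one subject's synchronized ECG/ABP/PPG record
#'
#' ECG R waves are Gaussian spikes at jittered beat times; PPG pulse onsets
#' trail each R wave by exactly `pat_true`; ABP pulses span `[dbp, sbp]`
#' mmHg (exactly, before noise). White noise is scaled by `noise_sd` as a
#' fraction of each channel's pulse amplitude (ABP receives 0.2 x the PPG
#' noise level: an invasive line is cleaner than an optical sensor).
#' Baseline wander is applied to the PPG only.
#'
#' @param spec a [subject_spec()].
#' @return A `ppgbp_record` list with fields `subject_id`, `fs`, `ecg`,
#'   `abp`, `ppg`, `duration` and `ground_truth` (R times, PPG onset times,
#'   true PAT/SBP/category, and closed-form landmark times relative to each
#'   onset).
#' @export
generate_subject <- function(spec) {
  if (!inherits(spec, "ppgbp_subject_spec")) {
    stop("spec must be created by subject_spec()")
  }
  fs <- spec$fs
  n <- round(fs * spec$duration)
  tt <- (0:(n - 1)) / fs
  with_seed(spec$seed, {
    base_period <- 60 / spec$heart_rate
    max_beats <- ceiling(spec$duration / base_period) + 5L
    jitter <- pmin(pmax(stats::rnorm(max_beats, 0, 0.02), -0.06), 0.06)
    periods <- base_period * (1 + jitter)
    r_times <- 0.4 + cumsum(c(0, periods))
    keep <- r_times <= spec$duration - 0.25
    r_times <- r_times[keep]
    periods <- periods[seq_len(length(r_times))]

    onsets <- r_times + spec$pat_true
    # pad one pulse at each end so interior beats see steady neighbours
    pad <- function(o) c(o[1L] - base_period, o, o[length(o)] + base_period)
    superpose <- function(centres) {
      out <- numeric(n)
      half <- 1.4
      for (o in centres) {
        i1 <- max(1L, floor((o - 0.3) * fs) + 1L)
        i2 <- min(n, ceiling((o + half) * fs) + 1L)
        if (i1 <= i2) {
          idx <- i1:i2
          out[idx] <- out[idx] + pulse_gaussians(tt[idx] - o, spec$morphology)
        }
      }
      out
    }

    ppg_train <- superpose(pad(onsets))
    ppg_train <- (ppg_train - min(ppg_train)) / (max(ppg_train) - min(ppg_train))
    dc_level <- 2.0
    pulse_amp <- 0.05 * dc_level
    wander <- spec$morphology$baseline_wander_amp *
      sin(2 * pi * spec$morphology$baseline_wander_freq * tt)
    ppg <- dc_level + pulse_amp *
      (ppg_train + wander + spec$noise_sd * stats::rnorm(n))

    abp_onsets <- r_times + 0.6 * spec$pat_true
    abp_train <- superpose(pad(abp_onsets))
    abp_train <- (abp_train - min(abp_train)) / (max(abp_train) - min(abp_train))
    abp <- spec$dbp + (spec$sbp - spec$dbp) * abp_train +
      0.2 * spec$noise_sd * (spec$sbp - spec$dbp) * stats::rnorm(n)

    ecg <- numeric(n)
    for (r in r_times) {
      i1 <- max(1L, floor((r - 0.06) * fs) + 1L)
      i2 <- min(n, ceiling((r + 0.06) * fs) + 1L)
      idx <- i1:i2
      ecg[idx] <- ecg[idx] + exp(-(tt[idx] - r)^2 / (2 * 0.008^2))
    }
    ecg <- ecg + spec$noise_sd * stats::rnorm(n)

    gt <- list(r_times = r_times,
               ppg_onset_times = onsets,
               pat_true = spec$pat_true,
               sbp_true = spec$sbp,
               category_true = label_bp_category(min(max(spec$sbp, 51), 299)),
               fiducial_rel = template_landmarks(spec$morphology,
                                                 base_period, fs))
    structure(list(subject_id = spec$subject_id, fs = fs,
                   ecg = ecg, abp = abp, ppg = ppg,
                   duration = spec$duration, ground_truth = gt,
                   spec = spec),
              class = "ppgbp_record")
  })
}

#' @export
print.ppgbp_record <- function(x, ...) {
  cat(sprintf("<ppgbp_record> subject %s: %.0f s at %g Hz, %d beats (truth: SBP %.1f, %s)\n",
              x$subject_id, x$duration, x$fs,
              length(x$ground_truth$r_times),
              x$ground_truth$sbp_true, x$ground_truth$category_true))
  invisible(x)
}

# class-level morphology defaults: index 0 = normotension, 1 = prehypertension,
# 2 = hypertension; shifts scaled by class_effect. Stiffer vessels give a
# faster upstroke, a larger and earlier reflected/dicrotic wave and a
# shallower notch.
class_morphology <- function(class_idx, class_effect, jitter_sd = 1) {
  k <- class_idx * class_effect
  clamp <- function(v, lo, hi) min(max(v, lo), hi)
  morphology_params(
    systolic_width = clamp(0.065 - 0.0045 * k +
                             jitter_sd * stats::rnorm(1, 0, 0.004), 0.045, 0.085),
    dicrotic_amplitude = clamp(0.30 + 0.09 * k +
                                 jitter_sd * stats::rnorm(1, 0, 0.04), 0.05, 0.95),
    dicrotic_delay = clamp(0.34 - 0.02 * k +
                             jitter_sd * stats::rnorm(1, 0, 0.02), 0.27, 0.44),
    notch_depth = clamp(0.85 - 0.18 * k +
                          jitter_sd * stats::rnorm(1, 0, 0.05), 0.05, 1),
    baseline_wander_amp = 0.05,
    baseline_wander_freq = 0.25
  )
}

#' Generate a cohort of synthetic subjects
#'
#' Draws SBP uniformly within each category's band (normotension 100-119,
#' prehypertension 120-139, hypertension 140-180 mmHg by default
#' thresholds), links the true PAT to SBP by a negative-slope linear model
#' with subject-level noise, and shifts pulse morphology monotonically with
#' category, scaled by `class_effect` (0 = identical morphology
#' distributions across classes).
#'
#' @param n_normo,n_prehyp,n_hyp subject counts per category.
#' @param class_effect non-negative scale of the between-class morphology
#'   shift.
#' @param seed integer seed; the cohort is reproducible given all arguments.
#' @param noise_sd per-subject additive noise level (fraction of pulse
#'   amplitude).
#' @param pat_slope PAT decrease per mmHg SBP (s/mmHg). The intercept is
#'   chosen so PAT = 0.275 s at SBP 140, spanning roughly 0.20-0.35 s over
#'   SBP 100-180 at the default slope.
#' @param pat_noise_sd subject-level SD (s) of the PAT around the linear
#'   PAT-SBP trend (emulates imperfect ECG/PPG synchronization).
#' @param morph_jitter scale of the within-class subject-to-subject
#'   morphology variability (1 = default SDs, 0 = every subject of a class
#'   shares one pulse shape).
#' @param duration,fs record length (s) and sampling rate (Hz).
#' @return List of [generate_subject()] records.
#' @export
generate_cohort <- function(n_normo, n_prehyp, n_hyp,
                            class_effect = 1, seed = 1L,
                            noise_sd = 0.05,
                            pat_slope = 0.001875,
                            pat_noise_sd = 0.035,
                            morph_jitter = 1,
                            duration = 120, fs = 125) {
  stopifnot(n_normo >= 0, n_prehyp >= 0, n_hyp >= 0, class_effect >= 0)
  counts <- c(n_normo, n_prehyp, n_hyp)
  sbp_lo <- c(100, 120, 140)
  sbp_hi <- c(119, 139, 180)
  pat0 <- 0.275 + pat_slope * 140
  records <- vector("list", sum(counts))
  idx <- 0L
  with_seed(seed, {
    for (cls in 1:3) {
      for (j in seq_len(counts[cls])) {
        idx <- idx + 1L
        sbp <- stats::runif(1, sbp_lo[cls], sbp_hi[cls])
        dbp <- min(0.55 * sbp + 10 + stats::rnorm(1, 0, 3), sbp - 20)
        hr <- min(max(stats::rnorm(1, 80, 8), 55), 110)
        pat <- pat0 - pat_slope * sbp + stats::rnorm(1, 0, pat_noise_sd)
        pat <- min(max(pat, 0.12), 0.45)
        morph <- class_morphology(cls - 1L, class_effect, morph_jitter)
        sub_seed <- (seed %% 10000L) * 100000L + idx
        spec <- subject_spec(
          subject_id = sprintf("S%03d", idx),
          heart_rate = hr, sbp = sbp, dbp = dbp, pat_true = pat,
          morphology = morph, noise_sd = noise_sd, seed = sub_seed,
          duration = duration, fs = fs)
        records[[idx]] <- generate_subject(spec)
      }
    }
  })
  records
}

#' Ground-truth summary table for a synthetic cohort
#'
#' @param records list of `ppgbp_record`s from [generate_cohort()].
#' @return data.frame with one row per subject: `subject_id`, `sbp_true`,
#'   `pat_true`, `category_true`, `n_beats`.
#' @export
cohort_truth <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    gt <- r$ground_truth
    data.frame(subject_id = r$subject_id, sbp_true = gt$sbp_true,
               pat_true = gt$pat_true,
               category_true = gt$category_true,
               n_beats = length(gt$r_times),
               stringsAsFactors = FALSE)
  }))
}
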