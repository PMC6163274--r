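#' Detect ECG R peaks
#'
#' Two-moving-average event detector: the filtered ECG is half-wave
#' rectified and squared, then an event moving average (default 97 ms) is
#' compared against a beat moving average (default 611 ms) plus a small
#' offset proportional to the mean squared signal. Blocks where the event
#' average exceeds the threshold and that are at least half the event
#' window wide are accepted; the R time is the (parabolically refined)
#' maximum of the filtered ECG within each block. A refractory period
#' (default 200 ms) keeps only the larger of two competing peaks.
#'
#' @param ecg_f filtered ECG samples.
#' @param fs sampling frequency, Hz.
#' @param config a [pipeline_config()].
#' @return Strictly increasing numeric vector of R-peak times (s); empty if
#'   no peaks are found.
#' @export
detect_r_peaks <- function(ecg_f, fs, config = pipeline_config()) {
  y <- pmax(ecg_f, 0)^2
  if (all(y == 0)) return(numeric(0))
  w1 <- max(3L, round(config$rpeak_w_peak * fs))
  ma_peak <- moving_average(y, w1)
  ma_beat <- moving_average(y, round(config$rpeak_w_beat * fs))
  thr <- ma_beat + config$rpeak_offset * mean(y)
  active <- ma_peak > thr
  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  peaks_i <- integer(0)
  for (k in which(runs$values & runs$lengths >= floor(w1 / 2))) {
    blk <- starts[k]:ends[k]
    peaks_i <- c(peaks_i, blk[which.max(ecg_f[blk])])
  }
  if (!length(peaks_i)) return(numeric(0))
  peaks_i <- sort(peaks_i)
  # refractory: drop the smaller of two peaks closer than the refractory gap
  keep <- rep(TRUE, length(peaks_i))
  last <- 1L
  for (k in seq_along(peaks_i)[-1L]) {
    if ((peaks_i[k] - peaks_i[last]) / fs < config$refractory) {
      if (ecg_f[peaks_i[k]] > ecg_f[peaks_i[last]]) {
        keep[last] <- FALSE; last <- k
      } else {
        keep[k] <- FALSE
      }
    } else {
      last <- k
    }
  }
  peaks_i <- peaks_i[keep]
  vapply(peaks_i, function(i) refine_time(ecg_f, i, fs), numeric(1))
}

#' Divide a processed record into heart beats
#'
#' One beat per consecutive R pair, covering `[r_time, r_next)`. Beats that
#' intersect the filter-transient margins at either end of the record are
#' excluded.
#'
#' @param proc a `ppgbp_processed` record from [process_record()].
#' @param r_times strictly increasing R-peak times (s).
#' @param config a [pipeline_config()].
#' @return List of beats, each a list with `r_time`, `r_next`, `i_start`,
#'   `i_end` (1-based sample indices into the record) and `fs`. Empty list
#'   if fewer than two R times are given.
#' @export
segment_beats <- function(proc, r_times, config = pipeline_config()) {
  if (length(r_times) < 2L) return(list())
  if (any(diff(r_times) <= 0)) stop("non-monotone R sequence")
  fs <- proc$fs
  dur <- proc$n / fs
  out <- list()
  for (k in seq_len(length(r_times) - 1L)) {
    r <- r_times[k]; rn <- r_times[k + 1L]
    if (r < proc$margin || rn > dur - proc$margin) next
    i_start <- floor(r * fs) + 1L
    i_end <- floor(rn * fs)
    if (i_start < 1L || i_end > proc$n || i_end - i_start < 4L) next
    out[[length(out) + 1L]] <- list(r_time = r, r_next = rn,
                                    i_start = i_start, i_end = i_end,
                                    fs = fs)
  }
  out
}

# the full landmark inventory, in canonical order, with its signal level
fid_inventory <- local({
  base <- c(O = "ppg", S = "ppg", N = "ppg", D = "ppg", O_next = "ppg",
            w = "vpg", x = "vpg", y = "vpg", z = "vpg",
            a = "apg", b = "apg", c = "apg", d = "apg", e = "apg")
  marks <- c(names(base),
             paste0(c("w", "x", "y", "z"), "_-1"),
             paste0(rep(c("a", "b", "c", "d", "e"), each = 2),
                    c("_-1", "_-2")))
  lvl <- vapply(marks, function(mk) {
    b <- sub("_-[12]$", "", mk)
    k <- if (grepl("_-1$", mk)) 1L else if (grepl("_-2$", mk)) 2L else 0L
    src <- match(base[[b]], c("ppg", "vpg", "apg")) - 1L
    c("ppg", "vpg", "apg")[src - k + 1L]
  }, character(1))
  data.frame(landmark = marks, level = unname(lvl),
             stringsAsFactors = FALSE)
})

#' Locate the fiducial landmarks of one beat
#'
#' Works down the derivative chain: the systolic peak S is the PPG maximum
#' in the beat and the onset O the PPG minimum between the R wave and S; the
#' VPG maximum w sits on the upstroke; the APG a wave is the early maximum,
#' b the following minimum, and c, d, e the subsequent alternating local
#' extrema; the dicrotic notch N is the PPG local minimum nearest the
#' e-wave time (falling back to the e time itself when the notch does not
#' reach a PPG-level minimum) and the diastolic peak D the first PPG local
#' maximum after N. Projections `q_-1` / `q_-2` sample the signal one / two
#' derivative levels below at exactly the source landmark's time.
#'
#' PPG amplitudes are measured from the beat baseline (the PPG value at O);
#' VPG and APG amplitudes from their zero lines. Landmark times are
#' parabolically refined to sub-sample precision.
#'
#' @param proc a `ppgbp_processed` record.
#' @param beat one element of [segment_beats()].
#' @param config a [pipeline_config()].
#' @return A data.frame (`landmark`, `level`, `index`, `time`, `amplitude`,
#'   `present`) with attributes `r_time` and `baseline`; `NULL` if the beat
#'   is invalid (S or O undetectable).
#' @export
locate_fiducials <- function(proc, beat, config = pipeline_config()) {
  fs <- proc$fs
  p <- proc$ppg_n; v <- proc$vpg; a2 <- proc$apg
  W <- beat$i_start:beat$i_end
  if (length(W) < 5L || !all(is.finite(p[W]))) return(NULL)
  if (max(p[W]) - min(p[W]) <= 0) return(NULL)

  nm <- fid_inventory$landmark
  idxv <- structure(rep(NA_integer_, length(nm)), names = nm)
  timev <- structure(rep(NA_real_, length(nm)), names = nm)
  ampv <- structure(rep(NA_real_, length(nm)), names = nm)
  put <- function(mk, i, tt, aa) {
    idxv[[mk]] <<- i; timev[[mk]] <<- tt; ampv[[mk]] <<- aa
  }

  iS <- W[which.max(p[W])]
  pre <- W[W <= iS]
  if (length(pre) < 2L) return(NULL)
  iO <- pre[which.min(p[pre])]
  if (iO == iS) return(NULL)
  baseline <- p[iO]
  put("O", iO, refine_time(p, iO, fs), 0)
  put("S", iS, refine_time(p, iS, fs), p[iS] - baseline)

  up <- pre[pre >= iO]
  iw <- up[which.max(v[up])]
  put("w", iw, refine_time(v, iw, fs), v[iw])

  awin <- W[W >= iO & W <= min(iw + round(config$a_window * fs), iS)]
  ia <- if (length(awin)) awin[which.max(a2[awin])] else NA_integer_
  if (!is.na(ia)) put("a", ia, refine_time(a2, ia, fs), a2[ia])

  ib <- NA_integer_
  if (!is.na(ia) && ia < beat$i_end) {
    post <- W[W > ia]
    ib <- post[which.min(a2[post])]
    put("b", ib, refine_time(a2, ib, fs), a2[ib])
  }

  # diastolic landmarks belong to the pulse launched in this beat, which can
  # spill past the next R wave at short periods; search from the systolic
  # peak (the onset minimum is biased early by filter undershoot) over
  # cde_frac of a period, capped at the record end
  bound <- min(iS + round(config$cde_frac * length(W)), proc$n)
  ic <- id <- ie <- NA_integer_
  if (!is.na(ib) && ib + 1L < bound) {
    cde <- (ib + 1L):bound
    mx <- cde[local_maxima(a2[cde])]
    mn <- cde[local_minima(a2[cde])]
    tol <- config$apg_prominence * (max(a2[W]) - min(a2[W]))
    kept <- prune_extrema(a2, c(mx, mn), tol)
    kmx <- kept[kept %in% mx]; kmn <- kept[kept %in% mn]
    if (length(kmx)) {
      ic <- kmx[1L]
      put("c", ic, refine_time(a2, ic, fs), a2[ic])
      kmn <- kmn[kmn > ic]
      if (length(kmn)) {
        id <- kmn[1L]
        put("d", id, refine_time(a2, id, fs), a2[id])
        kmx <- kmx[kmx > id]
        if (length(kmx)) {
          ie <- kmx[1L]
          put("e", ie, refine_time(a2, ie, fs), a2[ie])
        }
      }
    }
  }

  dia <- (iS + 1L):bound
  dia <- dia[dia <= proc$n]
  if (length(dia) > 3L) {
    ix <- dia[which.min(v[dia])]
    put("x", ix, refine_time(v, ix, fs), v[ix])
    ymx <- dia[local_maxima(v[dia])]
    ymx <- ymx[ymx > ix]
    if (length(ymx)) {
      iy <- ymx[1L]
      put("y", iy, refine_time(v, iy, fs), v[iy])
      zmn <- dia[local_minima(v[dia])]
      zmn <- zmn[zmn > iy]
      if (length(zmn)) put("z", zmn[1L], refine_time(v, zmn[1L], fs), v[zmn[1L]])
    }
  }

  if (!is.na(ie)) {
    Wx <- beat$i_start:bound
    pmins <- Wx[local_minima(p[Wx])]
    pmins <- pmins[pmins > iS]
    iN <- NA_integer_
    if (length(pmins)) {
      iN <- pmins[which.min(abs(pmins - ie))]
      put("N", iN, refine_time(p, iN, fs), p[iN] - baseline)
    } else {
      # notch does not reach a PPG-level minimum: fall back to the e time
      iN <- ie
      put("N", ie, refine_time(a2, ie, fs), p[ie] - baseline)
    }
    pmaxs <- Wx[local_maxima(p[Wx])]
    pmaxs <- pmaxs[pmaxs > iN]
    if (length(pmaxs)) {
      iD <- pmaxs[1L]
      put("D", iD, refine_time(p, iD, fs), p[iD] - baseline)
    }
  }

  # next onset: PPG minimum in a lookahead window past the beat end
  period <- beat$i_end - beat$i_start + 1L
  la <- beat$i_end:min(beat$i_end + round(0.6 * period), proc$n)
  if (length(la) > 3L) {
    iOn <- la[which.min(p[la])]
    put("O_next", iOn, refine_time(p, iOn, fs), p[iOn] - baseline)
  }

  # projections share the source landmark's time exactly
  for (q in c("w", "x", "y", "z")) {
    i <- idxv[[q]]
    if (!is.na(i)) put(paste0(q, "_-1"), i, timev[[q]], p[i] - baseline)
  }
  for (q in c("a", "b", "c", "d", "e")) {
    i <- idxv[[q]]
    if (!is.na(i)) {
      put(paste0(q, "_-1"), i, timev[[q]], v[i])
      put(paste0(q, "_-2"), i, timev[[q]], p[i] - baseline)
    }
  }

  out <- data.frame(landmark = nm, level = fid_inventory$level,
                    index = unname(idxv), time = unname(timev),
                    amplitude = unname(ampv), present = !is.na(idxv),
                    stringsAsFactors = FALSE)
  attr(out, "r_time") <- beat$r_time
  attr(out, "baseline") <- baseline
  out
}

#' Look up one landmark's time or amplitude
#'
#' @param fids a fiducial set from [locate_fiducials()].
#' @param landmark landmark name, e.g. `"S"`, `"b"`, `"c_-2"`.
#' @return The requested scalar, or `NA` if the landmark is absent.
#' @export
fid_time <- function(fids, landmark) {
  i <- match(landmark, fids$landmark)
  if (is.na(i) || !fids$present[i]) NA_real_ else fids$time[i]
}

#' @rdname fid_time
#' @export
fid_amp <- function(fids, landmark) {
  i <- match(landmark, fids$landmark)
  if (is.na(i) || !fids$present[i]) NA_real_ else fids$amplitude[i]
}
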