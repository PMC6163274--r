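test_that("R-peak detection recovers the true beat times on clean data", {
  rec <- generate_subject(quiet_spec("x", heart_rate = 60, seed = 5,
                                     duration = 60))
  proc <- process_record(rec)
  r_det <- detect_r_peaks(proc$ecg_f, proc$fs)
  gt <- rec$ground_truth$r_times
  expect_lte(abs(length(r_det) - length(gt)), 1)
  # match each detected peak to the nearest truth
  err <- vapply(r_det, function(r) min(abs(gt - r)), numeric(1))
  expect_lt(max(err), 1 / 125)
})

test_that("R detector returns empty on flat input and honours the refractory", {
  expect_length(detect_r_peaks(rep(0, 1000), 125), 0)
  rec <- generate_subject(quiet_spec("x", heart_rate = 178, seed = 6,
                                     duration = 30))
  r_det <- detect_r_peaks(process_record(rec)$ecg_f, 125)
  expect_gt(length(r_det), 10)
  expect_true(all(diff(r_det) >= 0.2))
})

test_that("beat segmentation pairs consecutive R waves and trims margins", {
  rec <- clean_record()
  proc <- process_record(rec)
  r <- seq(2, 28, by = 1)
  beats <- segment_beats(proc, r)
  expect_length(beats, length(r) - 1)
  expect_equal(beats[[1]]$r_time, 2)
  expect_lt(beats[[1]]$i_end, beats[[2]]$i_start + 1)

  # beats inside the transient margins are excluded
  expect_length(segment_beats(proc, c(0.2, 0.9, 2, 3)), 1)
  expect_length(segment_beats(proc, 5), 0)
  expect_error(segment_beats(proc, c(5, 5, 6)), "non-monotone")
})

test_that("fiducials of a clean beat sit where the template puts them", {
  rec <- clean_record()
  gt <- rec$ground_truth
  proc <- process_record(rec)
  beats <- segment_beats(proc, detect_r_peaks(proc$ecg_f, proc$fs))
  fids <- locate_fiducials(proc, beats[[5]])
  k <- which(gt$r_times >= beats[[5]]$r_time - 0.05 &
               gt$r_times < beats[[5]]$r_next - 0.05)
  onset <- gt$ppg_onset_times[k]
  for (mk in c("S", "N", "D", "w", "a", "b", "c", "d", "e")) {
    expect_lt(abs(fid_time(fids, mk) - (onset + gt$fiducial_rel[[mk]])),
              2 / 125)
  }
})

test_that("a single-lobe pulse yields no notch or diastolic landmarks", {
  m <- morphology_params(dicrotic_amplitude = 0, baseline_wander_amp = 0)
  rec <- generate_subject(quiet_spec("x", morphology = m, seed = 8))
  proc <- process_record(rec)
  beats <- segment_beats(proc, detect_r_peaks(proc$ecg_f, proc$fs))
  fids <- locate_fiducials(proc, beats[[3]])
  for (mk in c("O", "S", "w", "a", "b")) {
    expect_false(is.na(fid_time(fids, mk)))
  }
  expect_true(is.na(fid_time(fids, "N")))
  expect_true(is.na(fid_time(fids, "D")))
})

test_that("projected points copy the source time and sample the lower level", {
  rec <- clean_record()
  proc <- process_record(rec)
  beats <- segment_beats(proc, detect_r_peaks(proc$ecg_f, proc$fs))
  fids <- locate_fiducials(proc, beats[[4]])
  base <- attr(fids, "baseline")
  for (q in c("a", "b", "c", "d", "e")) {
    i <- fids$index[match(q, fids$landmark)]
    expect_identical(fid_time(fids, paste0(q, "_-1")), fid_time(fids, q))
    expect_identical(fid_time(fids, paste0(q, "_-2")), fid_time(fids, q))
    expect_identical(fid_amp(fids, paste0(q, "_-1")), proc$vpg[i])
    expect_identical(fid_amp(fids, paste0(q, "_-2")), proc$ppg_n[i] - base)
  }
  expect_identical(fid_amp(fids, "O"), 0)
})

test_that("landmark ordering holds across randomized morphologies", {
  set.seed(99)
  for (k in 1:8) {
    m <- morphology_params(
      systolic_width = runif(1, 0.055, 0.075),
      dicrotic_amplitude = runif(1, 0.2, 0.5),
      dicrotic_delay = runif(1, 0.26, 0.4),
      notch_depth = runif(1, 0.4, 1))
    rec <- generate_subject(quiet_spec("x", morphology = m, seed = 100 + k,
                                       duration = 20))
    proc <- process_record(rec)
    beats <- segment_beats(proc, detect_r_peaks(proc$ecg_f, proc$fs))
    for (b in beats) {
      fids <- locate_fiducials(proc, b)
      if (is.null(fids)) next
      tt <- function(mk) fid_time(fids, mk)
      expect_true(tt("O") <= tt("w") && tt("w") <= tt("S"))
      ord <- c(tt("a"), tt("b"), tt("c"), tt("d"), tt("e"))
      ord <- ord[!is.na(ord)]
      expect_true(all(diff(ord) > 0))
      if (!is.na(tt("N")) && !is.na(tt("D"))) {
        expect_true(tt("S") < tt("N") && tt("N") < tt("D"))
      }
    }
  }
})

test_that("the detector is translation-equivariant", {
  rec <- clean_record()
  k <- 25L                              # shift by 0.2 s
  shift <- function(x) c(x[(k + 1):length(x)], x[1:k])
  rec2 <- rec
  rec2$ecg <- shift(rec$ecg); rec2$ppg <- shift(rec$ppg)
  rec2$abp <- shift(rec$abp)
  p1 <- process_record(rec); p2 <- process_record(rec2)
  b1 <- segment_beats(p1, detect_r_peaks(p1$ecg_f, 125))
  b2 <- segment_beats(p2, detect_r_peaks(p2$ecg_f, 125))
  f1 <- locate_fiducials(p1, b1[[6]])
  # the same physiological beat sits one beat earlier after the shift
  match_beat <- which(abs(vapply(b2, `[[`, numeric(1), "r_time") -
                            (b1[[6]]$r_time - k / 125)) < 1e-3)
  f2 <- locate_fiducials(p2, b2[[match_beat]])
  for (mk in c("O", "S", "w", "a", "b")) {
    i1 <- f1$index[match(mk, f1$landmark)]
    i2 <- f2$index[match(mk, f2$landmark)]
    expect_identical(i2, i1 - k)
    # sub-sample refinement may wobble with the filter's edge transients
    expect_equal(fid_time(f2, mk), fid_time(f1, mk) - k / 125,
                 tolerance = 0.5 / 125)
  }
})
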