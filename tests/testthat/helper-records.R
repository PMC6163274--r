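# Shared fixtures, built in code. Short records keep the unit tests fast;
# the acceptance suite uses full-length cohorts.

quiet_spec <- function(..., duration = 30, noise_sd = 0) {
  subject_spec(..., duration = duration, noise_sd = noise_sd)
}

# one clean 30 s record reused across unit tests
clean_record <- local({
  rec <- NULL
  function() {
    if (is.null(rec)) {
      rec <<- generate_subject(quiet_spec("T001", heart_rate = 75,
                                          sbp = 120, dbp = 80,
                                          pat_true = 0.25, seed = 404))
    }
    rec
  }
})

# hand-built fiducial set: a minimal table with the landmarks the feature
# formulas consume, plus a matching fake processed record for power areas
make_hand_fids <- function(times, amps, indices, ppg_n, baseline = 0,
                           fs = 125) {
  marks <- names(times)
  fids <- data.frame(landmark = marks,
                     level = NA_character_,
                     index = unname(indices[marks]),
                     time = unname(times[marks]),
                     amplitude = unname(amps[marks]),
                     present = TRUE, stringsAsFactors = FALSE)
  attr(fids, "baseline") <- baseline
  attr(fids, "r_time") <- 0
  list(fids = fids, proc = list(ppg_n = ppg_n, fs = fs))
}

# random hand-built fiducial geometry with consistent times/indices
random_hand_fids <- function(seed) {
  set.seed(seed)
  fs <- 125
  n <- 120
  ppg_n <- runif(n, -0.02, 0.06)
  base_idx <- sort(sample(10:(n - 20), 7))
  names(base_idx) <- c("O", "S", "c", "d", "b", "w", "O_next")
  # impose the index relations the formulas rely on (projections share the
  # source's index): order O < w < b < S < c < d < O_next
  idx <- c(O = base_idx[[1]], w = base_idx[[2]], b = base_idx[[3]],
           S = base_idx[[4]], c = base_idx[[5]], d = base_idx[[6]],
           O_next = base_idx[[7]])
  times <- (idx - 1) / fs + runif(7, -0.003, 0.003)
  names(times) <- names(idx)
  baseline <- ppg_n[idx[["O"]]]
  amp_ppg <- function(i) ppg_n[i] - baseline
  # APG / VPG amplitudes drawn directly
  amps <- c(O = 0, S = amp_ppg(idx[["S"]]),
            w = runif(1, 0.2, 0.6),
            a = runif(1, 2, 8), b = runif(1, -10, -2),
            c = runif(1, 0.5, 3), d = runif(1, -3, -0.5),
            "c_-1" = runif(1, -0.5, -0.1),
            "b_-2" = amp_ppg(idx[["b"]]),
            "c_-2" = amp_ppg(idx[["c"]]),
            "d_-2" = amp_ppg(idx[["d"]]),
            O_next = amp_ppg(idx[["O_next"]]))
  all_times <- c(times["O"], times["S"], w = unname(times["w"]),
                 a = unname(times["w"]) - 0.01, b = unname(times["b"]),
                 c = unname(times["c"]), d = unname(times["d"]),
                 "c_-1" = unname(times["c"]), "b_-2" = unname(times["b"]),
                 "c_-2" = unname(times["c"]), "d_-2" = unname(times["d"]),
                 O_next = unname(times["O_next"]))
  all_idx <- c(idx["O"], idx["S"], w = unname(idx["w"]),
               a = unname(idx["w"]), b = unname(idx["b"]),
               c = unname(idx["c"]), d = unname(idx["d"]),
               "c_-1" = unname(idx["c"]), "b_-2" = unname(idx["b"]),
               "c_-2" = unname(idx["c"]), "d_-2" = unname(idx["d"]),
               O_next = unname(idx["O_next"]))
  make_hand_fids(all_times, amps, all_idx, ppg_n, baseline, fs)
}

# independent hand computation of the ten features from a hand-built set
hand_table1 <- function(h) {
  f <- h$fids; p <- h$proc$ppg_n; bl <- attr(f, "baseline")
  g <- function(mk, col) f[[col]][match(mk, f$landmark)]
  t_ <- function(mk) g(mk, "time"); a_ <- function(mk) g(mk, "amplitude")
  i_ <- function(mk) g(mk, "index")
  c(f1 = sum(p[i_("S"):i_("c_-2")]^2) / sum(p[i_("O"):i_("O_next")]^2),
    f2 = (a_("d_-2") - a_("b_-2")) / (t_("d_-2") - t_("b_-2")),
    f3 = t_("c_-2") - t_("S"),
    f4 = a_("c_-2") / a_("S"),
    f5 = t_("d_-2") - t_("S"),
    f6 = (a_("b") - a_("c") - a_("d")) / a_("a"),
    f7 = a_("d"),
    f8 = a_("c_-1") / a_("w"),
    f9 = a_("d") / a_("a"),
    f10 = (a_("c_-2") - a_("S")) / (t_("c_-2") - t_("S")))
}
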