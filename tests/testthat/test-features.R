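test_that("PAT is the R-to-b_-2 interval and missing b propagates", {
  h <- random_hand_fids(1)
  tb <- h$fids$time[match("b", h$fids$landmark)]
  expect_equal(compute_pat(0.1, h$fids), tb - 0.1)
  h$fids$present[h$fids$landmark %in% c("b", "b_-2")] <- FALSE
  expect_true(is.na(compute_pat(0.1, h$fids)))
})

test_that("span, amplitude, area, slope and composite operators are exact", {
  h <- random_hand_fids(2)
  f <- h$fids
  tS <- f$time[f$landmark == "S"]; tc <- f$time[f$landmark == "c_-2"]
  expect_equal(time_span(f, "S", "c_-2"), tc - tS)
  expect_equal(time_span(f, "S", "S"), 0)
  expect_equal(time_span(f, "c_-2", "S"), -(tc - tS))
  expect_equal(amplitude(f, "O"), 0)

  iS <- f$index[f$landmark == "S"]; iO <- f$index[f$landmark == "O"]
  bl <- attr(f, "baseline")
  expect_equal(waveform_area(h$proc, f, "O", "S"),
               sum(h$proc$ppg_n[iO:iS] - bl))
  expect_equal(power_area(h$proc, f, "O", "S"), sum(h$proc$ppg_n[iO:iS]^2))
  expect_gte(power_area(h$proc, f, "O", "S"), 0)
  expect_error(power_area(h$proc, f, "S", "O"), "out of order")
  # split additivity of the inclusive-endpoint waveform area
  iw <- f$index[f$landmark == "w"]
  expect_equal(waveform_area(h$proc, f, "O", "S"),
               waveform_area(h$proc, f, "O", "w") +
                 waveform_area(h$proc, f, "w", "S") -
                 (h$proc$ppg_n[iw] - bl))

  expect_equal(slope(f, "S", "c_-2"), slope(f, "c_-2", "S"))
  a <- amplitude(f, "a"); b <- amplitude(f, "b")
  cc <- amplitude(f, "c"); d <- amplitude(f, "d")
  expect_equal(apg_composite(f, "b/a"), b / a)
  expect_equal(apg_composite(f, "(b-c-d)/a"), (b - cc - d) / a)
})

test_that("the ten features match an independent hand computation", {
  for (seed in 1:25) {
    h <- random_hand_fids(seed)
    got <- compute_table1_features(h$proc, h$fids)
    expect_equal(got, hand_table1(h), tolerance = 1e-12,
                 info = paste("hand-built set", seed))
  }
})

test_that("feature homogeneity under rescaling of the normalized PPG", {
  h <- random_hand_fids(3)
  k <- 2.7
  h2 <- h
  h2$proc$ppg_n <- k * h$proc$ppg_n
  ppg_marks <- c("O", "S", "b_-2", "c_-2", "d_-2", "O_next")
  sel <- h2$fids$landmark %in% ppg_marks
  h2$fids$amplitude[sel] <- k * h2$fids$amplitude[sel]
  attr(h2$fids, "baseline") <- k * attr(h$fids, "baseline")
  f1v <- compute_table1_features(h$proc, h$fids)
  f2v <- compute_table1_features(h2$proc, h2$fids)
  for (inv in c("f1", "f3", "f4", "f5", "f6", "f7", "f8", "f9")) {
    expect_equal(f2v[[inv]], f1v[[inv]], info = inv)
  }
  for (hom in c("f2", "f10")) {
    expect_equal(f2v[[hom]], k * f1v[[hom]], info = hom)
  }
})

test_that("missing dicrotic structure propagates to the dependent features", {
  h <- random_hand_fids(4)
  h$fids$present[h$fids$landmark %in%
                   c("c", "d", "c_-1", "c_-2", "d_-2")] <- FALSE
  got <- compute_table1_features(h$proc, h$fids)
  expect_true(all(is.na(got[c("f1", "f2", "f3", "f4", "f5", "f6", "f7",
                              "f8", "f9", "f10")])))
})

test_that("subject aggregation is a component-wise median", {
  one <- c(pat = 0.3, f1 = 0.5)
  m <- rbind(one, one, one)
  expect_equal(aggregate_subject(m)[c("pat", "f1")], one)

  # one outlier among many identical beats does not move the aggregate
  m <- rbind(matrix(rep(one, 99), ncol = 2, byrow = TRUE,
                    dimnames = list(NULL, names(one))),
             c(pat = 9, f1 = -9))
  expect_equal(aggregate_subject(m)[c("pat", "f1")], one)

  # odd and even counts agree with a sort-based oracle
  set.seed(10)
  for (n in c(7, 8)) {
    m <- matrix(rnorm(2 * n), ncol = 2, dimnames = list(NULL, c("a", "b")))
    srt <- apply(m, 2, sort)
    oracle <- if (n %% 2) srt[(n + 1) / 2, ]
              else colMeans(srt[n / 2 + 0:1, ])
    expect_equal(aggregate_subject(m), oracle, ignore_attr = TRUE)
  }
  expect_error(aggregate_subject(matrix(NA_real_, 2, 2)), "no valid beats")
})

test_that("end-to-end feature extraction fills a labelled cohort table", {
  recs <- generate_cohort(2, 1, 1, seed = 55, duration = 20)
  tab <- cohort_feature_table(recs)
  expect_equal(nrow(tab), 4)
  expect_true(all(c("subject_id", "sbp", "label", "pat",
                    paste0("f", 1:10), "n_beats") %in% names(tab)))
  expect_true(all(tab$n_beats >= 1))
  truth <- cohort_truth(recs)
  expect_equal(tab$label, truth$category_true)
})
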