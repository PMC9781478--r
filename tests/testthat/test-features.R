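test_that("mean BP follows the diastole-weighted formula", {
  expect_equal(round(mean_bp(138.02, 82.69), 2), 101.13)
  expect_equal(mean_bp(120, 80), 93 + 1 / 3, tolerance = 1e-12)
  expect_error(mean_bp(80, 80), "sbp > dbp")
  expect_error(mean_bp(80, 90), "sbp > dbp")
})

test_that("beat features follow their defining arithmetic", {
  prof <- generate_subject(2)
  fid <- data.frame(beat = 1L, r_time = 1.000, rr_prev = 0.8, onset = 1.250,
                    ms = 1.200, sys_peak = 1.340, dicrotic = 1.450,
                    dia_peak = 1.530, a = 1.26, b = 1.28, c = 1.31, d = 1.33,
                    e = 1.44, p1 = 1.27, p2 = 1.33, amp_onset = -1.2,
                    amp_sys = 1.3, amp_dic = 0.1, amp_dia = 0.3, flag = "ok")
  row <- compute_beat_features(fid, list(dbp = 80, sbp = 120), prof)
  expect_equal(row$oPAT, 0.250)
  expect_equal(row$oPWV, prof$arterial_path_length / 0.250)
  expect_equal(row$MBP, mean_bp(120, 80))
  expect_equal(row$RoPAT, 0.250 / 0.8, tolerance = 1e-12)
  expect_equal(row$cT, 1.340 - 1.250, tolerance = 1e-12)
  # a fixed 1.5 m path over 0.25 s gives 6 m/s
  prof2 <- prof; prof2$arterial_path_length <- 1.5
  expect_equal(compute_beat_features(fid, list(dbp = 80, sbp = 120),
                                     prof2)$oPWV, 6)
  fid$rr_prev <- 0
  expect_error(compute_beat_features(fid, list(dbp = 80, sbp = 120), prof),
               "invalid beat")
})

test_that("table assembly drops masked beats and keeps provenance counts", {
  d <- fixture_detection()
  rec <- d$rec
  tab0 <- assemble_beat_table(d$fid, d$ab, rec$profile, "rest", mask = NULL)
  pv0 <- attr(tab0, "provenance")
  expect_equal(pv0$n_excluded, 0)
  expect_equal(pv0$n_after, nrow(tab0))
  # mask spanning beats 3-5
  r3 <- d$fid$r_time[3]; r6 <- d$fid$r_time[6]
  mask <- data.frame(start = r3 + 0.01, end = r6 - 0.01)
  tab1 <- assemble_beat_table(d$fid, d$ab, rec$profile, "rest", mask = mask)
  pv1 <- attr(tab1, "provenance")
  expect_equal(pv1$n_before - pv1$n_excluded, pv1$n_after)
  expect_equal(nrow(tab0) - nrow(tab1), 3)
  expect_false(any(tab1$beat %in% 3:5))
  expect_true(all(c("SBP", "DBP", "MBP", "oPAT", "dO", "dP") %in% names(tab1)))
})

test_that("cleaning drops NA rows first, then single-pass z outliers", {
  base <- data.frame(a = rep(0, 100), b = rnorm(100, 10, 1))
  t1 <- base
  t1$a[50] <- NA
  c1 <- clean_table(t1, z_thresh = 3)
  lg <- attr(c1, "cleaning_log")
  expect_equal(lg$n_dropped_na, 1)
  # the 101-row constructed outlier: 100 zeros and one 50 (|z| ~ 9.95)
  t2 <- data.frame(a = c(rep(0, 100), 50))
  c2 <- clean_table(t2, z_thresh = 3)
  expect_equal(nrow(c2), 100)
  expect_equal(attr(c2, "cleaning_log")$n_dropped_outlier, 1)
  # all-constant column never produces outliers
  t3 <- data.frame(a = rep(7, 30), b = rnorm(30))
  expect_equal(nrow(clean_table(t3, z_thresh = 3)), 30)
  expect_error(clean_table(t3, z_thresh = 0), "z_thresh")
})

test_that("one cleaning pass drops exactly the rows outside the pre-pass band", {
  set.seed(8)
  tab <- data.frame(x = rnorm(400), y = rnorm(400))
  tab$x[c(5, 9)] <- c(25, -30)
  out <- clean_table(tab, z_thresh = 3)
  z <- scale(tab)
  should_drop <- apply(abs(z) > 3, 1, any)
  expect_equal(nrow(out), sum(!should_drop))
  kept <- tab[!should_drop, ]
  expect_equal(out$x, kept$x)
})

test_that("end-to-end extraction reproduces the truth features closely", {
  rec <- fixture_record()
  tab <- extract_beat_table(rec, clean = TRUE)
  expect_gt(nrow(tab), 100)
  expect_equal(tab$MBP, (tab$SBP + 2 * tab$DBP) / 3, tolerance = 1e-9)
  truth <- ground_truth_beat_table(rec)
  m <- match(tab$beat, truth$beat)
  expect_lt(median(abs(tab$SBP - truth$SBP[m])), 0.3)
  expect_lt(median(abs(tab$DBP - truth$DBP[m])), 0.3)
  # onset-PAT from detection tracks the nominal law PAT up to the small
  # constant offset between nominal onset and rendered-waveform foot
  expect_lt(sd(tab$oPAT - truth$oPAT[m]), 0.004)
  expect_lt(median(abs(tab$rr - truth$rr[m])), 0.004)
})

test_that("artifact windows flow through extraction into beat exclusion", {
  rec <- fixture_record()
  rec2 <- inject_artifacts(rec, list(list(kind = "flat_line", start = 30,
                                          length = 2, channel = "abp")))
  tab <- extract_beat_table(rec2, clean = FALSE)
  mask <- attr(tab, "mask")
  expect_gte(nrow(mask), 1)
  fid <- attr(tab, "fiducials")
  rr_n <- c(diff(fid$r_time), median(diff(fid$r_time)))
  hit <- fid$r_time < 32 & (fid$r_time + rr_n) > 30
  expect_false(any(tab$beat %in% fid$beat[hit]))
})
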