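test_that("R-peak detection achieves perfect recall and precision on clean ECG", {
  d <- fixture_detection()
  tr <- d$rec$truth
  miss <- vapply(tr$r_time, function(x) min(abs(d$r - x)), numeric(1))
  expect_true(all(miss <= 0.010))                    # recall within 10 ms
  false_det <- vapply(d$r, function(x) min(abs(tr$r_time - x)) > 0.010,
                      logical(1))
  expect_equal(sum(false_det), 0)                    # precision
  expect_true(all(diff(d$r) > 0))
  expect_true(all(diff(d$r) >= 0.2))                 # refractory
})

test_that("flat ECG yields no detections and close spikes trigger the refractory", {
  expect_length(detect_r_peaks(rep(0, 5000), 1000), 0)
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  x <- exp(-(t - 1.0)^2 / (2 * 0.008^2)) + exp(-(t - 1.1)^2 / (2 * 0.008^2))
  expect_length(detect_r_peaks(x, fs), 1)            # 100 ms apart -> one
})

test_that("PPG fiducials hit ground truth within tolerance on >=95% of beats", {
  d <- fixture_detection()
  tr <- d$rec$truth
  idx <- match_truth(d$fid, tr)
  ok <- !is.na(idx)
  expect_gt(mean(ok), 0.95)
  eo <- abs(d$fid$onset - tr$ppg_onset_time[idx])[ok]
  es <- abs(d$fid$sys_peak - tr$ppg_peak_time[idx])[ok]
  expect_gte(mean(eo <= 0.002, na.rm = TRUE), 0.95)  # onset within 2 ms
  expect_gte(mean(es <= 0.005, na.rm = TRUE), 0.95)  # systolic peak within 5 ms
  ed <- abs(d$fid$dicrotic - tr$dicrotic_time[idx])[ok]
  expect_gte(mean(ed <= 0.010, na.rm = TRUE), 0.95)
})

test_that("resolved beats order their landmarks and a precedes b in d2", {
  d <- fixture_detection()
  f <- d$fid[d$fid$flag == "ok", ]
  expect_gt(nrow(f), 0)
  expect_true(all(f$r_time < f$onset))
  expect_true(all(f$onset < f$sys_peak))
  expect_true(all(f$sys_peak < f$dicrotic))
  expect_true(all(f$dicrotic <= f$dia_peak))
  ab <- !is.na(f$a) & !is.na(f$b)
  expect_true(all(f$a[ab] < f$b[ab]))
})

test_that("a pulse without a reflected lobe yields an absent dicrotic notch", {
  fs <- 1000
  t <- seq(0, 6, by = 1 / fs)
  ppg <- numeric(length(t))
  onset <- seq(0.5, 5.0, by = 0.75)
  for (o in onset) {
    v <- t - o
    # monotone decay after the systolic peak: no reflected lobe, and the
    # slow tail starts at the peak itself so no dip is created
    ppg <- ppg + ppg_pulse_template(v, ref_len = 0.75, dia_rel = 0,
                                    t_dia = 0.10, tail_c = 0.35,
                                    tail_tau = 0.30, mirror_exact = 0.0,
                                    mirror_blend = 0.02)
  }
  ppg <- pulserules:::fir_lowpass(ppg, fs, cutoff = 12)
  ppg_f <- zscore_normalize(bandpass_filter(ppg, fs, 0.5, 15))
  r_times <- onset - 0.25
  fid <- detect_ppg_fiducials(ppg_f, fs, r_times)
  mid <- fid[3:5, ]
  expect_true(all(is.na(mid$dicrotic) | is.na(mid$dia_peak) |
                    mid$flag == "missing_landmark") ||
                all(mid$flag == "missing_landmark"))
})

test_that("ABP foot and peak recover true DBP and SBP within 0.5 mmHg", {
  d <- fixture_detection()
  tr <- d$rec$truth
  ia <- d$ab$beat
  expect_gt(nrow(d$ab), 0.95 * nrow(tr))
  expect_true(all(abs(d$ab$dbp - tr$true_dbp[ia]) <= 0.5))
  expect_true(all(abs(d$ab$sbp - tr$true_sbp[ia]) <= 0.5))
  expect_true(all(d$ab$sbp > d$ab$dbp))
})

test_that("beats inside an exclusion interval are skipped, others unaffected", {
  d <- fixture_detection()
  excl <- data.frame(start = 30, end = 35)
  ab2 <- detect_abp_landmarks(d$rec$abp, d$rec$fs, d$r, exclusions = excl)
  rr_n <- c(diff(d$r), median(diff(d$r)))
  w0 <- d$r + 0.02; w1 <- w0 + rr_n
  r_in <- w0 < 35 & w1 > 30                 # beat windows overlapping the mask
  expect_false(any(ab2$beat %in% which(r_in)))
  common <- intersect(ab2$beat, d$ab$beat)
  expect_equal(ab2[match(common, ab2$beat), ],
               d$ab[match(common, d$ab$beat), ],
               ignore_attr = TRUE)
})

test_that("flat-line and flat-peak artifacts are detected and merged", {
  rec <- fixture_record()
  fs <- rec$fs
  clean_mask <- detect_flat_artifacts(rec$abp, fs, min_run = 0.2)
  expect_equal(nrow(clean_mask), 0)
  ## clip one whole beat interior so the plateau straddles its pulse peak
  i_ft <- which.min(abs(rec$truth$abp_foot_time - 40))
  f0 <- rec$truth$abp_foot_time[i_ft]
  f1 <- rec$truth$abp_foot_time[i_ft + 1]
  rec2 <- inject_artifacts(rec, list(
    list(kind = "flat_line", start = 15, length = 1, channel = "abp"),
    list(kind = "flat_peak", start = f0 + 0.02, length = f1 - f0 - 0.06,
         channel = "abp", quantile = 0.4)))
  mask <- detect_flat_artifacts(rec2$abp, fs, min_run = 0.2)
  fl <- mask[mask$kind == "flat_line", ]
  expect_equal(nrow(fl), 1)
  expect_lte(fl$start, 15.001)
  expect_gte(fl$end, 15.999)
  fp <- mask[mask$kind == "flat_peak", ]
  expect_equal(nrow(fp), 1)
  expect_gte(fp$end - fp$start, 0.2)
  expect_gte(fp$start, f0)
  expect_lte(fp$end, f1)
})

test_that("interval merging joins overlaps within a kind and sorts output", {
  m <- data.frame(start = c(5, 1, 2, 10), end = c(6, 2.5, 4, 11),
                  kind = c("flat_line", "flat_line", "flat_line", "flat_peak"))
  out <- merge_intervals(m)
  expect_equal(nrow(out), 3)
  expect_equal(out$start, c(1, 5, 10))
  expect_equal(out$end, c(4, 6, 11))
})
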