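test_that("subject generation is deterministic and physiologically bounded", {
  expect_identical(generate_subject(7), generate_subject(7))
  for (s in c(0, 3, 19, 240)) {
    p <- generate_subject(s)
    expect_gte(p$age, 13); expect_lte(p$age, 18)
    expect_equal(p$bmi, p$weight / p$height^2, tolerance = 1e-9)
    expect_gt(p$baseline_sbp, p$baseline_dbp)
    expect_gt(p$arterial_path_length, 0)
  }
  # hand arithmetic: 51.2 kg at 1.60 m is BMI 20
  expect_equal(51.2 / 1.60^2, 20, tolerance = 1e-9)
})

test_that("session generation is seed-deterministic", {
  prof <- generate_subject(5)
  sp <- session_spec("rest", duration = 20, seed = 4)
  r1 <- generate_session(prof, sp)
  r2 <- generate_session(prof, sp)
  expect_identical(r1$ppg, r2$ppg)
  expect_identical(r1$ecg, r2$ecg)
  expect_identical(r1$abp, r2$abp)
  expect_identical(r1$truth, r2$truth)
})

test_that("generated records satisfy their structural invariants", {
  rec <- fixture_record()
  tr <- rec$truth
  expect_equal(length(rec$ppg), round(rec$spec$duration * rec$fs))
  expect_equal(length(rec$ecg), length(rec$ppg))
  expect_true(all(diff(tr$r_time) > 0))
  expect_true(all(tr$ppg_onset_time > tr$r_time))
  expect_true(all(tr$ppg_peak_time > tr$ppg_onset_time))
  expect_true(all(tr$dicrotic_time > tr$ppg_peak_time))
  expect_true(all(tr$diastolic_peak_time >= tr$dicrotic_time))
  expect_true(all(tr$true_sbp > tr$true_dbp))
})

test_that("too-short sessions raise an empty-session error", {
  prof <- generate_subject(5)
  expect_error(generate_session(prof, session_spec("rest", duration = 1,
                                                   mean_rr = 0.7, seed = 1)),
               "empty session")
})

test_that("WBT shifts mean systolic pressure upward for every seed", {
  prof <- generate_subject(8)
  for (s in c(1, 2, 9)) {
    rest <- generate_session(prof, session_spec("rest", duration = 40, seed = s))
    wbt <- generate_session(prof, session_spec("wbt", duration = 40, seed = s))
    expect_gt(mean(wbt$truth$true_sbp), mean(rest$truth$true_sbp))
  }
})

test_that("a noiseless additive law is recovered exactly from the truth table", {
  law <- default_bp_law(noise_sd = 0, interaction_sbp = 0, interaction_dbp = 0)
  prof <- generate_subject(11, law = law)
  rec <- generate_session(prof, session_spec("rest", duration = 60, seed = 2))
  tab <- ground_truth_beat_table(rec)
  fit <- lm(SBP ~ I(1 / oPAT) + AM + rr, data = tab)
  cf <- prof$coupling$sbp
  expect_equal(unname(coef(fit)[2]), unname(cf["a_ipat"]), tolerance = 1e-6)
  expect_equal(unname(coef(fit)[3]), unname(cf["a_am"]), tolerance = 1e-6)
  expect_equal(unname(coef(fit)[4]), unname(cf["a_rr"]), tolerance = 1e-6)
  expect_lt(max(abs(residuals(fit))), 1e-8)
})

test_that("the ground-truth beat table is a per-beat bijection with exact MBP", {
  rec <- fixture_record()
  tab <- ground_truth_beat_table(rec)
  expect_equal(nrow(tab), nrow(rec$truth))
  expect_equal(tab$MBP, (tab$SBP + 2 * tab$DBP) / 3, tolerance = 1e-12)
  expect_equal(tab$RoPAT, tab$oPAT / tab$rr, tolerance = 1e-12)
  expect_true(all(tab$cT < tab$rr))
})

test_that("artifact injection alters only the targeted window", {
  rec <- fixture_record()
  expect_identical(inject_artifacts(rec, list()), rec)
  art <- list(list(kind = "flat_line", start = 10, length = 1, channel = "abp"),
              list(kind = "flat_peak", start = 20, length = 1.5,
                   channel = "abp", quantile = 0.95))
  rec2 <- inject_artifacts(rec, art)
  fs <- rec$fs
  w <- rec2$abp[(10 * fs + 1):(11 * fs)]
  expect_equal(var(w), 0)
  w0 <- rec$abp[(20 * fs + 1):(21.5 * fs)]
  w2 <- rec2$abp[(20 * fs + 1):(21.5 * fs)]
  expect_equal(max(w2), quantile(w0, 0.95, names = FALSE), tolerance = 1e-12)
  expect_identical(rec2$truth, rec$truth)
  expect_equal(nrow(rec2$excluded_intervals), 2)
  # samples outside the windows untouched
  expect_identical(rec2$abp[1:(10 * fs)], rec$abp[1:(10 * fs)])
  expect_warning(inject_artifacts(rec, list(list(kind = "flat_line",
                                                 start = 1e5, length = 1))),
                 "ignored")
})

test_that("records round-trip through the CSV + JSON writer", {
  rec <- generate_session(generate_subject(3),
                          session_spec("wbt", duration = 12, seed = 6))
  pre <- file.path(withr::local_tempdir(), "rec")
  write_record(rec, pre)
  rec2 <- read_record(pre)
  expect_equal(rec2$ppg, rec$ppg, tolerance = 1e-12)
  expect_equal(rec2$abp, rec$abp, tolerance = 1e-12)
  expect_equal(rec2$truth$true_sbp, rec$truth$true_sbp, tolerance = 1e-12)
  expect_equal(rec2$spec$state, "wbt")
  expect_equal(rec2$law$sbp, rec$law$sbp, tolerance = 1e-12)
})
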