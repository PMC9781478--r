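## Synthetic cardiovascular session generator.
##
## Emulates time-aligned ECG / PPG / ABP recordings of adolescents at rest and
## during an isometric weight-bearing task (WBT), with per-beat ground truth
## and a known generative law linking hemodynamic predictors to beat-to-beat
## blood pressure. Every downstream stage (filtering, fiducial detection,
## feature extraction, rule-ensemble fitting) is validated against these
## records.

#' Default generative blood-pressure law
#'
#' Per-beat pressures are produced as
#' `BP = a0 + a1/PAT + a2*AM + a3*RR + a4*I(PAT < tau)*AM
#'       + age_w*(age - 15.5) + bmi_w*(bmi - 21) + wbt_shift*I(state == wbt) + e`,
#' with `e ~ N(0, noise_sd)`. The reciprocal-PAT term encodes the usual
#' inverse relation between arrival time and pressure, and the thresholded
#' `PAT x AM` product plants a genuine non-additive interaction for the
#' rule-ensemble diagnostics to recover.
#'
#' @param noise_sd Beat-level noise SD in mmHg (applies to both targets).
#' @param interaction_sbp,interaction_dbp Weight of the threshold interaction
#'   term for each target; set to 0 for a purely additive law.
#' @return A list with components `sbp`, `dbp` (named coefficient vectors)
#'   and `tau` (PAT threshold, s).
#' @export
default_bp_law <- function(noise_sd = 2, interaction_sbp = 8,
                           interaction_dbp = 3) {
  list(
    sbp = c(a0 = 88.5, a_ipat = 6, a_am = 3, a_rr = -5, a_int = interaction_sbp,
            age_w = 0.4, bmi_w = 0.5, wbt_shift = 4.5, noise_sd = noise_sd),
    dbp = c(a0 = 63, a_ipat = 2, a_am = 1, a_rr = -2, a_int = interaction_dbp,
            age_w = 0.2, bmi_w = 0.3, wbt_shift = 4.0, noise_sd = noise_sd),
    tau = 0.245
  )
}

#' Generate a subject profile
#'
#' Draws demographic and vascular parameters of one adolescent subject
#' (age 13-18 years) plus the subject-level coefficients of the generative
#' blood-pressure law. Deterministic for a fixed seed.
#'
#' @param seed Non-negative integer seed.
#' @param law Generative law template, see [default_bp_law()].
#' @param state_shift Optional named numeric with per-state mean offsets
#'   `c(sbp = , dbp = )` overriding the law's default WBT shift.
#' @return An object of class `subject_profile`.
#' @export
generate_subject <- function(seed, law = default_bp_law(), state_shift = NULL) {
  stopifnot(length(seed) == 1, seed >= 0, seed == round(seed))
  set.seed(seed)
  age <- sample(13:18, 1)
  height <- round(stats::runif(1, 1.55, 1.85), 3)
  bmi <- round(stats::runif(1, 18, 26), 2)
  weight <- round(bmi * height^2, 1)
  # subject-level intercept scatter of the law
  law$sbp[["a0"]] <- law$sbp[["a0"]] + stats::rnorm(1, 0, 3)
  law$dbp[["a0"]] <- law$dbp[["a0"]] + stats::rnorm(1, 0, 2)
  if (!is.null(state_shift)) {
    if (!is.null(state_shift[["sbp"]])) law$sbp[["wbt_shift"]] <- state_shift[["sbp"]]
    if (!is.null(state_shift[["dbp"]])) law$dbp[["wbt_shift"]] <- state_shift[["dbp"]]
  }
  profile <- list(
    subject_id = sprintf("S%03d", seed %% 1000L),
    age = age, height = height, weight = weight / height^2 * height^2,
    bmi = weight / height^2,
    arterial_path_length = 0.5 * height,  # heart-to-finger approximation
    baseline_dbp = unname(law$dbp[["a0"]] + 11),
    baseline_sbp = unname(law$sbp[["a0"]] + 35),
    coupling = law,
    seed = as.integer(seed)
  )
  class(profile) <- "subject_profile"
  profile
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile %s> age %d y, height %.2f m, BMI %.1f kg/m2\n",
              x$subject_id, x$age, x$height, x$bmi))
  invisible(x)
}

#' Session specification
#'
#' @param state `"rest"` or `"wbt"` (isometric weight-bearing test).
#' @param duration Recording length in seconds.
#' @param fs Sampling rate, Hz.
#' @param mean_rr Mean RR interval, s. Default follows the state: 0.71 s at
#'   rest, 0.68 s during WBT.
#' @param rr_sd Stationary SD of the RR process, s.
#' @param seed Integer seed for all beat-level randomness.
#' @param noise Named numeric: measurement-noise SDs per channel,
#'   `c(ecg = , ppg = , abp = )` in channel units (ECG/PPG relative to a unit
#'   R spike / unit pulse template; ABP in mmHg).
#' @param artifacts Optional list of artifact descriptors for
#'   [inject_artifacts()], each `list(kind, start, length, channel, quantile)`.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(state = c("rest", "wbt"), duration = 120, fs = 1000,
                         mean_rr = NULL, rr_sd = 0.03, seed = 1,
                         noise = c(ecg = 0.01, ppg = 0.01, abp = 0.05),
                         artifacts = list()) {
  state <- match.arg(state)
  if (is.null(mean_rr)) mean_rr <- if (state == "rest") 0.71 else 0.68
  stopifnot(fs > 0, duration > 0, mean_rr > 0, mean_rr < duration, rr_sd >= 0)
  structure(list(state = state, duration = duration, fs = fs,
                 mean_rr = mean_rr, rr_sd = rr_sd, seed = as.integer(seed),
                 noise = noise, artifacts = artifacts),
            class = "session_spec")
}

## PPG pulse template ---------------------------------------------------------

#' PPG pulse template on a normalized beat window
#'
#' Builds one beat of the PPG contour on `[0, ref_len]`: a systolic lobe, a
#' reflected (diastolic) lobe producing the dicrotic notch and diastolic peak,
#' and a slow decay tail. A windowed start-correction pins the template to
#' zero value, zero slope and curvature `c_foot` at `v = 0`, and the last few
#' tens of milliseconds are blended into an exact time-mirror of the start,
#' so consecutive beats join in a locally *symmetric* foot valley whose
#' minimum is exactly the pulse onset. Symmetric minima pass through
#' zero-phase filtering and centered smoothing unshifted, which keeps onset
#' (and hence PAT) timing unbiased downstream; the mirrored approach also
#' yields a small pre-foot wave, as real PPG diastolic runoff often shows.
#'
#' @param v Time within the beat window, s (vector).
#' @param ref_len Reference beat length, s.
#' @param t_sys,sig_sys Center and width of the systolic lobe, s.
#' @param t_dia,sig_dia Center and width of the reflected lobe, s.
#' @param dia_rel Relative amplitude of the reflected lobe (0 removes the
#'   dicrotic notch and diastolic peak entirely).
#' @param tail_c,tail_tau Amplitude and time constant of the diastolic decay.
#' @param c_foot Second derivative of the template at both window ends
#'   (per s^2, unit amplitude); sets the sharpness of the foot valley.
#' @param margin Length of the start-correction window, s.
#' @param mirror_exact,mirror_blend The template equals the time-mirror of
#'   its start within `mirror_exact` seconds of the window end, blending back
#'   into the natural decay tail by `mirror_blend` seconds from the end.
#' @return Numeric vector of template values (unit systolic amplitude).
#' @export
ppg_pulse_template <- function(v, ref_len = 0.71, t_sys = 0.10, sig_sys = 0.035,
                               t_dia = 0.30, sig_dia = 0.065, dia_rel = 0.45,
                               tail_c = 0.18, tail_tau = 0.22, c_foot = 120,
                               margin = 0.10, mirror_exact = 0.03,
                               mirror_blend = 0.10) {
  raw <- function(u) {
    exp(-(u - t_sys)^2 / (2 * sig_sys^2)) +
      dia_rel * exp(-(u - t_dia)^2 / (2 * sig_dia^2)) +
      tail_c * stats::plogis((u - t_dia) / 0.02) * exp(-(u - t_dia) / tail_tau)
  }
  L <- ref_len
  eps <- 1e-5
  f0 <- raw(0)
  d0 <- (raw(eps) - raw(-eps)) / (2 * eps)
  dd0 <- (raw(eps) - 2 * f0 + raw(-eps)) / eps^2
  ## start shape: raw plus a local correction (A + B u + C u^2)(1 - u/m)^3
  ## forcing value 0, slope 0 and curvature c_foot at u = 0
  A <- -f0
  B <- -d0 + 3 * A / margin
  C <- (c_foot - dd0) / 2 + 3 * B / margin - 3 * A / margin^2
  S <- function(u) {
    phi <- ifelse(u < margin & u >= 0, (1 - u / margin)^3, 0)
    s <- raw(u) + (A + B * u + C * u^2) * phi
    ## exact parabolic core so the foot valley is symmetric to high order
    psi <- pmin(pmax((u - 0.015) / 0.02, 0), 1)
    psi <- psi * psi * (3 - 2 * psi)
    psi * s + (1 - psi) * 0.5 * c_foot * u^2
  }
  u_end <- L - v
  w <- (u_end - mirror_exact) / (mirror_blend - mirror_exact)
  w <- pmin(pmax(w, 0), 1)
  w <- w * w * (3 - 2 * w)          # smoothstep: 0 near the end, 1 inland
  out <- w * S(v) + (1 - w) * S(u_end)
  out[v < 0 | v > L] <- 0
  out
}

## locate landmarks of the unit template once, on a fine grid
template_landmarks <- function(ref_len = 0.71, ...) {
  dv <- 1e-4
  v <- seq(0, ref_len, by = dv)
  p <- ppg_pulse_template(v, ref_len = ref_len, ...)
  dp <- diff(p) / dv
  sys_i <- which.max(p[v < 0.6 * ref_len])
  ms_i <- which.max(dp[seq_len(sys_i)])
  # dicrotic notch: local minimum after the systolic peak
  post <- seq(sys_i + 1, length(p) - 1)
  locmin <- post[p[post] < p[post - 1] & p[post] <= p[post + 1]]
  locmin <- locmin[v[locmin] < 0.75 * ref_len]
  dic_i <- if (length(locmin)) locmin[1] else NA_integer_
  dia_i <- NA_integer_
  if (!is.na(dic_i)) {
    post2 <- seq(dic_i + 1, length(p) - 1)
    locmax <- post2[p[post2] > p[post2 - 1] & p[post2] >= p[post2 + 1]]
    if (length(locmax)) dia_i <- locmax[1]
  }
  list(sys = v[sys_i], ms = v[ms_i],
       dic = if (is.na(dic_i)) NA_real_ else v[dic_i],
       dia = if (is.na(dia_i)) NA_real_ else v[dia_i])
}

## ABP pulse lobe on s in [0,1]: zero at both feet, unit maximum at s* = 0.5^(4/3)
abp_pulse_lobe <- function(s) sin(pi * pmin(pmax(s, 0), 1)^0.75)^2

## zero-phase FIR lowpass (windowed sinc); pads with zeros at the edges
fir_lowpass <- function(x, fs, cutoff = 12, order = round(0.4 * fs)) {
  if (order %% 2 == 1) order <- order + 1
  h <- signal::fir1(order, cutoff / (fs / 2))
  pad <- length(h)
  y <- stats::filter(c(rep(0, pad), x, rep(0, pad)), h, sides = 2)
  as.numeric(y)[(pad + 1):(pad + length(x))]
}

## re-measure landmark times on the rendered (bandlimited) waveform in small
## windows around their nominal positions; sub-sample parabolic refinement
measure_landmark <- function(x, fs, nominal, half_s, maximum) {
  n <- length(x)
  out <- nominal
  for (k in seq_along(nominal)) {
    if (is.na(nominal[k])) next
    i <- round(nominal[k] * fs) + 1
    h <- round(half_s * fs)
    if (i - h < 1 || i + h > n) next
    seg <- (i - h):(i + h)
    ic <- seg[if (maximum) which.max(x[seg]) else which.min(x[seg])]
    idx <- if (maximum) refine_extremum(x, ic, 3L, TRUE)
           else refine_valley_quadratic(x, ic, round(0.012 * fs))
    out[k] <- (idx - 1) / fs
  }
  out
}

## Evaluate per-beat BP law; returns data.frame(sbp, dbp)
eval_bp_law <- function(law, pat, am, rr, profile, state, noise = TRUE) {
  one <- function(cf) {
    mu <- cf[["a0"]] + cf[["a_ipat"]] / pat + cf[["a_am"]] * am +
      cf[["a_rr"]] * rr + cf[["a_int"]] * (pat < law$tau) * am +
      cf[["age_w"]] * (profile$age - 15.5) + cf[["bmi_w"]] * (profile$bmi - 21) +
      cf[["wbt_shift"]] * (state == "wbt")
    if (noise && cf[["noise_sd"]] > 0) mu <- mu + stats::rnorm(length(pat), 0, cf[["noise_sd"]])
    mu
  }
  data.frame(sbp = one(law$sbp), dbp = one(law$dbp))
}

#' Generate a synthetic ECG/PPG/ABP session
#'
#' Produces a fully annotated, time-aligned recording for one subject and one
#' state. RR intervals follow an AR(1) process (coefficient 0.8) around
#' `spec$mean_rr`; each beat places an ECG complex (dominant R spike plus
#' small P and T waves), a PPG pulse whose onset lags the R peak by the
#' beat's pulse arrival time (PAT), and an ABP wave whose per-beat minimum
#' and maximum equal the ground-truth DBP and SBP. Beat-level SBP/DBP are
#' drawn from the subject's generative law (see [default_bp_law()]).
#'
#' @param profile A [generate_subject()] profile.
#' @param spec A [session_spec()].
#' @return An object of class `bp_record`: list with `t`, `ecg`, `ppg`, `abp`
#'   sample vectors, `fs`, a `truth` data frame of per-beat annotations,
#'   `excluded_intervals`, the `law` actually used, `profile` and `spec`.
#' @export
generate_session <- function(profile, spec) {
  stopifnot(inherits(profile, "subject_profile"), inherits(spec, "session_spec"))
  fs <- spec$fs
  n <- round(spec$duration * fs)
  set.seed(spec$seed)

  ## beat skeleton: AR(1) RR series
  phi <- 0.8
  margin <- 1.0                      # leave room for the final full beat
  max_beats <- ceiling(spec$duration / max(spec$mean_rr - 4 * spec$rr_sd, 0.3)) + 2
  innov <- stats::rnorm(max_beats, 0, spec$rr_sd * sqrt(1 - phi^2))
  rr <- numeric(max_beats)
  rr[1] <- spec$mean_rr + stats::rnorm(1, 0, spec$rr_sd)
  for (i in 2:max_beats) rr[i] <- spec$mean_rr + phi * (rr[i - 1] - spec$mean_rr) + innov[i]
  rr <- pmin(pmax(rr, 0.4), 1.5)
  r_times <- 0.35 + cumsum(c(0, rr[-max_beats]))
  keep <- r_times <= spec$duration - margin
  if (!any(keep)) stop("empty session: duration too short for one beat")
  r_times <- r_times[keep]
  nb <- length(r_times)
  rr_next <- diff(c(r_times, r_times[nb] + rr[nb + 1]))
  rr_prev <- c(rr_next[1], rr_next[-nb])  # RR preceding each beat

  ## per-beat hemodynamics
  pat_mean <- if (spec$state == "rest") 0.25 else 0.23
  pat <- pmin(pmax(pat_mean + stats::rnorm(nb, 0, 0.035), 0.13), 0.42)
  am_mean <- if (spec$state == "rest") 2.79 else 2.90
  am <- pmax(am_mean + stats::rnorm(nb, 0, 0.30), 0.5)
  bp <- eval_bp_law(profile$coupling, pat, am, rr_prev, profile, spec$state)
  bp$sbp <- pmax(bp$sbp, bp$dbp + 15)   # physiological pulse-pressure floor

  t <- seq(0, by = 1 / fs, length.out = n)

  ## ECG channel
  ecg <- numeric(n)
  add_gauss <- function(y, center, amp, sig) {
    i0 <- max(1L, floor((center - 4 * sig) * fs) + 1L)
    i1 <- min(n, ceiling((center + 4 * sig) * fs) + 1L)
    if (i0 > n || i1 < 1) return(y)
    idx <- i0:i1
    y[idx] <- y[idx] + amp * exp(-(t[idx] - center)^2 / (2 * sig^2))
    y
  }
  for (i in seq_len(nb)) {
    ecg <- add_gauss(ecg, r_times[i], 1.0, 0.008)
    ecg <- add_gauss(ecg, r_times[i] - 0.025, -0.12, 0.010)   # Q
    ecg <- add_gauss(ecg, r_times[i] + 0.028, -0.18, 0.012)   # S
    ecg <- add_gauss(ecg, r_times[i] - 0.16 * rr_prev[i], 0.08, 0.025)  # P
    ecg <- add_gauss(ecg, r_times[i] + 0.30 * rr_next[i], 0.16, 0.040)  # T
  }

  ## PPG channel: abutting beat windows between consecutive pulse onsets
  ref_len <- 0.71
  onset <- r_times + pat
  lm <- template_landmarks(ref_len = ref_len)
  ppg <- numeric(n)
  win_len <- c(diff(onset), rr_next[nb])
  scale <- win_len / ref_len
  ## lead-in pulse so the first annotated beat has a proper foot valley
  onset_all <- c(onset[1] - rr_prev[1], onset)
  win_all <- c(rr_prev[1], win_len)
  am_all <- c(am[1], am)
  for (i in seq_along(onset_all)) {
    i0 <- max(1L, floor(onset_all[i] * fs) + 1L)
    i1 <- min(n, ceiling((onset_all[i] + win_all[i]) * fs) + 1L)
    if (i0 > n || i1 < 1) next
    idx <- i0:i1
    v <- (t[idx] - onset_all[i]) / (win_all[i] / ref_len)
    ppg[idx] <- ppg[idx] + am_all[i] * ppg_pulse_template(v, ref_len = ref_len)
  }
  ## bandlimit the optical channel: real PPG front-ends are low-pass; this
  ## also guarantees the recorded waveform, not an idealized template, is
  ## what defines landmark ground truth
  if (fs > 60) ppg <- fir_lowpass(ppg, fs, cutoff = 12)
  ## ground-truth landmark times, measured on the rendered clean waveform
  ## around their nominal (template) positions
  on_t <- measure_landmark(ppg, fs, onset, 0.030, maximum = FALSE)
  sys_t <- measure_landmark(ppg, fs, onset + lm$sys * scale, 0.035, maximum = TRUE)
  dic_t <- measure_landmark(ppg, fs, onset + lm$dic * scale, 0.045, maximum = FALSE)
  dia_t <- measure_landmark(ppg, fs, onset + lm$dia * scale, 0.045, maximum = TRUE)
  dppg <- c(0, diff(ppg)) * fs
  ms_t <- measure_landmark(dppg, fs, onset + lm$ms * scale, 0.030, maximum = TRUE)

  ## ABP channel: piecewise-linear DBP baseline with knots at the feet, plus a
  ## per-beat pulse lobe vanishing at both feet, so every foot is an exact
  ## V-shaped minimum at true DBP and every peak is scaled to true SBP.
  peak_frac <- 0.5^(4 / 3)
  foot <- r_times + 0.20
  foot_end <- c(foot[-1], foot[nb] + rr_next[nb])
  base_t <- c(0, foot, foot_end[nb], spec$duration)
  base_v <- c(bp$dbp[1] + 2 * foot[1], bp$dbp, bp$dbp[nb], bp$dbp[nb])
  abp <- stats::approx(base_t, base_v, xout = t, rule = 2)$y
  for (i in seq_len(nb)) {
    i0 <- max(1L, floor(foot[i] * fs) + 1L)
    i1 <- min(n, ceiling(foot_end[i] * fs))
    if (i0 > n || i1 < i0) next
    idx <- i0:i1
    s <- (t[idx] - foot[i]) / (foot_end[i] - foot[i])
    base_at_peak <- bp$dbp[i] + peak_frac * (bp$dbp[min(i + 1, nb)] - bp$dbp[i])
    abp[idx] <- abp[idx] + (bp$sbp[i] - base_at_peak) * abp_pulse_lobe(s)
  }

  ## measurement noise; the ABP monitor output is nearly clean
  nz <- spec$noise
  if (nz[["ecg"]] > 0) ecg <- ecg + stats::rnorm(n, 0, nz[["ecg"]])
  if (nz[["ppg"]] > 0) ppg <- ppg + stats::rnorm(n, 0, nz[["ppg"]])
  if (nz[["abp"]] > 0) abp <- abp + stats::rnorm(n, 0, nz[["abp"]])

  truth <- data.frame(
    beat = seq_len(nb),
    r_time = r_times,
    ppg_onset_time = on_t,
    ppg_ms_time = ms_t,
    ppg_peak_time = sys_t,
    dicrotic_time = dic_t,
    diastolic_peak_time = dia_t,
    abp_foot_time = foot,
    abp_peak_time = foot + peak_frac * (foot_end - foot),
    true_pat = pat,
    true_am = am,
    true_rr = rr_prev,
    true_sbp = bp$sbp,
    true_dbp = bp$dbp
  )

  rec <- structure(list(
    t = t, ecg = ecg, ppg = ppg, abp = abp, fs = fs,
    truth = truth,
    excluded_intervals = data.frame(start = numeric(0), end = numeric(0),
                                    kind = character(0)),
    law = profile$coupling, profile = profile, spec = spec
  ), class = "bp_record")
  if (length(spec$artifacts)) rec <- inject_artifacts(rec, spec$artifacts)
  rec
}

#' @export
print.bp_record <- function(x, ...) {
  cat(sprintf("<bp_record> %s/%s: %.0f s @ %g Hz, %d beats, %d excluded interval(s)\n",
              x$profile$subject_id, x$spec$state, max(x$t) + 1 / x$fs, x$fs,
              nrow(x$truth), nrow(x$excluded_intervals)))
  invisible(x)
}

#' Inject flat-line / flat-peak artifacts into a record
#'
#' `flat_line` replaces the samples of an interval by a constant (the value at
#' the interval start); `flat_peak` clips samples above a quantile of the
#' interval to that quantile, producing the clipped-plateau morphology of
#' saturated pulse recordings. Ground-truth annotations are not modified; the
#' affected intervals are appended to `excluded_intervals`.
#'
#' @param record A `bp_record`.
#' @param artifacts List of descriptors:
#'   `list(kind = "flat_line"|"flat_peak", start, length, channel = "abp",
#'   quantile = 0.95)` with times in seconds.
#' @return The modified `bp_record`.
#' @export
inject_artifacts <- function(record, artifacts) {
  stopifnot(inherits(record, "bp_record"))
  if (!length(artifacts)) return(record)
  fs <- record$fs
  n <- length(record$t)
  for (a in artifacts) {
    kind <- match.arg(a$kind, c("flat_line", "flat_peak"))
    ch <- if (is.null(a$channel)) "abp" else match.arg(a$channel, c("ecg", "ppg", "abp"))
    i0 <- floor(a$start * fs) + 1L
    i1 <- min(n, floor((a$start + a$length) * fs))
    if (i0 > n || i1 < max(i0, 1L)) {
      warning("artifact interval outside record; ignored")
      next
    }
    idx <- max(1L, i0):i1
    x <- record[[ch]]
    if (kind == "flat_line") {
      x[idx] <- x[idx[1]]
    } else {
      q <- if (is.null(a$quantile)) 0.95 else a$quantile
      cap <- stats::quantile(x[idx], q, names = FALSE)
      x[idx] <- pmin(x[idx], cap)
    }
    record[[ch]] <- x
    record$excluded_intervals <- rbind(
      record$excluded_intervals,
      data.frame(start = (idx[1] - 1) / fs, end = idx[length(idx)] / fs, kind = kind)
    )
  }
  record
}

#' Ground-truth beat feature table
#'
#' Builds the per-beat feature/target table directly from the generator's
#' truth annotations, bypassing signal-level detection. Used as the oracle
#' for detector accuracy and for parameter-recovery studies of the
#' rule-ensemble model.
#'
#' @param record A `bp_record` with at least one beat.
#' @return A data frame, one row per beat, with the subject/state labels, the
#'   hemodynamic predictors (oPAT, pPAT, diaPAT, msPAT, relative PATs, PWVs,
#'   AM, crest time, beat intervals) and the SBP/DBP/MBP targets.
#' @export
ground_truth_beat_table <- function(record) {
  stopifnot(inherits(record, "bp_record"))
  tr <- record$truth
  if (!nrow(tr)) stop("record has no beats")
  p <- record$profile
  L <- p$arterial_path_length
  oPAT <- tr$true_pat            # the onset PAT the generative law used
  pPAT <- tr$ppg_peak_time - tr$r_time
  diaPAT <- tr$diastolic_peak_time - tr$r_time
  msPAT <- tr$ppg_ms_time - tr$r_time
  nb <- nrow(tr)
  dO <- c(diff(tr$ppg_onset_time), NA)
  dP <- c(diff(tr$ppg_peak_time), NA)
  data.frame(
    subject_id = p$subject_id, state = record$spec$state, beat = tr$beat,
    AM = tr$true_am,
    oPAT = oPAT, pPAT = pPAT, diaPAT = diaPAT, msPAT = msPAT,
    RoPAT = oPAT / tr$true_rr, RpPAT = pPAT / tr$true_rr,
    oPWV = L / oPAT, pPWV = L / pPAT, diaPWV = L / diaPAT,
    cT = tr$ppg_peak_time - tr$ppg_onset_time,
    dO = dO, dP = dP, rr = tr$true_rr,
    age = p$age, bmi = p$bmi,
    SBP = tr$true_sbp, DBP = tr$true_dbp,
    MBP = (tr$true_sbp + 2 * tr$true_dbp) / 3
  )
}

#' Write / read a generated record as CSV + JSON sidecar
#'
#' The waveform goes to `<prefix>.csv` with columns `time,ecg,ppg,abp`; the
#' truth annotations, generative law, profile and session spec go to
#' `<prefix>.json`.
#'
#' @param record A `bp_record`.
#' @param prefix Output path prefix (no extension).
#' @return `write_record` returns `prefix` invisibly; `read_record` returns
#'   the reconstructed `bp_record`.
#' @export
write_record <- function(record, prefix) {
  stopifnot(inherits(record, "bp_record"))
  utils::write.csv(
    data.frame(time = record$t, ecg = record$ecg, ppg = record$ppg, abp = record$abp),
    paste0(prefix, ".csv"), row.names = FALSE)
  side <- list(
    fs = record$fs, truth = record$truth,
    excluded_intervals = record$excluded_intervals,
    law = list(sbp = as.list(record$law$sbp), dbp = as.list(record$law$dbp),
               tau = record$law$tau),
    profile = record$profile[setdiff(names(record$profile), "coupling")],
    spec = unclass(record$spec)
  )
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_record
#' @export
read_record <- function(prefix) {
  w <- utils::read.csv(paste0(prefix, ".csv"))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  law <- side$law
  law$sbp <- unlist(law$sbp); law$dbp <- unlist(law$dbp)
  profile <- c(side$profile, list(coupling = law))
  class(profile) <- "subject_profile"
  spec <- side$spec
  spec$artifacts <- if (is.null(spec$artifacts)) list() else spec$artifacts
  class(spec) <- "session_spec"
  excl <- side$excluded_intervals
  if (is.null(excl) || !length(excl)) {
    excl <- data.frame(start = numeric(0), end = numeric(0), kind = character(0))
  }
  structure(list(t = w$time, ecg = w$ecg, ppg = w$ppg, abp = w$abp, fs = side$fs,
                 truth = as.data.frame(side$truth),
                 excluded_intervals = as.data.frame(excl),
                 law = law, profile = profile, spec = spec),
            class = "bp_record")
}
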