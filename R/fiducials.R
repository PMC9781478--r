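## Per-beat landmark detection on ECG, PPG (and its derivatives) and ABP,
## plus flat-line / flat-peak artifact screening.

## local extrema helpers on a numeric vector; return indices
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
}
local_minima <- function(x) local_maxima(-x)

## refine an extremum on the raw input by parabolic fit over +-half samples
refine_extremum <- function(x, i, half = 5L, maximum = TRUE) {
  n <- length(x)
  lo <- max(1L, i - half); hi <- min(n, i + half)
  w <- x[lo:hi]
  j <- if (maximum) which.max(w) else which.min(w)
  i2 <- lo + j - 1L
  if (i2 > 1 && i2 < n) {
    y1 <- x[i2 - 1]; y2 <- x[i2]; y3 <- x[i2 + 1]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > .Machine$double.eps) {
      d <- 0.5 * (y1 - y3) / den
      if (abs(d) <= 1) return(i2 + d)
    }
  }
  as.numeric(i2)
}

#' Detect ECG R peaks via a Shannon-energy envelope
#'
#' First-difference -> Shannon energy -> moving-average envelope, with peak
#' picking above an adaptive threshold and a 200 ms refractory period;
#' each detection is then refined to the local maximum of the input ECG.
#' The approach follows the energy-envelope family of QRS detectors.
#'
#' @param ecg Bandpass-filtered ECG samples.
#' @param fs Sampling rate, Hz.
#' @param refractory Minimum spacing between detections, s.
#' @param threshold Envelope threshold as a fraction of the 99th envelope
#'   percentile.
#' @return Numeric vector of strictly increasing R-peak times (s); empty if
#'   the signal carries no QRS energy.
#' @export
detect_r_peaks <- function(ecg, fs, refractory = 0.2, threshold = 0.25) {
  n <- length(ecg)
  if (n < 5) return(numeric(0))
  d <- c(0, diff(ecg)) * fs
  m <- max(abs(d))
  if (m == 0) return(numeric(0))
  z <- (d / m)^2
  se <- -z * log(pmax(z, 1e-12))
  env <- moving_average(se, ms_to_odd_samples(120, fs))
  thr <- threshold * stats::quantile(env, 0.99, names = FALSE)
  if (thr <= 0) return(numeric(0))
  cand <- local_maxima(env)
  cand <- cand[env[cand] > thr]
  if (!length(cand)) return(numeric(0))
  ## refractory: keep the larger envelope peak of any pair closer than 200 ms
  ord <- cand[order(-env[cand])]
  keep <- logical(0)
  sel <- integer(0)
  for (i in ord) {
    if (!length(sel) || all(abs(i - sel) >= refractory * fs)) sel <- c(sel, i)
  }
  sel <- sort(sel)
  ## refine on the ECG itself within +-60 ms
  half <- round(0.06 * fs)
  r_idx <- vapply(sel, function(i) refine_extremum(ecg, i, half, TRUE), numeric(1))
  r_t <- sort(unique((r_idx - 1) / fs))
  ## a second refractory pass after refinement
  if (length(r_t) > 1) {
    out <- r_t[1]
    for (tt in r_t[-1]) if (tt - out[length(out)] >= refractory) out <- c(out, tt)
    r_t <- out
  }
  r_t
}

## refine a valley by least-squares quadratic fit over +-half samples;
## falls back to the discrete minimum when the fit is not convex
refine_valley_quadratic <- function(x, i, half = 12L) {
  n <- length(x)
  lo <- max(1L, i - half); hi <- min(n, i + half)
  u <- (lo:hi) - i
  y <- x[lo:hi]
  cf <- stats::lm.fit(cbind(1, u, u^2), y)$coefficients
  if (is.na(cf[3]) || cf[3] <= 0) {
    return(refine_extremum(x, i, half, maximum = FALSE))
  }
  v <- -cf[2] / (2 * cf[3])
  if (abs(v) > half) v <- sign(v) * half
  i + v
}

## smoothed derivative: central differences then moving average
smooth_deriv <- function(x, fs, smooth_samples) {
  d <- c(x[2] - x[1], (x[seq(3, length(x))] - x[seq(1, length(x) - 2)]) / 2,
         x[length(x)] - x[length(x) - 1]) * fs
  moving_average(d, smooth_samples)
}

#' Detect per-beat PPG fiducial points
#'
#' For each R-R window, locates the pulse onset (pre-upstroke minimum), the
#' maximum-slope point `ms` on the first derivative, the systolic peak `s`,
#' the dicrotic notch `dic` (local waveform minimum after the systolic peak;
#' falls back to the second-derivative e-wave when the contour decays
#' monotonically), the diastolic peak `dia`, the `a`-`e` waves of the second
#' derivative within the systolic phase, and the early/late systolic
#' components `p1`,`p2` of the third derivative. Derivatives use smoothed
#' central differences (re-smoothing after each differentiation); extrema are
#' refined on the input signal so smoothing does not bias timing. Beats whose
#' landmarks cannot be resolved keep `NA` fields and are flagged.
#'
#' @param ppg Bandpassed, z-score-normalized PPG samples.
#' @param fs Sampling rate, Hz.
#' @param r_times R-peak times (s) bounding the beats.
#' @param smooth_ms Moving-average window for derivative estimation, ms.
#' @return Data frame with one row per beat: landmark times (s), landmark
#'   amplitudes, `rr_prev` and a `flag` column (`"ok"` or
#'   `"missing_landmark"`).
#' @export
detect_ppg_fiducials <- function(ppg, fs, r_times, smooth_ms = 51) {
  stopifnot(length(r_times) >= 1)
  nb <- length(r_times)
  sm <- ms_to_odd_samples(smooth_ms, fs)
  sm_d <- ms_to_odd_samples(max(11, smooth_ms / 2), fs)
  ppg_s <- moving_average(ppg, sm)
  d1 <- smooth_deriv(ppg_s, fs, sm_d)
  d2 <- smooth_deriv(d1, fs, sm_d)
  d3 <- smooth_deriv(d2, fs, sm_d)
  n <- length(ppg)
  med_rr <- if (nb > 1) stats::median(diff(r_times)) else 0.8

  empty <- function(beat, r, rr, why) {
    data.frame(beat = beat, r_time = r, rr_prev = rr, onset = NA_real_,
               ms = NA_real_, sys_peak = NA_real_, dicrotic = NA_real_,
               dia_peak = NA_real_, a = NA_real_, b = NA_real_, c = NA_real_,
               d = NA_real_, e = NA_real_, p1 = NA_real_, p2 = NA_real_,
               amp_onset = NA_real_, amp_sys = NA_real_, amp_dic = NA_real_,
               amp_dia = NA_real_, flag = why)
  }

  rows <- vector("list", nb)
  for (bi in seq_len(nb)) {
    r <- r_times[bi]
    rr <- if (bi > 1) r - r_times[bi - 1] else med_rr
    rr_next <- if (bi < nb) r_times[bi + 1] - r else med_rr
    if (rr_next < 0.25) {
      rows[[bi]] <- empty(bi, r, rr, "missing_landmark")
      next
    }
    i_r <- round(r * fs) + 1L
    i_end <- min(n, round((r + rr_next) * fs) + 1L)
    if (i_end - i_r < 0.25 * fs || i_r < 1) {
      rows[[bi]] <- empty(bi, r, rr, "missing_landmark")
      next
    }
    ## ms point: maximum of the 1st derivative in the PAT search band
    lo <- i_r + round(0.10 * fs)
    hi <- min(i_end, i_r + round(0.60 * fs))
    if (hi <= lo) {
      rows[[bi]] <- empty(bi, r, rr, "missing_landmark")
      next
    }
    seg <- lo:hi
    i_ms <- seg[which.max(d1[seg])]
    ## onset: pre-upstroke minimum. Located on the input signal, not the
    ## moving-average-smoothed one: wide smoothing fills the shallow foot
    ## valley and would bias the minimum early. A local quadratic fit then
    ## interpolates the vertex, which suppresses sample noise.
    back <- seq(max(i_r, i_ms - round(0.14 * fs)), max(i_r + 1L, i_ms - round(0.01 * fs)))
    i_on_c <- back[which.min(ppg[back])]
    i_on <- refine_valley_quadratic(ppg, round(i_on_c), round(0.018 * fs))
    ## systolic peak: first downward zero crossing of d1 after ms
    fwd <- seq(i_ms, min(i_end, i_ms + round(0.30 * fs)))
    neg <- fwd[d1[fwd] <= 0]
    i_sys_c <- if (length(neg)) neg[1] else fwd[which.max(ppg_s[fwd])]
    i_sys <- refine_extremum(ppg, round(i_sys_c), round(0.006 * fs), maximum = TRUE)
    if (!(i_on < i_sys) || (i_sys - i_r) / fs > 0.75 * rr_next) {
      rows[[bi]] <- empty(bi, r, rr, "missing_landmark")
      next
    }

    ## second-derivative a-e waves within the systolic phase
    sys_lo <- round(i_on); sys_hi <- min(i_end, round(i_on + 0.45 * rr_next * fs))
    seg2 <- sys_lo:sys_hi
    mx <- seg2[1] + local_maxima(d2[seg2]) - 1L
    mn <- seg2[1] + local_minima(d2[seg2]) - 1L
    ext <- sort(c(mx, mn))
    ## alternating sequence starting at the first maximum (the a-wave)
    abcde <- rep(NA_real_, 5)
    if (length(mx)) {
      start <- mx[1]
      ext <- ext[ext >= start]
      want_max <- TRUE
      k <- 1
      for (ei in ext) {
        if (k > 5) break
        is_max <- ei %in% mx
        if (is_max == want_max) {
          abcde[k] <- (ei - 1) / fs
          k <- k + 1
          want_max <- !want_max
        }
      }
    }

    ## dicrotic notch: local minima of the smoothed wave after the systolic
    ## peak; tie-break toward the e-wave of the 2nd derivative
    srch <- seq(round(i_sys) + round(0.03 * fs),
                min(i_end, round(i_sys) + round(0.6 * rr_next * fs)))
    i_dic <- NA_real_; i_dia <- NA_real_
    if (length(srch) > 2) {
      cand_dic <- srch[1] + local_minima(ppg_s[srch]) - 1L
      if (length(cand_dic)) {
        if (length(cand_dic) > 1 && !is.na(abcde[5])) {
          e_idx <- abcde[5] * fs + 1
          cand_dic <- cand_dic[order(abs(cand_dic - e_idx))]
        }
        i_dic <- refine_extremum(ppg, cand_dic[1], round(0.008 * fs), maximum = FALSE)
        after <- seq(round(i_dic) + 2L,
                     min(i_end, round(i_dic) + round(0.35 * fs)))
        if (length(after) > 2) {
          cand_dia <- after[1] + local_maxima(ppg_s[after]) - 1L
          if (length(cand_dia)) {
            i_dia <- refine_extremum(ppg, cand_dia[1], round(0.008 * fs), maximum = TRUE)
          }
        }
      }
    }

    ## p1/p2: extrema of the 3rd derivative delimited by its zero crossings,
    ## within the systolic upstroke-to-notch span
    p12 <- c(NA_real_, NA_real_)
    span <- seq(round(i_on), min(sys_hi, i_end))
    if (length(span) > 4) {
      zc <- span[which(diff(sign(d3[span])) != 0)]
      if (length(zc) >= 2) {
        segs <- cbind(zc[-length(zc)], zc[-1])
        pk <- apply(segs, 1, function(sg) {
          ii <- sg[1]:sg[2]
          ii[which.max(abs(d3[ii]))]
        })
        pos <- pk[d3[pk] > 0]
        if (length(pos) >= 1) p12[1] <- (pos[1] - 1) / fs
        if (length(pos) >= 2) p12[2] <- (pos[2] - 1) / fs
      }
    }

    t_on <- (i_on - 1) / fs; t_ms <- (i_ms - 1) / fs; t_sys <- (i_sys - 1) / fs
    t_dic <- if (is.na(i_dic)) NA_real_ else (i_dic - 1) / fs
    t_dia <- if (is.na(i_dia)) NA_real_ else (i_dia - 1) / fs
    ## ordering contract: drop landmarks violating it rather than emit them
    if (!is.na(t_dic) && t_dic <= t_sys) t_dic <- NA_real_
    if (!is.na(t_dia) && (is.na(t_dic) || t_dia < t_dic)) t_dia <- NA_real_
    flag <- if (anyNA(c(t_on, t_ms, t_sys, t_dic, t_dia))) "missing_landmark" else "ok"
    at <- function(ti) if (is.na(ti)) NA_real_ else ppg[round(ti * fs) + 1L]
    rows[[bi]] <- data.frame(
      beat = bi, r_time = r, rr_prev = rr, onset = t_on, ms = t_ms,
      sys_peak = t_sys, dicrotic = t_dic, dia_peak = t_dia,
      a = abcde[1], b = abcde[2], c = abcde[3], d = abcde[4], e = abcde[5],
      p1 = p12[1], p2 = p12[2],
      amp_onset = at(t_on), amp_sys = at(t_sys), amp_dic = at(t_dic),
      amp_dia = at(t_dia), flag = flag)
  }
  do.call(rbind, rows)
}

#' Detect per-beat ABP foot and peak (DBP and SBP)
#'
#' The ABP channel is used unfiltered. For each R-R window the peak is the
#' window maximum (SBP) and the foot is the pre-upstroke minimum before the
#' peak (DBP). Beats overlapping an exclusion interval are skipped.
#'
#' @param abp Raw ABP samples in mmHg.
#' @param fs Sampling rate, Hz.
#' @param r_times R-peak times (s).
#' @param exclusions Optional data frame with `start`,`end` columns (s).
#' @return Data frame: `beat`, `foot_time`, `dbp`, `peak_time`, `sbp`.
#' @export
detect_abp_landmarks <- function(abp, fs, r_times, exclusions = NULL) {
  nb <- length(r_times)
  n <- length(abp)
  med_rr <- if (nb > 1) stats::median(diff(r_times)) else 0.8
  out <- vector("list", nb)
  for (bi in seq_len(nb)) {
    r <- r_times[bi]
    rr_next <- if (bi < nb) r_times[bi + 1] - r else med_rr
    w0 <- r + 0.02
    w1 <- r + 0.02 + rr_next
    if (!is.null(exclusions) && nrow(exclusions) &&
        any(pmax(exclusions$start, w0) < pmin(exclusions$end, w1))) next
    i0 <- max(1L, round(w0 * fs) + 1L)
    i1 <- min(n, round(w1 * fs) + 1L)
    if (i1 - i0 < 0.2 * fs) next
    seg <- i0:i1
    i_pk <- seg[which.max(abp[seg])]
    pre <- i0:i_pk
    i_ft <- pre[which.min(abp[pre])]
    if (abp[i_pk] <= abp[i_ft]) next
    out[[bi]] <- data.frame(beat = bi, foot_time = (i_ft - 1) / fs,
                            dbp = abp[i_ft], peak_time = (i_pk - 1) / fs,
                            sbp = abp[i_pk])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(beat = integer(0), foot_time = numeric(0),
                      dbp = numeric(0), peak_time = numeric(0), sbp = numeric(0))
  }
  res
}

#' Detect flat-line and flat-peak artifacts
#'
#' Flat lines are runs of at least `min_run` seconds with zero first
#' difference; a run whose plateau sits strictly above both neighboring
#' samples (a clipped top) is classified as a flat peak instead. Overlapping
#' or adjacent intervals are merged per kind.
#'
#' @param x Signal samples.
#' @param fs Sampling rate, Hz.
#' @param min_run Minimum plateau duration, s.
#' @param tol Absolute tolerance on the first difference (default exact 0).
#' @return Data frame exclusion mask: `start`, `end` (s), `kind`.
#' @export
detect_flat_artifacts <- function(x, fs, min_run = 0.2, tol = 0) {
  stopifnot(min_run > 0)
  n <- length(x)
  empty <- data.frame(start = numeric(0), end = numeric(0), kind = character(0))
  if (n < 2) return(empty)
  flat <- abs(diff(x)) <= tol
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- empty
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    len <- r$lengths[k] + 1          # samples in the plateau
    if (len < min_run * fs) next
    i0 <- starts[k]; i1 <- ends[k] + 1
    v <- x[i0]
    above_left <- i0 == 1 || x[i0 - 1] < v
    above_right <- i1 == n || x[i1 + 1] < v
    kind <- if (above_left && above_right) "flat_peak" else "flat_line"
    out <- rbind(out, data.frame(start = (i0 - 1) / fs, end = (i1 - 1) / fs,
                                 kind = kind))
  }
  merge_intervals(out)
}

#' Merge overlapping intervals of an exclusion mask
#' @param mask Data frame with `start`, `end` and optionally `kind`.
#' @return Mask with overlapping/adjacent intervals of the same kind merged,
#'   sorted by start.
#' @export
merge_intervals <- function(mask) {
  if (!nrow(mask)) return(mask)
  if (is.null(mask$kind)) mask$kind <- "manual"
  out <- NULL
  for (kd in unique(mask$kind)) {
    m <- mask[mask$kind == kd, , drop = FALSE]
    m <- m[order(m$start), , drop = FALSE]
    s <- m$start[1]; e <- m$end[1]
    for (i in seq_len(nrow(m))[-1]) {
      if (m$start[i] <= e) e <- max(e, m$end[i]) else {
        out <- rbind(out, data.frame(start = s, end = e, kind = kd))
        s <- m$start[i]; e <- m$end[i]
      }
    }
    out <- rbind(out, data.frame(start = s, end = e, kind = kd))
  }
  out[order(out$start), , drop = FALSE]
}
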