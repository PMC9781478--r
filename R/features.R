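## Per-beat hemodynamic feature/target table and cleaning rules.

#' Mean blood pressure from systolic and diastolic pressure
#'
#' `MBP = (SBP + 2 DBP) / 3`, the standard diastole-weighted estimate.
#'
#' @param sbp,dbp Systolic and diastolic pressure, mmHg; `sbp > dbp > 0`.
#' @return Mean pressure in mmHg.
#' @examples
#' mean_bp(120, 80)    # 93.33
#' @export
mean_bp <- function(sbp, dbp) {
  if (any(dbp <= 0) || any(sbp <= dbp)) stop("require sbp > dbp > 0")
  (sbp + 2 * dbp) / 3
}

#' Compute the feature row of one cardiac cycle
#'
#' Combines the PPG/ECG fiducials of one beat with its ABP foot/peak values
#' and the subject's anthropometry into the hemodynamic predictors used for
#' beat-to-beat blood-pressure modelling: pulse arrival times from the R peak
#' to the pulse onset / systolic peak / diastolic peak / maximum-slope point
#' (oPAT, pPAT, diaPAT, msPAT), their RR-relative versions (RoPAT, RpPAT),
#' pulse wave velocities (arterial path length over PAT), pulse amplitude AM,
#' crest time cT, and waveform-shape descriptors. Fields whose landmarks are
#' absent are `NA`.
#'
#' @param fid One row of [detect_ppg_fiducials()] output.
#' @param abp_beat List or one-row data frame with `dbp` and `sbp` (mmHg).
#' @param profile The [generate_subject()] profile (or any list with
#'   `arterial_path_length`, `age`, `bmi`, `subject_id`).
#' @param state State label carried into the row.
#' @return One-row data frame of features and SBP/DBP/MBP targets.
#' @export
compute_beat_features <- function(fid, abp_beat, profile, state = "rest") {
  rr <- fid$rr_prev
  if (is.na(rr) || rr <= 0) stop("invalid beat: rr_prev must be positive")
  L <- profile$arterial_path_length
  oPAT <- fid$onset - fid$r_time
  pPAT <- fid$sys_peak - fid$r_time
  diaPAT <- fid$dia_peak - fid$r_time
  msPAT <- fid$ms - fid$r_time
  amp <- fid$amp_sys - fid$amp_onset
  ## shape descriptors (provisional definitions, isolated here):
  ## DA  = diastolic-to-systolic amplitude ratio
  ## AM25 here stands in for pulse width at quarter amplitude; without the
  ## sampled wave in scope we use the onset->dicrotic span as its proxy
  DA <- (fid$amp_dia - fid$amp_onset) / amp
  AM25 <- fid$dicrotic - fid$onset
  slope_BC <- if (!is.na(fid$b) && !is.na(fid$c) && fid$c > fid$b) {
    (fid$c - fid$b)
  } else NA_real_
  data.frame(
    subject_id = profile$subject_id, state = state, beat = fid$beat,
    AM = amp,
    oPAT = oPAT, pPAT = pPAT, diaPAT = diaPAT, msPAT = msPAT,
    RoPAT = oPAT / rr, RpPAT = pPAT / rr,
    oPWV = L / oPAT, pPWV = L / pPAT, diaPWV = L / diaPAT,
    cT = fid$sys_peak - fid$onset,
    rr = rr, DA = DA, AM25 = AM25, slope_BC = slope_BC,
    SBP = abp_beat$sbp, DBP = abp_beat$dbp,
    MBP = (abp_beat$sbp + 2 * abp_beat$dbp) / 3
  )
}

#' Assemble the beat feature table, removing masked beats
#'
#' Joins per-beat PPG fiducials and ABP landmarks beat-by-beat, computes each
#' feature row, drops beats whose R-R span intersects an exclusion interval,
#' and adds inter-beat intervals (onset-to-onset dO, peak-to-peak dP).
#' Provenance counts (rows before/after exclusion) are attached as the
#' `"provenance"` attribute.
#'
#' @param fiducials Output of [detect_ppg_fiducials()].
#' @param abp_beats Output of [detect_abp_landmarks()].
#' @param profile Subject profile.
#' @param state State label.
#' @param mask Optional exclusion mask (`start`,`end` seconds).
#' @return `BeatFeatureTable` data frame, one row per retained beat.
#' @export
assemble_beat_table <- function(fiducials, abp_beats, profile, state = "rest",
                                mask = NULL) {
  rows <- vector("list", nrow(fiducials))
  for (i in seq_len(nrow(fiducials))) {
    f <- fiducials[i, ]
    ab <- abp_beats[abp_beats$beat == f$beat, ]
    if (!nrow(ab)) next
    if (is.na(f$rr_prev) || f$rr_prev <= 0) next
    rows[[i]] <- compute_beat_features(f, ab, profile, state)
  }
  tab <- do.call(rbind, rows)
  n_before <- if (is.null(tab)) 0L else nrow(tab)
  if (!is.null(tab) && n_before) {
    ## inter-beat intervals on consecutive retained beats
    on <- fiducials$onset[match(tab$beat, fiducials$beat)]
    pk <- fiducials$sys_peak[match(tab$beat, fiducials$beat)]
    tab$dO <- c(diff(on), NA)
    tab$dP <- c(diff(pk), NA)
    if (!is.null(mask) && nrow(mask)) {
      r_t <- fiducials$r_time[match(tab$beat, fiducials$beat)]
      rr_n <- c(diff(r_t), stats::median(diff(r_t)))
      hit <- vapply(seq_along(r_t), function(i) {
        any(pmax(mask$start, r_t[i]) < pmin(mask$end, r_t[i] + rr_n[i]))
      }, logical(1))
      tab <- tab[!hit, , drop = FALSE]
    }
  }
  n_after <- if (is.null(tab)) 0L else nrow(tab)
  if (!n_after) warning("empty beat table")
  if (is.null(tab)) tab <- data.frame()
  attr(tab, "provenance") <- list(n_before = n_before,
                                  n_excluded = n_before - n_after,
                                  n_after = n_after)
  tab
}

#' Clean a beat feature table
#'
#' Two-step cleaning: (1) drop every row containing at least one missing
#' value; (2) on the remaining rows, compute per-column z-scores
#' `(x - mean)/SD` and drop rows where any `|z|` exceeds `z_thresh`.
#' Constant columns cannot produce outliers and are skipped in step 2.
#' The outlier pass uses the statistics of the post-step-1 table and is
#' applied once, not iterated. Step counts are attached as the
#' `"cleaning_log"` attribute.
#'
#' @param tab Beat feature table (data frame).
#' @param z_thresh Z-score cut-off in SD units (default 3).
#' @param columns Columns to consider; defaults to all numeric columns.
#' @return The cleaned table.
#' @export
clean_table <- function(tab, z_thresh = 3, columns = NULL) {
  stopifnot(is.data.frame(tab), z_thresh > 0)
  if (is.null(columns)) {
    columns <- names(tab)[vapply(tab, is.numeric, logical(1))]
  }
  n0 <- nrow(tab)
  keep1 <- stats::complete.cases(tab[, columns, drop = FALSE])
  t1 <- tab[keep1, , drop = FALSE]
  n1 <- nrow(t1)
  drop2 <- rep(FALSE, n1)
  if (n1 > 1) {
    for (cn in columns) {
      x <- t1[[cn]]
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) next
      z <- (x - mean(x)) / s
      drop2 <- drop2 | abs(z) > z_thresh
    }
  }
  out <- t1[!drop2, , drop = FALSE]
  attr(out, "cleaning_log") <- list(
    n_input = n0, n_dropped_na = n0 - n1,
    n_dropped_outlier = sum(drop2), n_output = nrow(out),
    z_thresh = z_thresh
  )
  out
}

#' Extract a session's cleaned beat table from raw channels
#'
#' Convenience wrapper running the full extraction chain on one record:
#' filter ECG and PPG, detect R peaks, PPG fiducials, ABP landmarks and flat
#' artifacts, assemble the feature table and (optionally) clean it.
#'
#' @param record A `bp_record` (or any list with `ecg`,`ppg`,`abp`,`fs`,
#'   `profile`, `spec$state`).
#' @param config Pipeline configuration, see [default_config()].
#' @param clean Apply [clean_table()] (default TRUE).
#' @return Cleaned beat feature table; detection intermediates are attached
#'   as attributes `fiducials`, `abp_beats`, `mask`.
#' @export
extract_beat_table <- function(record, config = default_config(), clean = TRUE) {
  fs <- record$fs
  ecg_f <- bandpass_filter(record$ecg, fs, config$ecg_band[1], config$ecg_band[2])
  ppg_f <- zscore_normalize(
    bandpass_filter(record$ppg, fs, config$ppg_band[1], config$ppg_band[2]))
  r <- detect_r_peaks(ecg_f, fs)
  if (!length(r)) stop("no R peaks detected")
  fid <- detect_ppg_fiducials(ppg_f, fs, r, smooth_ms = config$smooth_window_ms)
  mask <- rbind(
    detect_flat_artifacts(record$abp, fs, min_run = config$flat_min_run),
    detect_flat_artifacts(record$ppg, fs, min_run = config$flat_min_run))
  if (nrow(mask)) mask <- merge_intervals(mask)
  ab <- detect_abp_landmarks(record$abp, fs, r, exclusions = mask)
  state <- if (!is.null(record$spec$state)) record$spec$state else "rest"
  tab <- assemble_beat_table(fid, ab, record$profile, state, mask = mask)
  if (clean && nrow(tab)) tab <- clean_table(tab, z_thresh = config$z_thresh)
  attr(tab, "fiducials") <- fid
  attr(tab, "abp_beats") <- ab
  attr(tab, "mask") <- mask
  tab
}
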