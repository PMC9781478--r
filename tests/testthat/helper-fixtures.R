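# Shared fixtures, generated once per test run and cached.

the_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(the_cache[[key]])) the_cache[[key]] <- force(expr)
  the_cache[[key]]
}

# one clean 90 s resting session (~125 beats) plus its detection products
fixture_record <- function() {
  cached("record", {
    prof <- generate_subject(7)
    generate_session(prof, session_spec("rest", duration = 90, seed = 3))
  })
}

fixture_detection <- function() {
  cached("detection", {
    rec <- fixture_record()
    ecg_f <- bandpass_filter(rec$ecg, rec$fs, 0.5, 30)
    ppg_f <- zscore_normalize(bandpass_filter(rec$ppg, rec$fs, 0.5, 15))
    r <- detect_r_peaks(ecg_f, rec$fs)
    fid <- detect_ppg_fiducials(ppg_f, rec$fs, r)
    ab <- detect_abp_landmarks(rec$abp, rec$fs, r)
    list(rec = rec, r = r, fid = fid, ab = ab)
  })
}

# pooled ground-truth beat table: 2 subjects x 2 states, ~480 beats
fixture_truth_pool <- function() {
  cached("truth_pool", {
    tabs <- list()
    for (s in 1:2) {
      prof <- generate_subject(100 + s)
      for (st in c("rest", "wbt")) {
        rec <- generate_session(
          prof, session_spec(st, duration = 90, seed = 100 * s + (st == "wbt")))
        tabs <- c(tabs, list(ground_truth_beat_table(rec)))
      }
    }
    do.call(rbind, tabs)
  })
}

# match detected beats to truth rows by R time
match_truth <- function(fid, truth) {
  match(round(fid$r_time, 2), round(truth$r_time, 2))
}
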