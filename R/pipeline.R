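## Pipeline orchestration: a flat declarative configuration drives
## synthesize-or-load -> preprocess -> fiducials -> features -> rule-ensemble
## -> evaluation, writing one artifact bundle with full provenance.

#' Default pipeline configuration
#'
#' Flat named list of every tunable of the pipeline with its default.
#' Vector-valued entries (band edges, targets) round-trip through the
#' key-value config file as comma-separated strings.
#'
#' @return Named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    ## input source
    input = "synthetic",          # or "files"
    files = "",                   # comma-separated record prefixes when input = files
    n_subjects = 2L,
    duration = 120,               # s per session
    fs = 1000,                    # Hz
    ## preprocessing
    ecg_band = c(0.5, 30),        # Hz
    ppg_band = c(0.5, 15),        # Hz
    smooth_window_ms = 51,
    ## artifact screening + cleaning
    flat_min_run = 0.2,           # s
    z_thresh = 3,
    nan_policy = "drop_row",
    ## rule ensemble
    mode = "rules_plus_linear",
    tree_size_mean = 3,
    n_trees = 300L,
    shrinkage = 0.01,
    subsample = 0.5,
    winsor_delta = 0.025,
    n_null = 20L,
    run_interactions = FALSE,
    ## evaluation
    k = 10L,
    fold_policy = "beat",         # or "subject"
    targets = c("SBP", "DBP", "MBP"),
    seed = 1L
  ), class = "pipeline_config")
}

#' Validate a pipeline configuration
#' @param config Named list as from [default_config()].
#' @return The validated config (invisibly errors on bad keys/values).
#' @export
validate_config <- function(config) {
  ref <- default_config()
  extra <- setdiff(names(config), names(ref))
  if (length(extra)) stop("unknown config key(s): ", paste(extra, collapse = ", "))
  merged <- utils::modifyList(unclass(ref), config[names(config)])
  if (merged$z_thresh <= 0) stop("invalid config: z_thresh must be > 0")
  if (merged$k < 2) stop("invalid config: k must be >= 2")
  if (!merged$mode %in% c("linear_only", "rules_only", "rules_plus_linear")) {
    stop("invalid config: mode")
  }
  if (!merged$fold_policy %in% c("beat", "subject")) stop("invalid config: fold_policy")
  if (length(merged$ecg_band) != 2 || length(merged$ppg_band) != 2) {
    stop("invalid config: band edges need two values")
  }
  class(merged) <- "pipeline_config"
  merged
}

#' Write / read a configuration as flat `key = value` text
#' @param config A pipeline configuration.
#' @param path File path.
#' @return `read_config` returns the parsed, validated configuration.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k, paste(format(v, digits = 15, scientific = FALSE,
                                       trim = TRUE), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  ref <- default_config()
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    k <- trimws(kv[1])
    v <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    if (!length(parts)) parts <- ""
    tmpl <- ref[[k]]
    out[[k]] <- if (is.numeric(tmpl)) {
      if (is.integer(tmpl)) as.integer(parts) else as.numeric(parts)
    } else if (is.logical(tmpl)) as.logical(parts) else parts
  }
  validate_config(out)
}

#' Serialize / load a rule-ensemble model as JSON
#' @param model A `rule_ensemble` model.
#' @param path JSON file path.
#' @return `read_model` returns the reconstructed model.
#' @export
write_model <- function(model, path) {
  obj <- list(
    mode = model$mode, intercept = model$intercept,
    penalty = model$penalty, seed = model$seed,
    n_nonzero_terms = model$n_nonzero_terms,
    n_candidate_terms = model$n_candidate_terms,
    var_names = model$var_names,
    params = model$params,
    rules = lapply(model$rules, function(r) list(
      conditions = lapply(r$conditions, function(cd)
        list(var = model$var_names[cd$var], rel = cd$rel, thr = cd$thr)),
      coef = r$coef, support = r$support)),
    linear_terms = model$linear_terms
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  var_names <- unlist(obj$var_names)
  rules <- lapply(obj$rules, function(r) {
    conds <- lapply(r$conditions, function(cd)
      list(var = match(cd$var, var_names), rel = cd$rel, thr = cd$thr))
    list(conditions = conds, key = rule_key(conds),
         coef = r$coef, support = r$support)
  })
  lt <- NULL
  if (!is.null(obj$linear_terms) && length(obj$linear_terms)) {
    lt <- do.call(rbind, lapply(obj$linear_terms, as.data.frame))
  }
  structure(list(
    mode = obj$mode, intercept = obj$intercept, rules = rules,
    linear_terms = lt, var_names = var_names, penalty = obj$penalty,
    n_nonzero_terms = obj$n_nonzero_terms,
    n_candidate_terms = obj$n_candidate_terms,
    params = obj$params, seed = obj$seed
  ), class = "rule_ensemble")
}

## feature columns used as model predictors (targets and labels excluded)
predictor_columns <- function(tab) {
  drop <- c("SBP", "DBP", "MBP", "beat", "subject_id", "state")
  num <- names(tab)[vapply(tab, is.numeric, logical(1))]
  setdiff(num, drop)
}

#' Pipeline stages
#'
#' Each stage reads the previous stage's files and writes its own, so the
#' stages can be run one by one (e.g. from the command-line wrapper) or all
#' at once via [run_pipeline()], with identical results.
#'
#' `pipeline_synth` generates the configured subjects and rest/WBT sessions
#' and writes each record as CSV + JSON sidecar. `pipeline_extract` runs
#' preprocessing, fiducial detection and table assembly/cleaning on record
#' files and writes `beat_table.csv` and `exclusions.csv`.
#' `pipeline_fit` fits the configured rule-ensemble per target and writes
#' model JSON, term/variable importance CSVs and (optionally) the
#' interaction report. `pipeline_evaluate` writes the rest-vs-WBT
#' state-comparison report and the cross-validated model-comparison report.
#'
#' @param config A validated pipeline configuration.
#' @param out_dir Output directory.
#' @param prefixes Record path prefixes (for `pipeline_extract`).
#' @param beat_table_path Path of the beat table CSV.
#' @return Each stage returns the paths it wrote (invisibly where large).
#' @export
pipeline_synth <- function(config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prefixes <- character(0)
  for (s in seq_len(config$n_subjects)) {
    prof <- generate_subject(config$seed * 1000L + s)
    for (st in c("rest", "wbt")) {
      sp <- session_spec(st, duration = config$duration, fs = config$fs,
                         seed = config$seed * 1000L + s * 10L + (st == "wbt"))
      rec <- generate_session(prof, sp)
      pre <- file.path(out_dir, sprintf("record_%s_%s", prof$subject_id, st))
      write_record(rec, pre)
      prefixes <- c(prefixes, pre)
    }
  }
  prefixes
}

#' @rdname pipeline_synth
#' @export
pipeline_extract <- function(config, prefixes, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(); masks <- list(); logs <- list()
  for (pre in prefixes) {
    if (!file.exists(paste0(pre, ".csv"))) stop("unreadable input file: ", pre, ".csv")
    rec <- read_record(pre)
    tab <- extract_beat_table(rec, config, clean = TRUE)
    logs <- c(logs, list(list(subject = rec$profile$subject_id,
                              state = rec$spec$state,
                              cleaning = attr(tab, "cleaning_log"))))
    tabs <- c(tabs, list(tab))
    m <- attr(tab, "mask")
    if (!is.null(m) && nrow(m)) {
      m$subject <- rec$profile$subject_id; m$state <- rec$spec$state
      masks <- c(masks, list(m))
    }
  }
  beat_tab <- do.call(rbind, tabs)
  bt_path <- file.path(out_dir, "beat_table.csv")
  utils::write.csv(beat_tab, bt_path, row.names = FALSE)
  excl <- if (length(masks)) do.call(rbind, masks) else
    data.frame(start = numeric(0), end = numeric(0), kind = character(0),
               subject = character(0), state = character(0))
  ex_path <- file.path(out_dir, "exclusions.csv")
  utils::write.csv(excl, ex_path, row.names = FALSE)
  jsonlite::write_json(logs, file.path(out_dir, "extract_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  c(beat_table = bt_path, exclusions = ex_path,
    extract_log = file.path(out_dir, "extract_log.json"))
}

#' @rdname pipeline_synth
#' @export
pipeline_fit <- function(config, beat_table_path, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  beat_tab <- utils::read.csv(beat_table_path)
  X <- beat_tab[, predictor_columns(beat_tab)]
  paths <- character(0)
  for (tg in config$targets) {
    y <- beat_tab[[tg]]
    m <- rule_ensemble(X, y, mode = config$mode,
                       tree_size_mean = config$tree_size_mean,
                       n_trees = config$n_trees, shrinkage = config$shrinkage,
                       subsample = config$subsample,
                       winsor_delta = config$winsor_delta, seed = config$seed)
    mp <- file.path(out_dir, sprintf("model_%s.json", tg))
    write_model(m, mp)
    ip <- file.path(out_dir, sprintf("importance_%s.csv", tg))
    utils::write.csv(term_importance(m), ip, row.names = FALSE)
    vimp <- variable_importance(m)
    vp <- file.path(out_dir, sprintf("variable_importance_%s.csv", tg))
    utils::write.csv(data.frame(variable = names(vimp), importance = vimp),
                     vp, row.names = FALSE)
    paths <- c(paths, mp, ip, vp)
    if (isTRUE(config$run_interactions)) {
      ir <- interaction_strength(X, y, n_null = config$n_null,
                                 seed = config$seed, model = m,
                                 tree_size_mean = config$tree_size_mean,
                                 n_trees = config$n_trees,
                                 shrinkage = config$shrinkage,
                                 subsample = config$subsample,
                                 winsor_delta = config$winsor_delta)
      xp <- file.path(out_dir, sprintf("interactions_%s.csv", tg))
      utils::write.csv(ir, xp, row.names = FALSE)
      paths <- c(paths, xp)
    }
  }
  paths
}

#' @rdname pipeline_synth
#' @export
pipeline_evaluate <- function(config, beat_table_path, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  beat_tab <- utils::read.csv(beat_table_path)
  state_cmp <- wilcoxon_rest_vs_wbt(beat_tab)
  state_cmp$p_value_2dp <- sprintf("%.2f", state_cmp$p_value)
  sp <- file.path(out_dir, "report_state_comparison.csv")
  utils::write.csv(state_cmp, sp, row.names = FALSE)

  X <- beat_tab[, predictor_columns(beat_tab)]
  comparisons <- list()
  for (tg in config$targets) {
    cmp <- compare_model_variants(X, beat_tab[[tg]], k = config$k,
                                  seed = config$seed,
                                  tree_size_mean = config$tree_size_mean,
                                  n_trees = config$n_trees,
                                  shrinkage = config$shrinkage,
                                  subsample = config$subsample,
                                  winsor_delta = config$winsor_delta)
    cmp$target <- tg
    comparisons[[tg]] <- cmp
  }
  model_cmp <- do.call(rbind, comparisons)
  model_cmp$mae_2dp <- sprintf("%.2f", model_cmp$mae)
  model_cmp$rmse_2dp <- sprintf("%.2f", model_cmp$rmse)
  mp <- file.path(out_dir, "report_model_comparison.csv")
  utils::write.csv(model_cmp, mp, row.names = FALSE)
  c(state_comparison = sp, model_comparison = mp)
}

#' Run the full analysis pipeline
#'
#' Chains [pipeline_synth()] (or the configured input files),
#' [pipeline_extract()], [pipeline_fit()] and [pipeline_evaluate()] through
#' their on-disk artifacts, then writes a JSON run log with every effective
#' setting. Running the stages individually in sequence produces an
#' identical bundle.
#'
#' @param config Pipeline configuration (validated against
#'   [default_config()]).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the list of artifact paths.
#' @export
run_pipeline <- function(config = default_config(), out_dir = "pulserules_out") {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  started <- format(Sys.time())
  prefixes <- if (config$input == "files") {
    if (!all(nzchar(config$files))) stop("config input = files but no file prefixes given")
    config$files
  } else {
    pipeline_synth(config, out_dir)
  }
  p_ext <- pipeline_extract(config, prefixes, out_dir)
  p_fit <- pipeline_fit(config, p_ext[["beat_table"]], out_dir)
  p_eval <- pipeline_evaluate(config, p_ext[["beat_table"]], out_dir)
  log <- list(config = unclass(config), started = started,
              finished = format(Sys.time()),
              records = prefixes,
              artifacts = c(unname(p_ext), unname(p_fit), unname(p_eval)))
  lp <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, lp, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(as.list(p_ext), list(fit = p_fit), as.list(p_eval),
              list(run_log = lp)))
}
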