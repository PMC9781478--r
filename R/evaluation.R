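## Evaluation protocol: error metrics, 10-fold cross-validation, three-way
## model comparison, improvement arithmetic, and exact Wilcoxon signed-rank
## comparisons of rest vs weight-bearing state.

#' Mean absolute and root-mean-square error
#'
#' @param y_true,y_pred Equal-length numeric vectors (mmHg for BP targets).
#' @return Named vector `c(mae = , rmse = )`.
#' @export
error_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || !length(y_true)) {
    stop("y_true and y_pred must have equal nonzero length")
  }
  e <- y_pred - y_true
  c(mae = mean(abs(e)), rmse = sqrt(mean(e^2)))
}

#' Percentage improvement of a new error over a baseline
#'
#' `100 * (base - new) / base`; e.g. MAE falling from 2.303 to 2.056 is an
#' improvement of about 11 percent.
#'
#' @param base_mae Baseline error (> 0).
#' @param new_mae New error.
#' @return Percentage.
#' @export
percent_improvement <- function(base_mae, new_mae) {
  stopifnot(base_mae > 0)
  100 * (base_mae - new_mae) / base_mae
}

#' k-fold cross-validation of a rule-ensemble model
#'
#' Rows are shuffled with the given seed and split into `k` folds whose sizes
#' differ by at most one. Each fold is predicted by a model fitted on the
#' remaining folds (including the internal penalty selection). Pooled
#' metrics are computed over the concatenated held-out predictions, not by
#' averaging per-fold metrics.
#'
#' @param X Predictors.
#' @param y Response.
#' @param mode Model variant, see [rule_ensemble()].
#' @param k Number of folds (default 10).
#' @param seed Seed controlling fold assignment and fits.
#' @param ... Passed to [rule_ensemble()].
#' @return List of class `cv_result`: `fold_metrics` (per-fold MAE/RMSE and
#'   non-zero term count), `mae`, `rmse` (pooled), `predictions`, `folds`.
#' @export
kfold_cv <- function(X, y, mode = "rules_plus_linear", k = 10, seed = 1, ...) {
  X <- as_predictor_matrix(X)
  n <- nrow(X)
  if (k > n) stop("k exceeds number of rows")
  set.seed(seed)
  folds <- sample(rep_len(seq_len(k), n))
  pred <- numeric(n)
  fm <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    m <- rule_ensemble(X[tr, , drop = FALSE], y[tr], mode = mode,
                       seed = seed + f, ...)
    p <- predict(m, X[!tr, , drop = FALSE])
    pred[!tr] <- p
    em <- error_metrics(y[!tr], p)
    fm[[f]] <- data.frame(fold = f, mae = em["mae"], rmse = em["rmse"],
                          n_nonzero_terms = m$n_nonzero_terms,
                          n_test = sum(!tr))
  }
  pooled <- error_metrics(y, pred)
  structure(list(mode = mode, k = k, seed = seed,
                 fold_metrics = do.call(rbind, fm),
                 mae = unname(pooled["mae"]), rmse = unname(pooled["rmse"]),
                 n = n, predictions = pred, folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d-fold, n=%d: MAE %.3f, RMSE %.3f\n",
              x$mode, x$k, x$n, x$mae, x$rmse))
  invisible(x)
}

#' Compare the three rule-ensemble variants by cross-validation
#'
#' Runs [kfold_cv()] for the purely linear model, the additive rules-only
#' model (stumps) and the full rules-plus-linear model, and also reports
#' training-set refits of each variant. The result mirrors a
#' model-comparison report: per variant, the number of non-zero terms and
#' the cross-validated MAE and RMSE.
#'
#' @inheritParams kfold_cv
#' @return Data frame with one row per variant: `mode`, `n_terms` (median
#'   non-zero terms over folds), `n_terms_train` (non-zero terms of a fit on
#'   all rows), `mae`, `rmse` (pooled CV), `mae_train`, `rmse_train`.
#' @export
compare_model_variants <- function(X, y, k = 10, seed = 1, ...) {
  modes <- c("linear_only", "rules_only", "rules_plus_linear")
  rows <- lapply(modes, function(md) {
    cv <- kfold_cv(X, y, mode = md, k = k, seed = seed, ...)
    mfull <- rule_ensemble(X, y, mode = md, seed = seed, ...)
    tm <- error_metrics(y, predict(mfull, X))
    data.frame(mode = md,
               n_terms = stats::median(cv$fold_metrics$n_nonzero_terms),
               n_terms_train = mfull$n_nonzero_terms,
               n_candidate_terms = mfull$n_candidate_terms,
               mae = cv$mae, rmse = cv$rmse,
               mae_train = unname(tm["mae"]), rmse_train = unname(tm["rmse"]))
  })
  do.call(rbind, rows)
}

#' Exact two-sided Wilcoxon signed-rank test
#'
#' Computes the two-sided p-value of the paired signed-rank statistic. Zero
#' differences are dropped first (the exact-test convention). With no ties
#' among the absolute differences the exact null distribution
#' (`stats::psignrank`) is used; with ties, the p-value is computed by full
#' enumeration of the 2^n sign assignments (n <= 20), and beyond that by the
#' normal approximation with tie correction.
#'
#' @param x,y Paired samples, or `y = NULL` to test differences `x` directly.
#' @return List: `statistic` (V, sum of positive ranks), `p_value`, `n_used`.
#' @export
wilcoxon_signed_rank_exact <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (!n) return(list(statistic = 0, p_value = 1, n_used = 0L))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  has_ties <- any(duplicated(r))
  if (!has_ties) {
    lo <- stats::psignrank(v, n)                  # P(V <= v)
    hi <- 1 - stats::psignrank(v - 1, n)          # P(V >= v)
    p <- min(1, 2 * min(lo, hi))
  } else if (n <= 20) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.numeric(signs %*% r)
    lo <- mean(vs <= v)
    hi <- mean(vs >= v)
    p <- min(1, 2 * min(lo, hi))
  } else {
    mu <- sum(r) / 2
    sig2 <- sum(r^2) / 4
    z <- (v - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = v, p_value = p, n_used = n)
}

#' Rest-vs-WBT comparison of hemodynamic variables
#'
#' Collapses a beat table to per-subject means within each state, then tests
#' each variable with the exact two-sided Wilcoxon signed-rank test on the
#' paired per-subject differences. Subjects present in only one state are
#' excluded with a warning.
#'
#' @param beat_table Beat feature table with `subject_id` and `state`
#'   columns.
#' @param variables Variables to compare; defaults to all numeric columns.
#' @param alpha Significance level (default 0.05).
#' @return Data frame per variable: rest/WBT mean and SD (across subjects),
#'   `p_value`, `significant`, `n_pairs`.
#' @export
wilcoxon_rest_vs_wbt <- function(beat_table, variables = NULL, alpha = 0.05) {
  stopifnot(all(c("subject_id", "state") %in% names(beat_table)))
  if (is.null(variables)) {
    variables <- setdiff(names(beat_table)[vapply(beat_table, is.numeric,
                                                  logical(1))], "beat")
  }
  subj <- unique(beat_table$subject_id)
  both <- vapply(subj, function(s) {
    st <- unique(beat_table$state[beat_table$subject_id == s])
    all(c("rest", "wbt") %in% st)
  }, logical(1))
  if (any(!both)) {
    warning("subjects missing one state excluded: ",
            paste(subj[!both], collapse = ", "))
  }
  subj <- subj[both]
  if (!length(subj)) stop("no subjects with both states")
  rows <- lapply(variables, function(v) {
    m_rest <- vapply(subj, function(s) mean(beat_table[[v]][
      beat_table$subject_id == s & beat_table$state == "rest"], na.rm = TRUE),
      numeric(1))
    m_wbt <- vapply(subj, function(s) mean(beat_table[[v]][
      beat_table$subject_id == s & beat_table$state == "wbt"], na.rm = TRUE),
      numeric(1))
    wt <- wilcoxon_signed_rank_exact(m_wbt, m_rest)
    data.frame(variable = v,
               rest_mean = mean(m_rest), rest_sd = stats::sd(m_rest),
               wbt_mean = mean(m_wbt), wbt_sd = stats::sd(m_wbt),
               p_value = wt$p_value, significant = wt$p_value < alpha,
               n_pairs = wt$n_used)
  })
  do.call(rbind, rows)
}
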