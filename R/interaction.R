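## Friedman-Popescu H-statistic interaction screening with a null reference
## distribution built from an additive (main-effects) surrogate.

## Fast exact partial-dependence decomposition for a rule-ensemble model.
## For variable j, every rule factorizes as r_k(x) = I_kj(x_j) * I_k,-j(x_-j),
## so PD_j and PD_-j over the training rows reduce to rule-indicator means --
## no O(n^2) re-prediction needed.
h_components <- function(model, X, j_name) {
  n <- nrow(X)
  f <- predict(model, X)
  lt <- model$linear_terms
  lin_j <- 0; lin_rest <- 0
  pdj <- rep(0, n); pdr <- rep(0, n)
  if (!is.null(lt) && nrow(lt)) {
    for (k in seq_len(nrow(lt))) {
      if (lt$coef[k] == 0) next
      lx <- lt$coef[k] * winsor_clip(X[, lt$variable[k]], lt[k, ])
      if (lt$variable[k] == j_name) pdj <- pdj + lx else pdr <- pdr + lx
    }
  }
  j_idx <- match(j_name, model$var_names)
  for (r in model$rules) {
    if (r$coef == 0) next
    on_j <- vapply(r$conditions, function(cd) cd$var == j_idx, logical(1))
    ij <- rep(TRUE, n); irest <- rep(TRUE, n)
    for (k in seq_along(r$conditions)) {
      cd <- r$conditions[[k]]
      hit <- if (cd$rel == "<=") X[, cd$var] <= cd$thr else X[, cd$var] > cd$thr
      if (on_j[k]) ij <- ij & hit else irest <- irest & hit
    }
    ## PD_j(x_j)  = a_k I_kj(x_j)  * mean(I_k,-j)
    ## PD_-j(x_-j)= a_k mean(I_kj) * I_k,-j(x_-j)
    pdj <- pdj + r$coef * ij * mean(irest)
    pdr <- pdr + r$coef * mean(ij) * irest
  }
  list(f = f - mean(f), pdj = pdj - mean(pdj), pdr = pdr - mean(pdr))
}

## H_j for every requested variable on (a subsample of) X
h_statistic <- function(model, X, variables) {
  vapply(variables, function(v) {
    cmp <- h_components(model, X, v)
    denom <- sum(cmp$f^2)
    if (denom <= 0) return(0)
    h2 <- sum((cmp$f - cmp$pdj - cmp$pdr)^2) / denom
    sqrt(min(max(h2, 0), 1))
  }, numeric(1))
}

#' Interaction strength (H-statistic) with a null reference
#'
#' For each variable, computes the Friedman-Popescu H-statistic of a fitted
#' rule-ensemble model: the normalized discrepancy between the model and the
#' sum of its partial-dependence components in that variable, evaluated on
#' training rows (H = 0 for an additive fit, 1 if all variation is
#' non-additive). Because finite samples and adaptive fitting produce
#' non-zero H even without true interactions, a null distribution is
#' estimated by parametric bootstrap from an additive surrogate: a
#' main-effects-only model (stump rules + linear terms) is fitted, null
#' responses are formed as its predictions plus resampled residuals, the
#' full model is refitted on each, and the spread of the resulting H values
#' gives the per-variable null mean and SD. A variable is flagged when its
#' observed H exceeds `null_mean + 2 * null_sd`.
#'
#' @param X Predictors (data frame or matrix).
#' @param y Response.
#' @param variables Variables to score; default all.
#' @param n_null Number of null replicates (>= 10).
#' @param n_pd_rows Row subsample used for the H evaluation (keeps the
#'   partial-dependence sums cheap and stable).
#' @param seed Integer seed.
#' @param model Optionally, an already fitted full model to score.
#' @param ... Parameters passed to [rule_ensemble()] for the full model and
#'   the null refits.
#' @return Data frame: `variable`, `H`, `null_mean`, `null_sd`, `flag`.
#' @export
interaction_strength <- function(X, y, variables = NULL, n_null = 20,
                                 n_pd_rows = 300, seed = 1, model = NULL, ...) {
  if (n_null < 10) stop("n_null must be >= 10")
  X <- as_predictor_matrix(X)
  if (is.null(variables)) variables <- colnames(X)
  if (is.null(model)) {
    model <- rule_ensemble(X, y, mode = "rules_plus_linear", seed = seed, ...)
  }
  set.seed(seed + 1)
  rows <- if (nrow(X) > n_pd_rows) sort(sample.int(nrow(X), n_pd_rows)) else seq_len(nrow(X))
  Xs <- X[rows, , drop = FALSE]
  H <- h_statistic(model, Xs, variables)

  ## additive surrogate: stumps + linear terms (no multi-variable rules)
  surrogate <- rule_ensemble(X, y, mode = "rules_only", stump_additive = TRUE,
                             seed = seed, ...)
  g <- predict(surrogate, X)
  resid <- y - g
  null_h <- matrix(NA_real_, n_null, length(variables),
                   dimnames = list(NULL, variables))
  for (b in seq_len(n_null)) {
    set.seed(seed + 1000 + b)
    y_null <- g + sample(resid, length(resid), replace = TRUE)
    m_null <- rule_ensemble(X, y_null, mode = "rules_plus_linear",
                            seed = seed + 2000 + b, ...)
    null_h[b, ] <- h_statistic(m_null, Xs, variables)
  }
  nm <- colMeans(null_h)
  ns <- apply(null_h, 2, stats::sd)
  data.frame(variable = variables, H = unname(H),
             null_mean = unname(nm), null_sd = unname(ns),
             n_null = n_null,
             flag = unname(H > nm + 2 * ns))
}
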