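## Rule-ensemble regression: winsorized linear terms, L1-sparse fit over
## rules + linears, prediction, term/variable importance and partial
## dependence.

#' Winsorized linear terms
#'
#' For each predictor, computes clipping bounds at the `delta` and
#' `1 - delta` empirical quantiles (linear interpolation between order
#' statistics) and the standard deviation of the clipped variable. Clipping
#' limits the leverage of extreme values when the variable enters the sparse
#' linear model directly.
#'
#' @param X Predictor matrix or data frame.
#' @param delta Quantile trimming fraction in `[0, 0.5)`; 0 disables
#'   clipping.
#' @return Data frame with one row per predictor: `variable`, `winsor_lo`,
#'   `winsor_hi`, `sd_lj`.
#' @export
winsorize_linear_terms <- function(X, delta = 0.025) {
  stopifnot(delta >= 0, delta < 0.5)
  X <- as_predictor_matrix(X)
  out <- lapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    q <- stats::quantile(x, c(delta, 1 - delta), names = FALSE, type = 7)
    lx <- pmin(pmax(x, q[1]), q[2])
    data.frame(variable = colnames(X)[j], winsor_lo = q[1], winsor_hi = q[2],
               sd_lj = stats::sd(lx))
  })
  do.call(rbind, out)
}

## apply the winsor clip of one linear term to a vector
winsor_clip <- function(x, term) pmin(pmax(x, term$winsor_lo), term$winsor_hi)

## build the model design matrix: [rule indicators | winsorized linears]
build_design <- function(rules, linear_terms, X, mode) {
  parts <- list()
  if (mode %in% c("rules_only", "rules_plus_linear") && length(rules)) {
    parts$rules <- rule_matrix(rules, X)
  }
  if (mode %in% c("linear_only", "rules_plus_linear") && !is.null(linear_terms) &&
      nrow(linear_terms)) {
    lin <- vapply(seq_len(nrow(linear_terms)), function(j) {
      winsor_clip(X[, linear_terms$variable[j]], linear_terms[j, ])
    }, numeric(nrow(X)))
    if (is.null(dim(lin))) lin <- matrix(lin, nrow = nrow(X))
    colnames(lin) <- paste0("lin:", linear_terms$variable)
    parts$lin <- lin
  }
  do.call(cbind, parts)
}

#' Fit the sparse linear model over rules and linear terms
#'
#' Assembles the design matrix of 0/1 rule indicators and winsorized linear
#' terms according to `mode`, standardizes columns internally, and fits an
#' L1-penalized squared-error model. The penalty is chosen by internal
#' k-fold cross-validation over `penalty_grid` on the training data only
#' (one-SE-free minimum rule); coefficients are reported on the original
#' term scale. A penalty of exactly 0 is fitted by ordinary least squares
#' (the lasso limit), and a single very large penalty returns the
#' intercept-only model `mean(y)`.
#'
#' @param rules Rule list from [build_rule_ensemble()] (may be empty for
#'   `linear_only`).
#' @param linear_terms Data frame from [winsorize_linear_terms()] (may be
#'   NULL for `rules_only`).
#' @param X Predictor matrix/data frame (original variables).
#' @param y Response vector.
#' @param mode One of `"linear_only"`, `"rules_only"`, `"rules_plus_linear"`.
#' @param penalty_grid Numeric vector of L1 penalties; `NULL` lets the lasso
#'   path choose a 50-value log-spaced grid from the data.
#' @param cv_folds Internal folds for penalty selection.
#' @param seed Seed for the internal fold assignment.
#' @return A `rule_ensemble` model object.
#' @export
fit_sparse_linear <- function(rules, linear_terms, X, y,
                              mode = c("rules_plus_linear", "rules_only",
                                       "linear_only"),
                              penalty_grid = NULL, cv_folds = 5, seed = 1) {
  mode <- match.arg(mode)
  X <- as_predictor_matrix(X)
  if (!is.null(penalty_grid) && !length(penalty_grid)) stop("penalty grid is empty")
  if (mode != "linear_only" && !length(rules)) stop("mode needs rules but none supplied")
  if (mode != "rules_only" && (is.null(linear_terms) || !nrow(linear_terms))) {
    stop("mode needs linear terms but none supplied")
  }
  if (!is.null(penalty_grid) && !length(penalty_grid)) stop("penalty grid is empty")
  if (mode == "linear_only") rules <- list()
  if (mode == "rules_only") linear_terms <- NULL
  design <- build_design(rules, linear_terms, X, mode)
  if (is.null(design) || !ncol(design)) stop("empty design matrix")
  n_rules <- if (length(rules)) length(rules) else 0L

  single <- !is.null(penalty_grid) && length(penalty_grid) == 1
  keep <- which(apply(design, 2, stats::sd) > 0)
  coefs <- numeric(ncol(design))
  cvm_trace <- NULL
  if (!length(keep)) {
    intercept <- mean(y)
    lambda <- if (single) penalty_grid else NA_real_
  } else if (length(keep) == 1 && single && penalty_grid > 0) {
    ## one-predictor lasso in closed form (glmnet needs >= 2 columns):
    ## minimize (1/2n) sum (y - b0 - x b)^2 + lambda |b| on the
    ## population-standardized predictor
    x <- design[, keep]
    n <- length(y)
    mx <- mean(x); sx <- sqrt(mean((x - mx)^2))
    z <- (x - mx) / sx
    rho <- mean(z * (y - mean(y)))
    b_std <- sign(rho) * max(abs(rho) - penalty_grid, 0)
    coefs[keep] <- b_std / sx
    intercept <- mean(y) - coefs[keep] * mx
    lambda <- penalty_grid
  } else if (length(keep) == 1) {
    ## a single candidate term needs no penalty selection
    fit <- stats::lm.fit(cbind(1, design[, keep, drop = FALSE]), y)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    intercept <- beta[1]
    coefs[keep] <- beta[-1]
    lambda <- 0
  } else if (single && penalty_grid == 0) {
    fit <- stats::lm.fit(cbind(1, design[, keep, drop = FALSE]), y)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    intercept <- beta[1]
    coefs[keep] <- beta[-1]
    lambda <- 0
  } else if (single) {
    fit <- glmnet::glmnet(design[, keep, drop = FALSE], y, alpha = 1,
                          standardize = TRUE, thresh = 1e-12)
    cf <- as.numeric(stats::coef(fit, s = penalty_grid, exact = TRUE,
                                 x = design[, keep, drop = FALSE], y = y))
    intercept <- cf[1]
    coefs[keep] <- cf[-1]
    lambda <- penalty_grid
  } else {
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(cv_folds), length(y)))
    cv <- glmnet::cv.glmnet(design[, keep, drop = FALSE], y, alpha = 1,
                            lambda = penalty_grid, nlambda = 50,
                            lambda.min.ratio = 1e-3,
                            foldid = foldid, standardize = TRUE, thresh = 1e-7)
    cf <- as.numeric(stats::coef(cv, s = "lambda.min"))
    intercept <- cf[1]
    coefs[keep] <- cf[-1]
    lambda <- cv$lambda.min
    cvm_trace <- data.frame(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd,
                            nzero = as.integer(cv$nzero))
  }

  for (i in seq_along(rules)) rules[[i]]$coef <- coefs[i]
  if (!is.null(linear_terms) && nrow(linear_terms)) {
    linear_terms$coef <- coefs[n_rules + seq_len(nrow(linear_terms))]
  }
  structure(list(
    mode = mode, intercept = unname(intercept), rules = rules,
    linear_terms = linear_terms, var_names = colnames(X),
    penalty = lambda, penalty_trace = cvm_trace,
    n_nonzero_terms = sum(coefs != 0),
    n_candidate_terms = ncol(design), seed = seed
  ), class = "rule_ensemble")
}

#' Fit a rule-ensemble regression model
#'
#' One-call wrapper: generates rules from a boosted tree ensemble (unless
#' `mode = "linear_only"`), winsorizes linear terms (unless
#' `mode = "rules_only"`), and fits the L1-sparse combined model.
#' For `mode = "rules_only"` the trees are forced to stumps
#' (`tree_size_mean = 2`), whose single-variable rules span an additive
#' main-effects model.
#'
#' @inheritParams fit_sparse_linear
#' @inheritParams build_rule_ensemble
#' @param winsor_delta Trimming fraction for linear terms.
#' @param stump_additive Force stumps when `mode = "rules_only"`
#'   (default TRUE).
#' @return A `rule_ensemble` model.
#' @export
rule_ensemble <- function(X, y, mode = c("rules_plus_linear", "rules_only",
                                         "linear_only"),
                          tree_size_mean = 3, n_trees = 300, shrinkage = 0.01,
                          subsample = 0.5, min_node = 10, winsor_delta = 0.025,
                          penalty_grid = NULL, cv_folds = 5, seed = 1,
                          stump_additive = TRUE) {
  mode <- match.arg(mode)
  X <- as_predictor_matrix(X)
  rules <- list()
  if (mode != "linear_only") {
    ts <- if (mode == "rules_only" && stump_additive) 2 else tree_size_mean
    rules <- build_rule_ensemble(X, y, tree_size_mean = ts, n_trees = n_trees,
                                 shrinkage = shrinkage, subsample = subsample,
                                 min_node = min_node, seed = seed)
  }
  lt <- if (mode == "rules_only") NULL else winsorize_linear_terms(X, winsor_delta)
  model <- fit_sparse_linear(rules, lt, X, y, mode = mode,
                             penalty_grid = penalty_grid, cv_folds = cv_folds,
                             seed = seed)
  model$params <- list(tree_size_mean = tree_size_mean, n_trees = n_trees,
                       shrinkage = shrinkage, subsample = subsample,
                       min_node = min_node, winsor_delta = winsor_delta,
                       cv_folds = cv_folds)
  model
}

#' @export
print.rule_ensemble <- function(x, ...) {
  cat(sprintf("<rule_ensemble> mode %s: %d candidate terms, %d non-zero (penalty %.4g)\n",
              x$mode, x$n_candidate_terms, x$n_nonzero_terms, x$penalty))
  invisible(x)
}

#' Predict from a rule-ensemble model
#'
#' `intercept + sum(a_k r_k(x)) + sum(b_j l_j(x_j))` with `r_k` the 0/1 rule
#' indicators and `l_j` the winsorized linear terms.
#'
#' @param object A `rule_ensemble` model.
#' @param newdata Data frame or matrix containing every variable the model
#'   references.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.rule_ensemble <- function(object, newdata, ...) {
  X <- as_predictor_matrix(newdata)
  missing_vars <- setdiff(object$var_names, colnames(X))
  if (length(missing_vars)) {
    stop("newdata lacks variables: ", paste(missing_vars, collapse = ", "))
  }
  X <- X[, object$var_names, drop = FALSE]
  pred <- rep(object$intercept, nrow(X))
  for (r in object$rules) {
    if (r$coef != 0) pred <- pred + r$coef * as.numeric(eval_rule(r, X))
  }
  lt <- object$linear_terms
  if (!is.null(lt) && nrow(lt)) {
    for (j in seq_len(nrow(lt))) {
      if (lt$coef[j] != 0) {
        pred <- pred + lt$coef[j] * winsor_clip(X[, lt$variable[j]], lt[j, ])
      }
    }
  }
  pred
}

#' Term importance of a fitted rule ensemble
#'
#' Linear terms score `|b_j| * sd(l_j(x_j))`; rules score
#' `|a_k| * sqrt(s_k (1 - s_k))`, where `s_k` is the rule's training support
#' (the SD of a Bernoulli indicator). Terms are sorted by decreasing
#' importance with a deterministic tie-break on the term identifier.
#'
#' @param model A fitted `rule_ensemble`.
#' @return Data frame: `term`, `type`, `coef`, `support`, `importance`.
#' @export
term_importance <- function(model) {
  rows <- list()
  for (r in model$rules) {
    rows <- c(rows, list(data.frame(
      term = format_rule(r, model$var_names), type = "rule", coef = r$coef,
      support = r$support,
      importance = abs(r$coef) * sqrt(r$support * (1 - r$support)))))
  }
  lt <- model$linear_terms
  if (!is.null(lt) && nrow(lt)) {
    for (j in seq_len(nrow(lt))) {
      rows <- c(rows, list(data.frame(
        term = lt$variable[j], type = "linear", coef = lt$coef[j],
        support = NA_real_, importance = abs(lt$coef[j]) * lt$sd_lj[j])))
    }
  }
  out <- do.call(rbind, rows)
  out[order(-out$importance, out$term), , drop = FALSE]
}

#' Variable importance of a fitted rule ensemble
#'
#' A variable's importance is its linear-term importance plus, for every rule
#' it appears in, the rule's importance divided by the number of distinct
#' variables in that rule. Scores are normalized so the most important
#' variable reads 100.
#'
#' @param model A fitted `rule_ensemble`.
#' @param normalize Scale the maximum to 100 (default TRUE).
#' @return Named numeric vector over the model's variables, decreasing.
#' @export
variable_importance <- function(model, normalize = TRUE) {
  imp <- stats::setNames(numeric(length(model$var_names)), model$var_names)
  for (r in model$rules) {
    ri <- abs(r$coef) * sqrt(r$support * (1 - r$support))
    if (ri == 0) next
    vars <- unique(vapply(r$conditions, function(cd) cd$var, numeric(1)))
    imp[vars] <- imp[vars] + ri / length(vars)
  }
  lt <- model$linear_terms
  if (!is.null(lt) && nrow(lt)) {
    for (j in seq_len(nrow(lt))) {
      imp[lt$variable[j]] <- imp[lt$variable[j]] + abs(lt$coef[j]) * lt$sd_lj[j]
    }
  }
  if (normalize && max(imp) > 0) imp <- 100 * imp / max(imp)
  sort(imp, decreasing = TRUE)
}

#' Partial dependence of a rule-ensemble model
#'
#' `pd(v) = mean_i f(x_i with the chosen variable(s) set to v)`, evaluated
#' over a decile grid (or a supplied grid) of one or two variables.
#'
#' @param model A fitted `rule_ensemble`.
#' @param X Training data (data frame or matrix).
#' @param variables Character vector of one or two variable names.
#' @param grid Optional list of grid values per variable; defaults to
#'   deciles.
#' @return Data frame of grid value(s) and `pd`.
#' @export
partial_dependence <- function(model, X, variables, grid = NULL) {
  X <- as_predictor_matrix(X)
  stopifnot(length(variables) %in% 1:2, all(variables %in% colnames(X)))
  if (is.null(grid)) {
    grid <- lapply(variables, function(v)
      unname(stats::quantile(X[, v], probs = seq(0.05, 0.95, by = 0.1), type = 7)))
    names(grid) <- variables
  }
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  pd <- vapply(seq_len(nrow(pts)), function(i) {
    Xc <- X
    for (v in variables) Xc[, v] <- pts[i, v]
    mean(predict(model, Xc))
  }, numeric(1))
  cbind(pts, pd = pd)
}
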