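## Regression-tree and gradient-boosting machinery for rule generation.
##
## Rules are conjunctions of axis-aligned conditions harvested from the nodes
## of small boosted regression trees. Trees are grown best-first (the split
## with the largest squared-error reduction anywhere on the frontier is taken
## next) so the terminal-node count can be controlled exactly.

## best split of one node: returns list(var, thr, gain, left) or NULL
best_split <- function(X, y, rows, min_node) {
  n <- length(rows)
  if (n < 2 * min_node) return(NULL)
  yy <- y[rows]
  sy <- sum(yy)
  best <- NULL
  best_gain <- 1e-12
  for (j in seq_len(ncol(X))) {
    x <- X[rows, j]
    ord <- order(x)
    xs <- x[ord]
    ys <- yy[ord]
    cs <- cumsum(ys)
    k <- seq_len(n - 1)
    valid <- xs[k] < xs[k + 1] & k >= min_node & (n - k) >= min_node
    if (!any(valid)) next
    k <- k[valid]
    gain <- cs[k]^2 / k + (sy - cs[k])^2 / (n - k) - sy^2 / n
    i <- which.max(gain)
    if (gain[i] > best_gain) {
      best_gain <- gain[i]
      thr <- (xs[k[i]] + xs[k[i] + 1]) / 2
      best <- list(var = j, thr = thr, gain = gain[i])
    }
  }
  best
}

## grow a best-first regression tree with a fixed number of terminal nodes;
## returns a list of nodes, each list(path = list of (var, rel, thr), rows)
## where `path` excludes the root (which has none)
grow_tree <- function(X, y, rows, n_leaves, min_node = 10) {
  root <- list(path = list(), rows = rows)
  root$split <- best_split(X, y, rows, min_node)
  leaves <- list(root)
  internal <- list()
  while (length(leaves) < n_leaves) {
    gains <- vapply(leaves, function(nd)
      if (is.null(nd$split)) -Inf else nd$split$gain, numeric(1))
    if (all(!is.finite(gains))) break
    i <- which.max(gains)
    nd <- leaves[[i]]
    sp <- nd$split
    x <- X[nd$rows, sp$var]
    lrows <- nd$rows[x <= sp$thr]
    rrows <- nd$rows[x > sp$thr]
    left <- list(path = c(nd$path, list(list(var = sp$var, rel = "<=", thr = sp$thr))),
                 rows = lrows)
    right <- list(path = c(nd$path, list(list(var = sp$var, rel = ">", thr = sp$thr))),
                  rows = rrows)
    left$split <- best_split(X, y, lrows, min_node)
    right$split <- best_split(X, y, rrows, min_node)
    internal <- c(internal, list(nd))
    leaves <- c(leaves[-i], list(left, right))
  }
  list(leaves = leaves, internal = internal)
}

## terminal-node prediction of a tree on arbitrary rows of X
tree_predict <- function(tree, X, y_train, train_rows_used) {
  pred <- numeric(nrow(X))
  for (lf in tree$leaves) {
    mu <- mean(y_train[lf$rows])
    sel <- rep(TRUE, nrow(X))
    for (cond in lf$path) {
      sel <- sel & (if (cond$rel == "<=") X[, cond$var] <= cond$thr
                    else X[, cond$var] > cond$thr)
    }
    pred[sel] <- mu
  }
  pred
}

## simplify a condition path: keep the binding threshold per (var, rel)
simplify_path <- function(path) {
  if (!length(path)) return(path)
  key <- vapply(path, function(cd) paste(cd$var, cd$rel), character(1))
  out <- list()
  for (k in unique(key)) {
    cds <- path[key == k]
    thr <- vapply(cds, function(cd) cd$thr, numeric(1))
    cd <- cds[[1]]
    cd$thr <- if (cd$rel == "<=") min(thr) else max(thr)
    out <- c(out, list(cd))
  }
  ## canonical order for de-duplication
  ord <- order(vapply(out, function(cd) cd$var, numeric(1)),
               vapply(out, function(cd) cd$rel, character(1)))
  out[ord]
}

rule_key <- function(path) {
  paste(vapply(path, function(cd)
    sprintf("x%d%s%.12g", cd$var, cd$rel, cd$thr), character(1)), collapse = " & ")
}

## draw terminal-node counts whose mean equals tree_size_mean (>= 2):
## 2 + floor(Exp(mu)) with mu chosen so E[floor] = tree_size_mean - 2
draw_tree_sizes <- function(n, tree_size_mean) {
  if (tree_size_mean <= 2) return(rep(2L, n))
  p <- (tree_size_mean - 2) / (tree_size_mean - 1)
  mu <- -1 / log(p)
  2L + as.integer(floor(stats::rexp(n, rate = 1 / mu)))
}

#' Generate decision rules from a boosted tree ensemble
#'
#' Runs gradient boosting on squared loss: each iteration fits a small
#' best-first regression tree to the current residuals on a row subsample,
#' with the terminal-node count drawn so its mean equals `tree_size_mean`
#' (minimum 2; a mean of 2 forces stumps, whose rules involve a single
#' variable each and therefore span only additive main effects). Every
#' non-root node of every tree contributes one rule — the conjunction of the
#' conditions on its root path. Rules are simplified to their binding
#' thresholds and de-duplicated; supports are computed on all training rows.
#'
#' @param X Numeric matrix (or data frame) of predictors, no missing values.
#' @param y Numeric response.
#' @param tree_size_mean Mean terminal-node count per tree (study value 3,
#'   which admits pairwise and some higher-order interactions).
#' @param n_trees Number of boosting iterations.
#' @param shrinkage Learning rate.
#' @param subsample Row-subsampling fraction per tree.
#' @param min_node Minimum rows per terminal node.
#' @param seed Integer seed; the whole generation is deterministic given it.
#' @return List of rules, each `list(conditions, support, key)`; variable
#'   names are kept in the `"var_names"` attribute.
#' @export
build_rule_ensemble <- function(X, y, tree_size_mean = 3, n_trees = 300,
                                shrinkage = 0.01, subsample = 0.5,
                                min_node = 10, seed = 1) {
  X <- as_predictor_matrix(X)
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (anyNA(X) || anyNA(y)) stop("missing values in X or y")
  stopifnot(nrow(X) == length(y))
  set.seed(seed)
  n <- nrow(X)
  sizes <- draw_tree_sizes(n_trees, tree_size_mean)
  f <- rep(mean(y), n)
  seen <- new.env(hash = TRUE)
  rules <- list()
  for (m in seq_len(n_trees)) {
    res <- y - f
    rows <- sort(sample.int(n, max(2 * min_node, floor(subsample * n))))
    tree <- grow_tree(X, res, rows, sizes[m], min_node)
    if (length(tree$leaves) < 2) next
    f <- f + shrinkage * tree_predict(tree, X, res)
    for (nd in c(tree$leaves, tree$internal)) {
      if (!length(nd$path)) next
      path <- simplify_path(nd$path)
      key <- rule_key(path)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      rules <- c(rules, list(list(conditions = path, key = key)))
    }
  }
  ## supports on the full training set
  for (i in seq_along(rules)) {
    rules[[i]]$support <- mean(eval_rule(rules[[i]], X))
  }
  attr(rules, "var_names") <- colnames(X)
  rules
}

## evaluate one rule -> logical vector over rows of X
eval_rule <- function(rule, X) {
  sel <- rep(TRUE, nrow(X))
  for (cd in rule$conditions) {
    sel <- sel & (if (cd$rel == "<=") X[, cd$var] <= cd$thr else X[, cd$var] > cd$thr)
  }
  sel
}

## 0/1 indicator matrix of a rule list over rows of X
rule_matrix <- function(rules, X) {
  if (!length(rules)) return(matrix(0, nrow(X), 0))
  m <- vapply(rules, function(r) as.numeric(eval_rule(r, X)), numeric(nrow(X)))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(X))
  colnames(m) <- vapply(rules, function(r) r$key, character(1))
  m
}

## coerce a data frame / matrix of predictors to a plain numeric matrix
as_predictor_matrix <- function(X) {
  if (is.data.frame(X)) {
    num <- vapply(X, is.numeric, logical(1))
    X <- as.matrix(X[, num, drop = FALSE])
  }
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

#' Human-readable formatting of a rule
#' @param rule A rule as produced by [build_rule_ensemble()].
#' @param var_names Variable names indexed by the rule's condition columns.
#' @return Single string such as `"oPAT <= 0.241 & AM > 2.53"`.
#' @export
format_rule <- function(rule, var_names = NULL) {
  paste(vapply(rule$conditions, function(cd) {
    v <- if (is.null(var_names)) paste0("x", cd$var) else var_names[cd$var]
    sprintf("%s %s %.4g", v, cd$rel, cd$thr)
  }, character(1)), collapse = " & ")
}
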