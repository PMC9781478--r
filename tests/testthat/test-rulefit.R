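make_xy <- function(n = 400, seed = 1) {
  set.seed(seed)
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- 2 * X$x1 + 3 * (X$x1 > 0.3) * X$x2 + rnorm(n, 0, 0.5)
  list(X = X, y = y)
}

test_that("tree node enumeration yields the expected rule counts", {
  set.seed(2)
  X <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("x1", "x2")))
  y <- X[, 1] + rnorm(200, 0, 0.1)
  # a stump: 2 terminal nodes -> 2 non-root nodes -> 2 complementary rules
  tr2 <- pulserules:::grow_tree(X, y, seq_len(200), n_leaves = 2)
  nodes2 <- c(tr2$leaves, tr2$internal)
  paths2 <- Filter(length, lapply(nodes2, `[[`, "path"))
  expect_length(paths2, 2)
  thr <- unique(vapply(paths2, function(p) p[[1]]$thr, numeric(1)))
  expect_length(thr, 1)
  expect_setequal(vapply(paths2, function(p) p[[1]]$rel, character(1)),
                  c("<=", ">"))
  # a 3-leaf tree has 5 nodes, 4 of them non-root -> 4 rules
  tr3 <- pulserules:::grow_tree(X, y, seq_len(200), n_leaves = 3)
  nodes3 <- c(tr3$leaves, tr3$internal)
  paths3 <- Filter(length, lapply(nodes3, `[[`, "path"))
  expect_length(paths3, 4)
})

test_that("rule generation is deterministic and supports are sample fractions", {
  d <- make_xy()
  r1 <- build_rule_ensemble(d$X, d$y, n_trees = 40, seed = 9)
  r2 <- build_rule_ensemble(d$X, d$y, n_trees = 40, seed = 9)
  expect_identical(vapply(r1, `[[`, "", "key"), vapply(r2, `[[`, "", "key"))
  sup <- vapply(r1, `[[`, 0, "support")
  expect_true(all(sup >= 0 & sup <= 1))
  Xm <- pulserules:::as_predictor_matrix(d$X)
  expect_equal(r1[[5]]$support, mean(pulserules:::eval_rule(r1[[5]], Xm)))
  expect_error(build_rule_ensemble(d$X, d$y, n_trees = 0), "n_trees")
})

test_that("drawn tree sizes have the requested mean and floor at 2", {
  set.seed(4)
  s <- pulserules:::draw_tree_sizes(40000, 3)
  expect_true(all(s >= 2))
  expect_equal(mean(s), 3, tolerance = 0.05)
  expect_identical(pulserules:::draw_tree_sizes(10, 2), rep(2L, 10))
})

test_that("winsorization bounds, SDs and degenerate columns behave", {
  x <- 0:99
  lt <- winsorize_linear_terms(data.frame(a = x), delta = 0.05)
  expect_equal(lt$winsor_lo, quantile(x, 0.05, names = FALSE, type = 7))
  expect_equal(lt$winsor_hi, quantile(x, 0.95, names = FALSE, type = 7))
  expect_equal(lt$winsor_lo, 4.95)
  expect_equal(lt$winsor_hi, 94.05)
  lt0 <- winsorize_linear_terms(data.frame(a = x), delta = 0)
  expect_equal(lt0$sd_lj, sd(x))
  ltc <- winsorize_linear_terms(data.frame(a = rep(3, 50)), delta = 0.05)
  expect_equal(ltc$sd_lj, 0)
  m <- fit_sparse_linear(list(), ltc, data.frame(a = rep(3, 50)),
                         rnorm(50), mode = "linear_only", penalty_grid = 1e6)
  imp <- term_importance(m)
  expect_equal(imp$importance, 0)
})

test_that("the L1 limits bracket the fit: OLS at zero, mean at infinity", {
  set.seed(6)
  X <- data.frame(a = rnorm(8), b = rnorm(8))
  y <- 1 + 2 * X$a - X$b + rnorm(8, 0, 0.05)
  lt <- winsorize_linear_terms(X, 0)
  m0 <- fit_sparse_linear(list(), lt, X, y, mode = "linear_only",
                          penalty_grid = 0)
  ols <- coef(lm(y ~ a + b, X))
  expect_equal(m0$intercept, unname(ols[1]), tolerance = 1e-6)
  expect_equal(m0$linear_terms$coef, unname(ols[2:3]), tolerance = 1e-6)
  expect_equal(predict(m0, X), unname(fitted(lm(y ~ a + b, X))),
               tolerance = 1e-6)
  mi <- fit_sparse_linear(list(), lt, X, y, mode = "linear_only",
                          penalty_grid = 1e9)
  expect_equal(mi$intercept, mean(y), tolerance = 1e-9)
  expect_equal(mi$n_nonzero_terms, 0)
  expect_error(fit_sparse_linear(list(), lt, X, y, mode = "linear_only",
                                 penalty_grid = numeric(0)), "empty")
})

test_that("non-zero terms never exceed candidates and shrink along the penalty path", {
  d <- make_xy(300, 3)
  m <- rule_ensemble(d$X, d$y, n_trees = 60, seed = 2)
  expect_lte(m$n_nonzero_terms, m$n_candidate_terms)
  lt <- winsorize_linear_terms(d$X, 0)
  grid <- 10^seq(-3, 0.5, length.out = 7)
  nz <- vapply(grid, function(l)
    fit_sparse_linear(list(), lt, d$X, d$y, mode = "linear_only",
                      penalty_grid = l)$n_nonzero_terms, integer(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("prediction is the additive rule + linear expansion", {
  model <- structure(list(
    mode = "rules_plus_linear", intercept = 1,
    rules = list(list(conditions = list(list(var = 1, rel = ">", thr = 0)),
                      key = "x1>0", coef = 2, support = 0.5)),
    linear_terms = NULL, var_names = "x1"), class = "rule_ensemble")
  expect_equal(predict(model, data.frame(x1 = c(5, -5))), c(3, 1))
  m_const <- structure(list(mode = "rules_only", intercept = 4.2,
                            rules = list(), linear_terms = NULL,
                            var_names = "x1"), class = "rule_ensemble")
  expect_equal(predict(m_const, data.frame(x1 = rnorm(7))), rep(4.2, 7))
  expect_error(predict(model, data.frame(z = 1)), "lacks variables")
})

test_that("term importance follows coefficient times dispersion exactly", {
  mk_rule <- function(s, a) list(conditions = list(list(var = 1, rel = ">",
                                                        thr = 0)),
                                 key = paste0("r", s), coef = a, support = s)
  model <- structure(list(
    mode = "rules_plus_linear", intercept = 0,
    rules = list(mk_rule(0.5, 2), mk_rule(0, 3), mk_rule(1, -4)),
    linear_terms = data.frame(variable = "x1", winsor_lo = -1, winsor_hi = 1,
                              sd_lj = 2.5, coef = 0),
    var_names = "x1"), class = "rule_ensemble")
  imp <- term_importance(model)
  expect_equal(imp$importance[imp$support %in% 0.5], 2 * 0.5)
  expect_equal(imp$importance[imp$support %in% c(0, 1)], c(0, 0))
  expect_equal(imp$importance[imp$type == "linear"], 0)
})

test_that("variable importance splits rules evenly and conserves total mass", {
  model <- structure(list(
    mode = "rules_plus_linear", intercept = 0,
    rules = list(list(conditions = list(list(var = 1, rel = ">", thr = 0),
                                        list(var = 2, rel = "<=", thr = 1)),
                      key = "two", coef = 2, support = 0.5)),
    linear_terms = data.frame(variable = "x3", winsor_lo = -1, winsor_hi = 1,
                              sd_lj = 1, coef = 3),
    var_names = c("x1", "x2", "x3")), class = "rule_ensemble")
  vi <- variable_importance(model, normalize = FALSE)
  expect_equal(vi[["x1"]], vi[["x2"]])
  expect_equal(sum(vi), sum(term_importance(model)$importance))
  # single linear term -> that variable is 100, others 0
  m1 <- structure(list(mode = "linear_only", intercept = 0, rules = list(),
                       linear_terms = data.frame(variable = "x2",
                                                 winsor_lo = 0, winsor_hi = 1,
                                                 sd_lj = 1, coef = 5),
                       var_names = c("x1", "x2")), class = "rule_ensemble")
  vi1 <- variable_importance(m1)
  expect_equal(unname(vi1[c("x2", "x1")]), c(100, 0))
})

test_that("small-sample oracle: penalty-0 fits equal the normal equations", {
  set.seed(11)
  for (i in 1:3) {
    X <- data.frame(a = rnorm(8), b = rnorm(8))
    y <- rnorm(8)
    lt <- winsorize_linear_terms(X, 0)
    m <- fit_sparse_linear(list(), lt, X, y, mode = "linear_only",
                           penalty_grid = 0)
    beta <- solve(crossprod(cbind(1, as.matrix(X))),
                  crossprod(cbind(1, as.matrix(X)), y))
    expect_equal(m$intercept, beta[1], tolerance = 1e-6)
    expect_equal(m$linear_terms$coef, beta[2:3, 1], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("the full rule-ensemble fit is seed-deterministic", {
  d <- make_xy(300, 5)
  m1 <- rule_ensemble(d$X, d$y, n_trees = 50, seed = 21)
  m2 <- rule_ensemble(d$X, d$y, n_trees = 50, seed = 21)
  expect_identical(predict(m1, d$X), predict(m2, d$X))
  expect_identical(m1$penalty, m2$penalty)
})

test_that("partial dependence reduces to the coefficient for linear fits", {
  set.seed(12)
  n <- 300
  X <- data.frame(u = runif(n), v = runif(n))
  y <- 2 + 3 * X$u - X$v
  lt <- winsorize_linear_terms(X, 0)
  m <- fit_sparse_linear(list(), lt, X, y, mode = "linear_only",
                         penalty_grid = 0)
  pd <- partial_dependence(m, X, "u")
  expect_equal(unname(coef(lm(pd ~ u, pd))[2]), 3, tolerance = 1e-9)
  # pd over the grid of a single-variable linear model averages to the mean
  # prediction when the grid is the data itself
  pd_all <- partial_dependence(m, X, "u", grid = list(u = X$u))
  expect_equal(mean(pd_all$pd) + mean(-1 * X$v) - mean(-1 * X$v),
               mean(pd_all$pd), tolerance = 1e-12)
  expect_equal(mean(pd_all$pd), mean(predict(m, X)), tolerance = 1e-9)
  # a variable absent from every term has flat pd
  m0 <- structure(list(mode = "rules_only", intercept = 2,
                       rules = list(list(conditions = list(
                         list(var = 1, rel = ">", thr = 0.5)),
                         key = "u", coef = 1, support = 0.5)),
                       linear_terms = NULL, var_names = c("u", "v")),
                  class = "rule_ensemble")
  pd_v <- partial_dependence(m0, X, "v")
  expect_equal(diff(range(pd_v$pd)), 0)
})

test_that("rules-only mode with stumps yields single-variable rules", {
  d <- make_xy(300, 7)
  m <- rule_ensemble(d$X, d$y, mode = "rules_only", n_trees = 50, seed = 3)
  nvars <- vapply(m$rules, function(r)
    length(unique(vapply(r$conditions, `[[`, 0, "var"))), integer(1))
  expect_true(all(nvars == 1))
  expect_null(m$linear_terms)
})
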