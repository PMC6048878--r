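test_that("independence test is exact for small samples", {
  # numeric covariate, delta-valued response, n = 6: full enumeration oracle
  x <- c(1.2, 0.7, 2.5, 3.1, 0.1, 1.9)
  y <- c(-1, 0, 1, 1, -1, 0)
  got <- independence_test(x, y)
  expect_equal(got$p_value, brute_force_perm_p(x, y), tolerance = 1e-12)

  # n = 8 with ties in the response
  x8 <- c(5, 3, 8, 1, 9, 2, 7, 4)
  y8 <- c(-1, -1, 1, 0, 1, 0, 1, -1)
  expect_equal(independence_test(x8, y8)$p_value,
               brute_force_perm_p(x8, y8), tolerance = 1e-12)

  # degenerate response: no association possible
  expect_equal(independence_test(x, rep(1, 6))$p_value, 1)
  expect_true(independence_test(x, rep(1, 6))$degenerate)
  expect_equal(independence_test(rep(2, 6), y)$p_value, 1)
})

test_that("chi-square p agrees with a Monte-Carlo permutation oracle", {
  set.seed(120)
  x <- rnorm(200)
  y <- sample(c(-1, 0, 1), 200, replace = TRUE)   # independent of x
  got <- independence_test(x, y, exact = FALSE)
  # Monte-Carlo oracle: permute y, recompute the standardized statistic
  mu <- sum(x) * mean(y)
  s2 <- mean((y - mean(y))^2) * sum((x - mean(x))^2) * 200 / 199
  obs <- (sum(x * y) - mu)^2 / s2
  set.seed(121)
  mc <- mean(replicate(50000, {
    yp <- sample(y)
    (sum(x * yp) - mu)^2 / s2
  }) >= obs - 1e-12)
  expect_equal(got$p_value, mc, tolerance = 0.02)
})

test_that("variable selection Bonferroni-adjusts and respects node size", {
  set.seed(7)
  d <- data.frame(y = rep(c(-1, 1), each = 25),
                  x1 = rep(c(0, 1), each = 25), x2 = rnorm(50))
  d$x1[c(1, 30)] <- c(1, 0)   # near-perfect but not degenerate
  # node below min_split stops
  expect_null(select_variable(d[1:10, ], "y", c("x1", "x2"),
                              tree_control(min_split = 20, min_leaf = 7)))
  sel <- select_variable(d, "y", c("x1", "x2"), tree_control())
  expect_equal(sel$variable, "x1")
  raw <- independence_test(d$x1, d$y, exact = FALSE)$p_value
  expect_equal(sel$adjusted_p, min(1, raw * 2), tolerance = 1e-12)

  # single candidate: Bonferroni identity
  sel1 <- select_variable(d, "y", "x2", tree_control())
  raw2 <- independence_test(d$x2, d$y, exact = FALSE)$p_value
  if (raw2 <= 0.05) expect_equal(sel1$adjusted_p, raw2)
  else expect_null(sel1)
})

test_that("best split maximizes the two-sample statistic over all cuts", {
  # perfect separation at the midpoint
  sp <- best_split(c(1, 2, 3, 4), c(-1, -1, 1, 1),
                   tree_control(min_split = 2, min_leaf = 1))
  expect_equal(sp$threshold, 2.5)

  # min_leaf renders a split inadmissible
  expect_null(best_split(c(rep(0, 3), rep(1, 17)), c(rep(-1, 3), rep(1, 17)),
                         tree_control(min_split = 14, min_leaf = 7)))

  # 12-point fixture: exhaustive oracle over all midpoints
  set.seed(55)
  x <- rnorm(12); y <- sample(c(-1, 0, 1), 12, replace = TRUE)
  ctl <- tree_control(min_split = 2, min_leaf = 1)
  got <- best_split(x, y, ctl)
  xs <- sort(unique(x))
  zs <- vapply(head(xs, -1) + diff(xs) / 2, function(cc) {
    g <- as.numeric(x <= cc)
    mu <- sum(g) * mean(y)
    s2 <- mean((y - mean(y))^2) * sum((g - mean(g))^2) * 12 / 11
    abs(sum(g * y) - mu) / sqrt(s2)
  }, numeric(1))
  best_thr <- (head(xs, -1) + diff(xs) / 2)[which.max(zs)]
  expect_equal(got$threshold, best_thr, tolerance = 1e-12)
  expect_equal(got$stat, max(zs), tolerance = 1e-12)

  # categorical split: pick the level set separating the means
  xf <- factor(rep(c("a", "b", "c"), times = c(8, 8, 8)))
  yf <- c(rep(-1, 8), rep(1, 8), rep(1, 8))
  spf <- best_split(xf, yf, tree_control(min_split = 4, min_leaf = 2))
  expect_equal(spf$levels_left, "a")
})

test_that("the nominal scale detects distributional shifts the mean misses", {
  # two groups with identical means but different spread of delta:
  # x = 1 -> delta in {-1, +1}; x = 0 -> delta = 0
  x <- rep(c(0, 1), each = 60)
  y <- c(rep(0, 60), rep(c(-1, 1), 30))
  num <- independence_test(x, y, exact = FALSE, response_scale = "numeric")
  nom <- independence_test(x, y, exact = FALSE, response_scale = "nominal")
  expect_gt(num$p_value, 0.9)         # no mean shift to find
  expect_lt(nom$p_value, 1e-6)        # distribution shift is flagrant
  expect_equal(nom$df, 2L)            # 3 classes -> rank-2 covariance

  # and grow_tree splits on it only under the nominal scale
  d <- data.frame(delta_g = y, x = x)
  t_num <- grow_tree(d, predictors = "x")
  t_nom <- grow_tree(d, predictors = "x",
                     control = tree_control(response_scale = "nominal"))
  expect_equal(nrow(terminal_nodes(t_num)), 1)
  expect_equal(nrow(terminal_nodes(t_nom)), 2)
})

test_that("a perfect binary signal yields exactly one split", {
  d <- data.frame(delta_g = rep(c(-1L, 0L), each = 50),
                  x = rep(c(1, 0), each = 50),
                  z = rnorm(100))
  tree <- grow_tree(d, predictors = c("x", "z"))
  tn <- terminal_nodes(tree)
  expect_equal(nrow(tn), 2)
  sp <- tree_splits(tree)
  expect_equal(sp$variable, "x")
  expect_equal(sum(tn$n), 100)
})

test_that("terminal nodes partition the data and depth-first ids are stable", {
  tr <- simulate_trial(make_scenario("2B"), seed = 2)
  m <- mcart_fit(tr)
  tn <- terminal_nodes(m$tree)
  expect_equal(sum(tn$n), m$G2)
  asn <- predict_node(m$tree, m$averaged)
  expect_setequal(unique(asn), tn$node_id)
  expect_equal(as.vector(table(factor(asn, levels = tn$node_id))), tn$n)
})

test_that("smaller alpha prunes the tree grown at larger alpha", {
  tr <- simulate_trial(make_scenario("2B"), seed = 4)
  m5 <- mcart_fit(tr, control = tree_control(alpha = 0.05))
  m1 <- mcart_fit(tr, control = tree_control(alpha = 0.01))
  s5 <- tree_splits(m5$tree); s1 <- tree_splits(m1$tree)
  key <- function(s) paste(s$variable, signif(s$threshold, 10), s$levels_left)
  expect_true(all(key(s1) %in% key(s5)))
  expect_lte(nrow(terminal_nodes(m1$tree)), nrow(terminal_nodes(m5$tree)))
})

test_that("routing matches a hand-written rule evaluator and is inclusive left", {
  cut_a <- 0.2; cut_b <- -0.1
  leaf <- function(id) list(id = id, n = 0L, mean = 0, dist = NULL,
                            terminal = TRUE)
  tree <- structure(list(
    root = list(id = 1L, n = 0L, mean = 0, dist = NULL, terminal = FALSE,
      split = list(variable = "a", p_value = 0.001, type = "numeric",
                   threshold = cut_a, stat = 1),
      left = list(id = 2L, n = 0L, mean = 0, dist = NULL, terminal = FALSE,
        split = list(variable = "b", p_value = 0.001, type = "numeric",
                     threshold = cut_b, stat = 1),
        left = leaf(3L), right = leaf(4L)),
      right = leaf(5L)),
    response = "delta_g", predictors = c("a", "b"), control = NULL, n = 0L),
    class = "mcart_tree")

  set.seed(9)
  d <- data.frame(a = rnorm(100), b = rnorm(100))
  got <- predict_node(tree, d)
  oracle <- route_by_rules(d, cut_a, cut_b)
  expect_equal(got, unname(c(LL = 3L, LR = 4L, R = 5L)[oracle]))

  # boundary value goes left ("<= c" inclusive)
  expect_equal(predict_node(tree, data.frame(a = cut_a, b = cut_b)), 3L)
  expect_equal(predict_node(tree, data.frame(a = cut_a + 1e-12, b = cut_b)), 5L)

  expect_error(predict_node(tree, d[, "a", drop = FALSE]),
               "missing routed variable")
})

test_that("an empty tree routes everything to the root", {
  d <- data.frame(delta_g = rep(0L, 30), x = rnorm(30))
  tree <- grow_tree(d, predictors = "x")
  expect_equal(nrow(terminal_nodes(tree)), 1)
  expect_true(all(predict_node(tree, d) == tree$root$id))
})

test_that("JSON serialization round-trips structure and predictions", {
  tr <- simulate_trial(make_scenario("2B"), seed = 2)
  m <- mcart_fit(tr)
  js <- tree_to_json(m$tree)
  back <- tree_from_json(js)
  expect_equal(predict_node(back, tr), predict_node(m$tree, tr))
  expect_equal(terminal_nodes(back)$mean_delta,
               terminal_nodes(m$tree)$mean_delta, tolerance = 1e-12)
})
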