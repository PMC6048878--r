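make_toy_trial <- function() {
  # 6 treated + 6 controls, 2 continuous covariates, 1 binary, 1 factor
  set.seed(404)
  data.frame(
    age = c(60, 62, 64, 66, 68, 70, 61, 63, 65, 67, 69, 71),
    sbp = c(120, 135, 128, 140, 150, 132, 121, 136, 129, 141, 151, 133),
    sex = c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 1, 0),
    smoking = factor(c("never", "former", "current", "never", "former", "never",
                       "never", "former", "current", "never", "never", "former"),
                     levels = c("never", "former", "current")),
    Z = rep(c(1, 0), each = 6),
    Y = c(1, 0, 0, 1, 0, 1, 1, 1, 0, 0, 1, 0))
}

test_that("encoding follows the L-1 indicator convention", {
  tr <- make_toy_trial()
  enc <- encode_covariates(tr)
  # smoking {never, former, current} -> 2 columns (reference: lexicographic first)
  smoke_cols <- enc$map$column[enc$map$variable == "smoking"]
  expect_length(smoke_cols, 2)
  expect_setequal(enc$map$level[enc$map$variable == "smoking"],
                  c("never", "former"))  # "current" is lexicographically first
  # binary kept as a single unchanged column
  expect_equal(enc$x[, "sex"], tr$sex)
  expect_equal(ncol(enc$x), 2 + 1 + 2)

  # oncology schema: 1 continuous + 3 binary + (3-level, 4-level) -> 9 columns
  onc <- simulate_trial(make_scenario("1A"), seed = 8)
  expect_equal(ncol(encode_covariates(onc)$x), 9)

  tr$age[3] <- NA
  expect_error(encode_covariates(tr), "missing values in variable: age")
  expect_error(encode_covariates(make_toy_trial(), c("age", "nope")), "unknown")
})

test_that("rank-based Mahalanobis distances match a brute-force oracle", {
  set.seed(31)
  x <- cbind(a = rnorm(6), b = rnorm(6))
  tr <- data.frame(a = x[, 1], b = x[, 2], Z = rep(c(1, 0), 3), Y = 0)
  enc <- encode_covariates(tr, c("a", "b"))
  dm <- rank_mahalanobis(enc, tr$Z == 1)
  for (i in seq_along(dm$row_ids))
    for (j in seq_along(dm$col_ids))
      expect_equal(dm$d[i, j],
                   brute_force_rank_mahal(x, dm$row_ids[i], dm$col_ids[j]),
                   tolerance = 1e-10)
})

test_that("distances are symmetric in arm orientation and zero for twins", {
  tr <- make_toy_trial()
  tr2 <- tr
  tr2$age[7] <- tr$age[1]; tr2$sbp[7] <- tr$sbp[1]
  tr2$sex[7] <- tr$sex[1]; tr2$smoking[7] <- tr$smoking[1]
  enc <- encode_covariates(tr2)
  dm <- rank_mahalanobis(enc, tr2$Z == 1)
  # treated 1 and control 7 are identical -> distance 0
  expect_equal(dm$d[which(dm$row_ids == 1), which(dm$col_ids == 7)], 0,
               tolerance = 1e-10)
  # flipping the arm labels transposes the matrix but preserves distances
  dm_flip <- rank_mahalanobis(enc, tr2$Z == 0)
  expect_equal(unname(dm$d), unname(t(dm_flip$d)), tolerance = 1e-10)
})

test_that("ranking makes distances invariant to monotone transforms", {
  tr <- make_toy_trial()
  d1 <- rank_mahalanobis(encode_covariates(tr), tr$Z == 1)$d
  tr$age <- exp(tr$age / 10)          # strictly monotone
  tr$sbp <- tr$sbp^3
  d2 <- rank_mahalanobis(encode_covariates(tr), tr$Z == 1)$d
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("constant columns are dropped with a warning", {
  tr <- make_toy_trial()
  tr$flat <- 1
  expect_warning(rank_mahalanobis(encode_covariates(tr), tr$Z == 1),
                 "zero-variance")
})

test_that("optimal pair matching minimizes total distance", {
  # trivial cases
  d1 <- structure(list(d = matrix(3.2, 1, 1, dimnames = list(1, 2)),
                       row_ids = 1L, col_ids = 2L, rows_treated = TRUE),
                  class = "mcart_distmat")
  p1 <- pair_match(d1)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$distance, 3.2)

  d2 <- structure(list(d = matrix(c(1, 10, 10, 1), 2, 2),
                       row_ids = 1:2, col_ids = 3:4, rows_treated = TRUE),
                  class = "mcart_distmat")
  p2 <- pair_match(d2)
  expect_equal(p2$control_id[match(1:2, p2$treated_id)], c(3L, 4L))
  expect_equal(sum(p2$distance), 2)

  # square and rectangular random matrices vs exhaustive enumeration
  for (s in 1:6) {
    set.seed(s)
    nr <- sample(2:4, 1); nc <- nr + sample(0:2, 1)
    d <- matrix(runif(nr * nc), nr, nc)
    dm <- structure(list(d = d, row_ids = seq_len(nr),
                         col_ids = nr + seq_len(nc), rows_treated = TRUE),
                    class = "mcart_distmat")
    expect_equal(sum(pair_match(dm)$distance),
                 brute_force_assignment_cost(d), tolerance = 1e-12)
  }
})

test_that("matched total beats 1000 random alternative matchings", {
  set.seed(77)
  d <- matrix(runif(30 * 30), 30, 30)
  dm <- structure(list(d = d, row_ids = 1:30, col_ids = 30 + 1:30,
                       rows_treated = TRUE), class = "mcart_distmat")
  opt <- sum(pair_match(dm)$distance)
  for (k in 1:1000)
    expect_lte(opt, sum(d[cbind(1:30, sample(30))]))
  # greedy is valid (disjoint, complete) but no better than optimal
  gre <- pair_match(dm, method = "greedy")
  expect_equal(sort(unique(gre$treated_id)), 1:30)
  expect_gte(sum(gre$distance), opt - 1e-12)
})

test_that("exact categorical filtering discards mismatched pairs with reasons", {
  tr <- make_toy_trial()
  enc <- encode_covariates(tr)
  pairs <- pair_match(rank_mahalanobis(enc, tr$Z == 1))
  expect_equal(attr(pairs, "G"), 6)

  # force a known pattern: 5 pairs, 2 mismatching on one binary variable
  fake <- structure(data.frame(treated_id = 1:5, control_id = 7:11,
                               distance = 0),
                    G = 5L, G2 = 5L, class = c("mcart_pairs", "data.frame"))
  tr2 <- tr
  tr2$sex <- c(0, 0, 0, 0, 0, 0,  1, 0, 0, 1, 0, 0)  # pairs 1 and 4 mismatch
  f <- filter_exact_categorical(fake, tr2, "sex")
  expect_equal(attr(f, "G2"), 3)
  expect_equal(nrow(f), 3)
  disc <- attr(f, "discarded")
  expect_equal(disc$reason, c("sex", "sex"))
  expect_setequal(disc$treated_id, c(1L, 4L))

  # agreeing on everything keeps G2 = G
  all_ok <- filter_exact_categorical(fake, tr, character(0))
  expect_equal(attr(all_ok, "G2"), 5)

  # monotonicity: G2 never increases as the variable list grows
  g2_small <- attr(filter_exact_categorical(fake, tr2, "sex"), "G2")
  g2_big <- attr(filter_exact_categorical(fake, tr2, c("sex", "smoking")), "G2")
  expect_lte(g2_big, g2_small)
})

test_that("the averaged dataset averages continuous and carries categoricals", {
  tr <- data.frame(
    age = c(60, 64, 50, 70), sex = c(1, 1, 0, 0),
    Z = c(1, 0, 1, 0), Y = c(0, 1, 1, 1))
  pairs <- structure(data.frame(treated_id = c(1L, 3L), control_id = c(2L, 4L),
                                distance = 0),
                     G = 2L, G2 = 2L, categorical_vars = "sex",
                     class = c("mcart_pairs", "data.frame"))
  av <- build_averaged(pairs, tr, c("age", "sex"))
  expect_equal(av$delta_g, c(-1L, 0L))
  expect_equal(av$age, c(62, 60))
  expect_equal(av$sex, c(1, 0))

  # refuse to average unequal categorical values
  tr$sex <- c(1, 0, 0, 0)
  expect_error(build_averaged(pairs, tr, c("age", "sex")),
               "cannot average unequal categorical")
  # empty pair set is an explicit failure
  none <- pairs[0, , drop = FALSE]
  attr(none, "G2") <- 0L
  class(none) <- c("mcart_pairs", "data.frame")
  expect_error(build_averaged(none, tr), "no pairs survive")
})

test_that("within retained pairs every filtered categorical is identical", {
  tr <- simulate_trial(make_scenario("1A"), seed = 14)
  m <- mcart_fit(tr)
  av <- m$averaged
  for (v in m$categorical_vars)
    expect_identical(as.character(tr[[v]][av$treated_id]),
                     as.character(tr[[v]][av$control_id]))
  expect_equal(nrow(av), m$G2)
})
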