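# Independent brute-force oracles and shared fixtures.

# all permutations of 1..n (n small), as a list of integer vectors
perms_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms_of(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

# brute-force optimal bipartite matching cost over all row->column injections
brute_force_assignment_cost <- function(d) {
  nr <- nrow(d); nc <- ncol(d)
  stopifnot(nr <= nc)
  best <- Inf
  for (cols in combn(nc, nr, simplify = FALSE))
    for (p in perms_of(nr))
      best <- min(best, sum(d[cbind(seq_len(nr), cols[p])]))
  best
}

# brute-force rank-based Mahalanobis distances: explicit ranks, covariance,
# inverse, and a double loop
brute_force_rank_mahal <- function(x, i, j) {
  r <- apply(x, 2L, rank)
  S <- cov(r)
  Sinv <- solve(S)
  di <- r[i, ] - r[j, ]
  sqrt(drop(t(di) %*% Sinv %*% di))
}

# exact permutation p-value for the univariate standardized linear statistic
# ((sum g*y - mu)^2 / sigma^2), enumerating every index permutation of y
brute_force_perm_p <- function(g, y) {
  n <- length(y)
  mu <- sum(g) * mean(y)
  s2 <- mean((y - mean(y))^2) * sum((g - mean(g))^2) * n / (n - 1)
  obs <- (sum(g * y) - mu)^2 / s2
  stats <- vapply(perms_of(n), function(p) (sum(g * y[p]) - mu)^2 / s2,
                  numeric(1))
  mean(stats >= obs - 1e-9)
}

# hand-written rule evaluator for a two-level tree fixture (see test-ctree)
route_by_rules <- function(df, cut_a, cut_b) {
  ifelse(df$a <= cut_a,
         ifelse(df$b <= cut_b, "LL", "LR"),
         "R")
}

# ---- shared multi-seed pipeline runs (computed once per session) ----------

.run_cache <- new.env(parent = emptyenv())

# summaries of full mCART runs over seeds 1..20 for one scenario
mcart_seed_runs <- function(scenario_id, seeds = 1:20) {
  key <- paste0("mcart_", scenario_id)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  runs <- lapply(seeds, function(s) {
    tr <- simulate_trial(make_scenario(scenario_id), seed = s)
    m <- mcart_fit(tr)
    rep <- mcart_report(m, tr)
    sp <- tree_splits(m$tree)
    list(seed = s,
         n_terminal = nrow(terminal_nodes(m$tree)),
         split_vars = unique(sp$variable),
         egfr_cuts = sp$threshold[sp$variable == "egfr"],
         max_asd = rep$max_asd,
         bias = rep$bias)
  })
  .run_cache[[key]] <- runs
  runs
}

# LR + effect-partitioning comparator summaries on one scenario
lr_seed_runs <- function(scenario_id, seeds = 1:20) {
  key <- paste0("lr_", scenario_id)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  runs <- lapply(seeds, function(s) {
    tr <- simulate_trial(make_scenario(scenario_id), seed = s)
    # tiny fragmented nodes routinely have an empty arm; that warning is the
    # phenomenon under study, not a test failure
    pe <- suppressWarnings(partition_effects(lr_backward_aic(tr), tr))
    list(seed = s, n_nodes = nrow(pe$report),
         max_asd = pe$report$max_asd)
  })
  .run_cache[[key]] <- runs
  runs
}
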