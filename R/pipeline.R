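#' Fit the matching-plus-tree subgroup model
#'
#' Runs the full algorithm on a two-arm trial: encode the prognostic
#' covariates, compute the rank-based Mahalanobis distance between arms,
#' form G = min(C, T) optimal pairs, discard pairs disagreeing on any
#' categorical covariate (G2 remain), build the pair-averaged dataset of
#' effects \eqn{\delta_g} and covariates \eqn{P_g}, and grow a conditional
#' inference tree for \eqn{\delta_g} as a function of \eqn{P_g}.  Matching
#' on covariates before any outcome is examined guarantees that candidate
#' subgroups are approximately balanced between arms by construction, which
#' is what suppresses imbalance-driven false HTE discovery.
#'
#' All stages are deterministic given the inputs; `seed` is recorded as
#' provenance (and used only by stochastic extensions).
#'
#' @param trial data frame with covariates, treatment `Z` (0/1), outcome
#'   `Y` (0/1).
#' @param prognostic_vars covariates to match and split on (default: all
#'   columns but `Z`/`Y`).
#' @param categorical_vars variables requiring exact within-pair agreement
#'   (default: [default_categorical_vars()]).
#' @param control tree growth parameters ([tree_control()]).
#' @param match_method `"optimal"` (default) or `"greedy"`.
#' @param seed optional integer recorded in the model.
#' @return object of class `mcart_model`: list with `pairs`, `averaged`,
#'   `tree`, `control`, variable sets, `G`, `G2`, and `seed`.
#' @examples
#' tr <- simulate_trial(make_scenario("1A"), seed = 1)
#' m <- mcart_fit(tr)
#' m$tree
#' @export
mcart_fit <- function(trial,
                      prognostic_vars = setdiff(names(trial), c("Z", "Y")),
                      categorical_vars = NULL,
                      control = tree_control(),
                      match_method = c("optimal", "greedy"),
                      seed = NULL) {
  stopifnot(all(c("Z", "Y") %in% names(trial)),
            all(trial$Z %in% 0:1), all(trial$Y %in% 0:1))
  if (!any(trial$Z == 1) || !any(trial$Z == 0))
    stop("both arms must be non-empty")
  if (is.null(categorical_vars))
    categorical_vars <- default_categorical_vars(trial, prognostic_vars)
  match_method <- match.arg(match_method)

  enc <- encode_covariates(trial, prognostic_vars)
  dmat <- rank_mahalanobis(enc, trial$Z == 1)
  pairs <- pair_match(dmat, method = match_method)
  pairs <- filter_exact_categorical(pairs, trial, categorical_vars)
  if (nrow(pairs) == 0L)
    stop("no pairs survive exact filter; relax categorical_vars")
  averaged <- build_averaged(pairs, trial, prognostic_vars)
  tree <- grow_tree(averaged, response = "delta_g",
                    predictors = prognostic_vars, control = control)

  structure(list(pairs = pairs, averaged = averaged, tree = tree,
                 control = control, prognostic_vars = prognostic_vars,
                 categorical_vars = categorical_vars,
                 G = attr(pairs, "G"), G2 = attr(pairs, "G2"),
                 match_method = match_method, seed = seed),
            class = "mcart_model")
}

#' @export
print.mcart_model <- function(x, ...) {
  cat("mCART subgroup model\n")
  cat(sprintf("  pairs: G = %d matched, G2 = %d after exact filter on {%s}\n",
              x$G, x$G2, paste(x$categorical_vars, collapse = ", ")))
  nt <- nrow(terminal_nodes(x$tree))
  cat(sprintf("  tree: %d terminal node%s\n", nt, if (nt == 1) "" else "s"))
  print(x$tree)
  invisible(x)
}

# shared subgroup-report builder: given a node assignment over the trial,
# per-node sizes, event counts, risk difference + CI, balance, and truth
.subgroup_report <- function(trial, assignment, rules,
                             delta_dist = NULL, ci_correct = TRUE,
                             balance_vars = setdiff(names(trial), c("Z", "Y"))) {
  ids <- sort(unique(assignment))
  bal <- node_balance(trial, assignment, vars = balance_vars)
  truth <- attr(trial, "truth")
  rows <- lapply(ids, function(nid) {
    idx <- assignment == nid
    zt <- trial$Z[idx] == 1
    n_t <- sum(zt); n_c <- sum(!zt)
    e_t <- sum(trial$Y[idx][zt]); e_c <- sum(trial$Y[idx][!zt])
    if (n_t == 0L || n_c == 0L) {
      warning("node ", nid, " has an empty arm; risk difference undefined")
      ci <- c(rd = NA_real_, lo = NA_real_, hi = NA_real_)
    } else ci <- risk_difference_ci(e_t, n_t, e_c, n_c, correct = ci_correct)
    data.frame(node_id = nid,
               rule = rules[match(nid, as.integer(names(rules)))],
               n = sum(idx), n_t = n_t, n_c = n_c,
               events_t = e_t, events_c = e_c,
               rd = unname(ci["rd"]), ci_lo = unname(ci["lo"]),
               ci_hi = unname(ci["hi"]),
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rep$max_asd <- bal$per_node$max_asd[match(rep$node_id, bal$per_node$node_id)]
  if (!is.null(truth) && !is.null(truth$delta)) {
    rep$true_ate <- vapply(rep$node_id, function(nid)
      mean(truth$delta[assignment == nid]), numeric(1))
    rep$bias <- rep$rd - rep$true_ate
  } else {
    rep$true_ate <- NA_real_
    rep$bias <- NA_real_
  }
  if (!is.null(delta_dist))
    rep <- merge(rep, delta_dist, by = "node_id", all.x = TRUE, sort = TRUE)
  rep <- rep[, c("node_id", "rule", "n", "n_t", "n_c", "events_t", "events_c",
                 "rd", "ci_lo", "ci_hi", "true_ate", "bias", "max_asd",
                 intersect(c("pr_minus1", "pr_0", "pr_1"), names(rep)))]
  attr(rep, "assignment") <- assignment
  attr(rep, "balance") <- bal
  class(rep) <- c("mcart_report", "data.frame")
  rep
}

#' Project subgroups back onto the trial and estimate effects
#'
#' Every participant is routed down the fitted tree; within each terminal
#' node the average treatment effect is estimated on the original data as
#' the risk difference between arms with a 95% confidence interval, the
#' node's \eqn{\delta} distribution (\eqn{\Pr[\delta_i = -1], \Pr[\delta_i
#' = 0], \Pr[\delta_i = 1]}) is estimated by the node's pair-level
#' frequencies, per-covariate balance (ASD) is computed, and — when the
#' trial carries a truth attribute — the true subgroup ATE and bias.
#'
#' @param model an `mcart_model`.
#' @param trial the trial to project onto (typically the one the model was
#'   fitted to).
#' @param ci_correct continuity-correct the risk-difference CI (default
#'   `TRUE`).
#' @return an `mcart_report` data.frame: `node_id`, `rule`, `n`, `n_t`,
#'   `n_c`, `events_t`, `events_c`, `rd`, `ci_lo`, `ci_hi`, `true_ate`,
#'   `bias`, `max_asd`, `pr_minus1`, `pr_0`, `pr_1`; the participant-level
#'   node assignment is attached as `attr(, "assignment")`.
#' @export
mcart_report <- function(model, trial, ci_correct = TRUE) {
  stopifnot(inherits(model, "mcart_model"))
  assignment <- predict_node(model$tree, trial)
  tn <- terminal_nodes(model$tree)
  rules <- setNames(tn$rule, tn$node_id)
  dd <- if (!is.null(tn$pr_minus1))
    tn[, c("node_id", "pr_minus1", "pr_0", "pr_1")]
  .subgroup_report(trial, assignment, rules, delta_dist = dd,
                   ci_correct = ci_correct,
                   balance_vars = model$prognostic_vars)
}

#' @export
print.mcart_report <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) signif(col, digits))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Simulate, fit, evaluate and write out one benchmark scenario
#'
#' Convenience wrapper: simulate the scenario, fit the matching-plus-tree
#' model, project the subgroup report, compute baseline and per-node
#' balance, and (optionally) write all artifacts to a directory.
#'
#' @param scenario_id scenario id (`"1A"`, `"1B"`, `"2A"`, `"2B"`, `"2C"`).
#' @param seed integer seed for the simulation.
#' @param outdir optional output directory (created if missing): writes
#'   `trial.csv`, `truth.csv`, `pairs.csv`, `discarded.csv`,
#'   `averaged.csv`, `tree.json`, `report.csv`, `baseline.csv`,
#'   `balance.csv`.
#' @param control tree parameters.
#' @return list with `trial`, `model`, `report`, `baseline`.
#' @export
mcart_reproduce <- function(scenario_id, seed, outdir = NULL,
                            control = tree_control()) {
  trial <- simulate_trial(make_scenario(scenario_id), seed = seed)
  model <- mcart_fit(trial, seed = seed, control = control)
  report <- mcart_report(model, trial)
  base <- baseline_table(trial)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    write_trial_csv(trial, p("trial.csv"), p("truth.csv"))
    write_pairs_csv(model$pairs, p("pairs.csv"), p("discarded.csv"))
    write.csv(as.data.frame(model$averaged), p("averaged.csv"), row.names = FALSE)
    tree_to_json(model$tree, p("tree.json"))
    write.csv(as.data.frame(report), p("report.csv"), row.names = FALSE)
    write.csv(base, p("baseline.csv"), row.names = FALSE)
    bal <- attr(report, "balance")
    if (!is.null(bal$per_covariate))
      write.csv(bal$per_covariate, p("balance.csv"), row.names = FALSE)
  }
  list(trial = trial, model = model, report = report, baseline = base)
}
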