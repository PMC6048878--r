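#' Absolute standardized difference for a continuous covariate
#'
#' \eqn{|\bar x_t - \bar x_c| / \sqrt{(s_t^2 + s_c^2)/2}} with sample
#' (n-1) variances.  Values below 0.2 are conventionally taken as
#' acceptable treated-vs-control balance (the order of a small effect
#' size).
#'
#' @param treated,control numeric vectors (each of length >= 2).
#' @return nonnegative scalar; `Inf` when the pooled variance is zero but
#'   the means differ, `0` when both are degenerate and equal.
#' @export
asd_continuous <- function(treated, control) {
  treated <- as.numeric(treated); control <- as.numeric(control)
  stopifnot(length(treated) >= 2L, length(control) >= 2L)
  pooled <- (var(treated) + var(control)) / 2
  dm <- abs(mean(treated) - mean(control))
  if (pooled == 0) return(if (dm == 0) 0 else Inf)
  dm / sqrt(pooled)
}

#' Absolute standardized difference for a proportion
#'
#' \eqn{|p_t - p_c| / \sqrt{(p_t(1-p_t) + p_c(1-p_c))/2}}.  For an L-level
#' categorical variable, compute per-level proportions and summarize the
#' variable as the maximum over levels (see [covariate_asd()]).
#'
#' @param p_t,p_c proportions in each arm.
#' @param n_t,n_c arm sizes (retained for interface completeness; the
#'   classical formula does not use them).
#' @return nonnegative scalar; `Inf` when both proportions are degenerate
#'   (0 or 1) but unequal.
#' @export
asd_proportion <- function(p_t, n_t = NULL, p_c = NULL, n_c = NULL) {
  if (is.null(p_c)) stop("p_c is required")
  stopifnot(p_t >= 0, p_t <= 1, p_c >= 0, p_c <= 1)
  pooled <- (p_t * (1 - p_t) + p_c * (1 - p_c)) / 2
  dm <- abs(p_t - p_c)
  if (pooled == 0) return(if (dm == 0) 0 else Inf)
  dm / sqrt(pooled)
}

#' Per-covariate absolute standardized differences between arms
#'
#' Continuous covariates use [asd_continuous()]; binary 0/1 covariates use
#' [asd_proportion()]; categorical covariates are expanded per level and
#' summarized as the maximum per-level ASD.
#'
#' @param data data frame of covariates.
#' @param treated logical/0-1 arm indicator aligned with `data` rows.
#' @param vars covariate names (default: all columns except `Z` and `Y`).
#' @return data.frame with `variable`, `level` (`NA` for non-categorical),
#'   `asd`, and `variable_asd` (the per-variable summary, repeated across
#'   levels).
#' @export
covariate_asd <- function(data, treated, vars = setdiff(names(data), c("Z", "Y"))) {
  treated <- as.logical(treated)
  rows <- list()
  n_t <- sum(treated); n_c <- sum(!treated)
  for (v in vars) {
    x <- data[[v]]
    if (is.numeric(x) && !all(x %in% c(0, 1))) {
      a <- if (n_t < 2L || n_c < 2L) NA_real_
           else asd_continuous(x[treated], x[!treated])
      rows[[length(rows) + 1L]] <-
        data.frame(variable = v, level = NA_character_, asd = a,
                   variable_asd = a, stringsAsFactors = FALSE)
    } else if (is.numeric(x)) {
      a <- asd_proportion(mean(x[treated]), sum(treated),
                          mean(x[!treated]), sum(!treated))
      rows[[length(rows) + 1L]] <-
        data.frame(variable = v, level = NA_character_, asd = a,
                   variable_asd = a, stringsAsFactors = FALSE)
    } else {
      f <- factor(x)
      per <- vapply(levels(f), function(l)
        asd_proportion(mean(f[treated] == l), sum(treated),
                       mean(f[!treated] == l), sum(!treated)), numeric(1))
      rows[[length(rows) + 1L]] <-
        data.frame(variable = v, level = levels(f), asd = unname(per),
                   variable_asd = max(per), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Baseline balance table for the unsplit trial
#'
#' A Table-1-style summary: per covariate (and level), arm-wise mean (SD)
#' or count (%), and the ASD, mirroring how trial baseline tables report
#' randomization balance.
#'
#' @param trial an `mcart_trial`-style data frame with `Z`.
#' @return data.frame with `variable`, `level`, `control`, `treated`
#'   (formatted summaries), `asd`.
#' @export
baseline_table <- function(trial) {
  treated <- trial$Z == 1
  vars <- setdiff(names(trial), c("Z", "Y"))
  asd <- covariate_asd(trial, treated, vars)
  fmt <- character(nrow(asd)); fmt_t <- character(nrow(asd))
  for (i in seq_len(nrow(asd))) {
    v <- asd$variable[i]; l <- asd$level[i]
    x <- trial[[v]]
    if (is.na(l)) {
      if (all(x %in% c(0, 1))) {
        fmt[i]   <- sprintf("%d (%.1f%%)", sum(x[!treated] == 1), 100 * mean(x[!treated] == 1))
        fmt_t[i] <- sprintf("%d (%.1f%%)", sum(x[treated] == 1),  100 * mean(x[treated] == 1))
      } else {
        fmt[i]   <- sprintf("%.1f (+/-%.1f)", mean(x[!treated]), stats::sd(x[!treated]))
        fmt_t[i] <- sprintf("%.1f (+/-%.1f)", mean(x[treated]),  stats::sd(x[treated]))
      }
    } else {
      fmt[i]   <- sprintf("%d (%.1f%%)", sum(x[!treated] == l), 100 * mean(x[!treated] == l))
      fmt_t[i] <- sprintf("%d (%.1f%%)", sum(x[treated] == l),  100 * mean(x[treated] == l))
    }
  }
  data.frame(variable = asd$variable, level = asd$level, control = fmt,
             treated = fmt_t, asd = asd$asd, stringsAsFactors = FALSE)
}

#' Risk difference with confidence interval
#'
#' \eqn{\widehat{RD} = e_t/n_t - e_c/n_c} with a normal-approximation
#' interval.  The default applies the Yates continuity correction
#' (half-width widened by \eqn{(1/n_t + 1/n_c)/2}, as in
#' [stats::prop.test()]); `correct = FALSE` gives the plain Wald interval.
#'
#' @param events_t,n_t events and size in the treated arm.
#' @param events_c,n_c events and size in the control arm.
#' @param level confidence level (default 0.95).
#' @param correct continuity correction (default `TRUE`).
#' @return named numeric vector `c(rd, lo, hi)`.
#' @examples
#' risk_difference_ci(157, 3000, 203, 3000)  # -0.015 (-0.028, -0.0030)
#' @export
risk_difference_ci <- function(events_t, n_t, events_c, n_c,
                               level = 0.95, correct = TRUE) {
  stopifnot(n_t > 0, n_c > 0, events_t <= n_t, events_c <= n_c)
  p_t <- events_t / n_t; p_c <- events_c / n_c
  rd <- p_t - p_c
  z <- qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p_t * (1 - p_t) / n_t + p_c * (1 - p_c) / n_c)
  if (correct) half <- half + (1 / n_t + 1 / n_c) / 2
  c(rd = rd, lo = rd - half, hi = rd + half)
}

#' Per-group sample size for a two-proportion comparison
#'
#' Pooled-variance normal-approximation formula (two-sided, no continuity
#' correction):
#' \deqn{n = \frac{\left(z_{1-\alpha/2}\sqrt{2\bar p \bar q} +
#'   z_{power}\sqrt{p_0 q_0 + p_1 q_1}\right)^2}{(p_1 - p_0)^2}}
#' with \eqn{\bar p = (p_0 + p_1)/2}, rounded up.
#'
#' @param p0,p1 anticipated event proportions in the two groups.
#' @param alpha two-sided type-I error (default 0.05).
#' @param power target power (default 0.80).
#' @return integer sample size per group.
#' @examples
#' required_sample_size(59/81, 41/84)  # 64
#' @export
required_sample_size <- function(p0, p1, alpha = 0.05, power = 0.80) {
  stopifnot(p0 > 0, p0 < 1, p1 > 0, p1 < 1, p0 != p1)
  pbar <- (p0 + p1) / 2
  za <- qnorm(1 - alpha / 2); zb <- qnorm(power)
  n <- (za * sqrt(2 * pbar * (1 - pbar)) +
        zb * sqrt(p0 * (1 - p0) + p1 * (1 - p1)))^2 / (p1 - p0)^2
  as.integer(ceiling(n))
}

#' Per-node covariate balance of discovered subgroups
#'
#' For each subgroup (terminal node) the treated-vs-control ASD of every
#' covariate is computed on the original trial rows assigned to the node;
#' a node's balance is acceptable iff its maximum ASD is below the cutoff.
#'
#' @param trial the trial data frame (with `Z`).
#' @param assignment integer node id per participant (e.g. from
#'   [predict_node()]).
#' @param vars covariates to check (default: all but `Z`, `Y`).
#' @param cutoff balance threshold (default 0.2, strict).
#' @return list with `per_covariate` (node x covariate/level ASDs) and
#'   `per_node` (`node_id`, `max_asd`, `acceptable`).
#' @export
node_balance <- function(trial, assignment,
                         vars = setdiff(names(trial), c("Z", "Y")),
                         cutoff = 0.2) {
  per_cov <- list(); per_node <- list()
  for (nid in sort(unique(assignment))) {
    idx <- assignment == nid
    sub <- trial[idx, , drop = FALSE]
    tr <- sub$Z == 1
    if (!any(tr) || all(tr)) {
      per_node[[length(per_node) + 1L]] <-
        data.frame(node_id = nid, max_asd = NA_real_, acceptable = NA)
      next
    }
    a <- covariate_asd(sub, tr, vars)
    a$node_id <- nid
    per_cov[[length(per_cov) + 1L]] <- a
    mx <- if (all(is.na(a$asd))) NA_real_ else max(a$asd, na.rm = TRUE)
    per_node[[length(per_node) + 1L]] <-
      data.frame(node_id = nid, max_asd = mx,
                 acceptable = if (is.na(mx)) NA else mx < cutoff)
  }
  list(per_covariate = if (length(per_cov)) do.call(rbind, per_cov),
       per_node = do.call(rbind, per_node))
}

#' Within-subgroup bias against the known truth
#'
#' Bias of a discovered subgroup is its estimated risk difference minus the
#' subgroup's true average treatment effect, i.e. the mean of the true
#' individual effects \eqn{\delta_i} over the participants the subgroup
#' contains.  Requires a report whose node assignment is attached (as
#' produced by [mcart_report()] / [partition_effects()]).
#'
#' @param report a subgroup report (data.frame with `node_id`, `rd`, and an
#'   `assignment` attribute).
#' @param truth a potential-outcome table with a `delta` column, aligned
#'   with the trial rows.
#' @return data.frame `node_id`, `true_ate`, `bias` (`NA` where the node's
#'   risk difference is undefined).
#' @export
subgroup_bias <- function(report, truth) {
  assignment <- attr(report, "assignment")
  if (is.null(assignment)) stop("report carries no node assignment")
  stopifnot(!is.null(truth$delta), length(assignment) == nrow(truth))
  true_ate <- vapply(report$node_id, function(nid)
    mean(truth$delta[assignment == nid]), numeric(1))
  data.frame(node_id = report$node_id, true_ate = true_ate,
             bias = report$rd - true_ate)
}

#' Balance-versus-bias summary across methods
#'
#' One row per (method, subgroup): the node's maximum ASD and absolute
#' bias — the coordinates of the balance-bias scatter used to compare
#' subgroup-discovery methods.
#'
#' @param reports named list of subgroup reports (names = method labels),
#'   each with `node_id`, `max_asd` and `bias` columns.
#' @param file optional CSV output path.
#' @return data.frame `method`, `node_id`, `max_asd`, `abs_bias`.
#' @export
summary_table <- function(reports, file = NULL) {
  stopifnot(is.list(reports), !is.null(names(reports)))
  out <- do.call(rbind, lapply(names(reports), function(m) {
    r <- reports[[m]]
    data.frame(method = m, node_id = r$node_id, max_asd = r$max_asd,
               abs_bias = abs(r$bias), stringsAsFactors = FALSE)
  }))
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}
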