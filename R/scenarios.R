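#' Benchmark randomized-trial scenario specifications
#'
#' Returns the generative specification of one of five simulated two-arm
#' randomized trials with a binary adverse outcome and known individual
#' treatment effects.  Two study settings are covered: a small phase II
#' oncology trial (n = 200, 6 baseline covariates) and a large phase III
#' cardiovascular-disease (CVD) trial (n = 6000, 10 baseline covariates).
#' Scenario `"1A"` (oncology) and `"2A"` (CVD) have a constant
#' treatment-effect distribution (no HTE subgroups); `"1B"` has two age-based
#' subgroups; `"2B"` and `"2C"` have four subgroups defined by aspirin use
#' and eGFR (estimated glomerular filtration rate), with `"2C"` designed so
#' the overall average treatment effect is zero.
#'
#' The individual treatment effect is \eqn{\delta = Y_1 - Y_0 \in \{-1,0,1\}}
#' where \eqn{Y_1, Y_0} are the potential binary outcomes under treatment and
#' control.  Within each (possibly trivial) covariate-defined subgroup,
#' \eqn{\delta} is multinomial with probabilities
#' \eqn{(p_{-1}, p_0, p_{+1})}; the subgroup average treatment effect is
#' \eqn{p_{+1} - p_{-1}}.  Participants with \eqn{\delta = 0} have
#' \eqn{Y_1 = Y_0} equal to `zero_delta_outcome` (1 in the oncology setting,
#' 0 in the CVD setting), which pins the arm-level event rates.
#'
#' @param scenario_id one of `"1A"`, `"1B"`, `"2A"`, `"2B"`, `"2C"`.
#' @return an object of class `mcart_scenario`: a list with elements
#'   `scenario_id`, `n_total`, `covariates` (schema: name, kind,
#'   distribution parameters), `delta_model` (list of subgroup cells, each
#'   with `label`, `condition` (predicate on the covariate data frame) and
#'   `prob = c(p_minus1, p_0, p_1)`), `zero_delta_outcome`, and
#'   `true_subgroups` (labels of cells that constitute genuine HTE
#'   subgroups; empty when the scenario has none).
#' @seealso [simulate_trial()], [expected_subgroup_ate()]
#' @examples
#' sp <- make_scenario("2B")
#' sp$delta_model[[2]]$prob      # aspirin user, eGFR > 72
#' expected_subgroup_ate(sp)
#' @export
make_scenario <- function(scenario_id) {
  scenario_id <- as.character(scenario_id)
  if (!scenario_id %in% c("1A", "1B", "2A", "2B", "2C"))
    stop("unknown scenario_id: ", scenario_id)

  oncology <- list(
    list(name = "age",          kind = "continuous",  mean = 65, sd = 5),
    list(name = "stage4",       kind = "binary",      p = 0.98),
    list(name = "site",         kind = "categorical",
         levels = c("visceral", "bone_only", "other"),
         prob = c(0.5, 0.17, 0.33)),
    list(name = "prev_treat",   kind = "categorical",
         levels = c("none", "chemo_only", "hormonal_only", "chemo_hormonal"),
         prob = c(0.5, 0.2, 0.2, 0.1)),
    list(name = "ecog",         kind = "binary",      p = 0.55),
    list(name = "disease_free", kind = "binary",      p = 0.35)
  )
  cvd <- list(
    list(name = "age",        kind = "continuous", mean = 68,   sd = 10),
    list(name = "black",      kind = "binary",     p = 0.3),
    list(name = "sbp",        kind = "continuous", mean = 140,  sd = 15),
    list(name = "dbp",        kind = "continuous", mean = 78,   sd = 12),
    list(name = "creatinine", kind = "continuous", mean = 1.07, sd = 0.34),
    list(name = "egfr",       kind = "continuous", mean = 72,   sd = 20),
    list(name = "statin",     kind = "binary",     p = 0.43),
    list(name = "aspirin",    kind = "binary",     p = 0.51),
    list(name = "framingham", kind = "continuous", mean = 25,   sd = 12),
    list(name = "smoking",    kind = "categorical",
         levels = c("never", "former", "current"),
         prob = c(0.44, 0.42, 0.14))
  )

  cell <- function(label, condition, prob) {
    stopifnot(abs(sum(prob) - 1) < 1e-12)
    list(label = label, condition = condition,
         prob = c(p_minus1 = prob[1], p_0 = prob[2], p_1 = prob[3]))
  }
  all_rows <- function(df) rep(TRUE, nrow(df))

  spec <- switch(scenario_id,
    "1A" = list(
      n_total = 200L, covariates = oncology, zero_delta_outcome = 1L,
      delta_model = list(cell("all", all_rows, c(0.5, 0.2, 0.3))),
      true_subgroups = character(0)),
    "1B" = list(
      n_total = 200L, covariates = oncology, zero_delta_outcome = 1L,
      delta_model = list(
        cell("age<=65", function(df) df$age <= 65, c(0.6, 0.2, 0.2)),
        cell("age>65",  function(df) df$age > 65,  c(0.4, 0.2, 0.4))),
      true_subgroups = c("age<=65", "age>65")),
    "2A" = list(
      n_total = 6000L, covariates = cvd, zero_delta_outcome = 0L,
      delta_model = list(cell("all", all_rows, c(0.068, 0.88, 0.052))),
      true_subgroups = character(0)),
    "2B" = list(
      n_total = 6000L, covariates = cvd, zero_delta_outcome = 0L,
      delta_model = list(
        cell("aspirin&egfr<=72",
             function(df) df$aspirin == 1 & df$egfr <= 72, c(0.060, 0.88, 0.060)),
        cell("aspirin&egfr>72",
             function(df) df$aspirin == 1 & df$egfr > 72,  c(0.012, 0.88, 0.108)),
        cell("no_aspirin&egfr<=72",
             function(df) df$aspirin == 0 & df$egfr <= 72, c(0.116, 0.88, 0.004)),
        cell("no_aspirin&egfr>72",
             function(df) df$aspirin == 0 & df$egfr > 72,  c(0.084, 0.88, 0.036))),
      true_subgroups = c("aspirin&egfr<=72", "aspirin&egfr>72",
                         "no_aspirin&egfr<=72", "no_aspirin&egfr>72")),
    "2C" = list(
      n_total = 6000L, covariates = cvd, zero_delta_outcome = 0L,
      delta_model = list(
        cell("aspirin&egfr<=72",
             function(df) df$aspirin == 1 & df$egfr <= 72, c(0.036, 0.88, 0.084)),
        cell("aspirin&egfr>72",
             function(df) df$aspirin == 1 & df$egfr > 72,  c(0.004, 0.88, 0.116)),
        cell("no_aspirin&egfr<=72",
             function(df) df$aspirin == 0 & df$egfr <= 72, c(0.116, 0.88, 0.004)),
        cell("no_aspirin&egfr>72",
             function(df) df$aspirin == 0 & df$egfr > 72,  c(0.084, 0.88, 0.036))),
      true_subgroups = c("aspirin&egfr<=72", "aspirin&egfr>72",
                         "no_aspirin&egfr<=72", "no_aspirin&egfr>72"))
  )
  spec$scenario_id <- scenario_id
  stopifnot(spec$n_total %% 2L == 0L)
  class(spec) <- "mcart_scenario"
  spec
}

#' @export
print.mcart_scenario <- function(x, ...) {
  cat("Trial scenario", x$scenario_id, "- n =", x$n_total, "\n")
  cat("Covariates:", paste(vapply(x$covariates, `[[`, "", "name"),
                           collapse = ", "), "\n")
  cat("delta cells:\n")
  for (cl in x$delta_model)
    cat(sprintf("  %-22s (p-1, p0, p+1) = (%g, %g, %g)\n", cl$label,
                cl$prob[1], cl$prob[2], cl$prob[3]))
  cat("True HTE subgroups:",
      if (length(x$true_subgroups)) paste(x$true_subgroups, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Simulate a randomized trial with known potential outcomes
#'
#' Draws baseline covariates column-by-column in schema order, then the
#' individual treatment effect \eqn{\delta} from the multinomial of the
#' subgroup cell each participant falls in, sets the potential outcomes
#' \eqn{(Y_1,Y_0)} to (0,1) when \eqn{\delta=-1}, (1,0) when \eqn{\delta=1}
#' and both to the scenario's `zero_delta_outcome` when \eqn{\delta=0},
#' assigns exactly n/2 participants to treatment by a seeded permutation
#' (complete randomization), and reveals \eqn{Y = Z Y_1 + (1-Z) Y_0}.
#'
#' The generator is R's default Mersenne-Twister; a given `seed` yields a
#' byte-identical table.  Continuous covariates are not truncated: extreme
#' draws can produce clinically implausible values (e.g. negative
#' creatinine) with negligible probability, and are left as drawn.
#'
#' @param spec an `mcart_scenario` from [make_scenario()], or a scenario id
#'   string.
#' @param seed integer seed.
#' @return a `data.frame` (class `mcart_trial`) with the covariate columns
#'   (categorical as factors), treatment `Z` and outcome `Y`; the hidden
#'   truth (`Y1`, `Y0`, `delta`, `true_subgroup`) is attached as
#'   `attr(, "truth")`, and the scenario id as `attr(, "scenario_id")`.
#' @examples
#' tr <- simulate_trial(make_scenario("1A"), seed = 1)
#' table(tr$Z, tr$Y)
#' @export
simulate_trial <- function(spec, seed) {
  if (is.character(spec)) spec <- make_scenario(spec)
  stopifnot(inherits(spec, "mcart_scenario"))
  set.seed(as.integer(seed))
  n <- spec$n_total

  df <- data.frame(row.names = seq_len(n))
  for (cv in spec$covariates) {
    df[[cv$name]] <- switch(cv$kind,
      continuous  = rnorm(n, cv$mean, cv$sd),
      binary      = rbinom(n, 1L, cv$p),
      categorical = factor(sample(cv$levels, n, replace = TRUE, prob = cv$prob),
                           levels = cv$levels),
      stop("unknown covariate kind: ", cv$kind))
  }

  # delta: one uniform per participant, thresholds from the cell's multinomial
  cell_id <- rep(NA_integer_, n)
  for (k in seq_along(spec$delta_model)) {
    hit <- spec$delta_model[[k]]$condition(df)
    cell_id[is.na(cell_id) & hit] <- k
  }
  if (anyNA(cell_id)) stop("delta model cells do not cover the covariate space")
  probs <- t(vapply(spec$delta_model, `[[`, numeric(3), "prob"))
  u <- runif(n)
  p_m1 <- probs[cell_id, 1]
  p_0  <- probs[cell_id, 2]
  delta <- ifelse(u < p_m1, -1L, ifelse(u < p_m1 + p_0, 0L, 1L))

  z0 <- spec$zero_delta_outcome
  Y1 <- ifelse(delta == -1L, 0L, ifelse(delta == 1L, 1L, z0))
  Y0 <- ifelse(delta == -1L, 1L, ifelse(delta == 1L, 0L, z0))

  Z <- integer(n)
  Z[sample.int(n, n %/% 2L)] <- 1L
  df$Z <- Z
  df$Y <- as.integer(Z * Y1 + (1L - Z) * Y0)

  labels <- vapply(spec$delta_model, `[[`, "", "label")
  attr(df, "truth") <- data.frame(
    Y1 = as.integer(Y1), Y0 = as.integer(Y0), delta = as.integer(delta),
    true_subgroup = labels[cell_id], stringsAsFactors = FALSE)
  attr(df, "scenario_id") <- spec$scenario_id
  class(df) <- c("mcart_trial", "data.frame")
  df
}

#' Analytic subgroup treatment effects of a scenario
#'
#' For each subgroup cell of the scenario's \eqn{\delta} model the expected
#' individual treatment effect is \eqn{E[\delta] = p_{+1} - p_{-1}}; the
#' `overall` entry is the unweighted mean across cells.
#'
#' @param spec an `mcart_scenario` or scenario id string.
#' @return named numeric vector: one entry per cell plus `overall`.
#' @examples
#' expected_subgroup_ate("2B")[["aspirin&egfr>72"]]  # 0.096
#' @export
expected_subgroup_ate <- function(spec) {
  if (is.character(spec)) spec <- make_scenario(spec)
  stopifnot(inherits(spec, "mcart_scenario"))
  ates <- vapply(spec$delta_model,
                 function(cl) unname(cl$prob[3] - cl$prob[1]), numeric(1))
  names(ates) <- vapply(spec$delta_model, `[[`, "", "label")
  c(ates, overall = mean(ates))
}

#' Write a simulated trial (and optionally its hidden truth) to CSV
#'
#' @param trial an `mcart_trial`.
#' @param file path for the observed data (covariates, `Z`, `Y`).
#' @param truth_file optional path for the potential-outcome table
#'   (`Y1`, `Y0`, `delta`, `true_subgroup`).
#' @return `file`, invisibly.
#' @export
write_trial_csv <- function(trial, file, truth_file = NULL) {
  write.csv(as.data.frame(trial), file, row.names = FALSE)
  if (!is.null(truth_file)) {
    truth <- attr(trial, "truth")
    if (is.null(truth)) stop("trial carries no truth table")
    write.csv(truth, truth_file, row.names = FALSE)
  }
  invisible(file)
}

#' Read a trial dataset from CSV
#'
#' Character columns become factors; `treatment` and `outcome` name the arm
#' indicator and binary outcome columns.  An optional truth CSV (columns
#' `Y1`, `Y0`, `delta`, `true_subgroup`) is re-attached.
#'
#' @param file CSV with one row per participant.
#' @param treatment,outcome column names (defaults `"Z"`, `"Y"`).
#' @param truth_file optional truth CSV path.
#' @return an `mcart_trial` data frame.
#' @export
read_trial_csv <- function(file, treatment = "Z", outcome = "Y",
                           truth_file = NULL) {
  df <- utils::read.csv(file, stringsAsFactors = TRUE)
  for (nm in c(treatment, outcome))
    if (!nm %in% names(df)) stop("column not found in ", file, ": ", nm)
  if (treatment != "Z") { df$Z <- df[[treatment]]; df[[treatment]] <- NULL }
  if (outcome != "Y")   { df$Y <- df[[outcome]];   df[[outcome]] <- NULL }
  if (!all(df$Z %in% 0:1)) stop("treatment must be binary 0/1")
  if (!all(df$Y %in% 0:1)) stop("outcome must be binary 0/1")
  if (!is.null(truth_file))
    attr(df, "truth") <- utils::read.csv(truth_file, stringsAsFactors = FALSE)
  class(df) <- c("mcart_trial", "data.frame")
  df
}
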