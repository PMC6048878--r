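#' Individual effect estimates from logistic regression with backward-AIC
#' interaction selection
#'
#' Fits a logistic model of the outcome on all covariates, the treatment,
#' and every treatment-by-covariate interaction, then performs backward
#' elimination by AIC (via [stats::step()], which respects marginality: an
#' interaction is removed before its main effects).  From the final model
#' each participant's outcome probability is predicted with treatment set
#' to 1 (`p1`) and to 0 (`p0`); the estimated individual effect is
#' `p1 - p0`.
#'
#' @param trial data frame with covariates, `Z`, `Y`.
#' @param prognostic_vars covariates to enter (default: all but `Z`/`Y`).
#' @return object of class `mcart_effects`: list with `effects` (numeric,
#'   length N, in \[-1, 1\]), `method = "lr"`, `model` (the final `glm`),
#'   and `aic_path` (AIC after each elimination step).
#' @export
lr_backward_aic <- function(trial,
                            prognostic_vars = setdiff(names(trial), c("Z", "Y"))) {
  df <- as.data.frame(trial)[, c(prognostic_vars, "Z", "Y")]
  rhs <- paste(c(prognostic_vars, "Z",
                 paste0("Z:", prognostic_vars)), collapse = " + ")
  full <- glm(as.formula(paste("Y ~", rhs)), family = binomial(), data = df)
  if (!full$converged) stop("full logistic model did not converge")
  red <- step(full, direction = "backward", trace = 0)
  aic_path <- red$anova$AIC

  d1 <- df; d1$Z <- 1L
  d0 <- df; d0$Z <- 0L
  eff <- predict(red, newdata = d1, type = "response") -
         predict(red, newdata = d0, type = "response")
  structure(list(effects = unname(eff), method = "lr", model = red,
                 aic_path = aic_path),
            class = "mcart_effects")
}

#' Partition individual effect estimates into subgroups with one tree
#'
#' Grows a conditional inference tree with the estimated individual
#' treatment effects as the (numeric) response and the baseline covariates
#' as predictors; its terminal nodes are the method's discovered
#' subgroups.  The same reporting as for the matched pipeline is applied:
#' per-node risk differences on the original trial, balance (ASD) and, when
#' the truth is attached, bias.  Because the effect estimates are smooth
#' functions of the covariates, such trees can fragment the trial into many
#' spurious subgroups — the behaviour the matched pipeline is designed to
#' suppress.
#'
#' @param effects an `mcart_effects` object (or bare numeric vector).
#' @param trial the trial the effects refer to.
#' @param control tree parameters (defaults shared with [mcart_fit()]).
#' @param prognostic_vars predictor covariates.
#' @return list with `tree` (`mcart_tree`) and `report` (`mcart_report`).
#' @export
partition_effects <- function(effects, trial, control = tree_control(),
                              prognostic_vars = setdiff(names(trial), c("Z", "Y"))) {
  eff <- if (inherits(effects, "mcart_effects")) effects$effects else as.numeric(effects)
  stopifnot(length(eff) == nrow(trial))
  d <- as.data.frame(trial)[, prognostic_vars, drop = FALSE]
  d$.effect <- eff
  tree <- grow_tree(d, response = ".effect", predictors = prognostic_vars,
                    control = control)
  assignment <- predict_node(tree, trial)
  tn <- terminal_nodes(tree)
  report <- .subgroup_report(trial, assignment,
                             rules = setNames(tn$rule, tn$node_id),
                             balance_vars = prognostic_vars)
  list(tree = tree, report = report)
}

#' Forest-based individual effect estimates (adapter)
#'
#' `method = "rf"`: a classification random forest (package
#' \pkg{randomForest}, 500 trees, sqrt-p variables per split) is fitted to
#' the outcome on covariates plus the treatment indicator; each
#' participant's effect estimate is the difference of the majority-vote
#' predicted class with treatment forced to 1 versus 0, a value in
#' \{-1, 0, 1\}.  `method = "gradient_rf"`: delegated to an external
#' honest-estimation gradient-forest implementation; when no such package
#' is installed the adapter reports itself unavailable rather than
#' silently degrading.
#'
#' @param trial data frame with covariates, `Z`, `Y`.
#' @param method `"rf"` or `"gradient_rf"`.
#' @param seed integer seed for the forest's bootstrap.
#' @param ntree number of trees (default 500 for `"rf"`).
#' @param prognostic_vars predictor covariates.
#' @return an `mcart_effects` object, or — when the backing package is
#'   absent — a list of class `mcart_comparator_skipped` with a `reason`.
#' @export
forest_effects <- function(trial, method = c("rf", "gradient_rf"), seed = 1,
                           ntree = 500,
                           prognostic_vars = setdiff(names(trial), c("Z", "Y"))) {
  method <- match.arg(method)
  if (method == "gradient_rf") {
    if (!requireNamespace("grf", quietly = TRUE))
      return(structure(list(method = "gradient_rf", status = "skipped",
                            reason = "package 'grf' is not installed"),
                       class = "mcart_comparator_skipped"))
    X <- encode_covariates(trial, prognostic_vars)$x
    set.seed(seed)
    cf <- grf::causal_forest(X, as.numeric(trial$Y), as.numeric(trial$Z),
                             num.trees = 2000)
    return(structure(list(effects = as.numeric(predict(cf)$predictions),
                          method = "gradient_rf", model = cf),
                     class = "mcart_effects"))
  }
  if (!requireNamespace("randomForest", quietly = TRUE))
    return(structure(list(method = "rf", status = "skipped",
                          reason = "package 'randomForest' is not installed"),
                     class = "mcart_comparator_skipped"))
  df <- as.data.frame(trial)[, c(prognostic_vars, "Z")]
  yf <- factor(trial$Y, levels = c(0, 1))
  if (length(unique(trial$Y)) < 2L)   # constant outcome: forest is trivial
    return(structure(list(effects = rep(0, nrow(trial)), method = "rf",
                          model = NULL),
                     class = "mcart_effects"))
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = df, y = yf, ntree = ntree,
    mtry = max(1L, floor(sqrt(ncol(df)))))
  d1 <- df; d1$Z <- 1L
  d0 <- df; d0$Z <- 0L
  eff <- as.numeric(as.character(predict(fit, d1))) -
         as.numeric(as.character(predict(fit, d0)))
  structure(list(effects = eff, method = "rf", model = fit),
            class = "mcart_effects")
}

#' @export
print.mcart_effects <- function(x, ...) {
  cat(sprintf("Individual treatment-effect estimates (%s): n = %d, range [%.3f, %.3f]\n",
              x$method, length(x$effects), min(x$effects), max(x$effects)))
  invisible(x)
}

#' @export
print.mcart_comparator_skipped <- function(x, ...) {
  cat(sprintf("comparator '%s' skipped: %s\n", x$method, x$reason))
  invisible(x)
}
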