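#' Encode prognostic covariates as a numeric matrix
#'
#' Continuous variables are carried as-is, binary 0/1 variables as a single
#' column, and a categorical variable with L levels as L-1 indicator columns
#' (reference = lexicographically first level; factors are encoded by their
#' declared level order only through which level is dropped — indicators are
#' built per remaining level).  Missing values are an input error: matching
#' requires complete covariates.
#'
#' @param trial a data frame (typically an `mcart_trial`).
#' @param prognostic_vars character vector of covariate names to encode;
#'   default: every column except `Z` and `Y`.
#' @return object of class `mcart_encoded`: list with `x` (numeric matrix,
#'   one row per participant), `map` (data.frame mapping columns to source
#'   variables and levels), and `prognostic_vars`.
#' @export
encode_covariates <- function(trial, prognostic_vars = NULL) {
  if (is.null(prognostic_vars))
    prognostic_vars <- setdiff(names(trial), c("Z", "Y"))
  missing_vars <- setdiff(prognostic_vars, names(trial))
  if (length(missing_vars))
    stop("unknown variable(s): ", paste(missing_vars, collapse = ", "))

  cols <- list(); src <- character(0); lev <- character(0)
  for (v in prognostic_vars) {
    x <- trial[[v]]
    if (anyNA(x)) stop("missing values in variable: ", v)
    if (is.numeric(x) || is.logical(x)) {
      cols[[v]] <- as.numeric(x)
      src <- c(src, v); lev <- c(lev, NA_character_)
    } else {
      x <- if (is.factor(x)) droplevels(x) else factor(x)
      levs <- sort(levels(x))                    # lexicographic ordering
      for (l in levs[-1L]) {
        cn <- paste0(v, ".", l)
        cols[[cn]] <- as.numeric(x == l)
        src <- c(src, v); lev <- c(lev, l)
      }
      if (length(levs) == 1L) {                  # constant factor: no column
        next
      }
    }
  }
  x <- do.call(cbind, cols)
  structure(list(x = x,
                 map = data.frame(column = colnames(x), variable = src,
                                  level = lev, stringsAsFactors = FALSE),
                 prognostic_vars = prognostic_vars),
            class = "mcart_encoded")
}

#' Rank-based Mahalanobis distance between treated and control participants
#'
#' Each encoded column is replaced by its ranks over all N participants
#' (average ranks for ties); S is the sample covariance of the ranked
#' columns; the distance between participants i and j is
#' \eqn{\sqrt{(r_i - r_j)^\top S^{-1} (r_i - r_j)}}.  Ranking makes the
#' distance invariant to strictly monotone transforms of any continuous
#' covariate and caps the leverage of outliers.  A Moore-Penrose
#' pseudo-inverse is used when S is singular (e.g. collinear indicator
#' blocks in small trials).  Columns with zero variance are dropped with a
#' warning.  The matrix is oriented with the smaller arm as rows.
#'
#' @param enc an `mcart_encoded` object.
#' @param treated logical or 0/1 vector marking the treated arm.
#' @return object of class `mcart_distmat`: list with `d` (distance matrix,
#'   smaller arm x larger arm), `row_ids`/`col_ids` (participant row
#'   indices), and `rows_treated` (TRUE if rows are the treated arm).
#' @export
rank_mahalanobis <- function(enc, treated) {
  stopifnot(inherits(enc, "mcart_encoded"))
  treated <- as.logical(treated)
  x <- enc$x
  n <- nrow(x)
  stopifnot(length(treated) == n)
  if (!any(treated) || all(treated)) stop("both arms must be non-empty")

  keep <- apply(x, 2L, function(col) length(unique(col)) > 1L)
  if (!all(keep)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) == 0L) stop("no informative covariate columns remain")

  r <- apply(x, 2L, rank)                      # average ranks for ties
  S <- cov(r)
  Sinv <- tryCatch(solve(S), error = function(e) MASS::ginv(S))

  t_idx <- which(treated); c_idx <- which(!treated)
  if (length(t_idx) <= length(c_idx)) {
    row_ids <- t_idx; col_ids <- c_idx; rows_treated <- TRUE
  } else {
    row_ids <- c_idx; col_ids <- t_idx; rows_treated <- FALSE
  }
  A <- r[row_ids, , drop = FALSE]
  B <- r[col_ids, , drop = FALSE]
  AS <- A %*% Sinv
  qa <- rowSums(AS * A)
  qb <- rowSums((B %*% Sinv) * B)
  d2 <- outer(qa, qb, "+") - 2 * AS %*% t(B)
  d2[d2 < 0] <- 0                              # numerical noise
  d <- sqrt(d2)
  dimnames(d) <- list(row_ids, col_ids)
  structure(list(d = d, row_ids = row_ids, col_ids = col_ids,
                 rows_treated = rows_treated),
            class = "mcart_distmat")
}

#' Optimal treated-control pair matching
#'
#' Forms G = min(C, T) disjoint treated-control pairs minimizing the total
#' matched distance, by an exact optimal bipartite assignment (shortest
#' augmenting path).  A greedy nearest-neighbour alternative (repeatedly
#' take the globally smallest remaining distance; ties by lowest row then
#' column index) is available for sensitivity analysis.
#'
#' @param dmat an `mcart_distmat` from [rank_mahalanobis()].
#' @param method `"optimal"` (default) or `"greedy"`.
#' @return object of class `mcart_pairs`: data.frame with columns
#'   `treated_id`, `control_id`, `distance` (participant row indices in the
#'   original data), plus attributes `G` (pair count before filtering),
#'   `G2` (after; set by [filter_exact_categorical()]), and `discarded`.
#' @export
pair_match <- function(dmat, method = c("optimal", "greedy")) {
  stopifnot(inherits(dmat, "mcart_distmat"))
  method <- match.arg(method)
  d <- dmat$d
  if (length(d) == 0L) stop("empty distance matrix")

  if (method == "optimal") {
    j <- lap_solve(d)
    i <- seq_len(nrow(d))
  } else {
    nr <- nrow(d); nc <- ncol(d)
    ord <- order(d, arrayInd(seq_along(d), dim(d))[, 1L],
                 arrayInd(seq_along(d), dim(d))[, 2L])
    used_r <- logical(nr); used_c <- logical(nc)
    i <- integer(0); j <- integer(0)
    for (k in ord) {
      ri <- (k - 1L) %% nr + 1L; ci <- (k - 1L) %/% nr + 1L
      if (!used_r[ri] && !used_c[ci]) {
        used_r[ri] <- TRUE; used_c[ci] <- TRUE
        i <- c(i, ri); j <- c(j, ci)
        if (length(i) == min(nr, nc)) break
      }
    }
    o <- order(i); i <- i[o]; j <- j[o]
  }

  rows <- dmat$row_ids[i]; cols <- dmat$col_ids[j]
  pairs <- data.frame(
    treated_id = if (dmat$rows_treated) rows else cols,
    control_id = if (dmat$rows_treated) cols else rows,
    distance   = d[cbind(i, j)])
  structure(pairs, G = nrow(pairs), G2 = nrow(pairs),
            discarded = data.frame(treated_id = integer(0),
                                   control_id = integer(0),
                                   reason = character(0)),
            class = c("mcart_pairs", "data.frame"))
}

#' Discard pairs that disagree on any categorical covariate
#'
#' After distance matching, any pair whose members differ on one of the
#' listed categorical variables (e.g. race or sex) is discarded, leaving
#' G2 <= G exactly-agreeing pairs.  Binary 0/1 prognostic variables are
#' conventionally included in `categorical_vars`.
#'
#' @param pairs an `mcart_pairs` object.
#' @param trial the trial data frame the pair indices refer to.
#' @param categorical_vars character vector of variable names that must
#'   agree exactly within a pair; see [default_categorical_vars()].
#' @return the filtered `mcart_pairs`, with `G2` and a `discarded`
#'   attribute recording each dropped pair and the mismatched variable(s).
#' @export
filter_exact_categorical <- function(pairs, trial, categorical_vars) {
  stopifnot(inherits(pairs, "mcart_pairs"))
  G <- attr(pairs, "G")
  reasons <- character(nrow(pairs))
  for (v in categorical_vars) {
    if (!v %in% names(trial)) stop("unknown categorical variable: ", v)
    vt <- trial[[v]][pairs$treated_id]
    vc <- trial[[v]][pairs$control_id]
    bad <- as.character(vt) != as.character(vc)
    reasons[bad] <- ifelse(reasons[bad] == "", v, paste(reasons[bad], v, sep = ";"))
  }
  keep <- reasons == ""
  discarded <- data.frame(treated_id = pairs$treated_id[!keep],
                          control_id = pairs$control_id[!keep],
                          reason = reasons[!keep], stringsAsFactors = FALSE)
  out <- pairs[keep, , drop = FALSE]
  structure(out, G = G, G2 = nrow(out), discarded = discarded,
            categorical_vars = categorical_vars,
            class = c("mcart_pairs", "data.frame"))
}

#' Default exact-match variable set
#'
#' Factors, character columns, and numeric columns taking only the values
#' 0/1 among the prognostic variables.
#'
#' @param trial data frame.
#' @param prognostic_vars candidate variables (default: all but `Z`, `Y`).
#' @return character vector.
#' @export
default_categorical_vars <- function(trial,
                                     prognostic_vars = setdiff(names(trial), c("Z", "Y"))) {
  is_cat <- vapply(prognostic_vars, function(v) {
    x <- trial[[v]]
    is.factor(x) || is.character(x) ||
      (is.numeric(x) && all(x %in% c(0, 1)))
  }, logical(1))
  prognostic_vars[is_cat]
}

#' Build the pair-averaged dataset
#'
#' One row per retained pair g: the pair-level treatment effect
#' \eqn{\delta_g = Y^t_g - Y^c_g \in \{-1,0,1\}} and the averaged covariate
#' vector \eqn{P_g = (P^t_g + P^c_g)/2}.  Continuous covariates are
#' averaged; categorical covariates (and variables listed in the exact
#' filter) must be identical within the pair — the shared value is carried.
#' Averaging unequal categorical values is refused rather than guessed, so
#' running without the exact filter on disagreeing pairs is an error.
#'
#' @param pairs filtered `mcart_pairs` (G2 >= 1).
#' @param trial the trial data frame.
#' @param prognostic_vars covariates to carry into the averaged dataset;
#'   default: all but `Z`, `Y`.
#' @return class `mcart_averaged`: data.frame with `delta_g`, the averaged
#'   covariates, and `treated_id`/`control_id` bookkeeping columns.
#' @export
build_averaged <- function(pairs, trial,
                           prognostic_vars = setdiff(names(trial), c("Z", "Y"))) {
  stopifnot(inherits(pairs, "mcart_pairs"))
  if (nrow(pairs) == 0L) stop("no pairs survive exact filter")
  ti <- pairs$treated_id; ci <- pairs$control_id
  catvars <- attr(pairs, "categorical_vars")

  out <- data.frame(delta_g = as.integer(trial$Y[ti] - trial$Y[ci]))
  for (v in prognostic_vars) {
    x <- trial[[v]]
    carry <- is.factor(x) || is.character(x) || v %in% catvars
    if (carry) {
      if (any(as.character(x[ti]) != as.character(x[ci])))
        stop("cannot average unequal categorical values for variable: ", v,
             " (apply filter_exact_categorical first)")
      out[[v]] <- x[ti]
      if (is.factor(x)) out[[v]] <- factor(as.character(x[ti]), levels = levels(x))
    } else {
      out[[v]] <- (as.numeric(x[ti]) + as.numeric(x[ci])) / 2
    }
  }
  out$treated_id <- ti
  out$control_id <- ci
  structure(out, class = c("mcart_averaged", "data.frame"))
}

#' Write matched pairs (and discards) to CSV
#'
#' @param pairs `mcart_pairs`.
#' @param file output CSV (`pair_id, treated_id, control_id, distance`).
#' @param discarded_file optional sidecar CSV of discarded pairs + reasons.
#' @return `file`, invisibly.
#' @export
write_pairs_csv <- function(pairs, file, discarded_file = NULL) {
  df <- data.frame(pair_id = seq_len(nrow(pairs)), as.data.frame(pairs))
  write.csv(df, file, row.names = FALSE)
  if (!is.null(discarded_file))
    write.csv(attr(pairs, "discarded"), discarded_file, row.names = FALSE)
  invisible(file)
}
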