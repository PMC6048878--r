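#' Control parameters for conditional-inference tree growth
#'
#' @param alpha significance level a multiplicity-adjusted association
#'   p-value must reach before a node is split (default 0.05).
#' @param min_split minimum node size at which a split is attempted
#'   (default 20).
#' @param min_leaf minimum size of each child (default 7).
#' @param adjust multiplicity adjustment across candidate variables;
#'   only `"bonferroni"` is implemented.
#' @param response_scale `"numeric"` treats the pair-level effect
#'   \eqn{\delta_g \in \{-1,0,1\}} as a numeric score (mean-shift tests,
#'   the default); `"nominal"` uses class-indicator influence functions.
#' @param max_cat_levels refuse categorical splits beyond this many levels
#'   (combinatorial guard; default 10).
#' @return a list of class `mcart_tree_control`.
#' @export
tree_control <- function(alpha = 0.05, min_split = 20L, min_leaf = 7L,
                         adjust = "bonferroni",
                         response_scale = c("numeric", "nominal"),
                         max_cat_levels = 10L) {
  stopifnot(alpha > 0, alpha < 1, min_leaf >= 1, min_split >= 2 * min_leaf)
  adjust <- match.arg(adjust, "bonferroni")
  structure(list(alpha = alpha, min_split = as.integer(min_split),
                 min_leaf = as.integer(min_leaf), adjust = adjust,
                 response_scale = match.arg(response_scale),
                 max_cat_levels = as.integer(max_cat_levels)),
            class = "mcart_tree_control")
}

# ---- linear-statistic machinery -------------------------------------------

# transformation g(x): numeric -> itself (1 column); factor -> one indicator
# column per observed level
.g_matrix <- function(x) {
  if (is.numeric(x) || is.logical(x)) {
    matrix(as.numeric(x), ncol = 1L)
  } else {
    x <- droplevels(factor(x))
    sapply(levels(x), function(l) as.numeric(x == l))
  }
}

# influence function h(y): numeric score (1 column) or class indicators
# (nominal scale, one column per observed value)
.h_matrix <- function(y, response_scale = "numeric") {
  if (response_scale == "nominal") {
    vals <- sort(unique(y))
    if (length(vals) > 1L)
      return(sapply(vals, function(v) as.numeric(y == v)))
  }
  matrix(as.numeric(y), ncol = 1L)
}

# exact conditional moments of vec(T), T = g' h, under permutation of rows
# of h: mu = colSums(g) o mean(h); Sigma = V_h (x) [n/(n-1) * Gc],
# Gc = sum_i (g_i - gbar)(g_i - gbar)'
.lin_stat <- function(g, h) {
  n <- nrow(g)
  Tm <- crossprod(g, h)
  gs <- colSums(g)
  hbar <- colMeans(h)
  Vh <- crossprod(h - rep(hbar, each = n)) / n
  Gc <- crossprod(g - rep(colMeans(g), each = n))
  list(T = as.vector(Tm), mu = as.vector(outer(gs, hbar)),
       Sigma = kronecker(Vh, Gc * n / (n - 1)), n = n)
}

# quadratic form (T-mu)' Sigma^+ (T-mu) with chi-square reference on
# rank(Sigma) degrees of freedom
.quad_form <- function(ls) {
  d <- ls$T - ls$mu
  eg <- eigen(ls$Sigma, symmetric = TRUE)
  tol <- length(eg$values) * max(abs(eg$values), 0) * .Machine$double.eps^0.75
  pos <- eg$values > tol
  if (!any(pos))
    return(list(statistic = 0, df = 0L, p_value = 1, sinv = ls$Sigma * 0))
  V <- eg$vectors[, pos, drop = FALSE]
  sinv <- V %*% (t(V) / eg$values[pos])
  stat <- drop(crossprod(d, sinv %*% d))
  list(statistic = stat, df = sum(pos),
       p_value = pchisq(stat, df = sum(pos), lower.tail = FALSE),
       sinv = sinv)
}

#' Permutation test of independence between a covariate and the response
#'
#' The linear association statistic \eqn{T = \sum_i g(x_i) y_i} (with
#' \eqn{g} the identity for numeric `x` and level indicators for
#' categorical `x`) is standardized by its exact conditional mean and
#' covariance under permutation of `y`, and summarized as a quadratic form.
#' The p-value uses the chi-square reference distribution with
#' rank-of-covariance degrees of freedom; for small samples
#' (`n <= exact_max`, default 10) the exact conditional p-value is computed
#' by full enumeration of the distinct rearrangements of `y` instead.
#'
#' @param x covariate (numeric or factor).
#' @param y response scores (numeric; for tree growth the pair-level
#'   effects \eqn{\delta_g}).
#' @param exact force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   default `NULL` enumerates iff `length(y) <= exact_max`.
#' @param exact_max sample-size threshold for the exact path (exact
#'   enumeration is available for the numeric response scale).
#' @param response_scale `"numeric"` (identity influence, the default) or
#'   `"nominal"` (class-indicator influence: the test is sensitive to any
#'   difference in the response distribution, not just a mean shift).
#' @return list with `statistic`, `p_value`, `df`, and `degenerate`
#'   (`TRUE` when `x` or `y` carries no variation, in which case
#'   `p_value = 1`).
#' @export
independence_test <- function(x, y, exact = NULL, exact_max = 10L,
                              response_scale = c("numeric", "nominal")) {
  stopifnot(length(x) == length(y), length(y) >= 2L)
  response_scale <- match.arg(response_scale)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L ||
      ((is.numeric(x) || is.logical(x)) && length(unique(x)) < 2L) ||
      (!is.numeric(x) && !is.logical(x) && length(unique(as.character(x))) < 2L))
    return(list(statistic = 0, p_value = 1, df = 0L, degenerate = TRUE))
  g <- .g_matrix(x)
  ls <- .lin_stat(g, .h_matrix(y, response_scale))
  qf <- .quad_form(ls)
  use_exact <- if (is.null(exact)) length(y) <= exact_max else isTRUE(exact)
  if (use_exact && qf$df > 0L && response_scale == "numeric") {
    p <- perm_exact_pvalue(g, y, ls$mu, qf$sinv, qf$statistic)
    return(list(statistic = qf$statistic, p_value = p, df = qf$df,
                degenerate = FALSE))
  }
  list(statistic = qf$statistic, p_value = qf$p_value, df = qf$df,
       degenerate = FALSE)
}

#' Select the splitting variable at a node
#'
#' Tests each candidate covariate against the response with
#' [independence_test()], Bonferroni-adjusts across the K candidates
#' (p x K, capped at 1), and returns the minimizing variable if its
#' adjusted p-value reaches `control$alpha` and the node is at least
#' `control$min_split` rows; otherwise a STOP signal.  Ties are broken by
#' candidate order.
#'
#' @param data data frame holding the node's rows.
#' @param response name of the response column.
#' @param candidates character vector of candidate variable names.
#' @param control an [tree_control()] object.
#' @return `NULL` (STOP), or list with `variable`, `p_value` (raw) and
#'   `adjusted_p`.
#' @export
select_variable <- function(data, response, candidates, control = tree_control()) {
  n <- nrow(data)
  if (n < control$min_split) return(NULL)
  y <- as.numeric(data[[response]])
  if (length(unique(y)) < 2L) return(NULL)
  K <- length(candidates)
  praw <- vapply(candidates, function(v)
    independence_test(data[[v]], y, exact = FALSE,
                      response_scale = control$response_scale)$p_value,
    numeric(1))
  padj <- pmin(1, praw * K)
  best <- which.min(padj)            # first minimum = candidate order
  if (padj[best] > control$alpha) return(NULL)
  list(variable = candidates[best], p_value = unname(praw[best]),
       adjusted_p = unname(padj[best]))
}

# standardized two-sample statistic for binary partitions with k members on
# the left, under exact permutation moments.  Numeric scale: |T - mu|/sigma
# per split.  Nominal scale: the quadratic form (T - mu)' Sigma^+ (T - mu)
# with Sigma = V_h k(n-k)/(n-1) -- comparable across splits (constant df).
# `Tleft`: matrix of per-split left-sums, one row per candidate, one column
# per influence column of h.
.partition_stat <- function(Tleft, k, h) {
  n <- nrow(h)
  hbar <- colMeans(h)
  Vh <- crossprod(h - rep(hbar, each = n)) / n
  D <- Tleft - outer(k, hbar)
  scale <- k * (n - k) / (n - 1)
  if (ncol(h) == 1L) {
    sig2 <- drop(Vh) * scale
    return(ifelse(sig2 > 0, abs(D[, 1L]) / sqrt(sig2), 0))
  }
  eg <- eigen(Vh, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  Vinv <- eg$vectors[, pos, drop = FALSE] %*%
    (t(eg$vectors[, pos, drop = FALSE]) / eg$values[pos])
  ifelse(scale > 0, rowSums((D %*% Vinv) * D) / scale, 0)
}

#' Find the best binary split of a selected variable
#'
#' Numeric variables: every midpoint between consecutive distinct observed
#' values is evaluated; categorical: every binary partition of the observed
#' levels (refused above `control$max_cat_levels` levels).  The rule
#' maximizing the standardized two-sample mean-difference statistic is
#' chosen, subject to both children containing at least `control$min_leaf`
#' rows.  Ties go to the smallest threshold (numeric) or the
#' lexicographically first level set (categorical).
#'
#' @param x selected covariate values at the node.
#' @param y response values.
#' @param control an [tree_control()] object.
#' @return `NULL` if no admissible split, else list with `type`
#'   (`"numeric"`/`"categorical"`), `threshold` or `levels_left`, and
#'   `stat` (the standardized statistic).
#' @export
best_split <- function(x, y, control = tree_control()) {
  y <- as.numeric(y)
  n <- length(y)
  min_leaf <- control$min_leaf
  h <- .h_matrix(y, control$response_scale)
  if (is.numeric(x) || is.logical(x)) {
    x <- as.numeric(x)
    o <- order(x)
    xs <- x[o]
    cumh <- apply(h[o, , drop = FALSE], 2L, cumsum)
    ks <- which(diff(xs) > 0)
    ks <- ks[ks >= min_leaf & (n - ks) >= min_leaf]
    if (!length(ks)) return(NULL)
    z <- .partition_stat(cumh[ks, , drop = FALSE], ks, h)
    if (max(z) <= 0) return(NULL)
    b <- which.max(z)                       # first max = smallest threshold
    list(type = "numeric", threshold = (xs[ks[b]] + xs[ks[b] + 1L]) / 2,
         stat = z[b])
  } else {
    x <- droplevels(factor(x))
    levs <- sort(levels(x))
    L <- length(levs)
    if (L < 2L) return(NULL)
    if (L > control$max_cat_levels)
      stop("categorical variable with more than ", control$max_cat_levels,
           " levels refused for splitting")
    best <- NULL
    # each binary partition once: subsets excluding the last level
    for (m in seq_len(L - 1L)) {
      for (S in combn(levs[-L], m, simplify = FALSE)) {
        left <- as.character(x) %in% S
        k <- sum(left)
        if (k < min_leaf || n - k < min_leaf) next
        z <- .partition_stat(matrix(colSums(h[left, , drop = FALSE]), 1L),
                             k, h)
        key <- paste(S, collapse = ",")
        if (z > 0 && (is.null(best) || z > best$stat + 1e-12 ||
            (abs(z - best$stat) <= 1e-12 && key < best$key)))
          best <- list(type = "categorical", levels_left = S, stat = z, key = key)
      }
    }
    if (is.null(best)) return(NULL)
    best$key <- NULL
    best
  }
}

#' Grow a conditional inference tree
#'
#' Recursively applies [select_variable()] and [best_split()] until no node
#' admits a significant, admissible split.  Split selection is by
#' permutation tests of independence with Bonferroni multiplicity
#' adjustment, which separates variable selection from cut-point search and
#' holds the per-node false-split rate at `alpha` under the null.  Nodes
#' are numbered in depth-first preorder; terminal nodes partition the data.
#'
#' @param data data frame (e.g. an `mcart_averaged` dataset).
#' @param response response column name (default `"delta_g"`).
#' @param predictors candidate split variables (default: all columns except
#'   the response and bookkeeping ids).
#' @param control an [tree_control()] object.
#' @return object of class `mcart_tree`.
#' @examples
#' d <- data.frame(delta_g = rep(c(-1, 1), each = 50), x = rep(0:1, each = 50))
#' grow_tree(d, predictors = "x")
#' @export
grow_tree <- function(data, response = "delta_g", predictors = NULL,
                      control = tree_control()) {
  if (is.null(predictors))
    predictors <- setdiff(names(data), c(response, "treated_id", "control_id"))
  stopifnot(nrow(data) >= 1L, response %in% names(data),
            all(predictors %in% names(data)))
  counter <- new.env(); counter$next_id <- 1L

  build <- function(idx, depth) {
    id <- counter$next_id; counter$next_id <- id + 1L
    y <- as.numeric(data[[response]][idx])
    node <- list(id = id, n = length(idx), mean = mean(y),
                 dist = {
                   tb <- table(factor(y, levels = c(-1, 0, 1)))
                   if (all(y %in% c(-1, 0, 1))) as.numeric(tb) / length(y)
                   else NULL
                 },
                 terminal = TRUE)
    nd <- data[idx, , drop = FALSE]
    sel <- select_variable(nd, response, predictors, control)
    if (is.null(sel)) return(node)
    sp <- best_split(nd[[sel$variable]], y, control)
    if (is.null(sp)) return(node)
    xv <- nd[[sel$variable]]
    left <- if (sp$type == "numeric") as.numeric(xv) <= sp$threshold
            else as.character(xv) %in% sp$levels_left
    node$terminal <- FALSE
    node$split <- c(list(variable = sel$variable, p_value = sel$adjusted_p), sp)
    node$left  <- build(idx[left], depth + 1L)
    node$right <- build(idx[!left], depth + 1L)
    node
  }

  root <- build(seq_len(nrow(data)), 0L)
  structure(list(root = root, response = response, predictors = predictors,
                 control = control, n = nrow(data)),
            class = "mcart_tree")
}

# walk the tree collecting terminal nodes with their rule paths
.walk_terminals <- function(node, path = character(0)) {
  if (node$terminal) {
    return(list(list(id = node$id, n = node$n, mean = node$mean,
                     dist = node$dist, rule = if (length(path))
                       paste(path, collapse = " & ") else "<root>")))
  }
  s <- node$split
  if (s$type == "numeric") {
    lr <- sprintf("%s <= %.6g", s$variable, s$threshold)
    rr <- sprintf("%s > %.6g", s$variable, s$threshold)
  } else {
    lr <- sprintf("%s in {%s}", s$variable, paste(s$levels_left, collapse = ","))
    rr <- sprintf("%s not in {%s}", s$variable, paste(s$levels_left, collapse = ","))
  }
  c(.walk_terminals(node$left, c(path, lr)),
    .walk_terminals(node$right, c(path, rr)))
}

#' Terminal-node summary of a tree
#'
#' @param tree an `mcart_tree`.
#' @return data.frame: `node_id`, `rule`, `n`, `mean_delta`, and (when the
#'   response takes values in -1/0/1) the node-level distribution estimates
#'   `pr_minus1`, `pr_0`, `pr_1`.
#' @export
terminal_nodes <- function(tree) {
  tn <- .walk_terminals(tree$root)
  out <- data.frame(
    node_id = vapply(tn, `[[`, integer(1), "id"),
    rule = vapply(tn, `[[`, character(1), "rule"),
    n = vapply(tn, `[[`, integer(1), "n"),
    mean_delta = vapply(tn, `[[`, numeric(1), "mean"),
    stringsAsFactors = FALSE)
  if (!is.null(tn[[1]]$dist)) {
    dm <- t(vapply(tn, function(z) z$dist %||% rep(NA_real_, 3), numeric(3)))
    out$pr_minus1 <- dm[, 1]; out$pr_0 <- dm[, 2]; out$pr_1 <- dm[, 3]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Route observations to terminal nodes
#'
#' Applies the tree's rules to new covariate rows; numeric rules are
#' inclusive on the left (`x <= c` routes the boundary value left).
#'
#' @param tree an `mcart_tree`.
#' @param newdata data frame containing every variable the tree routes on.
#' @return integer vector of terminal node ids, one per row.
#' @export
predict_node <- function(tree, newdata) {
  stopifnot(inherits(tree, "mcart_tree"))
  n <- nrow(newdata)
  out <- integer(n)
  recurse <- function(node, idx) {
    if (!length(idx)) return(invisible())
    if (node$terminal) { out[idx] <<- node$id; return(invisible()) }
    s <- node$split
    v <- newdata[[s$variable]]
    if (is.null(v)) stop("missing routed variable: ", s$variable)
    vv <- v[idx]
    if (anyNA(vv)) stop("missing values in routed variable: ", s$variable)
    left <- if (s$type == "numeric") as.numeric(vv) <= s$threshold
            else as.character(vv) %in% s$levels_left
    recurse(node$left, idx[left])
    recurse(node$right, idx[!left])
  }
  recurse(tree$root, seq_len(n))
  out
}

# internal: all splits as a data.frame (variable, type, threshold/levels)
.tree_splits <- function(node) {
  if (node$terminal) return(NULL)
  s <- node$split
  rbind(data.frame(node_id = node$id, variable = s$variable, type = s$type,
                   threshold = if (s$type == "numeric") s$threshold else NA_real_,
                   levels_left = if (s$type == "categorical")
                     paste(s$levels_left, collapse = ",") else NA_character_,
                   p_value = s$p_value, stringsAsFactors = FALSE),
        .tree_splits(node$left), .tree_splits(node$right))
}

#' Splits of a fitted tree
#' @param tree an `mcart_tree`.
#' @return data.frame of internal nodes (empty when the root is terminal).
#' @export
tree_splits <- function(tree) {
  s <- .tree_splits(tree$root)
  if (is.null(s))
    s <- data.frame(node_id = integer(0), variable = character(0),
                    type = character(0), threshold = numeric(0),
                    levels_left = character(0), p_value = numeric(0))
  s
}

#' @export
print.mcart_tree <- function(x, digits = 4, ...) {
  cat(sprintf("Conditional inference tree on %d rows (response: %s)\n",
              x$n, x$response))
  rec <- function(node, indent) {
    pad <- strrep("  ", indent)
    info <- sprintf("n=%d, mean %s=%.*f", node$n, x$response, digits, node$mean)
    if (node$terminal) {
      cat(sprintf("%s[%d]* %s\n", pad, node$id, info))
    } else {
      s <- node$split
      rule <- if (s$type == "numeric") sprintf("%s <= %.6g", s$variable, s$threshold)
              else sprintf("%s in {%s}", s$variable, paste(s$levels_left, collapse = ","))
      cat(sprintf("%s[%d] %s (p=%.3g) %s\n", pad, node$id, rule, s$p_value, info))
      rec(node$left, indent + 1L)
      rec(node$right, indent + 1L)
    }
  }
  rec(x$root, 0L)
  invisible(x)
}

#' Serialize a tree to JSON (round-trippable)
#' @param tree an `mcart_tree`.
#' @param file optional path; when given, written there.
#' @return JSON string (invisibly when `file` is given).
#' @export
tree_to_json <- function(tree, file = NULL) {
  strip <- function(node) {
    if (node$terminal)
      return(list(id = node$id, n = node$n, mean = node$mean,
                  dist = node$dist, terminal = TRUE))
    s <- node$split
    list(id = node$id, n = node$n, mean = node$mean, dist = node$dist,
         terminal = FALSE,
         split = list(variable = s$variable, p_value = s$p_value,
                      type = s$type, threshold = s$threshold,
                      levels_left = s$levels_left, stat = s$stat),
         left = strip(node$left), right = strip(node$right))
  }
  js <- jsonlite::toJSON(list(response = tree$response,
                              predictors = tree$predictors, n = tree$n,
                              root = strip(tree$root)),
                         auto_unbox = TRUE, null = "null", digits = NA)
  if (!is.null(file)) { writeLines(js, file); return(invisible(js)) }
  js
}

#' Load a tree serialized with [tree_to_json()]
#' @param json JSON string or file path.
#' @return an `mcart_tree` (fit statistics preserved; refitting metadata
#'   such as the control object is not round-tripped).
#' @export
tree_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  rebuild <- function(nd) {
    node <- list(id = as.integer(nd$id), n = as.integer(nd$n),
                 mean = as.numeric(nd$mean),
                 dist = if (!is.null(nd$dist)) as.numeric(unlist(nd$dist)),
                 terminal = isTRUE(nd$terminal))
    if (!node$terminal) {
      sp <- nd$split
      node$split <- list(variable = sp$variable, p_value = sp$p_value,
                         type = sp$type,
                         threshold = if (!is.null(sp$threshold)) as.numeric(sp$threshold),
                         levels_left = if (!is.null(sp$levels_left)) unlist(sp$levels_left),
                         stat = sp$stat)
      node$left <- rebuild(nd$left)
      node$right <- rebuild(nd$right)
    }
    node
  }
  structure(list(root = rebuild(obj$root), response = obj$response,
                 predictors = unlist(obj$predictors), control = NULL,
                 n = as.integer(obj$n)),
            class = "mcart_tree")
}
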