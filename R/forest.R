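#' Per-patient explanatory feature table
#'
#' Validates and orders the 13 explanatory variables used throughout the
#' analysis: age (years), best-corrected visual acuity of the better and
#' worse eye (logMAR; better means lower logMAR), the mean total deviations
#' of the eight 10-2 IVF quadrant subfields and of the two 24-2 IVF
#' hemifields (dB).
#'
#' @param x data frame containing at least the 13 variables (see
#'   [feature_names()]); other columns are kept as responses/metadata.
#' @return `x` with class `feature_table`, the 13 explanatory variables
#'   first.
#' @export
feature_table <- function(x) {
  fv <- feature_names()
  miss <- setdiff(fv, names(x))
  if (length(miss)) {
    stop("feature table is missing variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(x[fv])) stop("feature table has missing values", call. = FALSE)
  if (any(x$bcva_better > x$bcva_worse + 1e-9)) {
    stop("better-eye logMAR must not exceed worse-eye logMAR", call. = FALSE)
  }
  out <- x[, c(fv, setdiff(names(x), fv)), drop = FALSE]
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Names of the 13 explanatory variables
#' @return Character vector of length 13.
#' @export
feature_names <- function() {
  c("age", "bcva_better", "bcva_worse",
    "mtd_inner_upper_right", "mtd_outer_upper_right",
    "mtd_inner_upper_left", "mtd_outer_upper_left",
    "mtd_inner_lower_left", "mtd_outer_lower_left",
    "mtd_inner_lower_right", "mtd_outer_lower_right",
    "mtd_upper", "mtd_lower")
}

#' Fit a regression random forest
#'
#' Bootstrap-aggregated, unpruned CART regression trees with random variable
#' subsetting per split, kept alongside their in-bag/out-of-bag (OOB) index
#' sets so that honest OOB prediction error and permutation importance can be
#' computed.  Fully deterministic given `seed`.
#'
#' @param x data frame or matrix of explanatory variables (numeric).
#' @param y numeric response.
#' @param num_trees number of trees (default 1000).
#' @param mtry variables tried per split; default `max(1, floor(p / 3))`.
#' @param min_leaf minimum terminal-node size (default 5).
#' @param seed integer seed for the forest's own RNG stream; drawn from R's
#'   RNG when missing.
#' @return An object of class `ivf_rf` with elements `trees`, `inbag`, `x`,
#'   `y`, `variables`, `oob_pred`, `oob_mse`, `oob_r2` and the
#'   hyperparameters.
#' @export
rf_fit <- function(x, y, num_trees = 1000L, mtry = NULL, min_leaf = 5L,
                   seed = NULL) {
  X <- as.matrix(as.data.frame(x))
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 20L) stop("random forest fit needs at least 20 observations", call. = FALSE)
  if (length(y) != n || anyNA(X) || anyNA(y)) {
    stop("x/y must be complete and conformable", call. = FALSE)
  }
  if (is.null(mtry)) mtry <- max(1L, ncol(X) %/% 3L)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  if (stats::var(y) < 1e-12) {
    warning("degenerate response: y is constant; importances will be ~0",
            call. = FALSE)
  }
  f <- rf_fit_cpp(X, y, as.integer(num_trees), as.integer(mtry),
                  as.integer(min_leaf), as.double(seed))
  oob <- rf_oob_predict_cpp(f$trees, f$inbag, X)
  ok <- !is.na(oob)
  structure(list(trees = f$trees, inbag = f$inbag, x = X, y = y,
                 variables = colnames(X), num_trees = as.integer(num_trees),
                 mtry = as.integer(mtry), min_leaf = as.integer(min_leaf),
                 seed = as.double(seed), oob_pred = oob,
                 oob_mse = mean((y[ok] - oob[ok])^2),
                 oob_r2 = 1 - mean((y[ok] - oob[ok])^2) /
                   max(stats::var(y) * (n - 1) / n, 1e-12)),
            class = "ivf_rf")
}

#' @export
print.ivf_rf <- function(x, ...) {
  cat(sprintf("regression random forest: %d trees, mtry %d, min leaf %d, n = %d\n",
              x$num_trees, x$mtry, x$min_leaf, length(x$y)))
  cat(sprintf("  OOB MSE %.4f, OOB R^2 %.3f\n", x$oob_mse, x$oob_r2))
  invisible(x)
}

#' Predict from a fitted forest
#'
#' @param object an `ivf_rf`.
#' @param newdata data frame/matrix with the training variables; default the
#'   training data.
#' @param per_tree return the n x trees matrix of per-tree predictions
#'   instead of the ensemble mean.
#' @param ... unused.
#' @return Numeric vector (or matrix when `per_tree = TRUE`).
#' @export
predict.ivf_rf <- function(object, newdata = NULL, per_tree = FALSE, ...) {
  X <- if (is.null(newdata)) object$x else {
    m <- as.matrix(as.data.frame(newdata)[, object$variables, drop = FALSE])
    storage.mode(m) <- "double"
    m
  }
  out <- rf_predict_cpp(object$trees, X, isTRUE(per_tree))
  if (isTRUE(per_tree)) out else as.numeric(out)
}

var_index <- function(model, variable) {
  i <- if (is.character(variable)) match(variable, model$variables)
       else as.integer(variable)
  if (is.na(i) || i < 1L || i > ncol(model$x)) {
    stop("unknown variable: ", variable, call. = FALSE)
  }
  i
}

#' Permutation importance of one variable
#'
#' Mean over trees of the increase in OOB mean squared error when the
#' variable's values are scrambled: each tree predicts its OOB cases with the
#' variable carrying permuted values, and the per-tree MSE increase over the
#' unpermuted baseline is averaged over trees.  A variable the forest never
#' uses changes no prediction, so its importance is ~0 (exactly 0 for the
#' identity permutation).
#'
#' @param model an [rf_fit()] forest.
#' @param variable variable name or index.
#' @param n_perm number of random permutations to average over (reduces the
#'   permutation noise of the point estimate; the p-value machinery in
#'   [importance_pvalues()] always uses single-permutation draws so that the
#'   observed statistic and the null draws stay exchangeable).
#' @param perm optional explicit permutation (or matrix of permutations, one
#'   per column) of `1:n`, overriding the random draws.
#' @param seed integer seed; drawn from R's RNG when missing.
#' @return The importance value (mean OOB MSE increase).
#' @export
permutation_importance <- function(model, variable, n_perm = 1L, perm = NULL,
                                   seed = NULL) {
  stopifnot(inherits(model, "ivf_rf"))
  v <- var_index(model, variable)
  n <- nrow(model$x)
  if (is.null(perm)) {
    if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
    set.seed(seed)
    perm <- replicate(n_perm, sample.int(n))
  }
  perm <- as.matrix(perm)
  vals <- apply(perm, 2L, function(p) {
    rf_perm_importance_cpp(model$trees, model$inbag, model$x, model$y,
                           v - 1L, as.integer(p))
  })
  mean(vals)
}

perm_pvalue <- function(observed, nulls) {
  (1 + sum(nulls >= observed)) / (length(nulls) + 1)
}

#' Permutation importance with empirical-null p-values
#'
#' For every explanatory variable: the observed permutation importance (one
#' random global permutation of the variable; mean per-tree OOB MSE increase
#' over the unpermuted baseline) and an empirical p-value against a
#' per-variable permutation null.  Each null draw repeats the importance
#' computation comparing two fresh independent permutations of the variable;
#' under the null hypothesis that the variable carries no information the
#' unpermuted assignment is exchangeable with any permutation, so
#' \eqn{p = (1 + \#\{null \ge obs\}) / (n_{null} + 1)} is a valid
#' finite-sample permutation p-value (the +1 smoothing keeps p > 0).
#'
#' A response-permutation null (refit the forest on permuted responses and
#' recompute every observed importance; one refit yields a null draw for all
#' variables) is available via `null = "response"`.
#'
#' @param model an [rf_fit()] forest.
#' @param n_null number of null draws (default 2000; at least 99).
#' @param seed integer seed; drawn from R's RNG when missing.
#' @param null `"variable"` (default) or `"response"`.
#' @param variables variables to test; default all.
#' @return A data frame of class `importance_report` with columns `variable`,
#'   `importance`, `p_value`; attribute `n_null`.
#' @export
importance_pvalues <- function(model, n_null = 2000L, seed = NULL,
                               null = c("variable", "response"),
                               variables = NULL) {
  stopifnot(inherits(model, "ivf_rf"))
  null <- match.arg(null)
  n_null <- as.integer(n_null)
  if (n_null < 99L) {
    warning("n_null < 99 gives a coarse p-value resolution", call. = FALSE)
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  if (is.null(variables)) variables <- model$variables
  vidx <- vapply(variables, function(v) var_index(model, v), integer(1L))

  if (null == "variable") {
    res <- rf_importance_cpp(model$trees, model$inbag, model$x, model$y,
                             as.integer(vidx - 1L), n_null, as.double(seed))
    out <- data.frame(variable = variables, importance = res$observed,
                      p_value = res$pvalue, stringsAsFactors = FALSE)
    attr(out, "nulls") <- res$nulls
  } else {
    # PIMP-style: permute y, refit, recompute all observed importances
    set.seed(seed)
    obs <- vapply(seq_along(vidx), function(j) {
      rf_perm_importance_cpp(model$trees, model$inbag, model$x, model$y,
                             vidx[j] - 1L, sample.int(nrow(model$x)))
    }, numeric(1L))
    nulls <- matrix(NA_real_, n_null, length(vidx))
    for (r in seq_len(n_null)) {
      yp <- model$y[sample.int(length(model$y))]
      fr <- rf_fit_cpp(model$x, yp, model$num_trees, model$mtry,
                       model$min_leaf, sample.int(.Machine$integer.max, 1L))
      nulls[r, ] <- vapply(seq_along(vidx), function(j) {
        rf_perm_importance_cpp(fr$trees, fr$inbag, model$x, yp,
                               vidx[j] - 1L, sample.int(nrow(model$x)))
      }, numeric(1L))
    }
    out <- data.frame(variable = variables, importance = obs,
                      p_value = vapply(seq_along(vidx), function(j) {
                        perm_pvalue(obs[j], nulls[, j])
                      }, numeric(1L)),
                      stringsAsFactors = FALSE)
    attr(out, "nulls") <- nulls
  }
  rownames(out) <- NULL
  attr(out, "n_null") <- n_null
  attr(out, "null_type") <- null
  class(out) <- c("importance_report", "data.frame")
  out
}

#' Rank the significant variables
#'
#' Variables with p below `alpha`, sorted by ascending p-value; ties broken
#' by descending observed importance, then variable name.  This is the
#' per-task "rank importance" report shape.
#'
#' @param report an [importance_pvalues()] result.
#' @param alpha significance level (default 0.05).
#' @return Data frame `rank`, `variable`, `importance`, `p_value` (possibly
#'   zero rows).
#' @export
rank_variables <- function(report, alpha = 0.05) {
  stopifnot(is.data.frame(report),
            all(c("variable", "importance", "p_value") %in% names(report)))
  sig <- report[report$p_value < alpha, , drop = FALSE]
  o <- order(sig$p_value, -sig$importance, sig$variable)
  sig <- sig[o, c("variable", "importance", "p_value"), drop = FALSE]
  rownames(sig) <- NULL
  cbind(rank = seq_len(nrow(sig)), sig)
}
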