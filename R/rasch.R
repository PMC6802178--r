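#' VRQoL questionnaire schema
#'
#' Layout of the 30-item, 7-task vision-related quality-of-life
#' questionnaire.  Each item belongs to exactly one task and is answered on a
#' three-category difficulty scale (0 = greatly disabled, 1 = slightly
#' disabled, 2 = not disabled).  The per-task item counts of the original
#' instrument are not public, so the default allocation below is plumbing --
#' a synthetic split of 30 items over the 7 tasks -- and can be replaced via
#' `items_per_task` or a YAML file ([read_schema_yaml()]).
#'
#' @param items_per_task named integer vector over the 7 task labels,
#'   summing to 30.
#' @return A list of class `vrqol_schema` with elements `tasks` (7 labels),
#'   `items` (data frame `item`, `task`) and `categories` (`0:2`).
#' @export
vrqol_schema <- function(items_per_task = c(letters = 5L, sentences = 5L,
                                            walking = 4L, going_out = 4L,
                                            dining = 4L, dressing = 4L,
                                            miscellaneous = 4L)) {
  tasks <- c("letters", "sentences", "walking", "going_out", "dining",
             "dressing", "miscellaneous")
  if (!setequal(names(items_per_task), tasks)) {
    stop("items_per_task must be named by the 7 task labels: ",
         paste(tasks, collapse = ", "), call. = FALSE)
  }
  items_per_task <- items_per_task[tasks]
  if (any(items_per_task < 1L)) stop("every task needs at least one item", call. = FALSE)
  if (sum(items_per_task) != 30L) {
    stop("the questionnaire has exactly 30 items; allocation sums to ",
         sum(items_per_task), call. = FALSE)
  }
  items <- data.frame(item = sprintf("item%02d", 1:30),
                      task = rep(tasks, items_per_task),
                      stringsAsFactors = FALSE)
  structure(list(tasks = tasks, items = items, categories = 0:2),
            class = "vrqol_schema")
}

#' @export
print.vrqol_schema <- function(x, ...) {
  cat("VRQoL questionnaire schema: 30 items, 7 tasks, categories 0/1/2\n")
  print(table(factor(x$items$task, levels = x$tasks)))
  invisible(x)
}

#' Read / write a questionnaire schema as YAML
#'
#' The YAML maps each task label to its list of item ids, e.g.
#' `letters: [item01, item02, ...]`.
#'
#' @param path YAML file path.
#' @return `read_schema_yaml()`: a `vrqol_schema`; `write_schema_yaml()`: the
#'   path, invisibly.
#' @export
read_schema_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  tasks <- c("letters", "sentences", "walking", "going_out", "dining",
             "dressing", "miscellaneous")
  if (!setequal(names(y), tasks)) {
    stop("schema YAML must have exactly the 7 task labels as keys", call. = FALSE)
  }
  items <- data.frame(item = unlist(y[tasks], use.names = FALSE),
                      task = rep(tasks, lengths(y[tasks])),
                      stringsAsFactors = FALSE)
  if (nrow(items) != 30L || anyDuplicated(items$item)) {
    stop("schema must assign 30 distinct items", call. = FALSE)
  }
  structure(list(tasks = tasks, items = items, categories = 0:2),
            class = "vrqol_schema")
}

#' @rdname read_schema_yaml
#' @param schema a `vrqol_schema`.
#' @export
write_schema_yaml <- function(schema, path) {
  y <- split(schema$items$item, factor(schema$items$task, levels = schema$tasks))
  yaml::write_yaml(y, path)
  invisible(path)
}

# coerce a response matrix/data.frame to an integer matrix aligned with the
# schema's item order; values must be 0/1/2 or NA
validate_responses <- function(responses, schema) {
  X <- as.matrix(responses)
  if (!is.null(colnames(X)) && all(schema$items$item %in% colnames(X))) {
    X <- X[, schema$items$item, drop = FALSE]
  } else if (ncol(X) != nrow(schema$items)) {
    stop("responses must have one column per schema item (", nrow(schema$items),
         ")", call. = FALSE)
  }
  storage.mode(X) <- "double"
  bad <- !is.na(X) & !(X %in% schema$categories)
  if (any(bad)) {
    stop("invalid category value(s): ",
         paste(unique(X[bad]), collapse = ", "), " (allowed: 0, 1, 2)",
         call. = FALSE)
  }
  colnames(X) <- schema$items$item
  X
}

#' Raw questionnaire scores
#'
#' Task raw score = simple sum of the task's item categories; patient raw
#' score = sum of the task raw scores.  Missing responses contribute 0 (the
#' count of missing entries is reported and returned).
#'
#' @param responses patients x items matrix or data frame of categories
#'   0/1/2 (optionally NA).
#' @param schema a [vrqol_schema()].
#' @return A list with `task` (patients x 7 matrix), `total` (vector) and
#'   `n_missing`.
#' @export
raw_scores <- function(responses, schema = vrqol_schema()) {
  X <- validate_responses(responses, schema)
  n_missing <- sum(is.na(X))
  if (n_missing > 0) {
    message("raw_scores: ", n_missing, " missing response(s) scored as 0")
    X[is.na(X)] <- 0
  }
  task_f <- factor(schema$items$task, levels = schema$tasks)
  task <- t(rowsum(t(X), task_f))[, schema$tasks, drop = FALSE]
  list(task = task, total = rowSums(X), n_missing = n_missing)
}

# --- polytomous Rasch machinery ---------------------------------------------
# Category probabilities are parameterised by cumulative category parameters
# kappa[i, k] (k = 1, 2), with log P(X_i = k | theta) = k*theta - kappa[i, k]
# - log(normaliser) and kappa[i, 0] = 0.  The rating-scale model constrains
# kappa[i, k] = k*delta_i + sum_{j<=k} tau_j with shared thresholds tau; the
# partial-credit model leaves kappa free per item.

rasch_probs <- function(theta, kappa) {
  L1 <- outer(theta, kappa[, 1L], `-`)
  L2 <- outer(2 * theta, kappa[, 2L], `-`)
  M <- pmax(0, L1, L2)
  e0 <- exp(-M); e1 <- exp(L1 - M); e2 <- exp(L2 - M)
  g <- e0 + e1 + e2
  P1 <- e1 / g
  P2 <- e2 / g
  E <- P1 + 2 * P2
  list(P0 = e0 / g, P1 = P1, P2 = P2, E = E, V = P1 + 4 * P2 - E^2)
}

# Newton solve of sum_i E[X_i | theta] = raw for each raw (monotone in theta)
solve_theta <- function(raw, kappa, tol = 1e-10, max_iter = 200L) {
  theta <- numeric(length(raw))
  for (it in seq_len(max_iter)) {
    pr <- rasch_probs(theta, kappa)
    f <- rowSums(pr$E) - raw
    step <- f / pmax(rowSums(pr$V), 1e-12)
    step <- pmin(pmax(step, -2), 2)
    theta <- pmin(pmax(theta - step, -30), 30)
    if (max(abs(step)) < tol) break
  }
  theta
}

rsm_kappa <- function(delta, tau) {
  cbind(delta + tau[1L], 2 * delta + tau[1L] + tau[2L])
}

#' Fit a polytomous Rasch model to the questionnaire
#'
#' Joint maximum likelihood (JML) fit of the rating-scale model (default) or
#' partial-credit model to a patients x items matrix of categories 0/1/2.
#' Persons with extreme raw scores (0 or the maximum) are excluded from
#' parameter estimation, and the scale is identified by constraining the mean
#' item difficulty to 0.  The rating-scale thresholds are estimated freely
#' (their ordering is not forced).  Item easiness (RADEP) is minus the item
#' difficulty.
#'
#' @param responses patients x items matrix of categories 0/1/2.  Rows with
#'   missing responses are dropped from estimation (with a message).
#' @param schema a [vrqol_schema()].
#' @param model `"rating_scale"` or `"partial_credit"`.
#' @param tol convergence tolerance: maximum absolute item/threshold
#'   parameter change per outer iteration, in logits.
#' @param max_iter maximum outer iterations.
#' @return An object of class `rasch_fit`: item difficulties `delta`, item
#'   easiness `radep = -delta`, thresholds `tau` (rating scale) or per-item
#'   step difficulties `steps` (partial credit), the cumulative category
#'   parameter matrix `kappa`, the raw-score-to-ability lookup tables
#'   `ability_overall` and `ability_task`, `loglik`, `converged`,
#'   `iterations`, and counts of excluded persons.
#' @export
fit_rasch <- function(responses, schema = vrqol_schema(),
                      model = c("rating_scale", "partial_credit"),
                      tol = 1e-6, max_iter = 200L) {
  model <- match.arg(model)
  X <- validate_responses(responses, schema)
  if (anyNA(X)) {
    drop <- rowSums(is.na(X)) > 0
    message("fit_rasch: dropping ", sum(drop), " patient(s) with missing responses")
    X <- X[!drop, , drop = FALSE]
  }
  n <- nrow(X); I <- ncol(X)
  if (I < 2L) stop("need at least 2 items", call. = FALSE)
  max_raw <- 2L * I
  raw <- rowSums(X)
  extreme <- raw == 0 | raw == max_raw
  Xe <- X[!extreme, , drop = FALSE]
  if (nrow(Xe) < 2L) {
    stop("degenerate data: fewer than 2 non-extreme patients", call. = FALSE)
  }
  if (length(unique(as.vector(X))) < 3L) {
    stop("degenerate data: all three categories must be observed", call. = FALSE)
  }
  S <- colSums(Xe)
  ne <- nrow(Xe)
  if (any(S == 0 | S == 2 * ne)) {
    stop("degenerate data: item(s) with extreme score: ",
         paste(colnames(Xe)[S == 0 | S == 2 * ne], collapse = ", "),
         call. = FALSE)
  }
  raws <- rowSums(Xe)
  urs <- sort(unique(raws))
  ridx <- match(raws, urs)

  if (model == "rating_scale") {
    delta <- numeric(I); tau <- c(0, 0)
    G1 <- sum(Xe >= 1); G2 <- sum(Xe >= 2)
    iterations <- 0L; converged <- FALSE
    for (outer_it in seq_len(max_iter)) {
      iterations <- outer_it
      delta_old <- delta; tau_old <- tau
      kappa <- rsm_kappa(delta, tau)
      theta <- solve_theta(urs, kappa)[ridx]
      # item difficulties: Newton on the score equation sum_n E[X_ni] = S_i
      for (inner in 1:25) {
        pr <- rasch_probs(theta, kappa)
        f <- colSums(pr$E) - S
        step <- pmin(pmax(f / pmax(colSums(pr$V), 1e-12), -1), 1)
        delta <- delta + step
        kappa <- rsm_kappa(delta, tau)
        if (max(abs(step)) < 1e-9) break
      }
      # shared thresholds: 2x2 Newton matching the category >= j counts
      pr <- rasch_probs(theta, kappa)
      Eg1 <- pr$P1 + pr$P2; Eg2 <- pr$P2
      s <- c(sum(Eg1) - G1, sum(Eg2) - G2)
      c11 <- sum(Eg1 * (1 - Eg1)); c22 <- sum(Eg2 * (1 - Eg2))
      c12 <- sum(Eg2 * (1 - Eg1))
      J <- -matrix(c(c11, c12, c12, c22), 2L, 2L)
      tstep <- tryCatch(solve(J, s), error = function(e) s * 0)
      tstep <- pmin(pmax(tstep, -0.5), 0.5)
      tau <- tau - tstep
      # identifiability: mean item difficulty = 0
      delta <- delta - mean(delta)
      if (max(abs(delta - delta_old), abs(tau - tau_old)) < tol) {
        converged <- TRUE
        break
      }
    }
    kappa <- rsm_kappa(delta, tau)
    steps <- NULL
  } else {
    kappa <- matrix(0, I, 2L)
    c1 <- colSums(Xe == 1); c2 <- colSums(Xe == 2)
    if (any(c1 == 0) || any(c2 == 0) || any(colSums(Xe == 0) == 0)) {
      stop("degenerate data: the partial-credit model needs every category ",
           "observed for every item", call. = FALSE)
    }
    iterations <- 0L; converged <- FALSE
    for (outer_it in seq_len(max_iter)) {
      iterations <- outer_it
      kappa_old <- kappa
      theta <- solve_theta(urs, kappa)[ridx]
      for (inner in 1:25) {
        pr <- rasch_probs(theta, kappa)
        s1 <- colSums(pr$P1) - c1
        s2 <- colSums(pr$P2) - c2
        a <- -colSums(pr$P1 * (1 - pr$P1))   # d s1 / d kappa1
        b <- colSums(pr$P1 * pr$P2)          # d s1 / d kappa2 = d s2 / d kappa1
        d <- -colSums(pr$P2 * (1 - pr$P2))   # d s2 / d kappa2
        det <- a * d - b * b
        det[abs(det) < 1e-12] <- 1e-12
        st1 <- (d * s1 - b * s2) / det
        st2 <- (a * s2 - b * s1) / det
        st1 <- pmin(pmax(st1, -1), 1); st2 <- pmin(pmax(st2, -1), 1)
        kappa[, 1L] <- kappa[, 1L] - st1
        kappa[, 2L] <- kappa[, 2L] - st2
        if (max(abs(st1), abs(st2)) < 1e-9) break
      }
      m <- mean(kappa[, 2L]) / 2
      kappa[, 1L] <- kappa[, 1L] - m
      kappa[, 2L] <- kappa[, 2L] - 2 * m
      if (max(abs(kappa - kappa_old)) < tol) {
        converged <- TRUE
        break
      }
    }
    delta <- kappa[, 2L] / 2
    tau <- NULL
    steps <- cbind(step1 = kappa[, 1L], step2 = kappa[, 2L] - kappa[, 1L])
  }
  names(delta) <- colnames(X)

  fit <- structure(list(model = model, schema = schema,
                        delta = delta, radep = -delta, tau = tau,
                        steps = steps, kappa = kappa,
                        converged = converged, iterations = iterations,
                        n_patients = n, n_extreme = sum(extreme)),
                   class = "rasch_fit")
  theta_all <- solve_theta(urs, kappa)
  fit$loglik <- {
    pr <- rasch_probs(theta_all[ridx], kappa)
    sum(log(pmax(ifelse(Xe == 0, pr$P0, ifelse(Xe == 1, pr$P1, pr$P2)), 1e-300)))
  }
  fit$ability_overall <- data.frame(raw = 0:max_raw,
                                    theta = ability_from_raw(fit, 0:max_raw))
  fit$ability_task <- lapply(stats::setNames(schema$tasks, schema$tasks),
                             function(tk) {
    it <- schema$items$item[schema$items$task == tk]
    data.frame(raw = 0:(2L * length(it)),
               theta = ability_from_raw(fit, 0:(2L * length(it)), items = it))
  })
  if (!converged) {
    cond <- structure(class = c("ivfqol_convergence_error", "error", "condition"),
                      list(message = paste0("fit_rasch did not converge within ",
                                            max_iter, " iterations"),
                           call = sys.call(-1L), fit = fit))
    stop(cond)
  }
  fit
}

#' @export
print.rasch_fit <- function(x, ...) {
  cat(sprintf("%s Rasch fit: %d items, %d patients (%d extreme excluded)\n",
              x$model, length(x$delta), x$n_patients, x$n_extreme))
  cat(sprintf("  log-likelihood %.2f after %d iterations (converged: %s)\n",
              x$loglik, x$iterations, x$converged))
  if (!is.null(x$tau)) {
    cat(sprintf("  thresholds tau = (%.3f, %.3f)\n", x$tau[1], x$tau[2]))
  }
  cat("  item easiness (RADEP) range: [",
      sprintf("%.3f", min(x$radep)), ", ", sprintf("%.3f", max(x$radep)), "]\n",
      sep = "")
  invisible(x)
}

#' Person ability from a raw score
#'
#' Maximum-likelihood ability (RADPAI, logits) given the fitted item and
#' threshold parameters and a raw score on an item subset.  The raw score is
#' a sufficient statistic, so the ability depends on the responses only
#' through it.  Extreme raw scores (0 and the maximum) are moved inwards by
#' 0.5 score units before solving, which keeps every ability finite.
#'
#' @param fit a [fit_rasch()] result.
#' @param raw integer raw score(s), between 0 and twice the number of items
#'   in the subset.
#' @param items item ids (or indices) defining the subset; default all items.
#' @return Numeric vector of abilities in logits, strictly increasing in
#'   `raw`.
#' @export
ability_from_raw <- function(fit, raw, items = NULL) {
  stopifnot(inherits(fit, "rasch_fit"))
  if (is.null(items)) {
    idx <- seq_along(fit$delta)
  } else if (is.character(items)) {
    idx <- match(items, names(fit$delta))
    if (anyNA(idx)) stop("unknown item id(s)", call. = FALSE)
  } else {
    idx <- as.integer(items)
  }
  max_raw <- 2L * length(idx)
  raw <- as.numeric(raw)
  if (any(raw < 0 | raw > max_raw)) {
    stop("raw score out of range [0, ", max_raw, "]", call. = FALSE)
  }
  adj <- raw
  adj[raw <= 0] <- 0.5
  adj[raw >= max_raw] <- max_raw - 0.5
  solve_theta(adj, fit$kappa[idx, , drop = FALSE])
}

#' Score a cohort: raw scores and RADPAI ability table
#'
#' Fits the Rasch model and returns, per patient, the task raw scores, the
#' patient raw score, the per-task RADPAI (computed from the task raw score
#' and the task's items, anchored to the joint fit) and the all-task RADPAI.
#' Higher RADPAI = better vision-related functioning.
#'
#' @inheritParams fit_rasch
#' @param ... passed to [fit_rasch()].
#' @return A data frame of class `ability_table` with columns `patient_id`,
#'   `raw_<task>`, `raw_total`, `radpai_<task>`, `radpai_total`; the fit is
#'   attached as attribute `fit`.
#' @export
score_cohort <- function(responses, schema = vrqol_schema(), ...) {
  fit <- fit_rasch(responses, schema, ...)
  rs <- raw_scores(responses, schema)
  ids <- rownames(responses)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(rs$task)))
  out <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (tk in schema$tasks) out[[paste0("raw_", tk)]] <- rs$task[, tk]
  out$raw_total <- rs$total
  for (tk in schema$tasks) {
    it <- schema$items$item[schema$items$task == tk]
    lut <- fit$ability_task[[tk]]
    out[[paste0("radpai_", tk)]] <- lut$theta[match(rs$task[, tk], lut$raw)]
  }
  out$radpai_total <- fit$ability_overall$theta[
    match(rs$total, fit$ability_overall$raw)]
  structure(out, fit = fit, class = c("ability_table", "data.frame"))
}
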