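test_that("default schema has 30 items in 7 non-empty tasks with 3 categories", {
  sc <- vrqol_schema()
  expect_identical(nrow(sc$items), 30L)
  expect_identical(length(sc$tasks), 7L)
  expect_identical(sc$categories, 0:2)
  expect_true(all(table(sc$items$task) >= 1L))
  expect_false(anyDuplicated(sc$items$item) > 0)
  expect_error(vrqol_schema(c(letters = 10L, sentences = 5L, walking = 4L,
                              going_out = 4L, dining = 4L, dressing = 4L,
                              miscellaneous = 4L)), "30 items")
  # YAML round trip
  path <- withr::local_tempfile(fileext = ".yaml")
  write_schema_yaml(sc, path)
  sc2 <- read_schema_yaml(path)
  expect_identical(sc2$items[order(sc2$items$item), ],
                   sc$items[order(sc$items$item), ])
})

test_that("raw scores are simple sums per task and patient", {
  sc <- vrqol_schema()
  all2 <- matrix(2L, 3, 30, dimnames = list(NULL, sc$items$item))
  rs <- raw_scores(all2, sc)
  expect_true(all(rs$total == 60))
  expect_true(all(rs$task[, "letters"] == 2 * sum(sc$items$task == "letters")))
  expect_true(all(raw_scores(all2 * 0L, sc)$total == 0))
  # mixed matrix vs independent summation oracle
  set.seed(5)
  X <- matrix(sample(0:2, 50 * 30, TRUE), 50, 30,
              dimnames = list(NULL, sc$items$item))
  rs2 <- raw_scores(X, sc)
  expect_equal(unname(rs2$total), unname(rowSums(X)))
  for (tk in sc$tasks) {
    expect_equal(unname(rs2$task[, tk]),
                 unname(rowSums(X[, sc$items$item[sc$items$task == tk]])))
  }
  # invalid category and missing handling
  Xbad <- X; Xbad[1, 1] <- 3L
  expect_error(raw_scores(Xbad, sc), "invalid category")
  Xna <- X; Xna[2, 5] <- NA
  expect_message(rs3 <- raw_scores(Xna, sc), "missing")
  expect_identical(rs3$n_missing, 1L)
  expect_equal(rs3$total[2], unname(sum(X[2, ]) - X[2, 5]))
})

test_that("items with identical response columns get equal easiness", {
  set.seed(13)
  theta <- rnorm(120, 0, 1.5)
  X <- rsm_sample_oracle(theta, delta = c(-1, 0.5, 1, 0, -0.5), tau = c(-0.7, 0.7),
                         seed = 14)
  X <- cbind(X, X[, 2])  # duplicate an item
  colnames(X) <- paste0("i", 1:6)
  sc <- list(tasks = "all",
             items = data.frame(item = colnames(X), task = "all"),
             categories = 0:2)
  class(sc) <- "vrqol_schema"
  fit <- fit_rasch(X, sc)
  expect_lt(abs(fit$radep[2] - fit$radep[6]), 1e-5)
  expect_equal(mean(fit$delta), 0, tolerance = 1e-9)  # identifiability anchor
})

test_that("tiny joint fit matches an independent multi-start optimiser", {
  X <- rbind(c(0L, 1L), c(1L, 1L), c(2L, 1L), c(2L, 0L), c(1L, 2L))
  colnames(X) <- c("i1", "i2")
  sc <- list(tasks = "all", items = data.frame(item = colnames(X), task = "all"),
             categories = 0:2)
  class(sc) <- "vrqol_schema"
  fit <- fit_rasch(X, sc, tol = 1e-9)

  # independent joint log-likelihood: parameters (d, tau1, tau2, theta per
  # unique raw score), with delta = (d, -d) enforcing the mean-zero anchor
  raws <- rowSums(X)
  urs <- sort(unique(raws))
  ll <- function(par) {
    d <- par[1]; tau <- par[2:3]; th <- par[3 + match(raws, urs)]
    delta <- c(d, -d)
    s <- 0
    for (p in seq_len(nrow(X))) for (i in 1:2) {
      pr <- rsm_prob_oracle(th[p], delta[i], tau)
      s <- s + log(pr[X[p, i] + 1])
    }
    s
  }
  best <- -Inf; bpar <- NULL
  set.seed(3)
  for (s in 1:30) {
    start <- c(rnorm(1), rnorm(2), rnorm(length(urs)))
    o <- optim(start, ll, control = list(fnscale = -1, maxit = 2000,
                                         reltol = 1e-12))
    if (o$value > best) { best <- o$value; bpar <- o$par }
  }
  # JML reaches the same maximum; delta is identified (tau sits on a ridge in
  # a dataset this small, so only the attained likelihood is compared for it)
  expect_gte(fit$loglik, best - 1e-4)
  expect_equal(fit$delta[["i1"]], bpar[1], tolerance = 0.01)
})

test_that("simulated rating-scale data recover the generating parameters", {
  set.seed(17)
  n <- 300
  delta <- seq(-1.4, 1.4, length.out = 12)
  tau <- c(-0.6, 0.6)
  theta <- rnorm(n, 0, 1.4)
  X <- rsm_sample_oracle(theta, delta, tau, seed = 18)
  sc <- list(tasks = "all", items = data.frame(item = colnames(X), task = "all"),
             categories = 0:2)
  class(sc) <- "vrqol_schema"
  fit <- fit_rasch(X, sc)
  expect_true(fit$converged)
  expect_gt(cor(fit$delta, delta), 0.95)
  ab <- ability_from_raw(fit, rowSums(X))
  expect_gt(cor(theta, ab, method = "spearman"), 0.85)
})

test_that("degenerate response matrices are rejected", {
  sc <- list(tasks = "all", items = data.frame(item = c("i1", "i2"), task = "all"),
             categories = 0:2)
  class(sc) <- "vrqol_schema"
  expect_error(fit_rasch(rbind(c(0L, 0L), c(2L, 2L), c(0L, 0L)), sc),
               "non-extreme")
  expect_error(fit_rasch(rbind(c(1L, 1L), c(1L, 1L), c(1L, 1L)), sc),
               "categories|extreme")
})

test_that("ability from raw score is symmetric, monotone and matches a bisection oracle", {
  # hand-built symmetric fit: 5 items at difficulty 0, thresholds (-t, t)
  kappa <- cbind(rep(-0.8, 5), rep(0, 5))
  fit <- structure(list(model = "rating_scale",
                        delta = setNames(rep(0, 5), paste0("i", 1:5)),
                        radep = rep(0, 5), tau = c(-0.8, 0.8), kappa = kappa),
                   class = "rasch_fit")
  expect_equal(ability_from_raw(fit, 5), 0, tolerance = 1e-8)  # half of max 10
  th <- ability_from_raw(fit, 0:10)
  expect_true(all(diff(th) > 0))          # strict monotonicity
  expect_true(all(is.finite(th)))         # extreme correction keeps it finite
  expect_error(ability_from_raw(fit, 11), "out of range")
  expect_error(ability_from_raw(fit, -1), "out of range")

  # independent oracle: uniroot on the closed-form expected score
  for (r in c(0.5, 2, 5, 7, 9.5)) {
    oracle <- uniroot(function(t) {
      rsm_expected_score_oracle(t, rep(0, 5), c(-0.8, 0.8)) - r
    }, c(-25, 25), tol = 1e-10)$root
    expect_equal(ability_from_raw(fit, r), oracle, tolerance = 1e-6)
  }
})

test_that("cohort scoring is raw-score-sufficient with finite extreme scores", {
  set.seed(23)
  sc <- vrqol_schema()
  theta <- rnorm(150, 0, 1.5)
  X <- rsm_sample_oracle(theta, seq(-1.2, 1.2, length.out = 30), c(-0.8, 0.8),
                         seed = 24)
  X[1, ] <- X[2, ]          # identical patients
  X[3, ] <- 2L              # all-maximum patient
  tab <- score_cohort(X, sc)
  expect_s3_class(tab, "ability_table")
  r1 <- unlist(tab[1, -1]); r2 <- unlist(tab[2, -1])
  expect_equal(r1, r2)
  expect_true(is.finite(tab$radpai_total[3]))
  expect_true(tab$radpai_total[3] >= max(tab$radpai_total[-3]))
  # raw-score sufficiency per task
  same <- tab$raw_letters == tab$raw_letters[1]
  expect_true(all(abs(tab$radpai_letters[same] - tab$radpai_letters[1]) < 1e-10))
  # monotone in the raw score on each subset
  o <- order(tab$raw_total)
  expect_true(all(diff(tab$radpai_total[o]) >= -1e-10))
})

test_that("partial-credit parameterisation recovers rating-scale truth", {
  set.seed(29)
  theta <- rnorm(400, 0, 1.4)
  delta <- seq(-1, 1, length.out = 10)
  X <- rsm_sample_oracle(theta, delta, c(-0.5, 0.5), seed = 30)
  sc <- list(tasks = "all", items = data.frame(item = colnames(X), task = "all"),
             categories = 0:2)
  class(sc) <- "vrqol_schema"
  fit <- fit_rasch(X, sc, model = "partial_credit")
  expect_true(fit$converged)
  expect_gt(cor(fit$delta, delta), 0.9)
  expect_identical(dim(fit$steps), c(10L, 2L))
})
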