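test_that("eligibility rules match the inclusion criteria and partition the cohort", {
  clinical <- data.frame(
    patient_id = c("a", "b", "c", "d"),
    md_od = c(-25, -15, -25, -25), md_os = c(-10, -18, -12, -22),
    bcva_od = c(0.6, 0.9, 0.4, 0.8), bcva_os = c(0.8, 0.9, 0.9, 0.7))
  tests <- data.frame(
    patient_id = c("a", "b", "c", "d", "d"),
    fl_rate = c(0.05, 0.01, 0.02, 0.25, 0.01),
    fp_rate = c(0.02, 0.02, 0.02, 0.02, 0.02),
    fn_rate = c(0.10, 0.10, 0.10, 0.10, 0.10))
  out <- eligibility_filter(clinical, tests)
  expect_identical(out$eligible, "a")
  expect_identical(out$excluded$reason[out$excluded$patient_id == "b"], "MD")
  expect_identical(out$excluded$reason[out$excluded$patient_id == "c"], "BCVA")
  expect_identical(out$excluded$reason[out$excluded$patient_id == "d"],
                   "reliability")
  # partition
  expect_setequal(c(out$eligible, out$excluded$patient_id), clinical$patient_id)
  # boundary behaviour: MD exactly -20 passes, fixation loss exactly 0.20 fails
  cl2 <- data.frame(patient_id = "e", md_od = -20, md_os = -5,
                    bcva_od = 0.5, bcva_os = 0.5)
  ts2 <- data.frame(patient_id = "e", fl_rate = 0.19, fp_rate = 0.14,
                    fn_rate = 0.32)
  expect_identical(eligibility_filter(cl2, ts2)$eligible, "e")
  ts2$fl_rate <- 0.20
  expect_identical(eligibility_filter(cl2, ts2)$excluded$reason, "reliability")
  expect_error(eligibility_filter(cl2[, -2], ts2), "missing field")
})

test_that("spearman screen equals a rank-then-pearson oracle and flags at 0.05/104", {
  set.seed(3)
  n <- 40
  feats <- data.frame(matrix(rnorm(n * 13), n, 13))
  names(feats) <- feature_names()
  feats$age <- sample(60:70, n, TRUE)            # tie-heavy column
  abil <- data.frame(matrix(rnorm(n * 8), n, 8))
  names(abil) <- paste0("radpai_", 1:8)
  abil[[1]] <- feats$mtd_lower + rnorm(n, 0, 0.1)
  ct <- spearman_matrix(feats, abil)
  expect_identical(attr(ct, "family_size"), 104L)
  expect_equal(attr(ct, "threshold"), 0.05 / 104)
  # brute-force oracle on every cell, including the tied column
  for (k in sample(nrow(ct), 20)) {
    x <- feats[[ct$variable[k]]]; y <- abil[[ct$response[k]]]
    expect_equal(ct$rho[k], cor(rank(x), rank(y)), tolerance = 1e-12)
  }
  # monotone relationship gives rho 1 and survives monotone transforms
  strong <- ct[ct$variable == "mtd_lower" & ct$response == "radpai_1", ]
  expect_gt(strong$rho, 0.95)
  abil2 <- abil; abil2[[1]] <- exp(abil2[[1]])
  ct2 <- spearman_matrix(feats, abil2)
  expect_equal(ct2$rho, ct$rho, tolerance = 1e-12)
  # Bonferroni flags never exceed raw p < 0.05 count
  expect_lte(sum(ct$significant), sum(ct$p_value < 0.05, na.rm = TRUE))
  perfect <- data.frame(a = sort(rnorm(n)))
  expect_equal(spearman_matrix(perfect, data.frame(b = sort(rnorm(n)) * 2 + 1))$rho, 1)
  expect_warning(spearman_matrix(data.frame(cst = rep(1, n)), abil["radpai_2"]),
                 "constant column")
})

test_that("one-way ANOVA and Scheffe match hand-worked sums of squares", {
  vals <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- anova_scheffe(vals, grp)
  # hand computation: SSB = 42, SSW = 6, F = (42/2)/(6/6) = 21
  expect_equal(res$F, 21)
  expect_equal(res$df, c(2L, 6L))
  expect_equal(res$p_value, pf(21, 2, 6, lower.tail = FALSE))
  # Scheffe a vs c: (2-7)^2 / (1 * (1/3 + 1/3)) / 2 = 18.75
  expect_equal(res$scheffe["a", "c"], pf(18.75, 2, 6, lower.tail = FALSE))
  expect_equal(res$scheffe["a", "b"], pf(0.75, 2, 6, lower.tail = FALSE))

  # identical groups: F = 0, nothing significant
  same <- anova_scheffe(data.frame(g1 = 1:4, g2 = 1:4, g3 = 1:4))
  expect_equal(same$F, 0)
  expect_true(all(same$scheffe >= 0.999, na.rm = TRUE))

  # two groups: F equals the square of the pooled-variance t statistic
  x <- rnorm(10, 0); y <- rnorm(10, 1)
  res2 <- anova_scheffe(c(x, y), rep(c("x", "y"), each = 10))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-10)

  # a strongly shifted group has the smallest pairwise p
  sh <- anova_scheffe(data.frame(g1 = rnorm(20), g2 = rnorm(20),
                                 g3 = rnorm(20) + 30))
  expect_lt(max(sh$scheffe["g3", c("g1", "g2")]), min(sh$scheffe["g1", "g2"]))
  expect_error(anova_scheffe(1:3, c("a", "a", "b")), ">= 2")
})

test_that("paired t-test matches manual arithmetic and handles degeneracy", {
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  # 5-pair toy vs mean(d) / (sd(d)/sqrt(n))
  up <- c(2.0, 3.5, 1.0, 4.0, 2.5); lo <- c(1.0, 2.0, 0.5, 2.0, 2.0)
  d <- up - lo
  res <- paired_t(up, lo)
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(5)))
  expect_equal(res$mean_diff, mean(d))
  expect_equal(res$p_value, 2 * pt(-abs(res$t), 4))
  # consistent direction, tiny jitter: p << 0.001
  set.seed(9)
  lower <- rnorm(30); upper <- lower + 1 + rnorm(30, 0, 0.01)
  expect_lt(paired_t(upper, lower)$p_value, 1e-10)
  expect_error(paired_t(c(1, 2, 3), c(0, 1, 2)), "zero variance")
})

test_that("descriptives use the lower-logMAR better-eye convention", {
  one <- data.frame(age = 70, bcva_logmar_od = -0.04, bcva_logmar_os = 0.21,
                    md_od = -28, md_os = -15)
  d1 <- descriptives(one)
  expect_true(all(d1$sd == 0))                                  # single patient
  expect_equal(d1$mean[d1$variable == "BCVA in better eye (logMAR)"], -0.04)
  expect_equal(d1$mean[d1$variable == "MD of better eye (dB)"], -28)

  expect_identical(better_eye(0.2, 0.1), "OS")
  expect_identical(better_eye(0.1, 0.1, md_od = -10, md_os = -20), "OD")
  expect_identical(better_eye(0.1, 0.1, md_od = -25, md_os = -20), "OS")

  set.seed(11)
  many <- data.frame(age = rnorm(40, 65, 10),
                     bcva_logmar_od = rnorm(40, 0.1, 0.1),
                     bcva_logmar_os = rnorm(40, 0.1, 0.1),
                     md_od = rnorm(40, -20, 5), md_os = rnorm(40, -25, 5))
  dm <- descriptives(many)
  expect_equal(dm$mean[dm$variable == "age"], mean(many$age))
  expect_equal(dm$sd[dm$variable == "age"], sd(many$age))
  better <- pmin(many$bcva_logmar_od, many$bcva_logmar_os)
  expect_equal(dm$mean[dm$variable == "BCVA in better eye (logMAR)"],
               mean(better))
})
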